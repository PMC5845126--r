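# Conformers, alignment, direction check, scorer, group efficiency.

test_that("conformer ensembles are deterministic, bounded and low-strain", {
  flex <- parse_smiles("CCOC(=O)c1ccc(N)cc1")
  a <- generate_conformers(flex, k = 6L, seed = 42L)
  b <- generate_conformers(flex, k = 6L, seed = 42L)
  expect_identical(lapply(a, `[[`, "coords"), lapply(b, `[[`, "coords"))
  expect_lte(length(a), 6L)
  expect_gte(length(a), 2L)
  expect_length(generate_conformers(flex, k = 1L, seed = 1L), 1L)

  # rigid benzene: requesting many conformers returns one, and it is planar
  bz <- generate_conformers(parse_smiles("c1ccccc1"), k = 10L, seed = 1L)
  expect_length(bz, 1L)
  X <- bz[[1L]]$coords
  sv <- svd(sweep(X, 2L, colMeans(X)))$d
  expect_lt(sv[3L], 0.05)
  # bond lengths near the aromatic ideal
  d12 <- sqrt(sum((X[1L, ] - X[2L, ])^2))
  expect_equal(d12, 1.39, tolerance = 0.05)
})

test_that("alignment maximizes overlap and never distorts internal geometry", {
  m <- parse_smiles("NC(=O)c1ccc(O)cc1")
  cf <- generate_conformers(m, k = 1L, seed = 9L)[[1L]]
  fmatch <- match_substructure(parse_smiles("Oc1ccccc1"), m)[[1L]]
  frag <- preserved_fragment(parse_smiles("Oc1ccccc1"),
                             cf$coords[fmatch, , drop = FALSE])

  # already posed: overlap ~ 1
  al0 <- align_to_preserved(cf, frag)
  expect_gt(al0$overlap, 0.99)

  # translated 50 A away: transform restores the overlap
  far <- list(mol = m, coords = sweep(cf$coords, 2L, c(50, 0, 0)))
  al <- align_to_preserved(far, frag)
  expect_gt(al$overlap, 0.99)
  expect_lt(max(abs(stats::dist(al$coords) - stats::dist(cf$coords))), 1e-6)

  # single-atom fragment: translation alone gives full overlap
  one <- preserved_fragment(parse_smiles("O"), matrix(c(1, 2, 3), 1L))
  alo <- align_to_preserved(list(mol = parse_smiles("O"),
                                 coords = matrix(c(9, 9, 9), 1L)), one)
  expect_gt(alo$overlap, 0.999)

  expect_error(align_to_preserved(cf, preserved_fragment(
    parse_smiles("c1ccncc1"), matrix(0, 6L, 3L))),
    class = "rxngrow_format_error")
})

test_that("check_direction wants strict progress and a compatible atom", {
  mol <- parse_smiles("CCO")
  coords <- matrix(c(0, 0, 0, 1.5, 0, 0, 2.9, 0, 0), 3L, byrow = TRUE)
  tgt <- interaction_target("t", c(5, 0, 0), "hbond-donor", 3)
  aligned <- list(mol = mol, coords = coords)
  # O (donor-capable) at distance 2.1 < previous best 4 -> progress
  expect_true(check_direction(aligned, 3L, tgt, 4))
  # grown away: previous best already closer
  expect_false(check_direction(aligned, 3L, tgt, 1.5))
  # equal distance: strict inequality rejects
  expect_false(check_direction(aligned, 3L, tgt, 5 - 2.9))
  # nearest new atom incompatible with the target kind
  expect_false(check_direction(aligned, 2L, tgt, 10))  # carbon vs hbond-donor
  hydro <- interaction_target("h", c(5, 0, 0), "hydrophobic", 3)
  expect_false(check_direction(aligned, 3L, hydro, 10))  # O vs hydrophobic
})

test_that("score_pose matches its definition and the brute-force oracle", {
  # single ideal donor-acceptor pair at 3.0 A, nothing else
  mol <- parse_smiles("O")
  rec1 <- receptor(data.frame(element = "N", x = 3, y = 0, z = 0),
                   donors = 1L, acceptors = integer(0),
                   hydrophobic = integer(0))
  E <- score_pose(list(mol = mol, coords = matrix(0, 1L, 3L)), rec1)
  expect_equal(E, -1.0, tolerance = 1e-12)

  # ligand far from every receptor atom: E = 0
  E0 <- score_pose(list(mol = mol, coords = matrix(c(50, 0, 0), 1L)), rec1)
  expect_equal(E0, 0)

  expect_error(score_pose(list(mol = mol,
                               coords = matrix(NA_real_, 1L, 3L)), rec1),
               class = "rxngrow_format_error")

  # 20 random poses of a mid-size ligand vs the toy pocket's receptor:
  # vectorized scorer equals the O(n^2) double loop to 1e-9
  pk <- get_pocket()
  lig <- parse_smiles("CCOC(=O)c1ccc(NC(C)=O)cc1")
  cf <- generate_conformers(lig, k = 1L, seed = 4L)[[1L]]
  set.seed(99)
  for (i in 1:20) {
    X <- sweep(cf$coords, 2L, stats::rnorm(3, 0, 4), "+")
    pose <- list(mol = lig, coords = X)
    expect_equal(score_pose(pose, pk$receptor),
                 brute_force_score(pose, pk$receptor), tolerance = 1e-9)
  }
})

test_that("scorer is invariant under joint rigid motion and decays with distance", {
  pk <- get_pocket()
  lig <- parse_smiles("Oc1cc(Br)cc(N)c1")
  cf <- generate_conformers(lig, k = 1L, seed = 2L)[[1L]]
  pose <- list(mol = lig, coords = cf$coords)
  E <- score_pose(pose, pk$receptor)
  # rotate + translate ligand AND receptor together
  R <- rxngrow:::rot3(0.7, 2L); t <- c(3, -2, 5)
  move <- function(X) sweep(X %*% t(R), 2L, -t)
  rec2 <- pk$receptor
  rec2$atoms[, c("x", "y", "z")] <- move(rxngrow:::receptor_coords(pk$receptor))
  E2 <- score_pose(list(mol = lig, coords = move(cf$coords)), rec2)
  expect_equal(E, E2, tolerance = 1e-9)
  # ligand translated far out of the pocket: energy goes to zero
  E3 <- score_pose(list(mol = lig, coords = sweep(cf$coords, 2L, -c(100, 0, 0))),
                   pk$receptor)
  expect_equal(E3, 0)
})

test_that("group efficiency follows its formula with strict boundaries", {
  expect_equal(group_efficiency(-7.5, -5.0, 25L, 20L), -0.5)
  expect_equal(group_efficiency(-5.0, -5.0, 24L, 20L), 0)
  # GE of exactly -0.1 is rejected by the strict threshold
  expect_equal(group_efficiency(-5.4, -5.0, 24L, 20L), -0.1)
  expect_false(ge_acceptable(-0.1, grow_config()))
  expect_true(ge_acceptable(-0.1 - 1e-9, grow_config()))
  expect_error(group_efficiency(-6, -5, 20L, 20L),
               class = "rxngrow_format_error")
  # formula vs recomputation agreement to 1e-9
  e1 <- -3.210987654; e2 <- -4.87654321
  expect_equal(group_efficiency(e2, e1, 27L, 22L), (e2 - e1) / 5,
               tolerance = 1e-9)
})
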