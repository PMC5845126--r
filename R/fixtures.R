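# The synthetic fixture world: a curated atom-mapped reaction set, a toy
# building-block catalog, and a pseudo-receptor pocket with a planted
# best-scoring product reachable by a known 3-step route.  Everything is
# code-embedded text, so the whole pipeline is testable offline.

.FIXTURE_REACTIONS <- c(
  amide_aryl = paste0(
    "[CH3:1][C:2](=[O:3])[OH:4].[NH2:5][c:6]1[cH:7][cH:8][cH:9][cH:10][cH:11]1",
    ">>[CH3:1][C:2](=[O:3])[NH:5][c:6]1[cH:7][cH:8][cH:9][cH:10][cH:11]1.[OH2:4]"),
  amide_alkyl = paste0(
    "[CH3:1][C:2](=[O:3])[OH:4].[NH2:5][CH3:6]",
    ">>[CH3:1][C:2](=[O:3])[NH:5][CH3:6].[OH2:4]"),
  ester = paste0(
    "[CH3:1][C:2](=[O:3])[OH:4].[OH:5][CH2:6][CH3:7]",
    ">>[CH3:1][C:2](=[O:3])[O:5][CH2:6][CH3:7].[OH2:4]"),
  williamson_ether = paste0(
    "[OH:2][c:1]1[cH:7][cH:8][cH:9][cH:10][cH:11]1.[Br:3][CH2:4][CH3:5]",
    ">>[c:1]1([O:2][CH2:4][CH3:5])[cH:7][cH:8][cH:9][cH:10][cH:11]1.[Br-:3]"),
  sulfonamide = paste0(
    "[Cl:1][S:2](=[O:3])(=[O:4])[c:5]1[cH:6][cH:7][cH:8][cH:9][cH:10]1.",
    "[NH2:11][CH3:12]",
    ">>[CH3:12][NH:11][S:2](=[O:3])(=[O:4])",
    "[c:5]1[cH:6][cH:7][cH:8][cH:9][cH:10]1.[ClH:1]"),
  suzuki_coupling = paste0(
    "[Br:1][c:2]1[cH:3][cH:4][cH:5][cH:6][cH:7]1.",
    "[OH:8][B:9]([OH:10])[c:11]1[cH:12][cH:13][cH:14][cH:15][cH:16]1",
    ">>[c:2]1([c:11]2[cH:12][cH:13][cH:14][cH:15][cH:16]2)",
    "[cH:3][cH:4][cH:5][cH:6][cH:7]1.[OH:8][BH:9][OH:10]"),
  urea_formation = paste0(
    "[CH3:1][N:2]=[C:3]=[O:4].[NH2:5][CH3:6]",
    ">>[CH3:1][NH:2][C:3](=[O:4])[NH:5][CH3:6]"),
  snar_amination = paste0(
    "[F:1][c:2]1[cH:3][cH:4][c:5]([N+:6](=[O:7])[O-:8])[cH:9][cH:10]1.",
    "[NH2:11][CH3:12]",
    ">>[CH3:12][NH:11][c:2]1[cH:3][cH:4][c:5]([N+:6](=[O:7])[O-:8])",
    "[cH:9][cH:10]1.[FH:1]"),
  reductive_amination = paste0(
    "[CH3:1][C:2](=[O:3])[CH3:4].[NH2:5][CH3:6]",
    ">>[CH3:1][CH:2]([NH:5][CH3:6])[CH3:4].[OH2:3]")
)

.FIXTURE_BLOCKS <- c(
  # carboxylic acids (alkyl): amide/ester donors
  acid_acetic = "CC(=O)O", acid_propionic = "CCC(=O)O",
  acid_butyric = "CCCC(=O)O", acid_isobutyric = "CC(C)C(=O)O",
  acid_cyclopropane = "C1CC1C(=O)O", acid_cyclohexane = "C1CCCCC1C(=O)O",
  acid_phenylacetic = "OC(=O)Cc1ccccc1",
  # primary alkyl amines
  amine_methyl = "NC", amine_ethyl = "NCC", amine_propyl = "NCCC",
  amine_benzyl = "NCc1ccccc1", amine_isopropyl = "NC(C)C",
  # anilines
  aniline_h = "Nc1ccccc1", aniline_4me = "Nc1ccc(C)cc1",
  aniline_4ome = "Nc1ccc(OC)cc1", aniline_3cl = "Nc1cccc(Cl)c1",
  # primary alcohols
  alcohol_ethanol = "OCC", alcohol_propanol = "OCCC",
  alcohol_isopropanol = "OC(C)C", alcohol_benzyl = "OCc1ccccc1",
  # phenols
  phenol_h = "Oc1ccccc1", phenol_4me = "Oc1ccc(C)cc1",
  phenol_4cl = "Oc1ccc(Cl)cc1",
  # primary alkyl bromides
  bromide_ethyl = "CCBr", bromide_propyl = "CCCBr",
  bromide_butyl = "CCCCBr", bromide_isobutyl = "CC(C)CBr",
  bromide_methoxyethyl = "BrCCOC",
  # aryl sulfonyl chlorides
  sulfonyl_benzene = "O=S(=O)(Cl)c1ccccc1",
  sulfonyl_tosyl = "O=S(=O)(Cl)c1ccc(C)cc1",
  sulfonyl_4cl = "O=S(=O)(Cl)c1ccc(Cl)cc1",
  # aryl bromides
  arylbr_benzene = "Brc1ccccc1", arylbr_4me = "Brc1ccc(C)cc1",
  arylbr_4ome = "Brc1ccc(OC)cc1",
  # aryl boronic acids
  boronic_phenyl = "OB(O)c1ccccc1", boronic_4me = "OB(O)c1ccc(C)cc1",
  boronic_4et = "OB(O)c1ccc(CC)cc1",
  # isocyanates
  isocyanate_methyl = "CN=C=O", isocyanate_ethyl = "CCN=C=O",
  isocyanate_propyl = "CCCN=C=O",
  # ketones
  ketone_acetone = "CC(C)=O", ketone_butanone = "CCC(C)=O",
  ketone_cyclohexanone = "O=C1CCCCC1",
  # activated aryl fluorides
  arf_4no2 = "[O-][N+](=O)c1ccc(F)cc1", arf_2no2 = "[O-][N+](=O)c1ccccc1F",
  arf_h = "Fc1ccccc1",
  # the pocket seed: phenol + aniline + aryl-bromide handles, 1,3,5-pattern
  seed_trisub = "Oc1cc(Br)cc(N)c1",
  # inert decoys
  decoy_cyclohexane = "C1CCCCC1", decoy_toluene = "Cc1ccccc1",
  decoy_ether = "CCOCC", decoy_pyridine = "c1ccncc1",
  decoy_anisole = "COc1ccccc1"
)

#' Fixture reaction set
#'
#' Nine hand-curated atom-mapped reactions (amide coupling to alkyl and aryl
#' amines, ester formation, Williamson ether, sulfonamide formation, Suzuki
#' aryl-aryl coupling, urea formation, SNAr amination, reductive amination).
#' Fixed text; the seed argument exists for interface symmetry only.
#'
#' @param seed ignored (the set is deterministic text)
#' @return list of `mapped_reaction`
#' @export
make_reaction_set <- function(seed = 0L) {
  lapply(names(.FIXTURE_REACTIONS), function(nm)
    parse_reaction_smiles(.FIXTURE_REACTIONS[[nm]], name = nm))
}

#' Fixture building-block library
#'
#' About fifty blocks spanning every fixture reactant-moiety class (at least
#' three per class) plus inert decoys; deterministic text.
#'
#' @param seed ignored (the library is deterministic text)
#' @return list of `building_block`
#' @export
make_block_library <- function(seed = 0L) {
  lapply(names(.FIXTURE_BLOCKS), function(id)
    building_block(id, .FIXTURE_BLOCKS[[id]], provenance = "fixture"))
}

# pocket sub-library: one seed, three choices per planted-route slot (the
# planted participant is the largest of each class), two decoys
.POCKET_BLOCK_IDS <- c("seed_trisub",
                       "acid_acetic", "acid_propionic",
                       "boronic_phenyl", "boronic_4me",
                       "bromide_ethyl", "bromide_propyl",
                       "decoy_toluene", "decoy_cyclohexane")

# Design of the planted route: the planted participant is the largest member
# of its class in the pocket sub-library, so the planted product gains
# strictly more probe contacts than any competitor while staying inside the
# MW/cLogP filters.  The ether participants are pure alkyl bromides on
# purpose: their new atoms are all carbon, so an ether step can never
# satisfy the hydrogen-bond target and the route order (amide, biaryl,
# ether) is pinned by the targets' chemotypes.
.POCKET_PLANTED <- list(
  list(rule = "amide_aryl", participant = "acid_propionic"),
  list(rule = "suzuki_coupling", participant = "boronic_4me"),
  list(rule = "williamson_ether", participant = "bromide_propyl"))

#' Build the toy pocket with a planted optimum
#'
#' Constructs a pseudo-receptor cleft around the pose of a planted product:
#' the seed (a 1,3,5-trisubstituted phenol with aniline and aryl-bromide
#' handles) is grown by three planted steps (aryl amidation with butyric
#' acid, Suzuki coupling with 4-ethylphenylboronic acid, Williamson
#' etherification with 1-bromobutane); a hydrogen-bond donor probe is placed
#' against the new amide carbonyl and hydrophobic probes against the planted
#' chains and ring, giving three ordered interaction targets (hydrogen bond,
#' aromatic, hydrophobic).  When `verify` is TRUE every molecule reachable in
#' at most three steps from the seed is enumerated and scored, and generation
#' fails loudly unless the planted product's refined energy is the strict
#' minimum.
#'
#' @param seed integer; jitters the probe coordinates by up to 0.03 Angstrom
#'   so different pockets are distinguishable, without disturbing the planted
#'   optimum (the internal conformer seed is fixed)
#' @param n_conformers ensemble size used inside the pocket's recommended
#'   config (default 4, chosen for test-time tractability; the pipeline
#'   default elsewhere remains 30)
#' @param verify run the exhaustive uniqueness check (default TRUE)
#' @param cache optional conformer cache environment to reuse
#' @return a `toy_pocket`: list(receptor, targets, frag, seed_id, library,
#'   db, config, planted, verification, cache)
#' @export
make_pocket <- function(seed = 7L, n_conformers = 4L, verify = TRUE,
                        cache = new.env(parent = emptyenv())) {
  full <- make_block_library()
  ids <- vapply(full, `[[`, "", "id")
  library <- full[ids %in% .POCKET_BLOCK_IDS]
  db <- build_rule_db(make_reaction_set(), library)
  config <- grow_config(n_conformers = n_conformers, beam = 3L, seed = 2024L)

  seed_block <- library[[which(vapply(library, `[[`, "", "id") == "seed_trisub")]]
  seed_mol <- seed_block$mol
  seed_key <- canonical_key(seed_mol)
  confs <- cached_conformers(seed_mol, NULL, config, cache, key = seed_key)
  seed_coords <- confs[[1L]]$coords

  # the preserved fragment carries both the phenol O and the aniline N: a
  # bare phenol ring is mirror-symmetric, which would let the alignment flip
  # the ring and swap the growth directions; the O/N pair pins the frame
  frag_pattern <- parse_smiles("Oc1cccc(N)c1")
  fm <- match_substructure(frag_pattern, seed_mol)[[1L]]
  frag <- preserved_fragment(frag_pattern, seed_coords[fm, , drop = FALSE])

  # walk the planted chain to the final product (recording the route), then
  # place every probe from the FINAL product's aligned pose: probes derived
  # from intermediate poses can clash with, or miss, the final conformers
  state_mol <- seed_mol; state_coords <- seed_coords; state_key <- seed_key
  planted_steps <- list()
  for (k in seq_along(.POCKET_PLANTED)) {
    pl <- .POCKET_PLANTED[[k]]
    prods <- enumerate_products(state_mol, db, library, coords = state_coords,
                                reactant_id = state_key)
    hit <- Filter(function(p) p$rule_id == pl$rule &&
                    p$participant_id == pl$participant, prods)
    if (!length(hit))
      stop("fixture-generation error: planted step ", k, " not enumerable")
    pr <- hit[[1L]]
    pcfs <- cached_conformers(pr$product, NULL, config, cache, key = pr$key)
    al <- align_to_preserved(pcfs[[1L]], frag)
    planted_steps[[k]] <- list(rule = pr$rule_id,
                               participant = pr$participant_id,
                               reactant_key = state_key, product_key = pr$key)
    state_mol <- pr$product; state_coords <- al$coords; state_key <- pr$key
  }
  final_mol <- state_mol; X <- state_coords

  # partition the final molecule: seed ring + O (fragment), amide branch,
  # distal biaryl ring branch, alkoxy chain
  fm2 <- match_substructure(frag_pattern, final_mol)[[1L]]
  o_frag <- fm2[which(frag_pattern$atoms$element == "O")]
  n_root <- fm2[which(frag_pattern$atoms$element == "N")]
  ring1 <- setdiff(fm2, c(o_frag, n_root))
  adjf <- adjacency(final_mol)
  branch_from <- function(start, excl) {
    seen <- logical(n_atoms(final_mol)); seen[excl] <- TRUE
    queue <- start; seen[start] <- TRUE; out <- start
    while (length(queue)) {
      v <- queue[1L]; queue <- queue[-1L]
      for (w in adjf[[v]]) if (!seen[w]) {
        seen[w] <- TRUE; out <- c(out, w); queue <- c(queue, w)
      }
    }
    out
  }
  chain_set <- branch_from(setdiff(adjf[[o_frag]], ring1), c(ring1, o_frag))
  amide_set <- branch_from(n_root, ring1)
  ring2_root <- setdiff(unlist(adjf[ring1]),
                        c(ring1, o_frag, n_root,
                          unlist(adjf[c(o_frag, n_root)])))
  ring2_root <- ring2_root[final_mol$atoms$arom[ring2_root]][1L]
  ring2_set <- branch_from(ring2_root, ring1)

  set.seed(seed)
  jitter <- function(x) x + stats::runif(length(x), -0.03, 0.03)
  ctr <- colMeans(X)
  probes <- list()
  add_probe <- function(element, pos, role) {
    # reject placements that would clash with (or hug) the planted pose
    dmin <- min(sqrt(colSums((t(X) - pos)^2)))
    if (dmin < 3.2) return(invisible(FALSE))
    probes[[length(probes) + 1L]] <<- list(element = element,
                                           pos = jitter(pos), role = role)
    invisible(TRUE)
  }
  outward_probe <- function(i, dist = 3.9) {
    u0 <- X[i, ] - ctr; u0 <- u0 / max(sqrt(sum(u0^2)), 1e-6)
    # try the outward direction, then rotations about a perpendicular axis
    perp <- c(u0[2L], -u0[1L], 0)
    if (sum(perp^2) < 1e-6) perp <- c(1, 0, 0)
    perp <- perp / sqrt(sum(perp^2))
    for (ang in c(0, 35, -35, 70, -70) * pi / 180) {
      u <- u0 * cos(ang) + perp * sin(ang)
      if (add_probe("C", X[i, ] + u * dist, "hydrophobic")) return(invisible(TRUE))
    }
    invisible(FALSE)
  }

  # t1: hydrogen-bond donor against the amide carbonyl O + acyl-chain probes
  o_am <- amide_set[final_mol$atoms$element[amide_set] == "O"][1L]
  c_am <- adjf[[o_am]][1L]
  u <- X[o_am, ] - X[c_am, ]; u <- u / sqrt(sum(u^2))
  donor_pos <- X[o_am, ] + u * 2.9
  probes[[length(probes) + 1L]] <- list(element = "N", pos = jitter(donor_pos),
                                        role = "donor")
  term1 <- chain_terminus(final_mol, amide_set)
  outward_probe(term1$terminal)
  outward_probe(term1$penultimate)
  targets <- list(interaction_target("t1_hinge_hbond", jitter(donor_pos),
                                     "hbond-acceptor", satisfied_radius = 4))

  # t2: pi probes over the distal ring faces + probes at its para alkyl
  # chain; the anchor sits in-plane beyond the para position so that only
  # the new ring can strictly decrease the distance to it (an off-plane
  # anchor would already be near the first-step atoms)
  ringa <- ring2_set[final_mol$atoms$arom[ring2_set]]
  cen <- colMeans(X[ringa, , drop = FALSE])
  nrm <- ring_normal(X[ringa, , drop = FALSE])
  add_probe("C", cen + 3.6 * nrm, "hydrophobic")
  add_probe("C", cen - 3.6 * nrm, "hydrophobic")
  term2 <- chain_terminus(final_mol, ring2_set[!final_mol$atoms$arom[ring2_set]])
  outward_probe(term2$terminal)
  if (term2$penultimate != term2$terminal) outward_probe(term2$penultimate)
  ring1_cen <- colMeans(X[ring1, , drop = FALSE])
  u2 <- cen - ring1_cen; u2 <- u2 / sqrt(sum(u2^2))
  # kind "hydrophobic": the nearest new atom may be the ring's para alkyl
  # carbon rather than an aromatic carbon, and the pocket's contract is one
  # hydrogen-bond target plus two hydrophobic ones
  targets[[2L]] <- interaction_target("t2_aryl_pocket",
                                      jitter(cen + 4.0 * u2),
                                      "hydrophobic", satisfied_radius = 4.5)

  # t3: probes along the alkoxy chain
  term3 <- chain_terminus(final_mol, chain_set)
  carbons3 <- chain_set[final_mol$atoms$element[chain_set] == "C"]
  for (i in unique(c(term3$terminal, term3$penultimate,
                     carbons3[1L])))
    outward_probe(i)
  t3_anchor <- colMeans(X[carbons3, , drop = FALSE])
  targets[[3L]] <- interaction_target("t3_hydrophobic_channel",
                                      jitter(t3_anchor), "hydrophobic",
                                      satisfied_radius = 5)

  pos <- do.call(rbind, lapply(probes, `[[`, "pos"))
  role <- vapply(probes, `[[`, "", "role")
  atoms <- data.frame(element = vapply(probes, `[[`, "", "element"),
                      x = pos[, 1L], y = pos[, 2L], z = pos[, 3L],
                      resname = "UNK", resnum = seq_along(probes), chain = "A",
                      atom_name = toupper(vapply(probes, `[[`, "", "element")),
                      stringsAsFactors = FALSE)
  rec <- receptor(atoms, donors = which(role == "donor"),
                  acceptors = integer(0),
                  hydrophobic = which(role == "hydrophobic"))

  pocket <- structure(list(
    receptor = rec, targets = targets, frag = frag,
    seed_id = seed_block$id, library = library, db = db, config = config,
    planted = list(key = state_key,
                   smiles = write_smiles(state_mol, keep_maps = FALSE),
                   mol = state_mol, route = planted_steps),
    verification = NULL, cache = cache), class = "toy_pocket")

  if (verify) {
    tab <- enumerate_reachable(pocket, max_steps = 3L)
    pocket$verification <- tab
    best <- tab$key[which.min(tab$energy)]
    others <- tab$energy[tab$key != pocket$planted$key]
    if (best != pocket$planted$key ||
        min(others) <= tab$energy[tab$key == pocket$planted$key])
      stop("fixture-generation error: planted product is not the unique ",
           "refined-energy optimum of the reachable space")
  }
  pocket
}

#' @export
print.toy_pocket <- function(x, ...) {
  cat(sprintf(paste0("<toy_pocket: %d receptor atoms, %d targets, planted %s",
                     " via %d steps%s>\n"),
              nrow(x$receptor$atoms), length(x$targets), x$planted$smiles,
              length(x$planted$route),
              if (!is.null(x$verification))
                sprintf(", verified over %d molecules", nrow(x$verification))
              else ""))
  invisible(x)
}

# terminal atom of the longest chain within an atom set (and its neighbor)
chain_terminus <- function(mol, atoms) {
  adj <- adjacency(mol)
  deg_in <- vapply(atoms, function(v) sum(adj[[v]] %in% atoms), 0L)
  sp3 <- is_sp3_carbon(mol)
  term_cand <- atoms[deg_in <= 1L & sp3[atoms]]
  if (!length(term_cand)) term_cand <- atoms[deg_in <= 1L]
  gd <- graph_dist(adj, atoms[1L], n_atoms(mol))
  terminal <- term_cand[which.max(gd[term_cand])]
  pen <- intersect(adj[[terminal]], atoms)
  list(terminal = terminal,
       penultimate = if (length(pen)) pen[1L] else terminal)
}

ring_normal <- function(X) {
  Xc <- sweep(X, 2L, colMeans(X))
  svd(Xc)$v[, 3L]
}

#' Exhaustively enumerate and score molecules reachable from the pocket seed
#'
#' Breadth-first expansion over [enumerate_products()] (no direction or GE
#' gating), up to `max_steps` reaction steps; each distinct molecule is
#' scored by its best aligned conformer, refined with [refine_pose()].
#'
#' @param pocket a `toy_pocket`
#' @param max_steps depth bound (default 3)
#' @return data.frame(key, smiles, n_steps, energy)
#' @export
enumerate_reachable <- function(pocket, max_steps = 3L) {
  cfg <- pocket$config
  seed_mol <- pocket$library[[which(vapply(pocket$library, `[[`, "",
                                           "id") == pocket$seed_id)]]$mol
  eval_one <- function(mol, key) {
    confs <- cached_conformers(mol, NULL, cfg, pocket$cache, key = key)
    best <- Inf; bestX <- NULL
    for (cf in confs) {
      al <- align_to_preserved(cf, pocket$frag)
      E <- score_pose(al, pocket$receptor, cfg$weights)
      if (E < best) { best <- E; bestX <- al$coords }
    }
    refine_pose(mol, bestX, pocket$receptor, cfg)$energy
  }
  seen <- character(0)
  rows <- list()
  frontier <- list(list(mol = seed_mol, key = canonical_key(seed_mol),
                        depth = 0L))
  seen <- frontier[[1L]]$key
  rows[[1L]] <- data.frame(key = frontier[[1L]]$key,
                           smiles = write_smiles(seed_mol, keep_maps = FALSE),
                           n_steps = 0L,
                           energy = eval_one(seed_mol, frontier[[1L]]$key))
  while (length(frontier)) {
    nxt <- list()
    for (node in frontier) {
      if (node$depth >= max_steps) next
      prods <- enumerate_products(node$mol, pocket$db, pocket$library)
      for (pr in prods) {
        if (pr$key %in% seen) next
        if (!has_substructure(pocket$frag$pattern, pr$product)) next
        seen <- c(seen, pr$key)
        rows[[length(rows) + 1L]] <- data.frame(
          key = pr$key, smiles = write_smiles(pr$product, keep_maps = FALSE),
          n_steps = node$depth + 1L, energy = eval_one(pr$product, pr$key))
        nxt[[length(nxt) + 1L]] <- list(mol = pr$product, key = pr$key,
                                        depth = node$depth + 1L)
      }
    }
    frontier <- nxt
  }
  do.call(rbind, rows)
}

#' Write the fixture world to a directory
#'
#' Emits `reactions.smi` (mapped reaction SMILES, tab-separated names),
#' `blocks.smi` (SMILES, tab-separated ids), `pocket.json` (receptor +
#' targets + planted route) and `query.sdf` (the posed seed), so the CLI can
#' run fully self-contained.
#'
#' @param dir output directory (created if needed)
#' @param seed pocket seed, see [make_pocket()]
#' @param verify passed to [make_pocket()] (default FALSE here: file export
#'   does not need the exhaustive check)
#' @return the directory, invisibly
#' @export
write_fixture_files <- function(dir, seed = 7L, verify = FALSE) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writeLines(paste(unname(.FIXTURE_REACTIONS), names(.FIXTURE_REACTIONS),
                   sep = "\t"),
             file.path(dir, "reactions.smi"))
  writeLines(paste(unname(.FIXTURE_BLOCKS), names(.FIXTURE_BLOCKS), sep = "\t"),
             file.path(dir, "blocks.smi"))
  pocket <- make_pocket(seed = seed, verify = verify)
  seed_mol <- pocket$library[[which(vapply(pocket$library, `[[`, "",
                                           "id") == pocket$seed_id)]]$mol
  confs <- cached_conformers(seed_mol, NULL, pocket$config, pocket$cache,
                             key = canonical_key(seed_mol))
  write_sdf(list(list(mol = seed_mol, coords = confs[[1L]]$coords,
                      props = list(id = pocket$seed_id))),
            file.path(dir, "query.sdf"))
  jsonlite::write_json(list(
    receptor = list(atoms = pocket$receptor$atoms,
                    donors = pocket$receptor$donors,
                    acceptors = pocket$receptor$acceptors,
                    hydrophobic = pocket$receptor$hydrophobic),
    targets = lapply(pocket$targets, unclass),
    fragment = list(smiles = write_smiles(pocket$frag$pattern),
                    reference_coords = pocket$frag$reference_coords),
    seed_id = pocket$seed_id,
    pocket_blocks = .POCKET_BLOCK_IDS,
    planted = list(smiles = pocket$planted$smiles,
                   route = pocket$planted$route)),
    file.path(dir, "pocket.json"), auto_unbox = TRUE, digits = 8,
    pretty = TRUE)
  invisible(dir)
}
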