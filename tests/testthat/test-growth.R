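# Growth engine: filters, ranking/refinement, degenerate configs, routes.

test_that("property filter applies strict boundaries", {
  cfg <- grow_config()
  d <- function(mw, lp) list(molecular_weight = mw, heavy_atom_count = 10L,
                             clogp = lp)
  expect_true(passes_filters(d(599.5, 4.9), cfg))
  expect_false(passes_filters(d(600.0, 4.9), cfg))
  expect_false(passes_filters(d(599.5, 5.0), cfg))
  # filter_candidates drops a candidate over the MW limit end-to-end
  greasy <- parse_smiles(paste0("C", strrep("C", 45)))  # C46 chain, MW > 600
  small <- parse_smiles("CCO")
  fake <- function(mol) structure(list(mol = mol, coords = NULL, energy = 0,
                                       route = list(), seed_id = "s",
                                       key = canonical_key(mol)),
                                  class = "growth_candidate")
  kept <- filter_candidates(list(fake(greasy), fake(small)), cfg)
  expect_length(kept, 1L)
  expect_equal(kept[[1L]]$key, canonical_key(small))
})

test_that("degenerate configs behave as specified", {
  pk <- get_pocket()
  seeds <- find_seed_blocks(pk$frag, pk$library)

  # no targets: each seed returned unchanged with an empty route
  out <- grow(seeds, list(), pk$db, pk$library, pk$receptor, pk$frag,
              pk$config, cache = pk$cache)
  expect_length(out, length(seeds))
  expect_length(out[[1L]]$route, 0L)

  # ge_threshold = -Inf: no step is ever acceptable, seeds only
  cfg <- pk$config; cfg$ge_threshold <- -Inf
  out2 <- grow(seeds, pk$targets, pk$db, pk$library, pk$receptor, pk$frag,
               cfg, cache = pk$cache)
  expect_true(all(vapply(out2, function(s) length(s$route) == 0L, TRUE)))
})

test_that("rank_candidates refines without ever increasing energy and sorts", {
  pk <- get_pocket()
  cands <- get_pocket_grow()
  flt <- filter_candidates(cands, pk$config)
  before <- vapply(flt, `[[`, 0, "energy")
  rk <- rank_candidates(flt, pk$receptor, pk$config)
  after_by_key <- stats::setNames(vapply(rk, `[[`, 0, "energy"),
                                  vapply(rk, `[[`, "", "key"))
  for (i in seq_along(flt))
    expect_lte(after_by_key[[flt[[i]]$key]], before[i] + 1e-12)
  expect_equal(vapply(rk, `[[`, 0L, "rank"), seq_along(rk))
  expect_false(is.unsorted(vapply(rk, `[[`, 0, "energy")))
})

test_that("refine_pose is a descent method on arbitrary poses", {
  pk <- get_pocket()
  lig <- parse_smiles("CCOc1cc(Br)cc(NC(C)=O)c1")
  cf <- generate_conformers(lig, k = 3L, seed = 12L)
  for (c_ in cf) {
    E0 <- score_pose(list(mol = lig, coords = c_$coords), pk$receptor)
    ref <- refine_pose(lig, c_$coords, pk$receptor, pk$config)
    expect_lte(ref$energy, E0 + 1e-12)
    expect_equal(score_pose(list(mol = lig, coords = ref$coords), pk$receptor),
                 ref$energy, tolerance = 1e-9)
  }
})

test_that("route export, replay and JSON round trip", {
  pk <- get_pocket()
  cands <- get_pocket_grow()
  best <- cands[[which.min(vapply(cands, `[[`, 0, "energy"))]]
  rt <- export_route(best)
  expect_length(rt$steps, 3L)
  rebuilt <- replay_route(rt, pk$db, pk$library)
  expect_equal(canonical_key(rebuilt), best$key)

  # seed-only candidate: empty step list replays to the seed itself
  seeds <- find_seed_blocks(pk$frag, pk$library)
  s0 <- grow(seeds, list(), pk$db, pk$library, pk$receptor, pk$frag,
             pk$config, cache = pk$cache)[[1L]]
  rt0 <- export_route(s0)
  expect_length(rt0$steps, 0L)
  expect_equal(canonical_key(replay_route(rt0, pk$db, pk$library)), s0$key)

  path <- withr::local_tempfile(fileext = ".json")
  write_routes_json(list(rt, rt0), path)
  back <- read_routes_json(path)
  expect_length(back, 2L)
  expect_equal(back[[1L]]$final_key, rt$final_key)
  expect_equal(length(back[[1L]]$steps), 3L)
  rebuilt2 <- replay_route(back[[1L]], pk$db, pk$library)
  expect_equal(canonical_key(rebuilt2), best$key)
  # human-readable rendering mentions every step's rule
  txt <- format_route(rt)
  for (st in rt$steps) expect_true(any(grepl(st$rule, txt, fixed = TRUE)))
})

test_that("preserved fragment is a substructure of every emitted candidate", {
  pk <- get_pocket()
  for (cd in get_pocket_grow())
    expect_true(has_substructure(pk$frag$pattern, cd$mol))
})
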