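# The synthetic fixture world.

test_that("reaction set is map-consistent, sized and deterministic", {
  rxns <- make_reaction_set()
  expect_gte(length(rxns), 8L)
  for (r in rxns) expect_s3_class(r, "mapped_reaction")  # ctor checks maps
  expect_identical(vapply(make_reaction_set(), write_reaction_smiles, ""),
                   vapply(rxns, write_reaction_smiles, ""))
})

test_that("block library is valence-valid with >= 3 participants per slot", {
  lib <- make_block_library()
  expect_gte(length(lib), 45L)
  ids <- vapply(lib, `[[`, "", "id")
  expect_false(anyDuplicated(ids) > 0L)
  for (b in lib) expect_silent(validate_mol(b$mol))
  db <- build_rule_db(make_reaction_set(), lib)
  for (rule in db$rules)
    for (s in seq_along(rule$reactant_moieties))
      expect_gte(length(db$block_index[[rule$id]][[s]]), 3L)
  expect_identical(vapply(make_block_library(), function(b)
    write_smiles(b$mol), ""), vapply(lib, function(b) write_smiles(b$mol), ""))
})

test_that("pocket construction is verified, planted and seed-sensitive", {
  pk <- get_pocket()
  expect_s3_class(pk, "toy_pocket")
  expect_length(pk$targets, 3L)
  expect_length(pk$planted$route, 3L)
  expect_lte(nrow(pk$receptor$atoms), 150L)
  # the exhaustive table exists and planted is its strict optimum
  v <- pk$verification
  expect_gte(nrow(v), 20L)   # reduced space: well under the 200-molecule cap
  expect_lte(nrow(v), 200L)
  planted_e <- v$energy[v$key == pk$planted$key]
  expect_lt(planted_e, min(v$energy[v$key != pk$planted$key]))
  # planted compound passes the property filters
  d <- compute_descriptors(pk$planted$mol)
  expect_true(passes_filters(d, pk$config))
  # a different seed moves the probe coordinates
  pk2 <- make_pocket(seed = 8L, verify = FALSE, cache = pk$cache)
  expect_false(isTRUE(all.equal(pk2$receptor$atoms$x, pk$receptor$atoms$x)))
  expect_lt(max(abs(pk2$receptor$atoms$x - pk$receptor$atoms$x)), 0.1)
})

test_that("fixture files and the config-driven CLI pipeline run end to end", {
  dir <- withr::local_tempdir()
  write_fixture_files(dir, verify = FALSE)
  expect_true(all(file.exists(file.path(dir,
    c("reactions.smi", "blocks.smi", "pocket.json", "query.sdf")))))
  pj <- jsonlite::read_json(file.path(dir, "pocket.json"),
                            simplifyVector = TRUE, simplifyDataFrame = FALSE)
  # restrict the library file to the pocket blocks to keep the CLI run small
  lines <- readLines(file.path(dir, "blocks.smi"))
  keep <- vapply(strsplit(lines, "\t"), `[[`, "", 2L) %in%
    unlist(pj$pocket_blocks)
  writeLines(lines[keep], file.path(dir, "blocks_small.smi"))
  rec_json <- file.path(dir, "receptor.json")
  jsonlite::write_json(pj$receptor, rec_json, auto_unbox = TRUE, digits = 8)
  cfgfile <- file.path(dir, "config.json")
  jsonlite::write_json(list(
    reactions = file.path(dir, "reactions.smi"),
    blocks = file.path(dir, "blocks_small.smi"),
    receptor = rec_json,
    query = file.path(dir, "query.sdf"),
    fragment_smiles = pj$fragment$smiles,
    targets = pj$targets,
    out_dir = file.path(dir, "out"),
    n_conformers = 2L, beam = 1L, step_cap = 1L, seed = 11L),
    cfgfile, auto_unbox = TRUE, digits = 8)
  res <- suppressMessages(rxngrow_main(c("grow", cfgfile)))
  expect_true(file.exists(file.path(dir, "out", "candidates.sdf")))
  expect_true(file.exists(file.path(dir, "out", "routes.json")))
  routes <- read_routes_json(file.path(dir, "out", "routes.json"))
  expect_gte(length(routes), 1L)
  cands <- read_sdf(file.path(dir, "out", "candidates.sdf"))
  expect_equal(length(cands), length(routes))
})
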