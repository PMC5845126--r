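# Building-block library: seed search, slot participants, index completeness.

test_that("find_seed_blocks returns exactly the fragment-containing blocks", {
  lib <- list(building_block("hit", "NC(=O)c1ccc(OC)cc1"),
              building_block("miss", "C1CCCCC1"),
              building_block("small", "CC"))
  frag <- parse_smiles("NC(=O)c1ccccc1")
  seeds <- find_seed_blocks(frag, lib)
  expect_equal(vapply(seeds, `[[`, "", "id"), "hit")

  # single-carbon (sp3) fragment matches every aliphatic-carbon-bearing
  # block, smallest first
  seeds2 <- find_seed_blocks(parse_smiles("C"), lib)
  expect_equal(vapply(seeds2, `[[`, "", "id"), c("small", "miss", "hit"))

  # fragment larger than every block: empty
  expect_length(find_seed_blocks(parse_smiles("CCCCCCCCCCCC"), lib), 0L)
})

test_that("participants_for_slot returns the indexed, moiety-bearing blocks", {
  lib <- make_block_library()
  db <- build_rule_db(make_reaction_set(), lib)
  rule <- db$rules[[which(vapply(db$rules, `[[`, "", "id") == "amide_alkyl")]]
  amines <- participants_for_slot(rule, 2L, db, lib)
  ids <- vapply(amines, `[[`, "", "id")
  expect_true(all(startsWith(ids, "amine_")))
  expect_gte(length(ids), 3L)
  for (b in amines)
    expect_true(has_substructure(rule$reactant_moieties[[2]]$pattern, b$mol,
                                 open = rule$reactant_moieties[[2]]$open))
  expect_error(participants_for_slot("nonexistent_rule", 1L, db, lib),
               class = "rxngrow_format_error")
  expect_error(participants_for_slot(rule, 5L, db, lib),
               class = "rxngrow_format_error")
})

test_that("block index equals brute-force substructure filtering", {
  lib <- make_block_library()
  db <- build_rule_db(make_reaction_set(), lib)
  for (rule in db$rules) {
    for (s in seq_along(rule$reactant_moieties)) {
      mo <- rule$reactant_moieties[[s]]
      brute <- vapply(lib, function(b)
        length(naive_embeddings(mo$pattern, b$mol, open = mo$open)) > 0L,
        FALSE)
      expect_setequal(db$block_index[[rule$id]][[s]],
                      vapply(lib[brute], `[[`, "", "id"))
    }
  }
})

test_that("library files and the rule DB round-trip through disk", {
  dir <- withr::local_tempdir()
  write_fixture_files(dir, verify = FALSE)
  lib <- read_block_library(file.path(dir, "blocks.smi"))
  expect_equal(length(lib), length(make_block_library()))
  rxns <- read_reaction_file(file.path(dir, "reactions.smi"))
  expect_gte(length(rxns), 8L)
  db <- build_rule_db(rxns, lib)
  path <- file.path(dir, "rules.json")
  write_rule_db(db, path)
  db2 <- read_rule_db(path)
  expect_equal(vapply(db2$rules, `[[`, "", "id"),
               vapply(db$rules, `[[`, "", "id"))
  expect_equal(db2$block_index, db$block_index)
  pj <- jsonlite::read_json(file.path(dir, "pocket.json"),
                            simplifyVector = TRUE, simplifyDataFrame = FALSE)
  pj$receptor$atoms <- do.call(rbind, lapply(pj$receptor$atoms, as.data.frame))
  rec <- receptor(as.data.frame(pj$receptor$atoms),
                  donors = pj$receptor$donors,
                  acceptors = pj$receptor$acceptors,
                  hydrophobic = pj$receptor$hydrophobic)
  expect_s3_class(rec, "receptor")
  expect_equal(length(pj$targets), 3L)
  q <- read_sdf(file.path(dir, "query.sdf"))
  expect_true(mols_isomorphic(q[[1L]]$mol, parse_smiles("Oc1cc(Br)cc(N)c1")))
})
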