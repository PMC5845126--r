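# Clipping, product assembly, enumeration.

amide_rule <- function() build_rule(parse_reaction_smiles(paste0(
  "[CH3:1][C:2](=[O:3])[OH:4].[NH2:5][CH3:6]",
  ">>[CH3:1][C:2](=[O:3])[NH:5][CH3:6].[OH2:4]"), "amide"))

clip_at <- function(mol, moiety) {
  m <- match_substructure(moiety$pattern, mol, open = moiety$open)[[1L]]
  clip(mol, m, moiety)
}

test_that("clip records attachments and is lossless", {
  rule <- amide_rule()
  # acetic acid clipped at its own (whole-molecule) moiety: empty remainder
  ac <- parse_smiles("CC(=O)O")
  cl <- clip_at(ac, rule$reactant_moieties[[1]])
  expect_length(cl$remainder, 0L)
  expect_equal(nrow(cl$attach), 0L)

  # 4-methylbenzylamine clipped at the amine moiety (N + sp3 C): remainder is
  # the 4-methylphenyl fragment with one attachment bond
  bn <- parse_smiles("NCc1ccc(C)cc1")
  cl2 <- clip_at(bn, rule$reactant_moieties[[2]])
  expect_length(cl2$remainder, 7L)
  expect_equal(nrow(cl2$attach), 1L)
  # reassembly: remainder + moiety atoms account for the whole molecule
  expect_setequal(c(cl2$remainder, cl2$match), seq_len(n_atoms(bn)))

  expect_error(clip(ac, c(1L, 1L, 2L, 3L), rule$reactant_moieties[[1]]),
               class = "rxngrow_format_error")
})

test_that("assemble_product joins remainders through the correspondence", {
  rule <- amide_rule()
  prop <- parse_smiles("CCC(=O)O")
  bn <- parse_smiles("NCc1ccc(C)cc1")
  rec <- assemble_product(rule, list(clip_at(prop, rule$reactant_moieties[[1]]),
                                     clip_at(bn, rule$reactant_moieties[[2]])))
  expect_true(mols_isomorphic(rec$product,
                              parse_smiles("CCC(=O)NCc1ccc(C)cc1")))
  validate_mol(rec$product)

  # degenerate join: participant is exactly its moiety
  me <- parse_smiles("NC")
  rec2 <- assemble_product(rule, list(clip_at(prop, rule$reactant_moieties[[1]]),
                                      clip_at(me, rule$reactant_moieties[[2]])))
  expect_true(mols_isomorphic(rec2$product, parse_smiles("CCC(=O)NC")))

  expect_error(assemble_product(rule, list(clip_at(prop, rule$reactant_moieties[[1]]))),
               class = "rxngrow_format_error")
})

test_that("every fixture rule round-trips through its own source reactants", {
  for (rxn in make_reaction_set()) {
    rule <- build_rule(rxn)
    rec <- apply_rule_to_source(rule, rxn$reactants)
    expect_true(any(vapply(rxn$products, function(p)
      mols_isomorphic(rec$product, p), TRUE)),
      info = rxn$name)
  }
})

test_that("coordinate inheritance covers exactly the posed reactant's atoms", {
  rule <- amide_rule()
  prop <- parse_smiles("CCC(=O)O")
  me <- parse_smiles("NC")
  coords <- generate_conformers(prop, k = 1L, seed = 3L)[[1L]]$coords
  rec <- assemble_product(rule,
                          list(clip_at(prop, rule$reactant_moieties[[1]]),
                               clip_at(me, rule$reactant_moieties[[2]])),
                          coords = coords, posed_slot = 1L)
  inh <- which(stats::complete.cases(rec$inherited_coords))
  expect_setequal(seq_len(n_atoms(rec$product)), c(inh, rec$new_atoms))
  # inherited = acid atoms minus the leaving OH: C,C,C,O(carbonyl) = 4
  expect_length(inh, 4L)
  # inherited coordinates are copied verbatim from the pose
  for (i in inh) {
    d <- sqrt(rowSums(sweep(coords, 2L, rec$inherited_coords[i, ])^2))
    expect_lt(min(d), 1e-12)
  }
})

test_that("enumerate_products expands, deduplicates and orders deterministically", {
  lib <- make_block_library()
  db <- build_rule_db(make_reaction_set(), lib)

  # no rule matches cyclohexane
  expect_length(enumerate_products(parse_smiles("C1CCCCC1"), db, lib), 0L)

  # acetic acid: brute-force expectation over (rule, slot, participant)
  ac <- parse_smiles("CC(=O)O")
  prods <- enumerate_products(ac, db, lib)
  expect_gt(length(prods), 0L)
  keys <- vapply(prods, `[[`, "", "key")
  expect_false(anyDuplicated(keys) > 0L)
  # acid matches amide_aryl, amide_alkyl and ester acid slots; expected
  # product count = union of per-slot participants after dedup
  expected <- 0L
  seen <- character(0)
  for (rid in c("amide_aryl", "amide_alkyl", "ester")) {
    rule <- db$rules[[which(vapply(db$rules, `[[`, "", "id") == rid)]]
    for (b in participants_for_slot(rule, 2L, db, lib)) {
      rec <- assemble_product(rule,
        list(clip_at(ac, rule$reactant_moieties[[1]]),
             clip_at(b$mol, rule$reactant_moieties[[2]])))
      k <- canonical_key(rec$product)
      if (!k %in% seen) { seen <- c(seen, k); expected <- expected + 1L }
    }
  }
  expect_equal(length(prods), expected)
  # deterministic order: (rule id, participant id) as produced twice
  prods2 <- enumerate_products(ac, db, lib)
  expect_identical(lapply(prods, `[[`, "key"), lapply(prods2, `[[`, "key"))

  # symmetric duplicate products collapse: succinic acid + one amine gives
  # one record per (rule, participant) despite two equivalent COOH matches
  succ <- parse_smiles("OC(=O)CCC(=O)O")
  sp <- enumerate_products(succ, db, lib)
  amide_me <- Filter(function(p) p$rule_id == "amide_alkyl" &&
                       p$participant_id == "amine_methyl", sp)
  expect_length(amide_me, 1L)
})
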