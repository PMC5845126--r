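# Reaction-core identification, moiety extension, rule building, matching.

amide_rxn <- function() parse_reaction_smiles(paste0(
  "[CH3:1][C:2](=[O:3])[OH:4].[NH2:5][CH3:6]",
  ">>[CH3:1][C:2](=[O:3])[NH:5][CH3:6].[OH2:4]"), "amide")

test_that("identify_reaction_core flags exactly the transformed atoms", {
  rxn <- amide_rxn()
  core <- identify_reaction_core(rxn)
  # reactant side: C2 and O4 of the acid, N5 of the amine (maps 2, 4, 5)
  expect_setequal(rxn$reactants[[1]]$atoms$map[core$reactants[[1]]], c(2L, 4L))
  expect_setequal(rxn$reactants[[2]]$atoms$map[core$reactants[[2]]], 5L)

  # identity reaction: empty core everywhere
  ident <- parse_reaction_smiles("[CH3:1][OH:2]>>[CH3:1][OH:2]", "id")
  expect_true(all(lengths(identify_reaction_core(ident)$reactants) == 0L))

  # Williamson on heavy atoms: core = {O2} + {Br3, C4}
  w <- parse_reaction_smiles(paste0(
    "[OH:2][c:1]1[cH:7][cH:8][cH:9][cH:10][cH:11]1.[Br:3][CH2:4][CH3:5]",
    ">>[c:1]1([O:2][CH2:4][CH3:5])[cH:7][cH:8][cH:9][cH:10][cH:11]1.[Br-:3]"),
    "ether")
  wc <- identify_reaction_core(w)
  expect_setequal(w$reactants[[1]]$atoms$map[wc$reactants[[1]]], 2L)
  expect_setequal(w$reactants[[2]]$atoms$map[wc$reactants[[2]]], c(3L, 4L))

  # inconsistent mapping: same map twice on one side, or an orphan product map
  expect_error(mapped_reaction(list(parse_smiles("[CH4:1]"),
                                    parse_smiles("[OH2:1]")),
                               list(parse_smiles("[CH3:1][OH:2]"))),
               class = "rxngrow_format_error")
  expect_error(mapped_reaction(list(parse_smiles("C")),
                               list(parse_smiles("[CH4:1]"))),
               class = "rxngrow_format_error")
})

test_that("moiety extension applies the sp3-stop and whole-ring rules", {
  rxn <- amide_rxn()
  mo <- extend_to_moieties(rxn)
  # acetic acid: extension from C2 stops at (and includes) sp3 C1
  expect_equal(sort(mo$reactants[[1]]$atoms), 1:4)
  # methylamine: N5 plus its sp3 stop carbon
  expect_equal(sort(mo$reactants[[2]]$atoms), 1:2)

  # benzoic amidation: the whole benzene ring joins the acid moiety
  b <- parse_reaction_smiles(paste0(
    "[OH:4][C:2](=[O:3])[c:10]1[cH:11][cH:12][cH:13][cH:14][cH:15]1.",
    "[NH2:5][CH3:6]>>[CH3:6][NH:5][C:2](=[O:3])",
    "[c:10]1[cH:11][cH:12][cH:13][cH:14][cH:15]1.[OH2:4]"), "benzamide")
  bm <- extend_to_moieties(b)
  expect_equal(n_atoms(bm$reactants[[1]]$pattern), 9L)  # COOH + 6-ring
  expect_true(all(b$reactants[[1]]$atoms$arom[bm$reactants[[1]]$atoms][4:9]))

  # a core atom with no neighbors outside the core: moiety equals the core
  iso <- parse_reaction_smiles("[CH4:1].[OH2:2]>>[CH3:1][OH:2]", "toy")
  mi <- extend_to_moieties(iso)
  expect_equal(mi$reactants[[1]]$atoms, 1L)
})

test_that("build_rule assembles a correspondence and rejects empty rules", {
  rule <- build_rule(amide_rxn(), "amide")
  expect_length(rule$reactant_moieties, 2L)
  expect_equal(nrow(rule$correspondence), 5L)  # all 5 product atoms paired
  expect_length(rule$introduced, 0L)
  expect_false(anyDuplicated(rule$correspondence$p_atom) > 0L)

  ident <- parse_reaction_smiles("[CH3:1][OH:2]>>[CH3:1][OH:2]", "id")
  expect_error(build_rule(ident), class = "rxngrow_chemistry_error")
})

test_that("fixture rules satisfy the moiety boundary law and core containment", {
  for (rxn in make_reaction_set()) {
    core <- identify_reaction_core(rxn)
    mo <- extend_to_moieties(rxn, core)
    sides <- list(list(rxn$reactants, core$reactants, mo$reactants),
                  list(rxn$products, core$products, mo$products))
    for (side in sides) {
      for (i in seq_along(side[[1]])) {
        m <- side[[3]][[i]]
        if (is.null(m)) next
        mol <- side[[1]][[i]]
        # core is contained in the moiety
        expect_true(all(side[[2]][[i]] %in% m$atoms))
        # every attachment atom is sp3 carbon or in a fully-included aromatic ring
        for (pa in m$attachment) {
          src <- m$atoms[pa]
          ok <- rxngrow:::is_sp3_carbon(mol, src) ||
            (mol$atoms$arom[src] && aromatic_ring_included(mol, src, m$atoms))
          expect_true(ok)
        }
      }
    }
  }
})

test_that("match_rules agrees with the naive embedding enumerator (<= 12 atoms)", {
  db <- build_rule_db(make_reaction_set())
  probes <- lapply(c("CC(=O)O", "CCC(=O)O", "NCC", "Nc1ccc(C)cc1",
                     "OCC", "Oc1ccc(Cl)cc1", "CCBr", "OC(=O)CCC(=O)O",
                     "C1CCCCC1", "CC(C)=O"), parse_smiles)
  for (mol in probes) {
    hits <- match_rules(mol, db)
    for (ri in seq_along(db$rules)) {
      rule <- db$rules[[ri]]
      for (s in seq_along(rule$reactant_moieties)) {
        mo <- rule$reactant_moieties[[s]]
        got <- Filter(function(h) h$rule == ri && h$slot == s, hits)
        want <- naive_embeddings(mo$pattern, mol, open = mo$open)
        expect_equal(length(got), length(want),
                     info = sprintf("%s slot %d vs %s", rule$id, s,
                                    write_smiles(mol)))
        # every returned match is a genuine embedding found by the oracle
        for (h in got) {
          expect_true(any(vapply(want, function(w)
            identical(sort(w), sort(h$match)), TRUE)))
        }
      }
    }
  }
  # succinic acid: two distinct acid-moiety matches
  succ <- parse_smiles("OC(=O)CCC(=O)O")
  acid_hits <- Filter(function(h) db$rules[[h$rule]]$id == "amide_alkyl" &&
                        h$slot == 1L, match_rules(succ, db))
  expect_length(acid_hits, 2L)
})
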