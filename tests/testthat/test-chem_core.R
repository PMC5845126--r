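# Molecular-graph core: parsing, descriptors, canonical keys, file formats.

test_that("parse_molecule handles SMILES, maps and valence errors", {
  m <- parse_molecule("CCO")
  expect_s3_class(m, "mol_graph")
  expect_equal(n_atoms(m), 3L)
  expect_true(all(m$atoms$map == 0L))

  mm <- parse_molecule("[CH3:1][OH:2]")
  expect_equal(n_atoms(mm), 2L)
  expect_setequal(mm$atoms$map, c(1L, 2L))
  expect_equal(mm$atoms$hcount, c(3L, 1L))

  expect_error(parse_molecule("C(C)(C)(C)(C)C"),
               class = "rxngrow_chemistry_error")
  expect_error(parse_smiles("C1CC"), class = "rxngrow_format_error")
  expect_error(parse_smiles("CCO.CC"), class = "rxngrow_format_error")
})

test_that("aromatic perception is spelling-invariant and kekulization sane", {
  a <- parse_smiles("c1ccccc1")
  b <- parse_smiles("C1=CC=CC=C1")
  expect_true(all(a$atoms$arom))
  expect_true(all(b$atoms$arom))
  expect_equal(canonical_key(a), canonical_key(b))
  expect_equal(sort(table(a$bonds$order)), sort(table(b$bonds$order)))
  # pyrrole N keeps its H; pyridine N has none; cyclohexane is not aromatic
  expect_equal(parse_smiles("c1cc[nH]c1")$atoms$hcount[4], 1L)
  expect_equal(parse_smiles("c1ccncc1")$atoms$hcount[4], 0L)
  expect_false(any(parse_smiles("C1CCCCC1")$atoms$arom))
})

test_that("descriptors match hand-derived values", {
  # benzene MW by direct summation of standard atomic weights
  benz <- parse_smiles("c1ccccc1")
  expect_equal(compute_descriptors(benz)$molecular_weight,
               6 * 12.011 + 6 * 1.008, tolerance = 1e-9)
  expect_equal(compute_descriptors(parse_smiles("CCO"))$heavy_atom_count, 3L)
  # longer alkyl chain is more lipophilic under any atom-contribution scheme
  expect_gt(clogp(parse_smiles("CCCCCCO")), clogp(parse_smiles("CCO")))
})

test_that("MW and heavy atoms agree with brute-force summation on fixtures", {
  w <- c(H = 1.008, B = 10.81, C = 12.011, N = 14.007, O = 15.999,
         F = 18.998, S = 32.06, Cl = 35.45, Br = 79.904)
  for (m in fixture_mols()) {
    expect_equal(molecular_weight(m),
                 sum(w[m$atoms$element]) + sum(m$atoms$hcount) * w[["H"]],
                 tolerance = 1e-9)
    expect_equal(heavy_atom_count(m), nrow(m$atoms))
  }
})

test_that("canonical_key separates isomers and ignores atom order", {
  expect_equal(canonical_key(parse_smiles("OCC")),
               canonical_key(parse_smiles("CCO")))
  expect_false(canonical_key(parse_smiles("CCO")) ==
                 canonical_key(parse_smiles("COC")))
  set.seed(11)
  for (m in fixture_mols()) {
    p <- sample(n_atoms(m))
    pm <- permute_mol(m, p)
    expect_equal(canonical_key(pm), canonical_key(m))
    expect_true(mols_isomorphic(m, pm))
  }
})

test_that("SMILES and MOL round trips are graph-isomorphic on all fixtures", {
  for (m in fixture_mols()) {
    expect_true(mols_isomorphic(parse_smiles(write_smiles(m)), m))
    rec <- parse_molblock(write_molblock(m))
    expect_true(mols_isomorphic(rec$mol, m))
  }
  # atom maps survive a SMILES round trip
  mm <- parse_smiles("[CH3:7][C:2](=O)[OH:4]")
  expect_setequal(parse_smiles(write_smiles(mm))$atoms$map, c(7L, 2L, 0L, 4L))
})

test_that("SDF read/write preserves molecules, coordinates and properties", {
  m <- parse_smiles("CC(=O)Nc1ccccc1")
  cf <- generate_conformers(m, k = 1L, seed = 5L)[[1L]]
  path <- withr::local_tempfile(fileext = ".sdf")
  write_sdf(list(list(mol = m, coords = cf$coords,
                      props = list(id = "x1", energy = "-1.25"))), path)
  rec <- read_sdf(path)
  expect_length(rec, 1L)
  expect_true(mols_isomorphic(rec[[1L]]$mol, m))
  expect_equal(rec[[1L]]$coords, cf$coords, tolerance = 1e-3)
  expect_equal(rec[[1L]]$props$id, "x1")
})

test_that("PDB reader extracts typed heavy atoms", {
  lines <- c(
    "ATOM      1  N   ALA A 905      10.000   2.000   3.000  1.00  0.00           N",
    "ATOM      2  O   ALA A 905      11.500   2.500   3.200  1.00  0.00           O",
    "ATOM      3  CB  LEU A 906      12.000   4.000   1.000  1.00  0.00           C",
    "HETATM    4  O   HOH A 999      20.000  20.000  20.000  1.00  0.00           O")
  path <- withr::local_tempfile(fileext = ".pdb")
  writeLines(lines, path)
  rec <- read_pdb(path)
  expect_equal(nrow(rec$atoms), 3L)   # water dropped
  expect_equal(rec$atoms$resnum, c(905L, 905L, 906L))
  expect_true(1L %in% rec$donors)      # backbone N
  expect_true(2L %in% rec$acceptors)   # backbone O
  expect_true(3L %in% rec$hydrophobic) # Leu side-chain carbon
})
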