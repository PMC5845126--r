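# Shared fixtures and independent oracles for the suite.
#
# The toy pocket is expensive (it verifies a planted optimum by exhaustive
# enumeration), so it is built once per test run and memoized here; its
# conformer cache is reused by every growth call.

.world <- new.env(parent = emptyenv())

get_pocket <- function() {
  if (is.null(.world$pocket)) .world$pocket <- make_pocket(verify = TRUE)
  .world$pocket
}

get_pocket_grow <- function() {
  if (is.null(.world$grow)) {
    pk <- get_pocket()
    seeds <- find_seed_blocks(pk$frag, pk$library)
    .world$grow <- grow(seeds, pk$targets, pk$db, pk$library, pk$receptor,
                        pk$frag, pk$config, cache = pk$cache)
  }
  .world$grow
}

# twenty structurally varied molecules used by round-trip/descriptor tests
FIXTURE_SMILES <- c(
  "C", "CCO", "CC(=O)O", "c1ccccc1", "Cc1ccccc1", "c1ccncc1",
  "CC(=O)Oc1ccccc1C(=O)O", "NC(=O)c1ccc(O)cc1", "C1CCCCC1", "CC(C)CBr",
  "O=S(=O)(Cl)c1ccc(C)cc1", "OB(O)c1ccccc1", "CN=C=O", "C#N",
  "[O-][N+](=O)c1ccc(F)cc1", "c1ccc2ccccc2c1", "CC(=O)NC1CC1",
  "CCOC(=O)c1cccc(N)c1", "Oc1cc(Br)cc(N)c1", "C[N+](C)(C)C"
)

fixture_mols <- function() lapply(FIXTURE_SMILES, parse_smiles)

# apply a random atom permutation: new index of old atom i is p[i]
permute_mol <- function(mol, p) {
  inv <- order(p)
  at <- mol$atoms[inv, , drop = FALSE]
  rownames(at) <- NULL
  bd <- mol$bonds
  bd$a <- p[mol$bonds$a]
  bd$b <- p[mol$bonds$b]
  mol_graph(at, bd, name = mol$name, validate = FALSE)
}

# brute-force subgraph monomorphism enumerator over all injections; the
# independent oracle for match_substructure on small graphs (<= 12 atoms)
naive_embeddings <- function(pattern, target, open = "all") {
  np <- n_atoms(pattern); nt <- n_atoms(target)
  if (np > nt) return(list())
  open_idx <- if (identical(open, "all")) seq_len(np) else as.integer(open)
  p_deg <- rxngrow:::degrees(pattern); t_deg <- rxngrow:::degrees(target)
  p_sp3 <- rxngrow:::is_sp3_carbon(pattern)
  t_sp3 <- rxngrow:::is_sp3_carbon(target)
  p_b <- pattern$bonds; t_key <- paste(pmin(target$bonds$a, target$bonds$b),
                                       pmax(target$bonds$a, target$bonds$b))
  ok_atom <- function(pi, ti) {
    pa <- pattern$atoms[pi, ]; ta <- target$atoms[ti, ]
    if (pa$element != ta$element || pa$arom != ta$arom ||
        pa$charge != ta$charge) return(FALSE)
    if (pi %in% open_idx)
      return(t_deg[ti] >= p_deg[pi] && (!p_sp3[pi] || t_sp3[ti]))
    t_deg[ti] == p_deg[pi] && ta$hcount == pa$hcount
  }
  out <- list(); seen <- character(0)
  rec <- function(m) {
    k <- length(m) + 1L
    if (k > np) {
      for (i in seq_len(nrow(p_b))) {
        a <- m[p_b$a[i]]; b <- m[p_b$b[i]]
        j <- match(paste(min(a, b), max(a, b)), t_key)
        if (is.na(j)) return()
        if (p_b$arom[i] != target$bonds$arom[j]) return()
        if (!p_b$arom[i] && p_b$order[i] != target$bonds$order[j]) return()
      }
      key <- paste(sort(m), collapse = ",")
      if (!key %in% seen) { seen <<- c(seen, key); out[[length(out) + 1L]] <<- m }
      return()
    }
    for (ti in setdiff(seq_len(nt), m))
      if (ok_atom(k, ti)) rec(c(m, ti))
  }
  rec(integer(0))
  out
}

# is `atom` inside an aromatic ring whose atoms are all in `included`?
aromatic_ring_included <- function(mol, atom, included) {
  rings <- rxngrow:::find_rings(mol)
  rings <- Filter(function(r) all(mol$atoms$arom[r]) && atom %in% r, rings)
  length(rings) > 0L &&
    all(vapply(rings, function(r) all(r %in% included), TRUE))
}

# O(n^2) double-loop scorer; the independent oracle for score_pose
brute_force_score <- function(aligned, rec, weights = default_score_weights()) {
  X <- aligned$coords; mol <- aligned$mol
  R <- rxngrow:::receptor_coords(rec)
  el <- mol$atoms$element
  don <- el %in% c("N", "O") & mol$atoms$hcount > 0L
  acc <- el %in% c("N", "O")
  hb <- function(d) {
    if (d < 2.2) 0 else if (d < 2.6) -(d - 2.2) / 0.4 else if (d <= 3.2) -1
    else if (d < 4.0) -(4.0 - d) / 0.8 else 0
  }
  ph <- function(d) if (d <= 4.5) -1 else if (d < 5.5) -(5.5 - d) else 0
  E <- 0
  for (i in seq_len(nrow(X))) for (j in seq_len(nrow(R))) {
    d <- sqrt(sum((X[i, ] - R[j, ])^2))
    if (don[i] && j %in% rec$acceptors) E <- E + weights$w_hb * hb(d)
    if (acc[i] && j %in% rec$donors) E <- E + weights$w_hb * hb(d)
    if (el[i] == "C" && j %in% rec$hydrophobic) E <- E + weights$w_ph * ph(d)
    if (d < 0.8 * (rxngrow:::vdw_radius(el[i]) +
                     rxngrow:::vdw_radius(rec$atoms$element[j])))
      E <- E + weights$w_cl * weights$clash_penalty
  }
  E
}
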