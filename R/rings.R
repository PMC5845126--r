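# Ring perception, aromaticity perception and kekulization.
#
# The aromaticity model is deliberately small and pinned: candidate rings are
# the smallest rings (one per cyclic bond), sizes 5 and 6 only, atoms drawn
# from {B,C,N,O,P,S}.  Pi contributions: an atom double-bonded to another
# ring-member atom contributes 1; a neutral N/O/S/P (or negatively charged C)
# with only single bonds contributes a lone pair (2); an atom with an
# exocyclic double bond to a non-ring atom contributes 0; anything else makes
# the ring non-aromatic.  A ring is aromatic when the contributions are
# defined for all members and sum to 4n+2.  Patterns and molecules always go
# through this same perception, so matching semantics are consistent.

#' Smallest ring through each cyclic bond
#'
#' @return list of integer vectors (atom indices ordered around the ring),
#'   de-duplicated by atom set.
#' @noRd
find_rings <- function(mol) {
  nb <- nrow(mol$bonds)
  if (!nb) return(list())
  adj <- adjacency(mol)
  n <- n_atoms(mol)
  rings <- list(); seen <- character(0)
  for (i in seq_len(nb)) {
    a <- mol$bonds$a[i]; b <- mol$bonds$b[i]
    # BFS shortest path a..b avoiding the direct edge
    prev <- rep.int(0L, n); prev[a] <- -1L
    queue <- a; found <- FALSE
    while (length(queue) && !found) {
      v <- queue[1L]; queue <- queue[-1L]
      for (w in adj[[v]]) {
        if (v == a && w == b) next
        if (prev[w] == 0L) {
          prev[w] <- v
          if (w == b) { found <- TRUE; break }
          queue <- c(queue, w)
        }
      }
    }
    if (!found) next  # bridge bond, not in a ring
    path <- b
    v <- b
    while (prev[v] != -1L) { v <- prev[v]; path <- c(path, v) }
    key <- paste(sort(path), collapse = ",")
    if (!key %in% seen) { seen <- c(seen, key); rings[[length(rings) + 1L]] <- rev(path) }
  }
  rings
}

#' Atom indices that sit in any ring
#' @noRd
ring_membership <- function(mol, rings = find_rings(mol)) {
  mem <- logical(n_atoms(mol))
  for (r in rings) mem[r] <- TRUE
  mem
}

#' Perceive aromaticity on a kekulized molecule (in place)
#'
#' Sets `atoms$arom` and `bonds$arom` for rings passing the pinned model.
#' Already-flagged aromatic atoms/bonds (from lowercase SMILES input) are kept.
#' @noRd
perceive_aromaticity <- function(mol) {
  rings <- find_rings(mol)
  if (!length(rings)) return(mol)
  in_ring <- ring_membership(mol, rings)
  bidx <- bond_index(mol)
  # per-atom: does it have a double bond, and to whom
  dbl_partner <- replicate(n_atoms(mol), integer(0), simplify = FALSE)
  if (nrow(mol$bonds)) {
    for (i in which(mol$bonds$order == 2L)) {
      a <- mol$bonds$a[i]; b <- mol$bonds$b[i]
      dbl_partner[[a]] <- c(dbl_partner[[a]], b)
      dbl_partner[[b]] <- c(dbl_partner[[b]], a)
    }
  }
  for (r in rings) {
    if (!length(r) %in% c(5L, 6L)) next
    pi_total <- 0L; ok <- TRUE
    for (v in r) {
      el <- mol$atoms$element[v]
      if (!el %in% .AROMATIC_ELEMENTS) { ok <- FALSE; break }
      dp <- dbl_partner[[v]]
      if (length(dp)) {
        # double bond into the ring system counts 1; exocyclic =X counts 0
        pi_total <- pi_total + if (any(in_ring[dp])) 1L else 0L
      } else if (el %in% c("N", "O", "S", "P") && mol$atoms$charge[v] >= 0L) {
        pi_total <- pi_total + 2L
      } else if (el == "C" && mol$atoms$charge[v] == -1L) {
        pi_total <- pi_total + 2L
      } else { ok <- FALSE; break }
    }
    if (!ok || pi_total %% 4L != 2L) next
    mol$atoms$arom[r] <- TRUE
    rc <- c(r, r[1L])
    for (k in seq_along(r)) {
      bi <- bidx[[paste(min(rc[k], rc[k + 1L]), max(rc[k], rc[k + 1L]))]]
      mol$bonds$arom[bi] <- TRUE
    }
  }
  mol
}

#' Kekulize aromatic systems that lack explicit bond orders
#'
#' Atoms flagged aromatic whose sigma framework leaves one valence unit open
#' must each receive exactly one double bond along an aromatic bond; this is a
#' perfect matching on those atoms, found by backtracking (systems are small).
#'
#' @param mol molecule whose aromatic bonds still have order 1
#' @param needs logical per atom: must gain a double bond
#' @return mol with kekulized orders, or error `rxngrow_chemistry_error`
#' @noRd
kekulize_aromatic <- function(mol, needs) {
  arom_b <- which(mol$bonds$arom)
  if (!length(arom_b) || !any(needs)) return(mol)
  want <- which(needs)
  # candidate edges between two atoms that both need a double bond
  edges <- arom_b[mol$bonds$a[arom_b] %in% want & mol$bonds$b[arom_b] %in% want]
  matched <- rep.int(FALSE, n_atoms(mol))
  chosen <- integer(0)
  solve <- function(remaining, chosen) {
    open <- want[!matched[want]]
    if (!length(open)) return(chosen)
    v <- open[1L]
    cand <- remaining[mol$bonds$a[remaining] == v | mol$bonds$b[remaining] == v]
    for (e in cand) {
      a <- mol$bonds$a[e]; b <- mol$bonds$b[e]
      if (matched[a] || matched[b]) next
      matched[a] <<- TRUE; matched[b] <<- TRUE
      res <- solve(setdiff(remaining, e), c(chosen, e))
      if (!is.null(res)) return(res)
      matched[a] <<- FALSE; matched[b] <<- FALSE
    }
    NULL
  }
  res <- solve(edges, chosen)
  if (is.null(res))
    stop_chem("aromatic system cannot be kekulized (no alternating bond assignment)")
  mol$bonds$order[res] <- 2L
  mol
}

#' Check that a molecule's aromatic systems admit a Kekule structure
#'
#' Strips the kekulized orders off aromatic bonds and re-derives them; used to
#' reject impossible assembled products.
#' @param mol a `mol_graph`
#' @return TRUE or error
#' @export
assert_kekulizable <- function(mol) {
  if (!any(mol$bonds$arom)) return(invisible(TRUE))
  test <- mol
  test$bonds$order[test$bonds$arom] <- 1L
  deg <- degrees(test)
  bsum <- integer(n_atoms(test))
  for (i in seq_len(nrow(test$bonds))) {
    bd <- test$bonds[i, ]
    bsum[bd$a] <- bsum[bd$a] + bd$order
    bsum[bd$b] <- bsum[bd$b] + bd$order
  }
  sigma <- bsum + test$atoms$hcount
  needs <- logical(n_atoms(test))
  for (v in which(test$atoms$arom)) {
    av <- allowed_valences(test$atoms$element[v], test$atoms$charge[v])
    vmin <- min(av[av >= sigma[v]], max(av))
    needs[v] <- sigma[v] == vmin - 1L
  }
  kekulize_aromatic(test, needs)
  invisible(TRUE)
}
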