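# Substructure matching (subgraph monomorphism) and canonical keys.
#
# Matching semantics: an atom of the pattern maps onto a target atom with the
# same element, aromatic flag and formal charge.  Pattern atoms designated
# "open" may carry arbitrary extra substituents in the target; closed atoms
# must reproduce the pattern's heavy degree and hydrogen count exactly
# (hydrogen counts at open positions are not compared, because a moiety's
# recorded hydrogens reflect its source molecule, not the match site).
# Pattern bonds must
# exist in the target with the same aromatic flag (and, for non-aromatic
# bonds, the same order); extra target bonds between open atoms are allowed
# (non-induced embedding).  This is what reactant-moiety matching needs:
# substitution is legal exactly where the extraction left an attachment
# point, while the reacting environment is matched verbatim.

#' Find embeddings of a pattern in a target molecule
#'
#' @param pattern `mol_graph` (connected)
#' @param target `mol_graph`
#' @param open which pattern atoms may carry extra substituents: `"all"`
#'   (plain substructure search, the default) or an integer index vector
#' @param max_matches stop after this many distinct embeddings
#' @param dedup collapse matches equal up to pattern automorphism (same
#'   target atom set); default TRUE
#' @return list of integer vectors m with m[i] = target atom playing pattern
#'   atom i; empty list if no match
#' @export
match_substructure <- function(pattern, target, open = "all",
                               max_matches = 1000L, dedup = TRUE) {
  np <- n_atoms(pattern); nt <- n_atoms(target)
  if (np == 0L || np > nt) return(list())
  open_idx <- if (identical(open, "all")) seq_len(np) else as.integer(open)
  is_open <- seq_len(np) %in% open_idx

  p_deg <- degrees(pattern); t_deg <- degrees(target)
  p_adj <- adjacency(pattern); t_adj <- adjacency(target)
  p_bidx <- bond_index(pattern); t_bidx <- bond_index(target)
  p_sp3c <- is_sp3_carbon(pattern); t_sp3c <- is_sp3_carbon(target)

  atom_ok <- function(pi, ti) {
    if (pattern$atoms$element[pi] != target$atoms$element[ti]) return(FALSE)
    if (pattern$atoms$arom[pi] != target$atoms$arom[ti]) return(FALSE)
    if (pattern$atoms$charge[pi] != target$atoms$charge[ti]) return(FALSE)
    if (is_open[pi]) {
      # open positions permit arbitrary substitution, but an sp3-carbon
      # pattern atom must still land on an sp3 carbon (a carbonyl carbon is
      # not a valid stand-in for an aliphatic stop atom)
      t_deg[ti] >= p_deg[pi] && (!p_sp3c[pi] || t_sp3c[ti])
    } else {
      # closed positions reproduce the pattern environment exactly
      t_deg[ti] == p_deg[pi] &&
        target$atoms$hcount[ti] == pattern$atoms$hcount[pi]
    }
  }

  bond_ok <- function(pb, tb) {
    if (pattern$bonds$arom[pb] != target$bonds$arom[tb]) return(FALSE)
    pattern$bonds$arom[pb] || pattern$bonds$order[pb] == target$bonds$order[tb]
  }

  # search order: BFS from the rarest-element atom, so adjacency prunes early
  t_counts <- table(target$atoms$element)
  rarity <- as.numeric(t_counts[pattern$atoms$element])
  rarity[is.na(rarity)] <- 0
  start <- which.min(rarity + p_deg * 1e-3)
  ord <- graph_bfs_order(p_adj, start, np)

  matches <- list(); seen <- character(0)
  assign_t <- rep.int(NA_integer_, np)
  used <- logical(nt)

  recurse <- function(k) {
    if (length(matches) >= max_matches) return()
    if (k > np) {
      m <- assign_t
      key <- paste(sort(m), collapse = ",")
      if (!dedup || !key %in% seen) {
        seen <<- c(seen, key)
        matches[[length(matches) + 1L]] <<- m
      }
      return()
    }
    pi <- ord[k]
    # candidates: neighbors of already-mapped pattern neighbors, else all
    mapped_nb <- p_adj[[pi]][!is.na(assign_t[p_adj[[pi]]])]
    cands <- if (length(mapped_nb)) {
      Reduce(intersect, lapply(mapped_nb, function(pn) t_adj[[assign_t[pn]]]))
    } else seq_len(nt)
    for (ti in cands) {
      if (used[ti] || !atom_ok(pi, ti)) next
      ok <- TRUE
      for (pn in p_adj[[pi]]) {
        tn <- assign_t[pn]
        if (is.na(tn)) next
        tb <- t_bidx[[paste(min(ti, tn), max(ti, tn))]]
        if (is.null(tb)) { ok <- FALSE; break }
        pb <- p_bidx[[paste(min(pi, pn), max(pi, pn))]]
        if (!bond_ok(pb, tb)) { ok <- FALSE; break }
      }
      if (!ok) next
      assign_t[pi] <<- ti; used[ti] <<- TRUE
      recurse(k + 1L)
      assign_t[pi] <<- NA_integer_; used[ti] <<- FALSE
    }
  }
  recurse(1L)
  matches
}

graph_bfs_order <- function(adj, start, n) {
  ord <- integer(0); seen <- logical(n)
  queue <- start; seen[start] <- TRUE
  while (length(queue)) {
    v <- queue[1L]; queue <- queue[-1L]
    ord <- c(ord, v)
    nxt <- adj[[v]][!seen[adj[[v]]]]
    seen[nxt] <- TRUE
    queue <- c(queue, nxt)
  }
  c(ord, which(!seen))  # disconnected pattern atoms appended (not expected)
}

#' Does `pattern` occur in `target`?
#' @rdname match_substructure
#' @export
has_substructure <- function(pattern, target, open = "all") {
  length(match_substructure(pattern, target, open = open, max_matches = 1L)) > 0L
}

#' Canonical key of a molecular graph
#'
#' Two molecules receive the same key iff their graphs (element, charge,
#' hydrogen count, bond order/aromaticity) are isomorphic; atom maps are
#' ignored.  Implemented via BLISS canonical labeling (igraph) on a
#' bond-subdivided, vertex-colored auxiliary graph: each bond becomes an
#' extra vertex colored by its order/aromaticity, so edge attributes ride on
#' vertex colors, which BLISS handles natively.
#'
#' @param mol a `mol_graph`
#' @return character scalar
#' @export
canonical_key <- function(mol) {
  n <- n_atoms(mol); nb <- nrow(mol$bonds)
  if (n == 0L) return("empty")
  atom_lab <- paste0(mol$atoms$element, "|", mol$atoms$charge, "|",
                     as.integer(mol$atoms$arom), "|", mol$atoms$hcount)
  bond_lab <- if (nb) paste0("B|", ifelse(mol$bonds$arom, "a", mol$bonds$order)) else character(0)
  labs <- c(atom_lab, bond_lab)
  # deterministic integer colors from the molecule's own label multiset:
  # isomorphism-invariant because the multiset is; radix sort keeps the key
  # independent of the session locale's collation
  lev <- sort(unique(labs), method = "radix")
  colors <- match(labs, lev) - 1L
  edges <- integer(0)
  if (nb) {
    bv <- n + seq_len(nb)
    edges <- as.integer(rbind(mol$bonds$a, bv, mol$bonds$b, bv))
  }
  g <- igraph::make_empty_graph(n = n + nb, directed = FALSE)
  if (length(edges)) g <- igraph::add_edges(g, edges)
  perm <- igraph::canonical_permutation(g, colors = colors)$labeling
  g2 <- igraph::permute(g, perm)
  el <- igraph::as_edgelist(g2, names = FALSE)
  el <- el[order(pmin(el[, 1], el[, 2]), pmax(el[, 1], el[, 2])), , drop = FALSE]
  lab2 <- character(length(labs)); lab2[perm] <- labs
  paste(c(paste(lab2, collapse = ";"),
          paste(pmin(el[, 1], el[, 2]), pmax(el[, 1], el[, 2]),
                sep = "-", collapse = ";")),
        collapse = "||")
}

#' Graph isomorphism between two molecules (matching semantics of
#' [canonical_key()]); used as an independent small-graph oracle in tests and
#' for route replay verification.
#' @param a,b `mol_graph`s
#' @return logical
#' @export
mols_isomorphic <- function(a, b) {
  if (n_atoms(a) != n_atoms(b) || nrow(a$bonds) != nrow(b$bonds)) return(FALSE)
  length(match_substructure(a, b, open = integer(0), max_matches = 1L)) > 0L
}
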