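# Reaction-rule extraction from atom-mapped reactions.
#
# Step 1 finds the reaction core: atoms that are unmapped, lose their map
# partner, or change any tracked attribute (element, formal charge, aromatic
# flag, heavy-neighbor count, or the multiset of (bond label, partner map)
# over mapped neighbors).  Step 2 extends each molecule's core outward to a
# chemically meaningful moiety: extension runs through sp2/hetero atoms,
# stops at (and includes) the first sp3 carbon in each direction, and pulls
# whole aromatic rings in before stopping.  The stop atoms (sp3 carbons and
# aromatic ring atoms) are the moiety's open positions: substitution is legal
# there when the moiety is matched against a new molecule.

#' Identify the reaction core of a mapped reaction
#'
#' @param rxn a `mapped_reaction`
#' @return list(reactants = list of atom-index vectors, products = likewise)
#' @export
identify_reaction_core <- function(rxn) {
  check_reaction_maps(rxn)
  sig <- function(mols) {
    # map number -> attribute signature
    out <- list()
    for (m in mols) {
      adj <- adjacency(m)
      bidx <- bond_index(m)
      for (i in seq_len(n_atoms(m))) {
        mp <- m$atoms$map[i]
        if (mp == 0L) next
        nb <- adj[[i]]
        nb_sig <- sort(vapply(nb, function(j) {
          bi <- bidx[[paste(min(i, j), max(i, j))]]
          lab <- if (m$bonds$arom[bi]) "a" else as.character(m$bonds$order[bi])
          mj <- m$atoms$map[j]
          if (mj > 0L) paste0(lab, ":", mj) else ""
        }, ""), method = "radix")
        nb_sig <- nb_sig[nzchar(nb_sig)]
        out[[as.character(mp)]] <- paste(
          m$atoms$element[i], m$atoms$charge[i], as.integer(m$atoms$arom[i]),
          length(nb), paste(nb_sig, collapse = ","), sep = "|")
      }
    }
    out
  }
  rs <- sig(rxn$reactants); ps <- sig(rxn$products)
  core_side <- function(mols, other_sig, own_sig) {
    lapply(mols, function(m) {
      which(vapply(seq_len(n_atoms(m)), function(i) {
        mp <- m$atoms$map[i]
        if (mp == 0L) return(TRUE)                      # unmapped: core
        key <- as.character(mp)
        if (is.null(other_sig[[key]])) return(TRUE)     # partner absent: core
        !identical(own_sig[[key]], other_sig[[key]])    # attribute changed
      }, FALSE))
    })
  }
  list(reactants = core_side(rxn$reactants, ps, rs),
       products = core_side(rxn$products, rs, ps))
}

#' Extend a core atom set to a moiety within one molecule
#'
#' @param mol the molecule
#' @param core integer atom indices (nonempty)
#' @return a `moiety`: list(pattern, atoms (source indices, pattern order),
#'   open (pattern indices of substitution-permitted atoms), attachment
#'   (pattern indices actually bonded to outside atoms in the source))
#' @export
extend_core_to_moiety <- function(mol, core) {
  stopifnot(length(core) > 0L)
  adj <- adjacency(mol)
  rings <- find_rings(mol)
  arings <- Filter(function(r) all(mol$atoms$arom[r]), rings)
  sp3 <- is_sp3_carbon(mol)

  included <- logical(n_atoms(mol))
  stopatom <- logical(n_atoms(mol))   # included but not expanded further
  included[core] <- TRUE

  pull_rings <- function() {
    repeat {
      grew <- FALSE
      for (r in arings) {
        if (any(included[r]) && !all(included[r])) {
          included[r] <<- TRUE; grew <- TRUE
        }
        if (all(included[r])) stopatom[r] <<- TRUE
      }
      if (!grew) break
    }
  }
  pull_rings()
  frontier <- which(included & !stopatom)
  while (length(frontier)) {
    nxt <- integer(0)
    for (v in frontier) {
      for (w in adj[[v]]) {
        if (included[w]) next
        included[w] <- TRUE
        if (mol$atoms$arom[w]) {
          # entering an aromatic ring: whole ring comes in, then stop
          stopatom[w] <- TRUE
        } else if (sp3[w]) {
          stopatom[w] <- TRUE   # the stopping sp3 carbon is part of the moiety
        } else {
          nxt <- c(nxt, w)
        }
      }
    }
    pull_rings()
    frontier <- nxt[!stopatom[nxt]]
  }
  # sp3 core atoms with no outside neighbors to visit are fine; aromatic core
  # atoms got their rings via pull_rings
  atoms <- which(included)
  sub <- induced_subgraph_mol(mol, atoms)
  open_src <- which(included & (stopatom | (sp3 & included)))
  open <- match(open_src, atoms)
  outside <- vapply(atoms, function(v) any(!included[adj[[v]]]), FALSE)
  # valence each pattern atom loses to excluded source neighbors; assembly
  # restores it through attachments or hydrogens
  bidx <- bond_index(mol)
  excised <- vapply(atoms, function(v) {
    out <- adj[[v]][!included[adj[[v]]]]
    if (!length(out)) return(0L)
    sum(vapply(out, function(w)
      mol$bonds$order[bidx[[paste(min(v, w), max(v, w))]]], 0L))
  }, 0L)
  structure(list(pattern = sub$mol, atoms = atoms, open = sort(open),
                 attachment = which(outside), excised = excised),
            class = "moiety")
}

#' @export
print.moiety <- function(x, ...) {
  cat(sprintf("<moiety: %d atoms (%s), open = {%s}>\n",
              n_atoms(x$pattern), write_smiles(x$pattern),
              paste(x$open, collapse = ",")))
  invisible(x)
}

#' Extend the full reaction core to per-molecule moieties
#'
#' @param rxn a `mapped_reaction`
#' @param core output of [identify_reaction_core()]
#' @return list(reactants = list of moiety or NULL, products = likewise);
#'   molecules with an empty core yield NULL
#' @export
extend_to_moieties <- function(rxn, core = identify_reaction_core(rxn)) {
  ext <- function(mols, cores) {
    lapply(seq_along(mols), function(i) {
      if (!length(cores[[i]])) return(NULL)
      extend_core_to_moiety(mols[[i]], cores[[i]])
    })
  }
  list(reactants = ext(rxn$reactants, core$reactants),
       products = ext(rxn$products, core$products))
}

#' Build a reaction rule from a mapped reaction
#'
#' The rule holds one reactant moiety per participating reactant, the product
#' moiety of the principal product (the product sharing the most mapped atoms
#' with the largest reactant), and the map-number correspondence between
#' them.  Moiety atoms whose maps are absent from the product moiety are
#' leaving atoms; product-moiety atoms without a reactant partner are
#' introduced by the reaction.
#'
#' @param rxn a `mapped_reaction`
#' @param id optional rule identifier (defaults to the reaction name)
#' @return object of class `reaction_rule`
#' @export
build_rule <- function(rxn, id = rxn$name) {
  core <- identify_reaction_core(rxn)
  if (!any(vapply(core$reactants, length, 0L) > 0L))
    stop_chem("empty rule: reaction core is empty (identity reaction?)")
  moieties <- extend_to_moieties(rxn, core)
  r_mo <- Filter(Negate(is.null), moieties$reactants)
  if (!length(r_mo)) stop_chem("no reactant moiety could be extracted")
  if (!length(rxn$products)) stop_format("reaction has no product")

  # principal product: most shared maps with the largest reactant
  largest <- which.max(vapply(rxn$reactants, n_atoms, 0L))
  lmaps <- rxn$reactants[[largest]]$atoms$map
  shared <- vapply(rxn$products, function(p)
    sum(p$atoms$map %in% lmaps[lmaps > 0L]), 0L)
  principal <- which.max(shared)
  p_mo <- moieties$products[[principal]]
  if (is.null(p_mo))
    stop_chem("principal product has an empty core; cannot form a product moiety")

  p_maps <- p_mo$pattern$atoms$map
  corr <- list()
  introduced <- integer(0)
  for (q in seq_len(n_atoms(p_mo$pattern))) {
    mp <- p_maps[q]
    hit <- FALSE
    if (mp > 0L) {
      for (s in seq_along(r_mo)) {
        r_at <- which(r_mo[[s]]$pattern$atoms$map == mp)
        if (length(r_at)) {
          corr[[length(corr) + 1L]] <- data.frame(slot = s, r_atom = r_at,
                                                  p_atom = q, map = mp)
          hit <- TRUE; break
        }
      }
    }
    if (!hit) introduced <- c(introduced, q)
  }
  corr <- if (length(corr)) do.call(rbind, corr) else
    data.frame(slot = integer(), r_atom = integer(), p_atom = integer(),
               map = integer())
  rule <- structure(list(id = id, source_name = rxn$name,
                         reactant_moieties = r_mo, product_moiety = p_mo,
                         correspondence = corr, introduced = introduced),
                    class = "reaction_rule")
  rule
}

#' @export
print.reaction_rule <- function(x, ...) {
  cat(sprintf("<reaction_rule %s: %d reactant moiety(ies) -> %s>\n",
              x$id, length(x$reactant_moieties),
              write_smiles(x$product_moiety$pattern)))
  invisible(x)
}
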