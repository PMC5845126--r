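# Virtual synthesis: clip a matched reactant around a reactant moiety,
# recombine clipped remainders with the product moiety through the rule's
# map correspondence, and enumerate products over a rule database and block
# library.

#' Clip a molecule at a moiety match
#'
#' @param mol the molecule (reactant or participant)
#' @param match integer vector from [match_substructure()]: pattern atom i ->
#'   mol atom match[i]
#' @param moiety the matched `moiety`
#' @return a `clipped_fragment`: list(source, remainder (mol atom indices),
#'   attach = data.frame(pattern_pos, src_atom, order, arom), match)
#' @export
clip <- function(mol, match, moiety) {
  np <- n_atoms(moiety$pattern)
  if (length(match) != np || anyDuplicated(match) ||
      any(match < 1L | match > n_atoms(mol)))
    stop_format("match is not a valid embedding of the moiety")
  in_moiety <- logical(n_atoms(mol)); in_moiety[match] <- TRUE
  attach <- list()
  for (i in seq_len(nrow(mol$bonds))) {
    a <- mol$bonds$a[i]; b <- mol$bonds$b[i]
    if (in_moiety[a] == in_moiety[b]) next
    inside <- if (in_moiety[a]) a else b
    outside <- if (in_moiety[a]) b else a
    ppos <- which(match == inside)
    if (!ppos %in% moiety$open)
      stop_format("substituent attached at a closed moiety atom (pattern pos ",
                  ppos, "): match is not a valid embedding")
    attach[[length(attach) + 1L]] <-
      data.frame(pattern_pos = ppos, src_atom = outside,
                 order = mol$bonds$order[i], arom = mol$bonds$arom[i])
  }
  attach <- if (length(attach)) do.call(rbind, attach) else
    data.frame(pattern_pos = integer(), src_atom = integer(),
               order = integer(), arom = logical())
  structure(list(source = mol, remainder = which(!in_moiety),
                 attach = attach, match = match),
            class = "clipped_fragment")
}

#' @export
print.clipped_fragment <- function(x, ...) {
  cat(sprintf("<clipped_fragment: %d remainder atoms, %d attachment bond(s)>\n",
              length(x$remainder), nrow(x$attach)))
  invisible(x)
}

#' Assemble a product from a rule and clipped reactants
#'
#' The product is the product moiety plus both remainders, joined through the
#' rule's map correspondence at the recorded attachment positions.  Hydrogens
#' on product-moiety atoms are the template's counts minus one per attached
#' external bond.  Atoms inherited from the posed reactant (slot
#' `posed_slot`) carry its coordinates; all other atoms have NA coordinates.
#'
#' @param rule a `reaction_rule`
#' @param clips list of `clipped_fragment`, one per reactant-moiety slot
#' @param coords optional pose of the posed reactant (n x 3 matrix)
#' @param posed_slot which slot is the posed reactant (default 1)
#' @param participant_id,reactant_id provenance strings
#' @return a `product_record`: list(product, inherited_coords, new_atoms,
#'   rule_id, reactant_id, participant_id, provenance)
#' @export
assemble_product <- function(rule, clips, coords = NULL, posed_slot = 1L,
                             reactant_id = "", participant_id = "") {
  nslot <- length(rule$reactant_moieties)
  if (length(clips) != nslot)
    stop_format("assembly error: rule has ", nslot, " slot(s), got ",
                length(clips), " clip(s)")
  pm <- rule$product_moiety$pattern
  npm <- n_atoms(pm)
  corr <- rule$correspondence

  atoms <- pm$atoms
  atoms$map <- 0L
  # free valence at excised positions is filled by attachments, else hydrogens
  atoms$hcount <- atoms$hcount + rule$product_moiety$excised
  bonds <- pm$bonds
  coords_out <- matrix(NA_real_, npm, 3L)
  inherited <- logical(npm)

  # map (slot, pattern_pos) -> product atom
  prod_pos <- function(slot, r_atom) {
    hit <- corr$p_atom[corr$slot == slot & corr$r_atom == r_atom]
    if (!length(hit)) NA_integer_ else hit[1L]
  }

  # coordinates inherited through the moiety correspondence of the posed slot
  if (!is.null(coords)) {
    cl <- clips[[posed_slot]]
    for (k in seq_len(nrow(corr))) {
      if (corr$slot[k] != posed_slot) next
      src <- cl$match[corr$r_atom[k]]
      coords_out[corr$p_atom[k], ] <- coords[src, ]
      inherited[corr$p_atom[k]] <- TRUE
    }
  }

  for (s in seq_len(nslot)) {
    cl <- clips[[s]]
    if (!inherits(cl, "clipped_fragment"))
      stop_format("assembly error: clip for slot ", s, " missing")
    rem <- cl$remainder
    offset <- nrow(atoms)
    newpos <- integer(n_atoms(cl$source))
    newpos[rem] <- offset + seq_along(rem)
    if (length(rem)) {
      ra <- cl$source$atoms[rem, , drop = FALSE]
      ra$map <- 0L
      atoms <- rbind(atoms, ra)
      rb <- cl$source$bonds
      keep <- rb$a %in% rem & rb$b %in% rem
      rb <- rb[keep, , drop = FALSE]
      if (nrow(rb)) { rb$a <- newpos[rb$a]; rb$b <- newpos[rb$b] }
      bonds <- rbind(bonds, rb)
      coords_out <- rbind(coords_out, matrix(NA_real_, length(rem), 3L))
      if (s == posed_slot && !is.null(coords)) {
        coords_out[offset + seq_along(rem), ] <- coords[rem, , drop = FALSE]
        inherited <- c(inherited, rep.int(TRUE, length(rem)))
      } else inherited <- c(inherited, rep.int(FALSE, length(rem)))
    }
    # re-attach external bonds at the mapped product positions
    for (k in seq_len(nrow(cl$attach))) {
      q <- prod_pos(s, cl$attach$pattern_pos[k])
      if (is.na(q))
        stop_chem("assembly error: substituent attached to a leaving atom ",
                  "(slot ", s, ", pattern pos ", cl$attach$pattern_pos[k], ")")
      bonds <- rbind(bonds, data.frame(a = q, b = newpos[cl$attach$src_atom[k]],
                                       order = cl$attach$order[k],
                                       arom = cl$attach$arom[k]))
      atoms$hcount[q] <- atoms$hcount[q] - 1L
      if (atoms$hcount[q] < 0L)
        stop_chem("assembly error: attachment exceeds available hydrogens at ",
                  "product atom ", q)
    }
  }
  rownames(atoms) <- NULL
  product <- mol_graph(atoms, bonds, name = "", validate = FALSE)
  validate_mol(product)      # chemistry error on valence violation
  assert_kekulizable(product)
  structure(list(product = product, inherited_coords = coords_out,
                 new_atoms = which(!inherited),
                 rule_id = rule$id, reactant_id = reactant_id,
                 participant_id = participant_id),
            class = "product_record")
}

#' @export
print.product_record <- function(x, ...) {
  cat(sprintf("<product_record [%s + %s via %s]: %s>\n", x$reactant_id,
              x$participant_id, x$rule_id, write_smiles(x$product)))
  invisible(x)
}

#' Apply a rule to its own source reactants (round-trip oracle support)
#'
#' Matches each reactant moiety back onto the rule's source reactants and
#' assembles; the result must be graph-isomorphic to the recorded principal
#' product.
#' @param rule a `reaction_rule`
#' @param reactants list of the source reactant `mol_graph`s
#' @return a `product_record`
#' @export
apply_rule_to_source <- function(rule, reactants) {
  nslot <- length(rule$reactant_moieties)
  clips <- vector("list", nslot)
  used <- logical(length(reactants))
  for (s in seq_len(nslot)) {
    mo <- rule$reactant_moieties[[s]]
    done <- FALSE
    for (ri in seq_along(reactants)) {
      if (used[ri]) next
      # map-guided embedding: source moieties come from these very molecules
      mm <- match_substructure(mo$pattern, reactants[[ri]], open = mo$open,
                               max_matches = 8L)
      mm <- Filter(function(m) {
        all(reactants[[ri]]$atoms$map[m] == mo$pattern$atoms$map)
      }, mm)
      if (length(mm)) {
        clips[[s]] <- clip(reactants[[ri]], mm[[1L]], mo)
        used[ri] <- TRUE; done <- TRUE; break
      }
    }
    if (!done) stop_chem("rule round-trip: moiety ", s,
                         " not found in source reactants")
  }
  assemble_product(rule, clips)
}

#' Enumerate products of a posed reactant over a rule database
#'
#' Cartesian expansion over (matched rule, matched slot, participant block
#' for the complementary slot), deduplicated by [canonical_key()], in
#' deterministic (rule id, participant id) order.
#'
#' @param reactant a `mol_graph`
#' @param db a `rule_db`
#' @param library list of building blocks (see [block_library()])
#' @param coords optional pose of `reactant`
#' @param reactant_id provenance string
#' @return list of `product_record`
#' @export
enumerate_products <- function(reactant, db, library, coords = NULL,
                               reactant_id = "") {
  hits <- match_rules(reactant, db)
  lib_by_id <- stats::setNames(library, vapply(library, `[[`, "", "id"))
  out <- list(); seen <- character(0)
  for (h in hits) {
    rule <- db$rules[[h$rule]]
    nslot <- length(rule$reactant_moieties)
    r_clip <- clip(reactant, h$match, rule$reactant_moieties[[h$slot]])
    if (nslot == 1L) {
      rec <- try_assemble(rule, list(r_clip), h$slot, coords, reactant_id, "")
      out <- add_product(out, rec, seen); seen <- attr(out, "seen")
    } else {
      other <- setdiff(seq_len(nslot), h$slot)[1L]
      part_ids <- db$block_index[[rule$id]][[other]]
      for (pid in part_ids) {
        block <- lib_by_id[[pid]]
        pm <- match_substructure(rule$reactant_moieties[[other]]$pattern,
                                 block$mol,
                                 open = rule$reactant_moieties[[other]]$open,
                                 max_matches = 4L)
        if (!length(pm)) next
        p_clip <- clip(block$mol, pm[[1L]], rule$reactant_moieties[[other]])
        clips <- vector("list", nslot)
        clips[[h$slot]] <- r_clip; clips[[other]] <- p_clip
        rec <- try_assemble(rule, clips, h$slot, coords, reactant_id, pid)
        out <- add_product(out, rec, seen); seen <- attr(out, "seen")
      }
    }
  }
  attr(out, "seen") <- NULL
  out
}

try_assemble <- function(rule, clips, posed_slot, coords, reactant_id, pid) {
  tryCatch(
    assemble_product(rule, clips, coords = coords, posed_slot = posed_slot,
                     reactant_id = reactant_id, participant_id = pid),
    rxngrow_chemistry_error = function(e) NULL)
}

add_product <- function(out, rec, seen) {
  if (!is.null(rec)) {
    key <- canonical_key(rec$product)
    if (!key %in% seen) {
      rec$key <- key
      out[[length(out) + 1L]] <- rec
      seen <- c(seen, key)
    }
  }
  attr(out, "seen") <- seen
  out
}

#' Match a molecule against every reactant moiety in a rule database
#'
#' @param mol a `mol_graph`
#' @param db a `rule_db`
#' @return list of list(rule = rule index, slot, match), in deterministic
#'   order (rule id, slot, match image)
#' @export
match_rules <- function(mol, db) {
  out <- list()
  for (ri in seq_along(db$rules)) {
    rule <- db$rules[[ri]]
    for (s in seq_along(rule$reactant_moieties)) {
      mo <- rule$reactant_moieties[[s]]
      for (m in match_substructure(mo$pattern, mol, open = mo$open,
                                   max_matches = 16L))
        out[[length(out) + 1L]] <- list(rule = ri, slot = s, match = m)
    }
  }
  out
}
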