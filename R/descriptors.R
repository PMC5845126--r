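# Molecular descriptors: molecular weight, heavy-atom count and a
# Crippen-type atom-contribution cLogP.
#
# The cLogP parameter table below is pinned for the life of the package.  It
# is a coarse atom-contribution scheme in the spirit of Wildman & Crippen
# (atom classes by element/aromaticity/heteroatom neighborhood, hydrogens
# contributing through their heavy atom); absolute values are
# implementation-relative, only ordering and the <5 filter semantics are
# relied upon downstream.

.CLOGP <- list(
  C_aliph      = 0.20,   # sp3/sp2 carbon bonded only to C/H
  C_aliph_het  = -0.10,  # aliphatic carbon with a heteroatom neighbor
  C_arom       = 0.29,   # aromatic carbon
  C_arom_het   = 0.10,   # aromatic carbon with exocyclic heteroatom neighbor
  N_aliph      = -1.00,
  N_arom       = -0.60,
  O_hydroxyl   = -0.45,
  O_ether      = -0.15,  # also aromatic O
  O_carbonyl   = -0.25,
  S            = 0.40,
  P            = -0.50,
  B            = 0.10,
  F            = 0.20,
  Cl           = 0.70,
  Br           = 0.90,
  I            = 1.10,
  H_on_C       = 0.12,
  H_on_het     = -0.30,
  charge_pen   = -1.00   # per unit of |formal charge|
)

#' Compute descriptors for a molecule
#'
#' @param mol a `mol_graph`
#' @return list with `molecular_weight` (g/mol, implicit hydrogens included),
#'   `heavy_atom_count` and `clogp`
#' @export
compute_descriptors <- function(mol) {
  list(molecular_weight = molecular_weight(mol),
       heavy_atom_count = n_atoms(mol),
       clogp = clogp(mol))
}

#' @rdname compute_descriptors
#' @export
molecular_weight <- function(mol) {
  sum(atomic_weight(mol$atoms$element)) +
    sum(mol$atoms$hcount) * .ATOMIC_WEIGHTS[["H"]]
}

#' @rdname compute_descriptors
#' @export
heavy_atom_count <- function(mol) n_atoms(mol)

#' @rdname compute_descriptors
#' @export
clogp <- function(mol) {
  adj <- adjacency(mol)
  p <- .CLOGP
  total <- 0
  for (i in seq_len(n_atoms(mol))) {
    el <- mol$atoms$element[i]
    ar <- mol$atoms$arom[i]
    nbr_el <- mol$atoms$element[adj[[i]]]
    has_het <- any(!nbr_el %in% "C")
    contrib <- switch(el,
      C = if (ar) { if (has_het) p$C_arom_het else p$C_arom }
          else { if (has_het) p$C_aliph_het else p$C_aliph },
      N = if (ar) p$N_arom else p$N_aliph,
      O = {
        bo <- mol$bonds[mol$bonds$a == i | mol$bonds$b == i, , drop = FALSE]
        if (any(bo$order == 2L)) p$O_carbonyl
        else if (mol$atoms$hcount[i] > 0L) p$O_hydroxyl
        else p$O_ether
      },
      S = p$S, P = p$P, B = p$B,
      F = p$F, Cl = p$Cl, Br = p$Br, I = p$I,
      0)
    h_term <- mol$atoms$hcount[i] * if (el == "C") p$H_on_C else p$H_on_het
    total <- total + contrib + h_term + abs(mol$atoms$charge[i]) * p$charge_pen
  }
  total
}

#' Parse a molecule from SMILES or a MOL block
#'
#' Dispatches on content: multi-line text containing `V2000` is treated as a
#' MOL block, otherwise as SMILES.  Atom-map numbers are preserved.
#'
#' @param text molecule text
#' @param format `"auto"`, `"smiles"` or `"mol"`
#' @return a valence-checked `mol_graph` (for MOL input, the conformer is
#'   attached as attribute `"coords"`)
#' @export
parse_molecule <- function(text, format = c("auto", "smiles", "mol")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("V2000", text) || grepl("\n", text)) "mol" else "smiles"
  if (format == "smiles") return(parse_smiles(text))
  rec <- parse_molblock(text)
  structure(rec$mol, coords = rec$coords)
}
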