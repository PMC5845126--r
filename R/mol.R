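# MolecularGraph: the package-wide molecule container.
#
# Heavy atoms only; hydrogens are implicit counts on each atom (hcount).
# Bonds carry a kekulized integer order (1/2/3) plus an aromatic flag, so
# valence arithmetic always sees integers while matching sees aromaticity.

#' Construct a molecular graph
#'
#' @param atoms data.frame with columns `element` (symbol), `charge` (integer),
#'   `arom` (logical aromatic flag), `hcount` (total attached hydrogens),
#'   `map` (atom-map number, 0 = unmapped).
#' @param bonds data.frame with columns `a`, `b` (1-based atom indices),
#'   `order` (1, 2 or 3; kekulized), `arom` (logical).
#' @param name optional molecule name.
#' @param validate check invariants (indices, duplicates, valence).
#' @return an object of class `mol_graph`.
#' @export
mol_graph <- function(atoms, bonds = NULL, name = "", validate = TRUE) {
  atoms <- as.data.frame(atoms, stringsAsFactors = FALSE)
  for (col in c("charge", "hcount", "map")) {
    if (is.null(atoms[[col]])) atoms[[col]] <- 0L
    atoms[[col]] <- as.integer(atoms[[col]])
  }
  if (is.null(atoms$arom)) atoms$arom <- FALSE
  if (is.null(bonds) || NROW(bonds) == 0L) {
    bonds <- data.frame(a = integer(), b = integer(), order = integer(),
                        arom = logical())
  } else {
    bonds <- as.data.frame(bonds, stringsAsFactors = FALSE)
    if (is.null(bonds$arom)) bonds$arom <- FALSE
    bonds$a <- as.integer(bonds$a); bonds$b <- as.integer(bonds$b)
    bonds$order <- as.integer(bonds$order)
  }
  mol <- structure(list(atoms = atoms, bonds = bonds, name = name),
                   class = "mol_graph")
  if (validate) validate_mol(mol)
  mol
}

#' @export
print.mol_graph <- function(x, ...) {
  cat(sprintf("<mol_graph%s: %d heavy atoms, %d bonds, formula-ish %s>\n",
              if (nzchar(x$name)) paste0(" ", x$name) else "",
              n_atoms(x), nrow(x$bonds),
              paste(names(table(x$atoms$element)), table(x$atoms$element),
                    sep = "", collapse = "")))
  invisible(x)
}

#' Number of heavy atoms in a molecular graph
#' @param mol a `mol_graph`
#' @export
n_atoms <- function(mol) nrow(mol$atoms)

#' Structural validation of a molecular graph
#'
#' Checks bond-index sanity, self/duplicate bonds, atom-map uniqueness and
#' chemical valence admissibility.  Called by every constructor and after
#' every graph edit.
#' @param mol a `mol_graph`.
#' @return `mol`, invisibly; errors with class `rxngrow_chemistry_error` or
#'   `rxngrow_format_error` on violation.
#' @export
validate_mol <- function(mol) {
  n <- n_atoms(mol)
  b <- mol$bonds
  if (nrow(b)) {
    if (any(b$a < 1L | b$a > n | b$b < 1L | b$b > n))
      stop_format("bond references an atom index outside 1..", n)
    if (any(b$a == b$b)) stop_format("self-bond found")
    key <- paste(pmin(b$a, b$b), pmax(b$a, b$b))
    if (anyDuplicated(key)) stop_format("duplicate bond found")
    if (!all(b$order %in% 1:3)) stop_format("bond order outside {1,2,3}")
  }
  maps <- mol$atoms$map[mol$atoms$map > 0L]
  if (anyDuplicated(maps))
    stop_format("duplicate atom-map numbers within one molecule: ",
                paste(maps[duplicated(maps)], collapse = ", "))
  check_valence(mol)
  invisible(mol)
}

#' @noRd
check_valence <- function(mol) {
  n <- n_atoms(mol)
  bsum <- integer(n)
  if (nrow(mol$bonds)) {
    for (i in seq_len(nrow(mol$bonds))) {
      bd <- mol$bonds[i, ]
      bsum[bd$a] <- bsum[bd$a] + bd$order
      bsum[bd$b] <- bsum[bd$b] + bd$order
    }
  }
  for (i in seq_len(n)) {
    el <- mol$atoms$element[i]
    av <- allowed_valences(el, mol$atoms$charge[i])
    if (is.null(av)) next  # unconstrained element (metals in receptors etc.)
    tot <- bsum[i] + mol$atoms$hcount[i]
    if (!tot %in% av && tot > max(av))
      stop_chem(sprintf(
        "valence violation at atom %d (%s%+d): total valence %d not admissible (allowed: %s)",
        i, el, mol$atoms$charge[i], tot, paste(av, collapse = "/")))
  }
  invisible(mol)
}

# ---- error helpers ---------------------------------------------------------

stop_format <- function(...) {
  stop(structure(class = c("rxngrow_format_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

stop_chem <- function(...) {
  stop(structure(class = c("rxngrow_chemistry_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

# ---- graph helpers ---------------------------------------------------------

#' Adjacency list: for each atom, data.frame of (nbr, order, arom)
#' @noRd
adjacency <- function(mol) {
  n <- n_atoms(mol)
  adj <- replicate(n, integer(0), simplify = FALSE)
  if (nrow(mol$bonds)) {
    for (i in seq_len(nrow(mol$bonds))) {
      bd <- mol$bonds[i, ]
      adj[[bd$a]] <- c(adj[[bd$a]], bd$b)
      adj[[bd$b]] <- c(adj[[bd$b]], bd$a)
    }
  }
  adj
}

#' heavy-atom degree of each atom
#' @noRd
degrees <- function(mol) {
  n <- n_atoms(mol)
  d <- integer(n)
  if (nrow(mol$bonds)) {
    t1 <- tabulate(mol$bonds$a, n); t2 <- tabulate(mol$bonds$b, n)
    d <- t1 + t2
  }
  d
}

#' bond lookup table: named vector "min max" -> row index
#' @noRd
bond_index <- function(mol) {
  if (!nrow(mol$bonds)) return(structure(integer(0), names = character(0)))
  structure(seq_len(nrow(mol$bonds)),
            names = paste(pmin(mol$bonds$a, mol$bonds$b),
                          pmax(mol$bonds$a, mol$bonds$b)))
}

#' Is atom i an sp3 carbon (aliphatic C with only single bonds)?
#' @noRd
is_sp3_carbon <- function(mol, idx = seq_len(n_atoms(mol))) {
  n <- n_atoms(mol)
  has_multiple <- logical(n)
  if (nrow(mol$bonds)) {
    mb <- mol$bonds$order > 1L | mol$bonds$arom
    has_multiple[unique(c(mol$bonds$a[mb], mol$bonds$b[mb]))] <- TRUE
  }
  (mol$atoms$element == "C" & !mol$atoms$arom & !has_multiple)[idx]
}

#' Extract the induced subgraph on a set of atoms
#'
#' @param mol a `mol_graph`
#' @param idx atom indices to keep (order preserved)
#' @return list(mol = sub-molecule, map = old index for each new atom)
#' @noRd
induced_subgraph_mol <- function(mol, idx, name = mol$name) {
  idx <- as.integer(idx)
  newpos <- integer(n_atoms(mol)); newpos[idx] <- seq_along(idx)
  keep <- mol$bonds$a %in% idx & mol$bonds$b %in% idx
  b <- mol$bonds[keep, , drop = FALSE]
  if (nrow(b)) { b$a <- newpos[b$a]; b$b <- newpos[b$b] }
  sub <- mol_graph(mol$atoms[idx, , drop = FALSE], b, name = name,
                   validate = FALSE)
  list(mol = sub, map = idx)
}

#' connected components of the molecular graph
#' @noRd
mol_components <- function(mol) {
  n <- n_atoms(mol)
  comp <- integer(n); cur <- 0L
  adj <- adjacency(mol)
  for (s in seq_len(n)) {
    if (comp[s] != 0L) next
    cur <- cur + 1L
    queue <- s; comp[s] <- cur
    while (length(queue)) {
      v <- queue[1L]; queue <- queue[-1L]
      for (w in adj[[v]]) if (comp[w] == 0L) { comp[w] <- cur; queue <- c(queue, w) }
    }
  }
  comp
}

#' shortest-path graph distances from a set of atoms (BFS)
#' @noRd
graph_dist <- function(adj, from, n) {
  d <- rep.int(NA_integer_, n)
  d[from] <- 0L
  queue <- from
  while (length(queue)) {
    v <- queue[1L]; queue <- queue[-1L]
    for (w in adj[[v]]) if (is.na(d[w])) { d[w] <- d[v] + 1L; queue <- c(queue, w) }
  }
  d
}
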