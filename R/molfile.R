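# MDL MOL/SDF (V2000) reader and writer.
#
# Order-4 bonds are read as aromatic and kekulized; charges come from
# M  CHG lines (the legacy atom-block charge column is ignored, as modern
# writers do).  Hydrogen counts are implicit, filled the same way as for
# SMILES; explicit hydrogen atoms in the file are folded into hcount.

#' Parse one MOL block (V2000)
#'
#' @param lines character vector (the block's lines) or a single string with
#'   embedded newlines
#' @return list(mol = `mol_graph`, coords = n x 3 matrix)
#' @export
parse_molblock <- function(lines) {
  if (length(lines) == 1L && grepl("\n", lines))
    lines <- strsplit(lines, "\n", fixed = TRUE)[[1L]]
  if (length(lines) < 4L) stop_format("MOL block too short")
  counts <- lines[4L]
  na <- suppressWarnings(as.integer(substr(counts, 1L, 3L)))
  nb <- suppressWarnings(as.integer(substr(counts, 4L, 6L)))
  if (is.na(na) || is.na(nb)) stop_format("cannot read MOL counts line: '", counts, "'")
  if (length(lines) < 4L + na + nb) stop_format("MOL block truncated")
  atom_lines <- lines[4L + seq_len(na)]
  bond_lines <- if (nb) lines[4L + na + seq_len(nb)] else character(0)
  coords <- matrix(0, na, 3L)
  element <- character(na); mapno <- integer(na)
  for (i in seq_len(na)) {
    ln <- atom_lines[i]
    coords[i, 1L] <- as.numeric(substr(ln, 1L, 10L))
    coords[i, 2L] <- as.numeric(substr(ln, 11L, 20L))
    coords[i, 3L] <- as.numeric(substr(ln, 21L, 30L))
    element[i] <- trimws(substr(ln, 32L, 34L))
    mm <- suppressWarnings(as.integer(substr(ln, 61L, 63L)))
    mapno[i] <- if (is.na(mm)) 0L else mm
  }
  if (any(!is.finite(coords))) stop_format("non-finite coordinates in MOL block")
  a <- b <- ord <- integer(nb); arom <- logical(nb)
  for (i in seq_len(nb)) {
    ln <- bond_lines[i]
    a[i] <- as.integer(substr(ln, 1L, 3L))
    b[i] <- as.integer(substr(ln, 4L, 6L))
    o <- as.integer(substr(ln, 7L, 9L))
    if (o == 4L) { ord[i] <- 1L; arom[i] <- TRUE } else ord[i] <- o
  }
  charge <- integer(na)
  for (ln in grep("^M  CHG", lines, value = TRUE)) {
    toks <- as.integer(strsplit(trimws(substring(ln, 7L)), "\\s+")[[1L]])
    k <- toks[1L]
    for (j in seq_len(k)) charge[toks[2L * j]] <- toks[2L * j + 1L]
  }
  atoms <- data.frame(element = element, charge = charge,
                      arom = arom_atom_flags(na, a, b, arom),
                      hcount = 0L, map = mapno, stringsAsFactors = FALSE)
  bonds <- data.frame(a = a, b = b, order = ord, arom = arom)
  # fold explicit hydrogens into hcount
  is_h <- atoms$element == "H"
  mol <- mol_graph(atoms, bonds, name = trimws(lines[1L]), validate = FALSE)
  if (any(is_h)) {
    keep <- which(!is_h)
    adj <- adjacency(mol)
    extra_h <- vapply(keep, function(v) sum(is_h[adj[[v]]]), 0L)
    sub <- induced_subgraph_mol(mol, keep)
    mol <- sub$mol
    mol$atoms$hcount <- mol$atoms$hcount + extra_h
    coords <- coords[keep, , drop = FALSE]
    declared_extra <- extra_h > 0L
  } else declared_extra <- logical(n_atoms(mol))

  # kekulize any order-4 aromatic bonds, then fill implicit H
  deg <- degrees(mol)
  needs <- logical(n_atoms(mol))
  for (v in which(mol$atoms$arom)) {
    sigma <- deg[v] + mol$atoms$hcount[v]
    av <- allowed_valences(mol$atoms$element[v], mol$atoms$charge[v])
    if (is.null(av)) next
    if (mol$atoms$element[v] == "C") { needs[v] <- sigma < 4L; next }
    vmin <- if (any(av >= sigma + 1L)) min(av[av >= sigma + 1L]) else max(av)
    # heteroatoms in MOL aromatic rings: assume pyridine-like when degree 2
    needs[v] <- deg[v] == 2L && mol$atoms$element[v] %in% c("N", "P") &&
      mol$atoms$hcount[v] == 0L && sigma == vmin - 1L
  }
  mol <- kekulize_aromatic(mol, needs)
  bsum <- integer(n_atoms(mol))
  for (i in seq_len(nrow(mol$bonds))) {
    bd <- mol$bonds[i, ]
    bsum[bd$a] <- bsum[bd$a] + bd$order
    bsum[bd$b] <- bsum[bd$b] + bd$order
  }
  for (v in seq_len(n_atoms(mol))) {
    if (declared_extra[v]) next  # explicit-H molecules trust the file
    av <- allowed_valences(mol$atoms$element[v], mol$atoms$charge[v])
    if (is.null(av)) next
    s <- bsum[v] + mol$atoms$hcount[v]
    vmin <- if (any(av >= s)) min(av[av >= s]) else max(av)
    mol$atoms$hcount[v] <- mol$atoms$hcount[v] + max(vmin - s, 0L)
  }
  mol <- perceive_aromaticity(mol)
  validate_mol(mol)
  list(mol = mol, coords = coords)
}

arom_atom_flags <- function(na, a, b, arom) {
  fl <- logical(na)
  fl[c(a[arom], b[arom])] <- TRUE
  fl
}

#' Write a molecule (+ optional conformer) as a MOL block
#'
#' @param mol a `mol_graph`
#' @param coords optional n x 3 coordinate matrix (default all-zero 2D stub)
#' @return character scalar (the block, newline-joined, no trailing `$$$$`)
#' @export
write_molblock <- function(mol, coords = NULL) {
  n <- n_atoms(mol); nb <- nrow(mol$bonds)
  if (is.null(coords)) coords <- matrix(0, n, 3L)
  stopifnot(nrow(coords) == n)
  header <- c(if (nzchar(mol$name)) mol$name else "mol",
              "  rxngrow", "",
              sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000", n, nb))
  atom_lines <- vapply(seq_len(n), function(i) {
    sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0%3d  0  0",
            coords[i, 1L], coords[i, 2L], coords[i, 3L],
            mol$atoms$element[i], mol$atoms$map[i])
  }, "")
  bond_lines <- if (nb) vapply(seq_len(nb), function(i) {
    sprintf("%3d%3d%3d  0", mol$bonds$a[i], mol$bonds$b[i], mol$bonds$order[i])
  }, "") else character(0)
  chg <- which(mol$atoms$charge != 0L)
  chg_lines <- if (length(chg)) {
    vapply(split(chg, ceiling(seq_along(chg) / 8)), function(grp) {
      paste0("M  CHG", sprintf("%3d", length(grp)),
             paste0(sprintf("%4d%4d", grp, mol$atoms$charge[grp]), collapse = ""))
    }, "")
  } else character(0)
  paste(c(header, atom_lines, bond_lines, chg_lines, "M  END"), collapse = "\n")
}

#' Read an SDF file
#'
#' @param path file path
#' @return list of records: each list(mol, coords, props = named character)
#' @export
read_sdf <- function(path) {
  lines <- readLines(path, warn = FALSE)
  ends <- grep("^\\$\\$\\$\\$", lines)
  starts <- c(1L, head(ends, -1L) + 1L)
  if (!length(ends)) { starts <- 1L; ends <- length(lines) + 1L }
  out <- list()
  for (k in seq_along(starts)) {
    blk <- lines[starts[k]:(ends[k] - 1L)]
    if (!length(blk) || all(!nzchar(trimws(blk)))) next
    mend <- grep("^M  END", blk)[1L]
    rec <- parse_molblock(blk[seq_len(mend)])
    props <- list()
    prop_lines <- blk[-seq_len(mend)]
    tag_at <- grep("^> *<", prop_lines)
    for (t in tag_at) {
      tag <- sub("^> *<([^>]+)>.*$", "\\1", prop_lines[t])
      val <- character(0); j <- t + 1L
      while (j <= length(prop_lines) && nzchar(trimws(prop_lines[j]))) {
        val <- c(val, prop_lines[j]); j <- j + 1L
      }
      props[[tag]] <- paste(val, collapse = "\n")
    }
    rec$props <- props
    out[[length(out) + 1L]] <- rec
  }
  out
}

#' Write records to an SDF file
#'
#' @param records list of list(mol, coords = NULL, props = named list)
#' @param path output file
#' @export
write_sdf <- function(records, path) {
  con <- file(path, "w"); on.exit(close(con))
  for (rec in records) {
    writeLines(write_molblock(rec$mol, rec$coords), con)
    for (tag in names(rec$props %||% list())) {
      writeLines(sprintf(">  <%s>", tag), con)
      writeLines(as.character(rec$props[[tag]]), con)
      writeLines("", con)
    }
    writeLines("$$$$", con)
  }
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
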