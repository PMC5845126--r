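# SMILES reader/writer with the atom-map extension.
#
# Supported: organic subset + bracket atoms (charge, explicit H, atom map),
# aromatic lowercase, branches, ring closures (incl. %nn), explicit bond
# symbols - = # :, dot-separated fragments.  Stereo markers (@, /, \) are
# parsed and dropped; isotopes are parsed and dropped.  Aromatic input is
# kekulized at parse time; Kekule input is aromatized by the pinned
# perception model (see rings.R), so both spellings of a ring meet in the
# same internal form.

#' Parse a (possibly dot-separated) SMILES into molecules
#'
#' @param text SMILES string
#' @param name optional name attached to each molecule
#' @return list of `mol_graph`
#' @export
parse_smiles_multi <- function(text, name = "") {
  text <- trimws(text)
  if (!nzchar(text)) stop_format("empty SMILES string")
  st <- smiles_tokens_to_graph(text)
  frag <- st$fragment
  lapply(sort(unique(frag)), function(f) {
    idx <- which(frag == f)
    finish_parsed_molecule(st, idx, name)
  })
}

#' Parse a single-molecule SMILES
#'
#' @param text SMILES string (must encode one connected structure; use
#'   [parse_smiles_multi()] for dot-separated inputs)
#' @param name optional molecule name
#' @return a `mol_graph`
#' @export
parse_smiles <- function(text, name = "") {
  mols <- parse_smiles_multi(text, name)
  if (length(mols) != 1L)
    stop_format("expected a single molecule, got ", length(mols),
                " dot-separated fragments")
  mols[[1L]]
}

# ---- tokenizer/graph builder ----------------------------------------------

smiles_tokens_to_graph <- function(text) {
  chars <- strsplit(text, "", fixed = TRUE)[[1L]]
  n <- length(chars)
  atoms <- list()           # each: list(element, arom, charge, h (NA=implicit), map)
  bonds <- list()           # each: list(a, b, sym)
  frag_of <- integer(0)     # fragment id per atom
  prev <- NA_integer_
  pending <- ""             # pending bond symbol
  stack <- integer(0)
  ring_open <- list()       # digit -> list(atom, sym)
  frag <- 1L
  i <- 1L

  add_atom <- function(a) {
    atoms[[length(atoms) + 1L]] <<- a
    frag_of[length(atoms)] <<- frag
    idx <- length(atoms)
    if (!is.na(prev)) bonds[[length(bonds) + 1L]] <<- list(a = prev, b = idx, sym = pending)
    pending <<- ""
    prev <<- idx
    idx
  }

  while (i <= n) {
    ch <- chars[i]
    if (ch == "[") {
      j <- i
      while (j <= n && chars[j] != "]") j <- j + 1L
      if (j > n) stop_format("unclosed bracket atom at position ", i)
      body <- paste(chars[(i + 1L):(j - 1L)], collapse = "")
      add_atom(parse_bracket_atom(body))
      i <- j + 1L
    } else if (ch %in% c("-", "=", "#", ":", "/", "\\")) {
      pending <- switch(ch, "/" = "-", "\\" = "-", ch)
      i <- i + 1L
    } else if (ch == "(") {
      stack <- c(stack, prev); i <- i + 1L
    } else if (ch == ")") {
      if (!length(stack)) stop_format("unbalanced ')' at position ", i)
      prev <- stack[length(stack)]; stack <- stack[-length(stack)]
      i <- i + 1L
    } else if (ch == ".") {
      frag <- frag + 1L; prev <- NA_integer_; pending <- ""
      i <- i + 1L
    } else if (grepl("[0-9]", ch) || ch == "%") {
      if (ch == "%") {
        if (i + 2L > n) stop_format("truncated %nn ring closure")
        num <- paste(chars[(i + 1L):(i + 2L)], collapse = ""); i <- i + 3L
      } else { num <- ch; i <- i + 1L }
      if (is.na(prev)) stop_format("ring closure before any atom")
      if (is.null(ring_open[[num]])) {
        ring_open[[num]] <- list(atom = prev, sym = pending)
        pending <- ""
      } else {
        op <- ring_open[[num]]; ring_open[[num]] <- NULL
        sym <- if (nzchar(pending)) pending else op$sym
        if (nzchar(op$sym) && nzchar(pending) && op$sym != pending)
          stop_format("conflicting bond symbols on ring closure ", num)
        bonds[[length(bonds) + 1L]] <- list(a = op$atom, b = prev, sym = sym)
        pending <- ""
      }
    } else if (grepl("[A-Za-z*]", ch)) {
      two <- if (i < n) paste0(ch, chars[i + 1L]) else ""
      if (two %in% c("Cl", "Br")) {
        add_atom(list(element = two, arom = FALSE, charge = 0L, h = NA_integer_, map = 0L))
        i <- i + 2L
      } else if (ch %in% c("B", "C", "N", "O", "P", "S", "F", "I")) {
        add_atom(list(element = ch, arom = FALSE, charge = 0L, h = NA_integer_, map = 0L))
        i <- i + 1L
      } else if (ch %in% c("b", "c", "n", "o", "p", "s")) {
        add_atom(list(element = toupper(ch), arom = TRUE, charge = 0L,
                      h = NA_integer_, map = 0L))
        i <- i + 1L
      } else stop_format("unexpected token '", ch, "' at position ", i)
    } else stop_format("unexpected character '", ch, "' at position ", i)
  }
  if (length(stack)) stop_format("unbalanced '(' in SMILES")
  if (length(ring_open)) stop_format("unclosed ring bond(s): ",
                                     paste(names(ring_open), collapse = ", "))
  list(atoms = atoms, bonds = bonds, fragment = frag_of)
}

parse_bracket_atom <- function(body) {
  m <- regmatches(body, regexec(
    "^([0-9]*)([A-Za-z][a-z]?|\\*)(@{0,2})(H[0-9]*)?([+-][0-9]*|\\+{2,}|-{2,})?(:([0-9]+))?$",
    body))[[1L]]
  if (!length(m)) stop_format("cannot parse bracket atom '[", body, "]'")
  sym <- m[3L]
  arom <- sym %in% c("b", "c", "n", "o", "p", "s", "se", "as")
  element <- if (arom) paste0(toupper(substr(sym, 1, 1)), substring(sym, 2)) else sym
  if (element == "*") stop_format("wildcard atoms are not supported")
  h <- if (nzchar(m[5L])) {
    if (m[5L] == "H") 1L else as.integer(substring(m[5L], 2L))
  } else 0L
  chg <- 0L
  if (nzchar(m[6L])) {
    cs <- m[6L]
    if (grepl("^\\++$", cs)) chg <- nchar(cs)
    else if (grepl("^-+$", cs)) chg <- -nchar(cs)
    else chg <- as.integer(paste0(substr(cs, 1, 1),
                                  if (nchar(cs) > 1L) substring(cs, 2L) else "1"))
  }
  map <- if (nzchar(m[8L])) as.integer(m[8L]) else 0L
  list(element = element, arom = arom, charge = chg, h = h, map = map,
       bracket = TRUE)
}

# assemble one fragment into a validated mol_graph
finish_parsed_molecule <- function(st, idx, name) {
  sel <- st$atoms[idx]
  newpos <- integer(length(st$fragment)); newpos[idx] <- seq_along(idx)
  atoms <- data.frame(
    element = vapply(sel, `[[`, "", "element"),
    charge = vapply(sel, `[[`, 0L, "charge"),
    arom = vapply(sel, `[[`, FALSE, "arom"),
    hcount = vapply(sel, function(a) if (is.na(a$h)) 0L else a$h, 0L),
    map = vapply(sel, `[[`, 0L, "map"),
    stringsAsFactors = FALSE
  )
  declared <- !vapply(sel, function(a) is.na(a$h), FALSE)
  bl <- Filter(function(b) b$a %in% idx, st$bonds)
  bonds <- if (length(bl)) data.frame(
    a = newpos[vapply(bl, `[[`, 0L, "a")],
    b = newpos[vapply(bl, `[[`, 0L, "b")],
    sym = vapply(bl, `[[`, "", "sym"),
    stringsAsFactors = FALSE
  ) else data.frame(a = integer(), b = integer(), sym = character())
  if (nrow(bonds)) {
    both_arom <- atoms$arom[bonds$a] & atoms$arom[bonds$b]
    bonds$order <- ifelse(bonds$sym == "=", 2L, ifelse(bonds$sym == "#", 3L, 1L))
    bonds$arom <- (bonds$sym == ":") | (bonds$sym == "" & both_arom)
    bonds$sym <- NULL
  } else {
    bonds$order <- integer(); bonds$arom <- logical(); bonds$sym <- NULL
  }
  mol <- mol_graph(atoms, bonds, name = name, validate = FALSE)

  # which aromatic atoms still need a double bond (see rings.R header)
  deg <- degrees(mol)
  needs <- logical(n_atoms(mol))
  for (v in which(mol$atoms$arom)) {
    el <- mol$atoms$element[v]
    has_exo_double <- any((mol$bonds$a == v | mol$bonds$b == v) &
                            mol$bonds$order == 2L & !mol$bonds$arom)
    if (has_exo_double) { needs[v] <- FALSE; next }
    sigma <- deg[v] + if (declared[v]) mol$atoms$hcount[v] else 0L
    av <- allowed_valences(el, mol$atoms$charge[v])
    if (is.null(av)) next
    vmin <- if (any(av >= sigma)) min(av[av >= sigma]) else max(av)
    needs[v] <- if (el == "C" && !declared[v]) deg[v] < 4L else sigma == vmin - 1L
  }
  mol <- kekulize_aromatic(mol, needs)

  # implicit hydrogens for non-bracket atoms
  bsum <- integer(n_atoms(mol))
  for (i in seq_len(nrow(mol$bonds))) {
    bd <- mol$bonds[i, ]
    bsum[bd$a] <- bsum[bd$a] + bd$order
    bsum[bd$b] <- bsum[bd$b] + bd$order
  }
  for (v in which(!declared)) {
    av <- allowed_valences(mol$atoms$element[v], mol$atoms$charge[v])
    if (is.null(av)) { mol$atoms$hcount[v] <- 0L; next }
    vmin <- if (any(av >= bsum[v])) min(av[av >= bsum[v]]) else max(av)
    mol$atoms$hcount[v] <- max(vmin - bsum[v], 0L)
  }
  mol <- perceive_aromaticity(mol)
  validate_mol(mol)
  mol
}

# ---- writer ----------------------------------------------------------------

#' Write a molecule as SMILES
#'
#' Emits aromatic atoms in lowercase with implicit aromatic bonds; brackets
#' are used whenever charge, atom map, unusual element or a non-default
#' hydrogen count requires them.  Round trip through [parse_smiles()] is
#' graph-isomorphic.
#'
#' @param mol a `mol_graph`
#' @param keep_maps write atom-map numbers (default TRUE)
#' @return SMILES string
#' @export
write_smiles <- function(mol, keep_maps = TRUE) {
  n <- n_atoms(mol)
  if (!n) return("")
  adj <- adjacency(mol)
  bidx <- bond_index(mol)
  deg <- degrees(mol)

  bsum <- integer(n)
  for (i in seq_len(nrow(mol$bonds))) {
    bd <- mol$bonds[i, ]
    bsum[bd$a] <- bsum[bd$a] + bd$order
    bsum[bd$b] <- bsum[bd$b] + bd$order
  }

  atom_token <- function(v) {
    el <- mol$atoms$element[v]; ar <- mol$atoms$arom[v]
    chg <- mol$atoms$charge[v]; h <- mol$atoms$hcount[v]
    map <- if (keep_maps) mol$atoms$map[v] else 0L
    sym <- if (ar) tolower(el) else el
    av <- allowed_valences(el, chg)
    default_h <- if (is.null(av)) 0L else {
      if (ar && !el %in% c("C")) 0L  # lowercase heteroatoms imply 0 H
      else {
        vmin <- if (any(av >= bsum[v])) min(av[av >= bsum[v]]) else max(av)
        max(vmin - bsum[v], 0L)
      }
    }
    need_br <- chg != 0L || map > 0L || !el %in% .ORGANIC_SUBSET ||
      h != default_h
    if (!need_br) return(sym)
    paste0("[", sym,
           if (h == 1L) "H" else if (h > 1L) paste0("H", h) else "",
           if (chg > 0L) paste0("+", if (chg > 1L) chg else "") else "",
           if (chg < 0L) paste0("-", if (chg < -1L) -chg else "") else "",
           if (map > 0L) paste0(":", map) else "",
           "]")
  }

  bond_token <- function(bi, from, to) {
    if (mol$bonds$arom[bi]) return("")
    ord <- mol$bonds$order[bi]
    if (ord == 2L) return("=")
    if (ord == 3L) return("#")
    if (mol$atoms$arom[from] && mol$atoms$arom[to]) return("-")
    ""
  }

  visited <- logical(n)
  ring_num <- 0L
  ring_at <- replicate(n, character(0), simplify = FALSE)  # closure digits per atom
  tree_edge <- matrix(FALSE, 1, 1)
  in_tree <- logical(nrow(mol$bonds) + 1L)
  # first pass: DFS to classify tree vs ring-closure bonds and assign digits
  closures <- list()
  order_visit <- integer(0)
  dfs1 <- function(v, parent_bond) {
    visited[v] <<- TRUE
    for (w in adj[[v]]) {
      bi <- bidx[[paste(min(v, w), max(v, w))]]
      if (bi == parent_bond) next
      if (visited[w]) {
        if (!in_tree[bi] && is.null(closures[[as.character(bi)]])) {
          ring_num <<- ring_num + 1L
          closures[[as.character(bi)]] <<- ring_num
        }
      } else {
        in_tree[bi] <<- TRUE
        dfs1(w, bi)
      }
    }
  }
  out <- character(0)
  emit <- function(v, parent_bond) {
    visited[v] <<- TRUE
    piece <- atom_token(v)
    # ring closure digits on this atom
    for (w in adj[[v]]) {
      bi <- bidx[[paste(min(v, w), max(v, w))]]
      cl <- closures[[as.character(bi)]]
      if (!is.null(cl) && !in_tree[bi]) {
        numtok <- if (cl > 9L) paste0("%", cl) else as.character(cl)
        sym <- if (visited[w]) "" else bond_token(bi, v, w)
        piece <- paste0(piece, sym, numtok)
      }
    }
    kids <- Filter(function(w) {
      bi <- bidx[[paste(min(v, w), max(v, w))]]
      in_tree[bi] && !visited[w]
    }, adj[[v]])
    parts <- character(0)
    for (k in seq_along(kids)) {
      w <- kids[[k]]
      if (visited[w]) next
      bi <- bidx[[paste(min(v, w), max(v, w))]]
      sub <- paste0(bond_token(bi, v, w), emit(w, bi))
      parts <- c(parts, sub)
    }
    if (length(parts) > 1L)
      piece <- paste0(piece,
                      paste0("(", parts[-length(parts)], ")", collapse = ""),
                      parts[length(parts)])
    else if (length(parts) == 1L) piece <- paste0(piece, parts)
    piece
  }

  pieces <- character(0)
  comp <- mol_components(mol)
  for (f in sort(unique(comp))) {
    root <- which(comp == f)[1L]
    visited[] <- FALSE
    # keep closures/in_tree across both passes but reset visitation
    dfs1(root, 0L)
    visited[] <- visited & FALSE
    # re-run visitation for already-handled components
    done <- comp != f & seq_len(n) %in% order_visit
    visited[done] <- TRUE
    pieces <- c(pieces, emit(root, 0L))
    order_visit <- c(order_visit, which(comp == f))
  }
  paste(pieces, collapse = ".")
}
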