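# Atom-mapped reactions: parsing and map-consistency checks.

#' Construct / parse an atom-mapped reaction
#'
#' Reaction SMILES `reactants >> products` (an agents field
#' `reactants > agents > products` is tolerated and the agents ignored).
#' Every atom-map number on the product side must also occur on the reactant
#' side; reactant maps missing from the products are leaving atoms.
#'
#' @param text reaction SMILES with atom maps
#' @param name reaction name
#' @return object of class `mapped_reaction`: list(reactants, products, name)
#' @export
parse_reaction_smiles <- function(text, name = "") {
  parts <- strsplit(text, ">", fixed = TRUE)[[1L]]
  if (!length(parts) %in% c(2L, 3L))
    stop_format("reaction SMILES must have 2 or 3 '>'-separated fields")
  lhs <- parts[1L]; rhs <- parts[length(parts)]
  rxn <- mapped_reaction(parse_smiles_multi(lhs), parse_smiles_multi(rhs), name)
  rxn
}

#' @rdname parse_reaction_smiles
#' @param reactants,products lists of `mol_graph`
#' @export
mapped_reaction <- function(reactants, products, name = "") {
  rxn <- structure(list(reactants = reactants, products = products, name = name),
                   class = "mapped_reaction")
  check_reaction_maps(rxn)
  rxn
}

#' @export
print.mapped_reaction <- function(x, ...) {
  cat(sprintf("<mapped_reaction %s: %d reactant(s) >> %d product(s)>\n",
              x$name, length(x$reactants), length(x$products)))
  invisible(x)
}

side_maps <- function(mols) {
  unlist(lapply(mols, function(m) m$atoms$map[m$atoms$map > 0L]), use.names = FALSE)
}

check_reaction_maps <- function(rxn) {
  rm_ <- side_maps(rxn$reactants); pm <- side_maps(rxn$products)
  if (anyDuplicated(rm_))
    stop_format("atom map used twice on the reactant side: ",
                paste(unique(rm_[duplicated(rm_)]), collapse = ", "))
  if (anyDuplicated(pm))
    stop_format("atom map used twice on the product side: ",
                paste(unique(pm[duplicated(pm)]), collapse = ", "))
  orphan <- setdiff(pm, rm_)
  if (length(orphan))
    stop_format("product atom map(s) with no reactant partner: ",
                paste(orphan, collapse = ", "))
  invisible(rxn)
}

#' Write a reaction as mapped reaction SMILES
#' @param rxn a `mapped_reaction`
#' @export
write_reaction_smiles <- function(rxn) {
  paste0(paste(vapply(rxn$reactants, write_smiles, ""), collapse = "."),
         ">>",
         paste(vapply(rxn$products, write_smiles, ""), collapse = "."))
}

#' Read a tab-separated reaction file (one mapped reaction SMILES + name per line)
#' @param path file path
#' @return list of `mapped_reaction`
#' @export
read_reaction_file <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  lapply(lines, function(ln) {
    f <- strsplit(ln, "\t", fixed = TRUE)[[1L]]
    parse_reaction_smiles(f[1L], name = if (length(f) > 1L) f[2L] else "")
  })
}
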