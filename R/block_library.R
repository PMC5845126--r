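# Building-block library and the rule database (rules + per-slot block
# index), with JSON persistence.

#' Construct a building block / read a library
#'
#' @param id unique identifier
#' @param mol a `mol_graph` (or SMILES string)
#' @param provenance free-text source note
#' @return a `building_block`
#' @export
building_block <- function(id, mol, provenance = "") {
  if (is.character(mol)) mol <- parse_smiles(mol, name = id)
  structure(list(id = id, mol = mol, provenance = provenance),
            class = "building_block")
}

#' Read a block library from a SMILES file (`SMILES<TAB>id`) or an SDF
#' (ids from the `id` property or the molecule name)
#' @param path file path
#' @return list of `building_block`
#' @export
read_block_library <- function(path) {
  if (grepl("\\.sdf$", path, ignore.case = TRUE)) {
    recs <- read_sdf(path)
    blocks <- lapply(seq_along(recs), function(i) {
      id <- recs[[i]]$props$id %||%
        (if (nzchar(recs[[i]]$mol$name)) recs[[i]]$mol$name else paste0("B", i))
      building_block(id, recs[[i]]$mol, provenance = path)
    })
  } else {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
    blocks <- lapply(seq_along(lines), function(i) {
      f <- strsplit(lines[i], "\t", fixed = TRUE)[[1L]]
      id <- if (length(f) > 1L) f[2L] else paste0("B", i)
      building_block(id, f[1L], provenance = path)
    })
  }
  ids <- vapply(blocks, `[[`, "", "id")
  if (anyDuplicated(ids))
    stop_format("duplicate building-block id(s): ",
                paste(unique(ids[duplicated(ids)]), collapse = ", "))
  blocks
}

#' Seed blocks: library members containing the preserved fragment
#'
#' Plain 2D substructure containment (all pattern atoms open), ordered by
#' ascending heavy-atom count so the smallest viable seed is tried first.
#'
#' @param frag a `preserved_fragment` (see [preserved_fragment()]) or a
#'   `mol_graph` pattern
#' @param library list of `building_block`
#' @return list of `building_block` (possibly empty)
#' @export
find_seed_blocks <- function(frag, library) {
  pattern <- if (inherits(frag, "preserved_fragment")) frag$pattern else frag
  hits <- Filter(function(b) has_substructure(pattern, b$mol), library)
  hits[order(vapply(hits, function(b) n_atoms(b$mol), 0L),
             vapply(hits, `[[`, "", "id"), method = "radix")]
}

#' The user-designated preserved fragment with its reference pose
#'
#' @param pattern connected `mol_graph` fragment (or SMILES)
#' @param reference_coords n x 3 matrix, Angstrom, as posed in the query
#' @return a `preserved_fragment`
#' @export
preserved_fragment <- function(pattern, reference_coords) {
  if (is.character(pattern)) pattern <- parse_smiles(pattern)
  reference_coords <- as.matrix(reference_coords)
  if (nrow(reference_coords) != n_atoms(pattern) || ncol(reference_coords) != 3L)
    stop_format("reference_coords must be ", n_atoms(pattern), " x 3")
  if (any(!is.finite(reference_coords)))
    stop_format("non-finite reference coordinates")
  structure(list(pattern = pattern, reference_coords = reference_coords),
            class = "preserved_fragment")
}

#' Build a rule database from reactions and a block library
#'
#' Extracts one rule per reaction, rejects ter-molecular rules (>2 reactant
#' moieties), and indexes, for every (rule, slot), the blocks containing that
#' slot's moiety as a substructure.
#'
#' @param reactions list of `mapped_reaction`
#' @param library list of `building_block`
#' @return a `rule_db`: list(rules, block_index, reactions)
#' @export
build_rule_db <- function(reactions, library = list()) {
  rules <- list()
  kept_rxn <- list()
  for (i in seq_along(reactions)) {
    rxn <- reactions[[i]]
    id <- if (nzchar(rxn$name)) rxn$name else paste0("R", i)
    rule <- build_rule(rxn, id = id)
    if (length(rule$reactant_moieties) > 2L)
      stop_chem("rule '", id, "' is ter-molecular (",
                length(rule$reactant_moieties),
                " reactant moieties); only uni/bimolecular rules are supported")
    rules[[length(rules) + 1L]] <- rule
    kept_rxn[[length(kept_rxn) + 1L]] <- rxn
  }
  ids <- vapply(rules, `[[`, "", "id")
  if (anyDuplicated(ids))
    stop_format("duplicate rule id(s): ",
                paste(unique(ids[duplicated(ids)]), collapse = ", "))
  db <- structure(list(rules = rules, block_index = NULL,
                       reactions = kept_rxn), class = "rule_db")
  index_blocks(db, library)
}

#' @rdname build_rule_db
#' @param db a `rule_db`
#' @export
index_blocks <- function(db, library) {
  idx <- list()
  for (rule in db$rules) {
    slots <- lapply(seq_along(rule$reactant_moieties), function(s) {
      mo <- rule$reactant_moieties[[s]]
      hit <- vapply(library, function(b)
        has_substructure(mo$pattern, b$mol, open = mo$open), FALSE)
      vapply(library[hit], `[[`, "", "id")
    })
    idx[[rule$id]] <- slots
  }
  db$block_index <- idx
  db
}

#' @export
print.rule_db <- function(x, ...) {
  cat(sprintf("<rule_db: %d rule(s)%s>\n", length(x$rules),
              if (!is.null(x$block_index)) ", block index built" else ""))
  invisible(x)
}

#' Participant blocks for a rule's reactant-moiety slot
#'
#' @param rule a `reaction_rule` (or its id)
#' @param slot moiety position (1-based)
#' @param db a `rule_db` with a block index
#' @param library the library the index was built from
#' @return list of `building_block`
#' @export
participants_for_slot <- function(rule, slot, db, library) {
  id <- if (is.character(rule)) rule else rule$id
  entry <- db$block_index[[id]]
  if (is.null(entry)) stop_format("rule '", id, "' is not indexed")
  if (slot < 1L || slot > length(entry)) stop_format("invalid slot ", slot)
  ids <- entry[[slot]]
  library[vapply(library, `[[`, "", "id") %in% ids]
}

# ---- persistence -----------------------------------------------------------

#' Save / load a rule database as JSON
#'
#' Rules are persisted as mapped reaction SMILES plus a sidecar of moiety
#' atom maps and open positions (by map number, so the text is
#' order-independent and auditable); the block index rides along as id lists.
#'
#' @param db a `rule_db`
#' @param path JSON file path
#' @export
write_rule_db <- function(db, path) {
  ser_moiety <- function(mo) list(
    smiles = write_smiles(mo$pattern),
    maps = mo$pattern$atoms$map,
    open_maps = mo$pattern$atoms$map[mo$open])
  obj <- list(
    reactions = lapply(db$reactions, function(r)
      list(smiles = write_reaction_smiles(r), name = r$name)),
    rules = lapply(db$rules, function(rl) list(
      id = rl$id,
      reactant_moieties = lapply(rl$reactant_moieties, ser_moiety),
      product_moiety = ser_moiety(rl$product_moiety))),
    block_index = db$block_index)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = 8, pretty = TRUE)
  invisible(path)
}

#' @rdname write_rule_db
#' @export
read_rule_db <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  reactions <- lapply(obj$reactions, function(r)
    parse_reaction_smiles(r$smiles, name = r$name))
  db <- build_rule_db(reactions, library = list())
  db$block_index <- lapply(obj$block_index, function(slots)
    lapply(slots, function(s) as.character(unlist(s))))
  db
}
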