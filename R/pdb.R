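# Receptor model: a typed point cloud read from PDB ATOM/HETATM records or
# from a fixtures JSON.  Only heavy atoms are kept.  Interaction typing is a
# small residue/atom-name rule table (or supplied explicitly), sufficient for
# the built-in scorer; it is not a full protonation model.

#' Construct a receptor
#'
#' @param atoms data.frame with columns `element`, `x`, `y`, `z`,
#'   `resname`, `resnum`, `chain`, `atom_name`
#' @param donors,acceptors,hydrophobic integer atom indices (1-based into
#'   `atoms`); derived by [type_receptor_sites()] when omitted
#' @return object of class `receptor`
#' @export
receptor <- function(atoms, donors = NULL, acceptors = NULL, hydrophobic = NULL) {
  atoms <- as.data.frame(atoms, stringsAsFactors = FALSE)
  stopifnot(all(c("element", "x", "y", "z") %in% names(atoms)))
  if (any(!is.finite(as.matrix(atoms[, c("x", "y", "z")]))))
    stop_format("non-finite receptor coordinates")
  for (col in c("resname", "resnum", "chain", "atom_name"))
    if (is.null(atoms[[col]])) atoms[[col]] <- ""
  r <- structure(list(atoms = atoms, donors = donors, acceptors = acceptors,
                      hydrophobic = hydrophobic), class = "receptor")
  if (is.null(donors) || is.null(acceptors) || is.null(hydrophobic))
    r <- type_receptor_sites(r)
  nr <- nrow(atoms)
  if (any(c(r$donors, r$acceptors, r$hydrophobic) > nr))
    stop_format("typed site references a nonexistent receptor atom")
  r
}

#' @export
print.receptor <- function(x, ...) {
  cat(sprintf("<receptor: %d atoms, %d donors, %d acceptors, %d hydrophobic>\n",
              nrow(x$atoms), length(x$donors), length(x$acceptors),
              length(x$hydrophobic)))
  invisible(x)
}

receptor_coords <- function(rec) as.matrix(rec$atoms[, c("x", "y", "z")])

#' Derive typed interaction sites from residue/atom-name rules
#'
#' Donors: backbone N; side-chain N of Lys/Arg/His/Trp/Asn/Gln; OH oxygens of
#' Ser/Thr/Tyr (donor and acceptor).  Acceptors: backbone O; side-chain O of
#' Asp/Glu/Asn/Gln/Ser/Thr/Tyr.  Hydrophobic: side-chain carbons of
#' Ala/Val/Leu/Ile/Phe/Met/Pro/Trp and generic C atoms of unknown residues.
#' @param rec a `receptor`
#' @return the receptor with `donors`, `acceptors`, `hydrophobic` filled
#' @export
type_receptor_sites <- function(rec) {
  a <- rec$atoms
  el <- a$element; rn <- toupper(a$resname); an <- toupper(a$atom_name)
  backbone_n <- el == "N" & an == "N"
  backbone_o <- el == "O" & an %in% c("O", "OXT")
  sc_n_donor <- el == "N" & rn %in% c("LYS", "ARG", "HIS", "TRP", "ASN", "GLN")
  oh <- el == "O" & rn %in% c("SER", "THR", "TYR") & an %in% c("OG", "OG1", "OH")
  sc_o_acc <- el == "O" & rn %in% c("ASP", "GLU", "ASN", "GLN")
  hydro <- el == "C" &
    (rn %in% c("ALA", "VAL", "LEU", "ILE", "PHE", "MET", "PRO", "TRP") |
       rn == "" | rn == "UNK") & !an %in% c("C", "CA")
  if (is.null(rec$donors)) rec$donors <- which(backbone_n | sc_n_donor | oh)
  if (is.null(rec$acceptors)) rec$acceptors <- which(backbone_o | sc_o_acc | oh)
  if (is.null(rec$hydrophobic)) rec$hydrophobic <- which(hydro)
  rec
}

#' Read a receptor from a PDB file
#'
#' Parses ATOM/HETATM records (heavy atoms; waters skipped), coordinates in
#' Angstrom.  Typed sites are derived from the rule table unless supplied.
#' @param path PDB file path
#' @return a `receptor`
#' @export
read_pdb <- function(path) {
  lines <- readLines(path, warn = FALSE)
  recs <- lines[grepl("^(ATOM  |HETATM)", lines)]
  if (!length(recs)) stop_format("no ATOM/HETATM records in ", path)
  atom_name <- trimws(substr(recs, 13L, 16L))
  resname <- trimws(substr(recs, 18L, 20L))
  chain <- trimws(substr(recs, 22L, 22L))
  resnum <- suppressWarnings(as.integer(substr(recs, 23L, 26L)))
  x <- as.numeric(substr(recs, 31L, 38L))
  y <- as.numeric(substr(recs, 39L, 46L))
  z <- as.numeric(substr(recs, 47L, 54L))
  element <- trimws(substr(recs, 77L, 78L))
  guess <- toupper(substr(gsub("^[0-9]", "", atom_name), 1L, 1L))
  element <- ifelse(nzchar(element), element, guess)
  element <- paste0(toupper(substr(element, 1L, 1L)),
                    tolower(substring(element, 2L)))
  keep <- element != "H" & resname != "HOH"
  receptor(data.frame(element = element, x = x, y = y, z = z,
                      resname = resname, resnum = resnum, chain = chain,
                      atom_name = atom_name,
                      stringsAsFactors = FALSE)[keep, , drop = FALSE])
}

#' Read/write a receptor as fixtures JSON
#'
#' The JSON carries the atom table plus explicit typed-site index lists, so a
#' synthetic pocket needs no residue rules.
#' @param path JSON path
#' @return a `receptor`
#' @export
read_receptor_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  receptor(as.data.frame(obj$atoms, stringsAsFactors = FALSE),
           donors = as.integer(obj$donors),
           acceptors = as.integer(obj$acceptors),
           hydrophobic = as.integer(obj$hydrophobic))
}

#' @rdname read_receptor_json
#' @param rec a `receptor`
#' @export
write_receptor_json <- function(rec, path) {
  jsonlite::write_json(list(atoms = rec$atoms, donors = rec$donors,
                            acceptors = rec$acceptors,
                            hydrophobic = rec$hydrophobic),
                       path, auto_unbox = FALSE, digits = 8)
  invisible(path)
}
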