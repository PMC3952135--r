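# Structure file input: mol2 ligands and PDB receptors. Parsing of the
# TRIPOS / PDB formats is delegated to bio3d; this layer validates the
# records, resolves alternate locations, and builds the package's typed
# ligand / receptor containers.

mol2_text_to_file <- function(x) {
  # accept a path, a single string with newlines, or a character vector of lines
  if (length(x) == 1 && !grepl("\n", x) && file.exists(x)) return(x)
  tf <- tempfile(fileext = ".mol2")
  writeLines(if (length(x) == 1) strsplit(x, "\n", fixed = TRUE)[[1]] else x, tf)
  tf
}

validate_mol2_records <- function(path) {
  lines <- readLines(path, warn = FALSE)
  sec <- rep(NA_character_, length(lines))
  cur <- NA_character_
  for (i in seq_along(lines)) {
    if (grepl("^@<TRIPOS>", lines[i])) cur <- sub("^@<TRIPOS>", "", trimws(lines[i]))
    sec[i] <- cur
  }
  for (need in c("MOLECULE", "ATOM", "BOND")) {
    if (!need %in% sec) stop("malformed mol2: missing @<TRIPOS>", need, " section")
  }
  body <- function(what) which(sec == what & !grepl("^@<TRIPOS>", lines) & nzchar(trimws(lines)))
  for (i in body("ATOM")) {
    f <- strsplit(trimws(lines[i]), "[[:space:]]+")[[1]]
    if (length(f) < 6 || anyNA(suppressWarnings(as.numeric(f[3:5]))))
      stop("malformed mol2 ATOM record at line ", i, ": '", lines[i], "'")
  }
  for (i in body("BOND")) {
    f <- strsplit(trimws(lines[i]), "[[:space:]]+")[[1]]
    if (length(f) < 4 || anyNA(suppressWarnings(as.integer(f[2:3]))))
      stop("malformed mol2 BOND record at line ", i, ": '", lines[i], "'")
  }
  invisible(lines)
}

mol2_element <- function(elety) {
  e <- sub("\\..*$", "", elety)
  # normalise case: first letter upper, rest lower (CL -> Cl)
  paste0(toupper(substr(e, 1, 1)), tolower(substr(e, 2, nchar(e))))
}

#' Parse a mol2 ligand
#'
#' Reads a TRIPOS mol2 document (file path, text, or character vector of
#' lines) into a `ligand` object: a typed atom table plus a bond table.
#' Partial charges are taken from the file when present; otherwise they are
#' set to zero with a warning (the electrostatic term then contributes
#' nothing). Atom types, hydrogen-bond roles and rotatable-bond flags are
#' assigned on the way in (see [detect_rotatable_bonds()]).
#'
#' @param x mol2 file path, document text, or lines.
#' @return an object of class `ligand`: `list(name, atoms, bonds)` where
#'   `atoms` has columns `index, name, element, x, y, z, charge, atom_type,
#'   hbond_role` and `bonds` has `a, b, mol2_type, order, rotatable`.
#' @export
parse_mol2 <- function(x) {
  path <- mol2_text_to_file(x)
  lines <- validate_mol2_records(path)
  # a charge column is optional in TRIPOS mol2; patch zeros in before the
  # parser so charge-less files load, and warn
  sec <- cumsum(grepl("^@<TRIPOS>", lines))
  atom_sec <- which(grepl("^@<TRIPOS>ATOM", lines))
  in_atom <- sec == sec[atom_sec[1]] & !grepl("^@<TRIPOS>", lines) &
    nzchar(trimws(lines))
  short <- in_atom & lengths(strsplit(trimws(lines), "[[:space:]]+")) < 9
  if (any(short)) {
    warning("mol2 file carries no partial charges; setting charges to zero")
    lines[short] <- paste(lines[short],
                          ifelse(lengths(strsplit(trimws(lines[short]),
                                                  "[[:space:]]+")) < 8,
                                 "LIG 0.000", "0.000"))
    path <- tempfile(fileext = ".mol2")
    writeLines(lines, path)
  }
  m <- bio3d::read.mol2(path)
  at <- m$atom
  charges <- suppressWarnings(as.numeric(at$charge))
  if (anyNA(charges)) {
    warning("mol2 file carries no partial charges; setting charges to zero")
    charges[is.na(charges)] <- 0
  }
  atoms <- data.frame(
    index = seq_len(nrow(at)),
    name = as.character(at$elena),
    element = mol2_element(as.character(at$elety)),
    x = as.numeric(at$x), y = as.numeric(at$y), z = as.numeric(at$z),
    charge = charges,
    mol2_type = as.character(at$elety),
    stringsAsFactors = FALSE)
  if (any(!is.finite(as.matrix(atoms[, c("x", "y", "z")]))))
    stop("non-finite coordinates in mol2 ATOM records")
  bt <- as.character(m$bond$type)
  bonds <- data.frame(
    a = as.integer(m$bond$origin),
    b = as.integer(m$bond$target),
    mol2_type = bt,
    order = ifelse(bt %in% c("1", "2", "3"), suppressWarnings(as.integer(bt)), 1L),
    stringsAsFactors = FALSE)
  if (any(bonds$a == bonds$b) || any(bonds$a < 1) || any(bonds$b < 1) ||
      any(bonds$a > nrow(atoms)) || any(bonds$b > nrow(atoms)))
    stop("invalid bond endpoints in mol2 BOND records")
  lig <- structure(list(name = m$name, atoms = atoms, bonds = bonds),
                   class = "ligand")
  g <- ligand_graph(lig)
  if (igraph::components(g)$no != 1)
    stop("ligand bond graph is disconnected (", igraph::components(g)$no,
         " components)")
  lig <- assign_atom_types(lig)
  detect_rotatable_bonds(lig)
}

#' Write a ligand to mol2
#'
#' Serialises a `ligand` back to TRIPOS mol2 (via bio3d). Used by the
#' synthetic-fixture generator and for round-trip checks.
#'
#' @param ligand a `ligand`.
#' @param path output file; when `NULL`, the mol2 text is returned as a
#'   character vector instead.
#' @return invisibly the path, or the mol2 lines when `path` is `NULL`.
#' @export
write_mol2 <- function(ligand, path = NULL) {
  a <- ligand$atoms
  n <- nrow(a)
  mol <- list(
    atom = data.frame(
      eleno = a$index, elena = a$name,
      x = a$x, y = a$y, z = a$z,
      elety = if (!is.null(a$mol2_type)) a$mol2_type else a$element,
      resno = 1, resid = "LIG", charge = a$charge,
      statbit = NA, stringsAsFactors = FALSE),
    bond = data.frame(
      id = seq_len(nrow(ligand$bonds)),
      origin = ligand$bonds$a, target = ligand$bonds$b,
      type = ligand$bonds$mol2_type, statbit = NA,
      stringsAsFactors = FALSE),
    substructure = NULL,
    xyz = as.numeric(t(as.matrix(a[, c("x", "y", "z")]))),
    info = c(n, nrow(ligand$bonds), 1, NA, NA),
    name = ligand$name)
  class(mol) <- "mol2"
  ret_text <- is.null(path)
  if (ret_text) path <- tempfile(fileext = ".mol2")
  bio3d::write.mol2(mol, file = path)
  if (ret_text) return(readLines(path, warn = FALSE))
  invisible(path)
}

# receptor-side table: element -> (atom_type, hbond_role). Protein structures
# usually lack hydrogens, so donor capability is approximated at the heavy
# atom: N treated as donor+acceptor, O and S as acceptors.
receptor_type_table <- function() {
  data.frame(
    element = c("C", "N", "O", "S", "P", "F", "Cl", "Br", "I"),
    atom_type = c("C", "NA", "OA", "SA", "P", "F", "Cl", "Br", "I"),
    hbond_role = c("none", "both", "acceptor", "acceptor", "none",
                   "acceptor", "none", "none", "none"),
    stringsAsFactors = FALSE)
}

#' Parse a PDB receptor
#'
#' Extracts the heavy atoms of a protein structure: ATOM and HETATM records
#' (waters excluded), hydrogens dropped, alternate locations resolved to the
#' highest-occupancy copy. Atom types and hydrogen-bond roles are assigned
#' from a fixed element table (no CONECT records are needed).
#'
#' @param x PDB file path, document text, or lines.
#' @return a data.frame of class `receptor` with columns
#'   `name, resid, resno, element, x, y, z, charge, atom_type, hbond_role`.
#' @export
parse_pdb_receptor <- function(x) {
  path <- if (length(x) == 1 && !grepl("\n", x) && file.exists(x)) x else {
    tf <- tempfile(fileext = ".pdb")
    writeLines(if (length(x) == 1) strsplit(x, "\n", fixed = TRUE)[[1]] else x, tf)
    tf
  }
  p <- suppressWarnings(bio3d::read.pdb(path, rm.alt = FALSE))
  at <- p$atom
  if (is.null(at) || nrow(at) == 0) stop("empty structure: no ATOM/HETATM records")
  at <- at[!(at$resid %in% c("HOH", "WAT", "DOD")), , drop = FALSE]
  elem <- trimws(at$elesy)
  elem[is.na(elem) | elem == ""] <- substr(trimws(at$elety[is.na(elem) | elem == ""]), 1, 1)
  elem <- paste0(toupper(substr(elem, 1, 1)), tolower(substr(elem, 2, nchar(elem))))
  at$element <- elem
  at <- at[at$element != "H" & at$element != "D", , drop = FALSE]
  if (nrow(at) == 0) stop("empty structure: no heavy atoms after filtering")
  # alternate locations: keep highest occupancy within (chain, resno, insert, name)
  key <- paste(at$chain, at$resno, at$insert, at$elety, sep = "|")
  occ <- at$o; occ[is.na(occ)] <- 1
  keep <- unlist(lapply(split(seq_len(nrow(at)), key), function(idx) {
    idx[which.max(occ[idx])]
  }), use.names = FALSE)
  at <- at[sort(keep), , drop = FALSE]
  tab <- receptor_type_table()
  mi <- match(at$element, tab$element)
  if (anyNA(mi)) {
    bad <- which(is.na(mi))[1]
    stop("receptor atom of unknown type: atom '", at$elety[bad], "' (",
         at$resid[bad], " ", at$resno[bad], "), element '", at$element[bad], "'")
  }
  out <- data.frame(
    name = trimws(at$elety), resid = at$resid, resno = at$resno,
    element = at$element,
    x = at$x, y = at$y, z = at$z,
    charge = 0,
    atom_type = tab$atom_type[mi], hbond_role = tab$hbond_role[mi],
    stringsAsFactors = FALSE)
  class(out) <- c("receptor", "data.frame")
  out
}

#' Ligand coordinates as a matrix
#' @param ligand a `ligand`.
#' @return n x 3 numeric matrix (Angstrom).
#' @export
ligand_coords <- function(ligand) {
  unname(as.matrix(ligand$atoms[, c("x", "y", "z")]))
}

#' @export
print.ligand <- function(x, ...) {
  cat("ligand '", x$name, "': ", nrow(x$atoms), " atoms (",
      sum(x$atoms$element != "H"), " heavy), ", nrow(x$bonds), " bonds, ",
      sum(x$bonds$rotatable), " rotatable\n", sep = "")
  invisible(x)
}
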