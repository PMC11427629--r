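# PDB-format structure parsing and the AtomicStructure container.

#' Load an atomic structure from PDB-format text
#'
#' Parses fixed-column `ATOM`/`HETATM` records into an `AtomicStructure`.
#' Water molecules (HOH/WAT/DOD) are excluded. Van der Waals radii are
#' assigned from `radius_table` keyed by element; any hydrogen whose table
#' radius is 0 receives the 0.6 A floor used for force-field parameter sets
#' that give polar hydrogens zero radius. Simplified partial charges are
#' assigned from the packaged charge table unless `charges` is supplied.
#'
#' @param pdb Path to a PDB file, or a character vector of PDB-format lines.
#' @param radius_table Named numeric vector of radii (A) keyed by element or
#'   atom name; defaults to [default_radius_table()].
#' @param charges Optional numeric vector of per-atom partial charges (e),
#'   recycled against the parsed atoms.
#' @return An object of class `AtomicStructure`: a list with `atoms` (a
#'   data.frame with serial, name, element, resname, resno, chain, x, y, z,
#'   radius, charge), `chains`, and `residue` (atom -> residue index, where
#'   residues are unique chain/resno/resname combinations in order of first
#'   appearance).
#' @export
load_structure <- function(pdb, radius_table = default_radius_table(),
                           charges = NULL) {
  lines <- if (length(pdb) == 1L && !grepl("\n", pdb) && file.exists(pdb)) {
    readLines(pdb, warn = FALSE)
  } else {
    unlist(strsplit(pdb, "\n", fixed = TRUE))
  }
  rec <- substr(lines, 1, 6)
  keep <- which(rec %in% c("ATOM  ", "HETATM"))
  if (length(keep) == 0L) stop("no ATOM/HETATM records found")

  fld <- function(l, a, b) trimws(substr(l, a, b))
  num <- function(l, a, b, what, idx) {
    s <- fld(l, a, b)
    v <- suppressWarnings(as.numeric(s))
    bad <- which(is.na(v) | s == "")
    if (length(bad)) {
      stop(sprintf("malformed %s in PDB record at line %d: '%s'",
                   what, idx[bad[1]], lines[idx[bad[1]]]))
    }
    v
  }

  l <- lines[keep]
  atoms <- data.frame(
    serial = num(l, 7, 11, "serial", keep),
    name = fld(l, 13, 16),
    altloc = fld(l, 17, 17),
    resname = fld(l, 18, 20),
    chain = fld(l, 22, 22),
    resno = num(l, 23, 26, "residue number", keep),
    x = num(l, 31, 38, "coordinate", keep),
    y = num(l, 39, 46, "coordinate", keep),
    z = num(l, 47, 54, "coordinate", keep),
    element = toupper(fld(l, 77, 78)),
    stringsAsFactors = FALSE)

  # element fallback from the atom name when columns 77-78 are blank
  blank <- atoms$element == ""
  if (any(blank)) {
    nm <- gsub("[0-9']", "", atoms$name[blank])
    atoms$element[blank] <- toupper(substr(nm, 1, 1))
  }
  atoms <- atoms[!(atoms$resname %in% c("HOH", "WAT", "DOD")), , drop = FALSE]
  atoms <- atoms[atoms$altloc %in% c("", "A"), , drop = FALSE]
  atoms$altloc <- NULL
  if (nrow(atoms) == 0L) stop("no non-water atoms found")

  key <- atoms$name
  r <- radius_table[key]
  miss <- is.na(r)
  r[miss] <- radius_table[atoms$element[miss]]
  miss <- is.na(r)
  if (any(miss)) {
    warning(sprintf("unknown element(s) %s: using fallback radius %.2f A",
                    paste(unique(atoms$element[miss]), collapse = ", "),
                    .fallback_radius))
    r[miss] <- .fallback_radius
  }
  hz <- atoms$element == "H" & r == 0
  r[hz] <- 0.6
  r[r == 0] <- 0.6  # never allow a zero radius through
  atoms$radius <- unname(r)

  atoms$charge <- if (is.null(charges)) {
    partial_charges(atoms$resname, atoms$name)
  } else {
    rep_len(charges, nrow(atoms))
  }

  rk <- paste(atoms$chain, atoms$resno, atoms$resname, sep = "|")
  residue <- match(rk, unique(rk))
  structure(
    list(atoms = atoms, chains = unique(atoms$chain), residue = residue),
    class = "AtomicStructure")
}

#' @export
print.AtomicStructure <- function(x, ...) {
  cat(sprintf("AtomicStructure: %d atoms, %d residues, %d chain(s)\n",
              nrow(x$atoms), max(x$residue), length(x$chains)))
  invisible(x)
}

#' Number of residues of a structure
#' @param structure An `AtomicStructure`.
#' @return Integer residue count.
#' @export
n_residues <- function(structure) max(structure$residue)

#' Per-residue summary table
#' @param structure An `AtomicStructure`.
#' @return data.frame with residue index, chain, resno, resname.
#' @export
residue_table <- function(structure) {
  first <- !duplicated(structure$residue)
  data.frame(residue = structure$residue[first],
             chain = structure$atoms$chain[first],
             resno = structure$atoms$resno[first],
             resname = structure$atoms$resname[first],
             stringsAsFactors = FALSE)
}

#' Write a structure as PDB-format text
#'
#' @param structure An `AtomicStructure`.
#' @param path Output file; if `NULL` the lines are returned invisibly.
#' @param bfactor Optional per-atom or per-residue numeric values stamped into
#'   the B-factor column (per-residue values are broadcast to atoms), e.g.
#'   residue-level binding probabilities for visualization.
#' @return Invisibly, the PDB lines.
#' @export
write_pdb <- function(structure, path = NULL, bfactor = NULL) {
  a <- structure$atoms
  b <- rep(0, nrow(a))
  if (!is.null(bfactor)) {
    b <- if (length(bfactor) == nrow(a)) bfactor else bfactor[structure$residue]
    b[is.na(b)] <- 0
  }
  name4 <- ifelse(nchar(a$name) < 4, paste0(" ", a$name), a$name)
  lines <- sprintf(
    "ATOM  %5d %-4s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
    a$serial %% 100000, name4, a$resname, a$chain, a$resno %% 10000,
    a$x, a$y, a$z, 1.0, b, a$element)
  lines <- c(lines, "END")
  if (!is.null(path)) writeLines(lines, path)
  invisible(lines)
}

# atom coordinate matrix helper
atom_xyz <- function(structure) {
  as.matrix(structure$atoms[, c("x", "y", "z")])
}

#' Apply a rigid motion to a structure
#' @param structure An `AtomicStructure`.
#' @param R 3x3 rotation matrix.
#' @param t length-3 translation vector (A).
#' @return Transformed `AtomicStructure`.
#' @export
transform_structure <- function(structure, R = diag(3), t = c(0, 0, 0)) {
  xyz <- atom_xyz(structure) %*% t(R)
  structure$atoms$x <- xyz[, 1] + t[1]
  structure$atoms$y <- xyz[, 2] + t[2]
  structure$atoms$z <- xyz[, 3] + t[3]
  structure
}
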