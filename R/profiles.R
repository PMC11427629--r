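# Parsers for sequence-profile files: PSI-BLAST ASCII PSSMs and HHblits
# .hhm profile HMMs. Only parsing is supported; the searches that produce
# these files are external.

#' Parse a PSI-BLAST ASCII PSSM
#'
#' Reads the 20 log-odds columns of a PSSM produced with
#' `psiblast -out_ascii_pssm` and squashes them to (0, 1) with the logistic
#' function `1 / (1 + exp(-s))`, giving features PSSM1..PSSM20 per residue.
#'
#' @param path PSSM file path (or character vector of its lines).
#' @param chain_length Optional expected residue count; a mismatch raises an
#'   alignment error reporting the offset.
#' @return A `ResidueProfile`: list with `values` (residues x 20 matrix,
#'   columns PSSM1..PSSM20), `resno`, `aa` (one-letter codes).
#' @export
parse_pssm <- function(path, chain_length = NULL) {
  lines <- if (length(path) == 1L && file.exists(path))
    readLines(path, warn = FALSE) else path
  # data rows: index, residue letter, >= 20 integers
  pat <- "^\\s*\\d+\\s+[A-Zx]\\s+(-?\\d+\\s+){19}-?\\d+"
  rows <- grep(pat, lines, value = TRUE)
  if (!length(rows)) stop("no PSSM rows found: not a PSI-BLAST ascii PSSM?")
  tok <- strsplit(trimws(rows), "\\s+")
  resno <- vapply(tok, function(x) as.numeric(x[1]), numeric(1))
  aa <- vapply(tok, function(x) x[2], character(1))
  logodds <- t(vapply(tok, function(x) as.numeric(x[3:22]), numeric(20)))
  vals <- 1 / (1 + exp(-logodds))
  colnames(vals) <- paste0("PSSM", 1:20)
  .check_profile_length(nrow(vals), chain_length, "PSSM")
  structure(list(values = vals, resno = resno, aa = aa, kind = "pssm"),
            class = "ResidueProfile")
}

#' Parse an HHblits .hhm profile
#'
#' Decodes match-emission and transition probabilities from the
#' integer-coded `-1000 log2(p)` values of the hhm dialect (`*` decodes to
#' probability 0), plus the three Neff diversity values divided by 1000,
#' giving 30 features HMM1..HMM30 per residue (20 emissions, 7 transitions,
#' 3 diversities).
#'
#' @param path hhm file path (or character vector of its lines).
#' @param chain_length Optional expected residue count (mismatch -> error).
#' @return A `ResidueProfile` with a residues x 30 matrix `values`.
#' @export
parse_hhm <- function(path, chain_length = NULL) {
  lines <- if (length(path) == 1L && file.exists(path))
    readLines(path, warn = FALSE) else path
  start <- grep("^HMM\\s", lines)[1]
  if (is.na(start)) stop("no HMM block found: not an hhm file?")
  body <- lines[(start + 3):length(lines)]  # skip the 2 header rows after HMM
  body <- body[!grepl("^(//|\\s*$)", body)]
  # residue rows come in pairs: emissions line (AA resno 20 values pos) then
  # transitions line (10 values: 7 transitions + 3 Neff)
  em_idx <- grep("^[A-Z]\\s+\\d+\\s", body)
  if (!length(em_idx)) stop("no residue rows found in hhm file")
  decode <- function(x) ifelse(x == "*", 0, 2^(-suppressWarnings(as.numeric(x)) / 1000))
  vals <- matrix(0, length(em_idx), 30)
  resno <- numeric(length(em_idx)); aa <- character(length(em_idx))
  for (i in seq_along(em_idx)) {
    t1 <- strsplit(trimws(body[em_idx[i]]), "\\s+")[[1]]
    aa[i] <- t1[1]; resno[i] <- as.numeric(t1[2])
    vals[i, 1:20] <- decode(t1[3:22])
    t2 <- strsplit(trimws(body[em_idx[i] + 1]), "\\s+")[[1]]
    vals[i, 21:27] <- decode(t2[1:7])
    vals[i, 28:30] <- suppressWarnings(as.numeric(t2[8:10])) / 1000
  }
  vals[!is.finite(vals)] <- 0
  colnames(vals) <- paste0("HMM", 1:30)
  .check_profile_length(nrow(vals), chain_length, "HMM")
  structure(list(values = vals, resno = resno, aa = aa, kind = "hhm"),
            class = "ResidueProfile")
}

.check_profile_length <- function(n, chain_length, what) {
  if (!is.null(chain_length) && n != chain_length) {
    stop(sprintf(
      "%s profile length (%d) does not match chain length (%d): offset %+d",
      what, n, chain_length, n - chain_length))
  }
}

#' Map a residue profile onto mesh vertices
#'
#' Profile rows are aligned to the structure's residues in order; rows are
#' broadcast residue -> atoms and mapped atom -> vertex by inverse-distance
#' weighting (2.5 A cutoff).
#'
#' @param structure An `AtomicStructure`.
#' @param mesh A `SurfaceMesh` with vertex maps.
#' @param profile A `ResidueProfile`.
#' @param chain Optional chain id to align against (default: all residues).
#' @return Vertices x features matrix.
#' @export
profile_to_vertices <- function(structure, mesh, profile, chain = NULL) {
  rt <- residue_table(structure)
  target <- if (is.null(chain)) rt else rt[rt$chain == chain, , drop = FALSE]
  .check_profile_length(nrow(profile$values), nrow(target), toupper(profile$kind))
  per_res <- matrix(0, nrow(rt), ncol(profile$values))
  per_res[match(target$residue, rt$residue), ] <- profile$values
  per_atom <- per_res[structure$residue, , drop = FALSE]
  out <- map_atom_to_vertices(structure, mesh, per_atom)
  colnames(out) <- colnames(profile$values)
  out
}
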