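# Packaged lookup tables: van der Waals radii, Atchley factors, hydrophobicity,
# reference accessibilities, hydrogen-bond donor/acceptor atoms and a
# simplified partial-charge set. Tables are plain R objects so the package
# ships as pure text.

#' Default van der Waals radius table
#'
#' Element-keyed van der Waals radii in angstroms, in the spirit of the AMBER
#' force-field parameter sets. Polar hydrogens carry a radius of 0 in such
#' sets; [load_structure()] replaces any 0 radius with the 0.6 A floor.
#'
#' @return Named numeric vector of radii (A) keyed by element symbol.
#' @export
default_radius_table <- function() {
  c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80,
    H = 0.00, F = 1.47, CL = 1.75, BR = 1.85, I = 1.98,
    FE = 1.40, ZN = 1.39, MG = 1.73, CA = 1.80, "NA" = 1.80, K = 2.00,
    MN = 1.40, SE = 1.90, B = 1.65)
}

# fallback when the element is missing from the table
.fallback_radius <- 1.7

# Atchley factors: five numerical summaries of amino-acid physicochemical
# variation (polarity/accessibility, secondary-structure propensity, size,
# codon diversity, charge).
.atchley <- matrix(c(
  -0.591, -1.302, -0.733,  1.570, -0.146,  # ALA
  -1.343,  0.465, -0.862, -1.020, -0.255,  # CYS
   1.050,  0.302, -3.656, -0.259, -3.242,  # ASP
   1.357, -1.453,  1.477,  0.113, -0.837,  # GLU
  -1.006, -0.590,  1.891, -0.397,  0.412,  # PHE
  -0.384,  1.652,  1.330,  1.045,  2.064,  # GLY
   0.336, -0.417, -1.673, -1.474, -0.078,  # HIS
  -1.239, -0.547,  2.131,  0.393,  0.816,  # ILE
   1.831, -0.561,  0.533, -0.277,  1.648,  # LYS
  -1.019, -0.987, -1.505,  1.266, -0.912,  # LEU
  -0.663, -1.524,  2.219, -1.005,  1.212,  # MET
   0.945,  0.828,  1.299, -0.169,  0.933,  # ASN
   0.189,  2.081, -1.628,  0.421, -1.392,  # PRO
   0.931, -0.179, -3.005, -0.503, -1.853,  # GLN
   1.538, -0.055,  1.502,  0.440,  2.897,  # ARG
  -0.228,  1.399, -4.760,  0.670, -2.647,  # SER
  -0.032,  0.326,  2.213,  0.908,  1.313,  # THR
  -1.337, -0.279, -0.544,  1.242, -1.262,  # VAL
  -0.595,  0.009,  0.672, -2.128, -0.184,  # TRP
   0.260,  0.830,  3.097, -0.838,  1.512), # TYR
  ncol = 5, byrow = TRUE,
  dimnames = list(c("ALA", "CYS", "ASP", "GLU", "PHE", "GLY", "HIS", "ILE",
                    "LYS", "LEU", "MET", "ASN", "PRO", "GLN", "ARG", "SER",
                    "THR", "VAL", "TRP", "TYR"),
                  paste0("AF", 1:5)))

#' Atchley factor table
#'
#' @return 20 x 5 matrix of Atchley factors, rows named by three-letter
#'   residue code, columns AF1..AF5.
#' @export
atchley_table <- function() .atchley

# Black & Mould normalized hydrophobicity, shifted so glycine = 0 (the
# convention used by spatial aggregation propensity).
.hydrophobicity_raw <- c(
  ALA = 0.616, CYS = 0.680, ASP = 0.028, GLU = 0.043, PHE = 1.000,
  GLY = 0.501, HIS = 0.165, ILE = 0.943, LYS = 0.283, LEU = 0.943,
  MET = 0.738, ASN = 0.236, PRO = 0.711, GLN = 0.251, ARG = 0.000,
  SER = 0.359, THR = 0.450, VAL = 0.825, TRP = 0.878, TYR = 0.880)

#' Residue hydrophobicity scale used by SAP
#'
#' Black-Mould-type normalized hydrophobicity shifted to glycine = 0, the
#' centring used by the spatial aggregation propensity measure.
#'
#' @return Named numeric vector keyed by three-letter residue code.
#' @export
hydrophobicity_table <- function() .hydrophobicity_raw - .hydrophobicity_raw[["GLY"]]

# Theoretical maximum accessible surface areas (A^2) per residue
# (Tien et al.-style reference values) for relative exposure.
.max_asa <- c(
  ALA = 129, ARG = 274, ASN = 195, ASP = 193, CYS = 167,
  GLU = 223, GLN = 225, GLY = 104, HIS = 224, ILE = 197,
  LEU = 201, LYS = 236, MET = 224, PHE = 240, PRO = 159,
  SER = 155, THR = 172, TRP = 285, TYR = 263, VAL = 174)

#' Maximum accessible surface areas
#' @return Named numeric vector (A^2) keyed by three-letter residue code.
#' @export
max_asa_table <- function() .max_asa

# Hydrogen-bond donor / acceptor heavy atoms. Backbone N is a donor for all
# residues except proline; backbone O (and terminal OXT) accepts for all.
.hb_acceptors <- list(
  "*"   = c("O", "OXT"),
  ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2"),
  ASN = c("OD1"), GLN = c("OE1"),
  SER = c("OG"), THR = c("OG1"), TYR = c("OH"),
  HIS = c("ND1"), MET = c("SD"))
.hb_donors <- list(
  "*"   = c("N"),
  ARG = c("NE", "NH1", "NH2"), LYS = c("NZ"),
  ASN = c("ND2"), GLN = c("NE2"),
  SER = c("OG"), THR = c("OG1"), TYR = c("OH"),
  HIS = c("NE2"), TRP = c("NE1"), CYS = c("SG"))

#' Hydrogen-bond donor/acceptor lookup
#'
#' @param kind `"donor"` or `"acceptor"`.
#' @return Named list: element `"*"` holds backbone atom names applying to all
#'   residues (backbone N of proline is excluded at lookup time); other
#'   elements are per-residue side-chain atom names.
#' @export
hbond_table <- function(kind = c("donor", "acceptor")) {
  kind <- match.arg(kind)
  if (kind == "donor") .hb_donors else .hb_acceptors
}

# Simplified partial charges (units of e): a backbone dipole plus formal
# side-chain charges concentrated on the terminal polar atoms. Deliberately
# compact; a full force-field charge set can be supplied via the
# radius/charge hooks of load_structure().
.charge_backbone <- c(N = -0.40, CA = 0.10, C = 0.55, O = -0.55, OXT = -0.55)
.charge_sidechain <- list(
  ASP = c(CG = 0.20, OD1 = -0.60, OD2 = -0.60),
  GLU = c(CD = 0.20, OE1 = -0.60, OE2 = -0.60),
  LYS = c(NZ = 1.00),
  ARG = c(CZ = 0.20, NH1 = 0.40, NH2 = 0.40),
  HIS = c(ND1 = 0.05, NE2 = 0.05))

#' Simplified partial-charge assignment
#'
#' @param resname three-letter residue codes
#' @param atname atom names
#' @return Numeric vector of charges in units of e.
#' @export
partial_charges <- function(resname, atname) {
  q <- .charge_backbone[atname]
  q[is.na(q)] <- 0
  for (i in seq_along(resname)) {
    sc <- .charge_sidechain[[resname[i]]]
    if (!is.null(sc) && atname[i] %in% names(sc)) q[i] <- sc[[atname[i]]]
  }
  unname(q)
}

.standard_residues <- rownames(.atchley)

#' Names of the 18 structural vertex features
#' @return Character vector of feature column names.
#' @export
structural_feature_names <- function() {
  c("PH1", "PH2", paste0("AF", 1:5), "SAP", "HBA", "HBD",
    paste0("CV", 1:3), "MC", paste0("HK", 1:4))
}

#' Names of the 50 MSA profile features
#' @return Character vector: PSSM1..PSSM20, HMM1..HMM30.
#' @export
msa_feature_names <- function() c(paste0("PSSM", 1:20), paste0("HMM", 1:30))

# one-letter -> three-letter residue code map (used by profile parsers)
.aa1to3 <- c(A = "ALA", C = "CYS", D = "ASP", E = "GLU", F = "PHE",
             G = "GLY", H = "HIS", I = "ILE", K = "LYS", L = "LEU",
             M = "MET", N = "ASN", P = "PRO", Q = "GLN", R = "ARG",
             S = "SER", T = "THR", V = "VAL", W = "TRP", Y = "TYR")
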