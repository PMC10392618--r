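# Amino-acid constant tables used throughout the package.
# Values are the standard reference constants; sources noted per table.

#' Canonical one-letter amino-acid alphabet
#'
#' The 20 canonical residues. Ambiguity/rare codes (B, J, O, U, X, Z) are
#' rejected by the sequence readers because substitution statistics depend on
#' exact residue counts.
#' @keywords internal
AA_ALPHABET <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
                 "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

#' Kyte-Doolittle hydropathy scale
#'
#' Per-residue hydropathy values (Kyte & Doolittle 1982). Positive values are
#' hydrophobic. This is the single hydropathy scale used by the package.
#' @keywords internal
KD_SCALE <- c(
  A =  1.8, R = -4.5, N = -3.5, D = -3.5, C =  2.5,
  Q = -3.5, E = -3.5, G = -0.4, H = -3.2, I =  4.5,
  L =  3.8, K = -3.9, M =  1.9, F =  2.8, P = -1.6,
  S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V =  4.2
)

#' Average residue masses (Da)
#'
#' Average isotopic residue masses (amino acid minus water), matching the
#' ExPASy ProtParam convention. Add one water (18.01524 Da) for a peptide.
#' @keywords internal
AA_MASS_AVG <- c(
  A =  71.0788, R = 156.1875, N = 114.1038, D = 115.0886, C = 103.1388,
  Q = 128.1307, E = 129.1155, G =  57.0519, H = 137.1411, I = 113.1594,
  L = 113.1594, K = 128.1741, M = 131.1926, F = 147.1766, P =  97.1167,
  S =  87.0782, T = 101.1051, W = 186.2132, Y = 163.1760, V =  99.1326
)

#' Mass of one water molecule (Da), average isotopic
#' @keywords internal
WATER_MASS <- 18.01524

# The QTY substitution code: hydrophobic residue -> structurally analogous
# neutral polar residue. The mapping is exactly L->Q, I->T, V->T, F->Y.
QTY_MAP <- c(L = "Q", I = "T", V = "T", F = "Y")

# Side-chain water hydrogen-bond capacity of the replacement residues:
# glutamine's amide offers two donors (-NH2) and two acceptors (C=O);
# the hydroxyls of threonine and tyrosine offer one donor and two acceptors.
HBOND_CAPACITY <- c(Q = 4L, T = 3L, Y = 3L)

# pKa sets for isoelectric-point calculation.
# "Bjellqvist" is the ExPASy-style table: residue-specific N-terminal pKas
# and C-terminal overrides for D/E; side-chain values from Bjellqvist et al.
# "EMBOSS" is the classical set shipped with the EMBOSS iep tool.
PKA_SETS <- list(
  Bjellqvist = list(
    nterm_default = 7.5,
    nterm = c(A = 7.59, M = 7.00, S = 6.93, P = 8.36, T = 6.82,
              V = 7.44, E = 7.70, G = 7.50),
    cterm_default = 3.55,
    cterm = c(D = 4.55, E = 4.75),
    positive = c(K = 10.0, R = 12.0, H = 5.98),
    negative = c(D = 4.05, E = 4.45, C = 9.00, Y = 10.00)
  ),
  EMBOSS = list(
    nterm_default = 8.6,
    nterm = c(),
    cterm_default = 3.6,
    cterm = c(),
    positive = c(K = 10.8, R = 12.5, H = 6.5),
    negative = c(D = 3.9, E = 4.1, C = 8.5, Y = 10.1)
  )
)

# Three-letter -> one-letter residue codes for PDB parsing.
AA_THREE_TO_ONE <- c(
  ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C",
  GLN = "Q", GLU = "E", GLY = "G", HIS = "H", ILE = "I",
  LEU = "L", LYS = "K", MET = "M", PHE = "F", PRO = "P",
  SER = "S", THR = "T", TRP = "W", TYR = "Y", VAL = "V"
)

AA_ONE_TO_THREE <- stats::setNames(names(AA_THREE_TO_ONE), AA_THREE_TO_ONE)

# Van der Waals radii (A) used for solvent-accessible surface area.
# Unknown elements fall back to 1.70 A (carbon) with a warning.
VDW_RADII <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, H = 1.20, P = 1.80)
VDW_DEFAULT <- 1.70

# Coarse sphere radius (A) assigned to alpha-carbons when a structure has no
# side-chain atoms: one pseudo-atom per residue approximating the residue
# envelope.
CA_COARSE_RADIUS <- 3.0

# Residues the QTY code targets; also the default "hydrophobic set" for the
# surface-patch metric, so the metric measures exactly what QTY changes.
QTY_TARGET_SET <- c("L", "I", "V", "F")

# Broader hydrophobic class selectable via flag in surface analysis.
HYDROPHOBIC_BROAD_SET <- c("L", "I", "V", "F", "A", "M", "W", "C")

#' Round half away from zero
#'
#' Base R's round() rounds half to even; printed percentages in reports use
#' conventional half-up rounding (26.825 -> 26.83).
#' @param x numeric vector
#' @param digits decimal places
#' @keywords internal
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# Validate a sequence string against the canonical alphabet; returns the
# uppercased sequence or stops naming the first offending position.
check_canonical <- function(seq, id = "sequence") {
  if (!is.character(seq) || length(seq) != 1L || is.na(seq)) {
    stop("sequence must be a single character string", call. = FALSE)
  }
  seq <- toupper(gsub("[[:space:]]", "", seq))
  if (nchar(seq) == 0L) {
    stop(sprintf("%s: sequence is empty", id), call. = FALSE)
  }
  chars <- strsplit(seq, "")[[1]]
  bad <- which(!chars %in% AA_ALPHABET)
  if (length(bad) > 0L) {
    stop(sprintf("%s: non-canonical residue '%s' at position %d",
                 id, chars[bad[1]], bad[1]), call. = FALSE)
  }
  seq
}
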