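# Physical constants and residue tables shared across modules.

# Gas constant in kcal mol^-1 K^-1 (the unit system used for activation
# energies throughout).
RGAS_KCAL <- 1.987e-3

# Molar volume of water, cm^3 mol^-1.
VW_DEFAULT <- 18.07

# Default cell volume-to-area ratio, cm: sphere of radius 2.5 um (r/3).
V0A_DEFAULT <- 8.3e-5

celsiusToKelvin <- function(x) x + 273.15

# Van der Waals radii (Angstrom) used for pore profiling; the usual
# HOLE-style element set.
DEFAULT_VDW_SET <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, H = 1.20)
VDW_FALLBACK <- 1.70

# Amino-acid tables -----------------------------------------------------

AA1 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
         "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

AA3 <- c(A = "ALA", R = "ARG", N = "ASN", D = "ASP", C = "CYS",
         Q = "GLN", E = "GLU", G = "GLY", H = "HIS", I = "ILE",
         L = "LEU", K = "LYS", M = "MET", F = "PHE", P = "PRO",
         S = "SER", T = "THR", W = "TRP", Y = "TYR", V = "VAL")

aaThreeToOne <- function(x) {
  out <- names(AA3)[match(toupper(x), AA3)]
  out
}

# Binary hydropathy classification of pore-lining residues (one-letter
# codes); everything else in the 20-residue alphabet counts as hydrophilic.
HYDROPHOBIC_BINARY <- c("A", "V", "L", "I", "M", "F", "W", "C", "P")

# Kyte-Doolittle hydropathy index, for the threshold classification mode.
KYTE_DOOLITTLE <- c(
  A =  1.8, R = -4.5, N = -3.5, D = -3.5, C =  2.5,
  Q = -3.5, E = -3.5, G = -0.4, H = -3.2, I =  4.5,
  L =  3.8, K = -3.9, M =  1.9, F =  2.8, P = -1.6,
  S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V =  4.2)

# Physicochemical similarity groups (the pluggable alternative to the
# BLOSUM62-positive rule for column classification).
PHYSCHEM_GROUPS <- list(
  aliphatic = c("I", "L", "V", "M", "A"),
  aromatic  = c("F", "W", "Y"),
  hydroxyl  = c("S", "T"),
  acidic    = c("D", "E"),
  basic     = c("K", "R", "H"),
  amide     = c("N", "Q"),
  small     = c("G", "P"),
  thiol     = c("C"))

# Groups used by the alignment generator for "similar" columns: within each
# group every residue pair scores > 0 under BLOSUM62, so a generated column
# is guaranteed to classify as similar under the default rule.
GENERATOR_SIMILAR_GROUPS <- list(
  c("I", "L", "V", "M"),
  c("F", "W", "Y"),
  c("S", "T"),
  c("D", "E"),
  c("K", "R"))

# Cached BLOSUM62 matrix from Biostrings.
blosum62 <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      e <- new.env()
      utils::data("BLOSUM62", package = "Biostrings", envir = e)
      cache <<- e$BLOSUM62
    }
    cache
  }
})
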