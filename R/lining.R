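# Pore-lining residue identification and residue-level hydropathy ratios.

#' Identify pore-lining residues
#'
#' A residue lines the pore when at least one of its atoms has its surface
#' (center minus vdw radius) within `contactCutoff` of the surface of any
#' inscribed sphere of the profile, i.e.
#' `||atom - sphereCenter|| - vdw - sphereRadius <= contactCutoff`.
#' Open planes (radius clamped at the capture radius) and blocked planes
#' are skipped.
#'
#' @param structure the [ChannelStructure-class] the profile was computed on
#' @param profile a [PoreProfile-class]
#' @param contactCutoff Angstrom, default 1.5
#' @return data.frame with columns `chain`, `resNo`, `resName`, one row
#'   per lining residue, ordered by chain then residue number
#' @export
poreLiningResidues <- function(structure, profile, contactCutoff = 1.5) {
  a <- structure@atoms
  xyz <- axisFrame(as.matrix(a[, c("x", "y", "z")]), profile@meta$axis %||% "z")
  cap <- profile@meta$captureRadius %||% Inf
  lining <- logical(nrow(a))
  usable <- !profile@blocked & profile@radius < cap
  for (p in which(usable)) {
    d <- sqrt((xyz[, 1L] - profile@centerX[p])^2 +
              (xyz[, 2L] - profile@centerY[p])^2 +
              (xyz[, 3L] - profile@z[p])^2) - a$vdw - profile@radius[p]
    lining <- lining | d <= contactCutoff
  }
  res <- unique(a[lining, c("chain", "resNo", "resName")])
  res <- res[order(res$chain, res$resNo), , drop = FALSE]
  rownames(res) <- NULL
  res
}

`%||%` <- function(x, y) if (is.null(x)) y else x

classifyResidueHydropathy <- function(resNames, scale, kdThreshold) {
  one <- aaThreeToOne(resNames)
  if (anyNA(one))
    stop("unknown residue name(s): ",
         paste(unique(resNames[is.na(one)]), collapse = ", "))
  if (scale == "binary") one %in% HYDROPHOBIC_BINARY
  else KYTE_DOOLITTLE[one] >= kdThreshold
}

#' Hydrophobicity/hydrophilicity ratio of pore-lining residues
#'
#' Counts hydrophobic and hydrophilic residues among the supplied
#' pore-lining set and reports their ratio, for the whole pore or for one
#' side of an axial split. Two classifications are available: a binary
#' hydrophobic set (`{A,V,L,I,M,F,W,C,P}`) and a Kyte-Doolittle threshold
#' rule (hydrophobic when the index is >= `kdThreshold`).
#'
#' Region membership is decided by the residue's atom-centroid z
#' coordinate against the split boundary (upper: `z >= boundaryZ`).
#'
#' @param structure the [ChannelStructure-class] providing coordinates
#' @param residues data.frame as returned by [poreLiningResidues()]
#' @param scale `"binary"` or `"kd"`
#' @param split a [PoreRegionSplit-class]; required unless `region`
#'   is `"whole"`
#' @param region `"whole"`, `"upper"` or `"lower"`
#' @param kdThreshold threshold for the `"kd"` scale
#' @return a [HydropathyRatio-class]; when no residue is hydrophilic the
#'   ratio is `Inf` with the counts intact
#' @export
hydropathyRatio <- function(structure, residues, scale = c("binary", "kd"),
                            split = NULL, region = c("whole", "upper", "lower"),
                            kdThreshold = 0) {
  scale <- match.arg(scale)
  region <- match.arg(region)
  a <- structure@atoms
  if (region != "whole") {
    if (is.null(split)) stop("a PoreRegionSplit is required for region = ", region)
    key <- paste(a$chain, a$resNo)
    centroidZ <- tapply(a$z, key, mean)
    rz <- centroidZ[paste(residues$chain, residues$resNo)]
    keep <- if (region == "upper") rz >= split@boundaryZ else rz < split@boundaryZ
    residues <- residues[keep, , drop = FALSE]
  }
  hydrophobic <- classifyResidueHydropathy(residues$resName, scale, kdThreshold)
  nh <- sum(hydrophobic)
  np <- sum(!hydrophobic)
  new("HydropathyRatio",
      ratio = if (np > 0L) nh / np else Inf,
      nHydrophobic = as.integer(nh), nHydrophilic = as.integer(np),
      region = region, scaleName = scale)
}
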