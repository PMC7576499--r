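# Procedural toy channel structures: rings of pseudo-atoms around the
# z-axis whose inscribed-sphere radius is known by construction, used as
# ground-truth fixtures for the pore profiler.

#' Generate a synthetic channel structure
#'
#' Places `nPerRing` pseudo-atoms on rings of radius `wall(z) + atomVdw`
#' around the z-axis at axial steps of `atomSpacing`, so the largest
#' inscribed sphere centered on the axis at height z has radius `wall(z)`
#' by construction. The wall is a base cylinder optionally pinched by a
#' Gaussian constriction:
#' `wall(z) = base - (base - constrictionRadius) * exp(-((z-z0)/halfWidth)^2 * log(2))`.
#'
#' Residue numbers increase along z (one residue per ring); residue names
#' cycle through `residueLabels`.
#'
#' @param axisLength channel length, Angstrom
#' @param baseRadius base cylinder (wall) radius, Angstrom
#' @param constrictionRadius minimum wall radius at the constriction;
#'   `NA` for a uniform cylinder
#' @param constrictionZ axial position of the constriction
#' @param constrictionHalfWidth half-width at half-depth of the pinch
#' @param atomSpacing axial distance between rings, Angstrom
#' @param atomVdw van der Waals radius given to every pseudo-atom
#' @param nPerRing atoms per ring
#' @param residueLabels cyclic vector of 3-letter residue names
#' @param jitter small uniform angular offset per ring (0 disables)
#' @param seed integer seed (only used when `jitter > 0`)
#' @return a [ChannelStructure-class] with `vdw` already set to `atomVdw`
#' @examples
#' cyl <- makeChannelStructure(axisLength = 40, baseRadius = 4)
#' @export
makeChannelStructure <- function(axisLength = 40, baseRadius = 4,
                                 constrictionRadius = NA,
                                 constrictionZ = axisLength / 2,
                                 constrictionHalfWidth = 4,
                                 atomSpacing = 1, atomVdw = 1.7,
                                 nPerRing = 12L,
                                 residueLabels = c("LEU", "SER", "VAL",
                                                   "ASN", "PHE", "THR"),
                                 jitter = 0, seed = 0L) {
  if (atomSpacing <= 0) stop("invalid-spec: atomSpacing must be > 0")
  if (!is.na(constrictionRadius)) {
    if (constrictionRadius > baseRadius)
      stop("invalid-spec: constriction radius must be <= base radius")
    if (constrictionZ < 0 || constrictionZ > axisLength)
      stop("invalid-spec: constriction z outside [0, axisLength]")
  }
  wall <- function(z) {
    if (is.na(constrictionRadius)) return(rep(baseRadius, length(z)))
    baseRadius - (baseRadius - constrictionRadius) *
      exp(-((z - constrictionZ) / constrictionHalfWidth)^2 * log(2))
  }
  zRings <- seq(0, axisLength, by = atomSpacing)
  ang0 <- if (jitter > 0)
    withLocalSeed(seed, runif(length(zRings), 0, jitter)) else
      rep(0, length(zRings))
  rows <- vector("list", length(zRings))
  for (i in seq_along(zRings)) {
    z <- zRings[i]
    rr <- wall(z) + atomVdw
    ang <- ang0[i] + 2 * pi * (seq_len(nPerRing) - 1L) / nPerRing
    rows[[i]] <- data.frame(
      element = "C",
      resName = residueLabels[(i - 1L) %% length(residueLabels) + 1L],
      resNo = i,
      chain = "A",
      x = rr * cos(ang), y = rr * sin(ang), z = z,
      vdw = atomVdw,
      stringsAsFactors = FALSE)
  }
  atoms <- do.call(rbind, rows)
  atoms <- cbind(serial = seq_len(nrow(atoms)), atoms)
  new("ChannelStructure", atoms = atoms)
}
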