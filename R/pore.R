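# Pore-radius profiling by largest-inscribed-sphere search, HOLE-style:
# at each plane along the channel axis, find the in-plane center that
# maximizes the clearance min_a(||atom - center|| - vdw_a) over all atoms.

# Project coordinates onto the channel axis frame. For "principal", the
# axis is the leading eigenvector of the coordinate covariance (channels
# are elongated along their pore). The axis sign is canonicalized so that
# atom file order correlates positively with z, making the profile
# invariant under rigid motions.
axisFrame <- function(coords, axis) {
  if (axis == "z") {
    return(coords)
  }
  ctr <- colMeans(coords)
  cc <- sweep(coords, 2L, ctr)
  ev <- eigen(crossprod(cc) / nrow(cc), symmetric = TRUE)$vectors
  a3 <- ev[, 1L]                       # largest-variance direction
  if (stats::cor(seq_len(nrow(cc)), cc %*% a3) < 0) a3 <- -a3
  # complete a right-handed orthonormal frame
  ref <- if (abs(a3[1L]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  a1 <- ref - sum(ref * a3) * a3
  a1 <- a1 / sqrt(sum(a1^2))
  a2 <- c(a3[2L] * a1[3L] - a3[3L] * a1[2L],
          a3[3L] * a1[1L] - a3[1L] * a1[3L],
          a3[1L] * a1[2L] - a3[2L] * a1[1L])
  cbind(cc %*% a1, cc %*% a2, cc %*% a3)
}

# clearance of candidate centers (nc x 2 matrix) at plane z against atoms
# (matrix x, y, z, vdw); returns vector of min_a(dist - vdw)
planeClearance <- function(centers, z, ax, ay, az, avdw) {
  best <- rep(Inf, nrow(centers))
  dz2 <- (az - z)^2
  for (i in seq_along(ax)) {
    d <- sqrt((centers[, 1L] - ax[i])^2 + (centers[, 2L] - ay[i])^2 + dz2[i]) -
      avdw[i]
    best <- pmin(best, d)
  }
  best
}

#' Pore radius profile of a channel structure
#'
#' For each plane along the axis the profiler maximizes, over the in-plane
#' center, the clearance to the nearest atom surface (largest inscribed
#' sphere constrained to the plane's axial position). Two search modes:
#' \describe{
#'   \item{grid}{exhaustive search on a `gridStep` (default 0.1 A) grid
#'     over the structure's bounding box — the brute-force oracle.}
#'   \item{anneal}{stochastic refinement: `nProposals` Gaussian moves with
#'     geometrically cooling step size, seeded from the previous plane's
#'     center.}
#' }
#' Radii are clamped at `captureRadius` where the channel opens to bulk; a
#' plane whose best clearance is negative is marked blocked.
#'
#' Both modes keep the search connected to the pore: candidate centers are
#' confined to `centerDrift` of the previous plane's center (otherwise the
#' optimum near a tight constriction escapes to the channel exterior,
#' where clearance is unbounded), and the best center found is polished
#' with a deterministic Nelder-Mead refinement so that reported radii are
#' resolution-independent.
#'
#' @param structure a [ChannelStructure-class] with radii assigned
#' @param axis `"z"` (models pre-oriented, periplasmic side = +z) or
#'   `"principal"` (inertia axis of the atom cloud)
#' @param zStep plane spacing, Angstrom
#' @param search `"grid"` or `"anneal"`
#' @param seed integer seed for the anneal proposals
#' @param captureRadius clamp radius where the pore opens to bulk, Angstrom
#' @param gridStep grid resolution for `"grid"` mode
#' @param nProposals,stepSd,cooling anneal schedule: proposals per plane,
#'   initial Gaussian step (A), geometric cooling factor
#' @param centerDrift maximum in-plane center displacement between
#'   consecutive planes, Angstrom
#' @return a [PoreProfile-class]
#' @export
poreProfile <- function(structure, axis = c("z", "principal"), zStep = 0.5,
                        search = c("grid", "anneal"), seed = 0L,
                        captureRadius = 10, gridStep = 0.1,
                        nProposals = 200L, stepSd = 0.3, cooling = 0.98,
                        centerDrift = max(2 * zStep, 1)) {
  axis <- match.arg(axis)
  search <- match.arg(search)
  a <- structure@atoms
  if (nrow(a) < 10L) stop("need at least 10 atoms")
  if (anyNA(a$vdw)) stop("assign vdw radii first (assignVdwRadii)")
  xyz <- axisFrame(as.matrix(a[, c("x", "y", "z")]), axis)
  vdw <- a$vdw
  zGrid <- seq(min(xyz[, 3L]), max(xyz[, 3L]), by = zStep)
  n <- length(zGrid)
  radius <- numeric(n); cx <- numeric(n); cy <- numeric(n)
  blocked <- logical(n)
  vmax <- max(vdw)
  prev <- c(mean(xyz[, 1L]), mean(xyz[, 2L]))

  for (p in seq_len(n)) {
    z <- zGrid[p]
    near <- abs(xyz[, 3L] - z) <= captureRadius + vmax
    if (!any(near)) {               # open to bulk: nothing within reach
      radius[p] <- captureRadius
      cx[p] <- prev[1L]; cy[p] <- prev[2L]
      next
    }
    ax <- xyz[near, 1L]; ay <- xyz[near, 2L]; az <- xyz[near, 3L]
    av <- vdw[near]
    if (search == "grid") {
      gx <- seq(max(min(ax), prev[1L] - centerDrift),
                min(max(ax), prev[1L] + centerDrift), by = gridStep)
      gy <- seq(max(min(ay), prev[2L] - centerDrift),
                min(max(ay), prev[2L] + centerDrift), by = gridStep)
      if (!length(gx)) gx <- prev[1L]
      if (!length(gy)) gy <- prev[2L]
      centers <- cbind(rep(gx, times = length(gy)),
                       rep(gy, each = length(gx)))
      keep <- (centers[, 1L] - prev[1L])^2 + (centers[, 2L] - prev[2L])^2 <=
        centerDrift^2
      if (any(keep)) centers <- centers[keep, , drop = FALSE]
      val <- planeClearance(centers, z, ax, ay, az, av)
      best <- which.max(val)
      r <- val[best]
      ctr <- centers[best, ]
    } else {
      ctr <- prev
      r <- planeClearance(rbind(ctr), z, ax, ay, az, av)
      sdp <- stepSd
      props <- withLocalSeed(seed + p, matrix(rnorm(2L * nProposals), ncol = 2L))
      for (j in seq_len(nProposals)) {
        cand <- ctr + props[j, ] * sdp
        if (sum((cand - prev)^2) > centerDrift^2) next
        v <- planeClearance(rbind(cand), z, ax, ay, az, av)
        if (v > r) { r <- v; ctr <- cand }
        sdp <- sdp * cooling
      }
    }
    if (r > 0) {
      # deterministic local polish: makes the radius independent of the
      # grid resolution / proposal sequence
      opt <- stats::optim(ctr, function(c2)
        -planeClearance(rbind(c2), z, ax, ay, az, av),
        method = "Nelder-Mead",
        control = list(reltol = 1e-12, maxit = 400L))
      if (-opt$value >= r && sum((opt$par - prev)^2) <= centerDrift^2) {
        r <- -opt$value
        ctr <- opt$par
      }
    }
    if (r <= 0) {
      blocked[p] <- TRUE
      radius[p] <- 0
    } else {
      radius[p] <- min(r, captureRadius)
    }
    cx[p] <- ctr[1L]; cy[p] <- ctr[2L]
    if (!blocked[p]) prev <- c(ctr[1L], ctr[2L])
  }
  new("PoreProfile", z = zGrid, radius = radius, centerX = cx, centerY = cy,
      blocked = blocked,
      meta = list(axis = axis, zStep = zStep, search = search, seed = seed,
                  captureRadius = captureRadius))
}

#' Narrowest constriction of a pore profile
#'
#' Global radius minimum over non-blocked planes; ties are broken toward
#' smaller z.
#'
#' @param profile a [PoreProfile-class]
#' @return named numeric `c(z = , radius = )`
#' @export
minConstriction <- function(profile) {
  ok <- !profile@blocked
  if (!any(ok)) stop("blocked-channel: no open plane in profile")
  r <- profile@radius[ok]
  z <- profile@z[ok]
  i <- which.min(r)          # which.min returns the first (smallest z) tie
  c(z = z[i], radius = r[i])
}

#' Per-plane difference between two pore profiles
#'
#' Computes `b - a` per plane; when the z grids differ, `b` is linearly
#' interpolated onto `a`'s grid over the overlapping range.
#'
#' @param a,b [PoreProfile-class] objects
#' @return list with `z`, `delta` (per-plane radius difference),
#'   `meanDelta`, and `deltaAtConstriction` (difference at `a`'s
#'   constriction plane)
#' @export
profileDelta <- function(a, b) {
  lo <- max(min(a@z), min(b@z))
  hi <- min(max(a@z), max(b@z))
  if (lo > hi) stop("no-overlap: profiles cover disjoint z ranges")
  keep <- a@z >= lo & a@z <= hi
  z <- a@z[keep]
  rb <- if (length(b@z) == length(a@z) && all(b@z == a@z)) b@radius[keep]
        else stats::approx(b@z, b@radius, xout = z)$y
  delta <- rb - a@radius[keep]
  zc <- minConstriction(a)[["z"]]
  ic <- which.min(abs(z - zc))
  list(z = z, delta = delta, meanDelta = mean(delta),
       deltaAtConstriction = delta[ic])
}

#' Split a profile into upper (periplasmic) and lower regions
#'
#' The upper region is the periplasmic side of the ar/R constriction,
#' i.e. larger z by the package's orientation convention. Membership is
#' `z >= arRZ` for the upper region and `z < arRZ` for the lower, so every
#' plane belongs to exactly one region.
#'
#' @param profile a [PoreProfile-class]
#' @param arRZ axial position of the ar/R constriction, Angstrom
#' @return a [PoreRegionSplit-class]
#' @export
splitRegions <- function(profile, arRZ) {
  zmin <- min(profile@z); zmax <- max(profile@z)
  if (arRZ < zmin || arRZ > zmax)
    stop("invalid-boundary: arRZ outside the profiled range")
  new("PoreRegionSplit", boundaryZ = arRZ,
      upper = c(arRZ, zmax), lower = c(zmin, arRZ),
      upperEmpty = !any(profile@z >= arRZ),
      lowerEmpty = !any(profile@z < arRZ))
}
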