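# Pore profiling: grid-oracle geometry on constructed fixtures, anneal
# agreement, constriction detection, deltas, lining residues, hydropathy
# and region splits.

test_that("grid profiler reproduces the constructed cylinder and hourglass geometry", {
  cyl <- cylinderFixture(axisLength = 20, baseRadius = 4, atomVdw = 1.5)
  pr <- poreProfile(cyl, search = "grid", zStep = 1)
  expect_true(all(abs(profileRadius(pr) - 4) <= 0.05))

  hg <- hourglassFixture()
  ph <- poreProfile(hg, search = "grid", zStep = 0.5)
  cons <- minConstriction(ph)
  expect_lt(abs(cons[["radius"]] - 1.4), 0.05)
  expect_lte(abs(cons[["z"]] - 20), 0.5)
})

test_that("anneal search agrees with the exhaustive grid oracle", {
  fixtures <- list(cylinderFixture(axisLength = 20, baseRadius = 4),
                   hourglassFixture(axisLength = 30, constrictionZ = 15))
  for (st in fixtures) {
    g <- poreProfile(st, search = "grid", zStep = 1)
    a <- poreProfile(st, search = "anneal", zStep = 1, seed = 0)
    expect_true(all(abs(profileRadius(g) - profileRadius(a)) <= 0.05))
  }
})

test_that("adding an axial obstacle can only shrink the profile", {
  st <- cylinderFixture(axisLength = 20, baseRadius = 4)
  pr <- poreProfile(st, search = "grid", zStep = 1)
  a <- atomTable(st)
  obstacle <- data.frame(serial = max(a$serial) + 1L, element = "C",
                         resName = "ALA", resNo = max(a$resNo) + 1L,
                         chain = "A", x = 0, y = 0, z = 10, vdw = 1.7)
  st2 <- new("ChannelStructure", atoms = rbind(a, obstacle))
  pr2 <- poreProfile(st2, search = "grid", zStep = 1)
  expect_true(all(profileRadius(pr2) <= profileRadius(pr) + 1e-9))
  # and the plane at the obstacle is strictly narrower
  expect_lt(profileRadius(pr2)[profileZ(pr2) == 10],
            profileRadius(pr)[profileZ(pr) == 10])
})

test_that("constriction ties break toward smaller z and blocked profiles error", {
  prof <- new("PoreProfile", z = c(0, 1, 2, 3), radius = c(3, 1.2, 1.2, 2),
              centerX = numeric(4), centerY = numeric(4),
              blocked = rep(FALSE, 4), meta = list())
  expect_equal(minConstriction(prof)[["z"]], 1)
  cyl <- poreProfile(cylinderFixture(), search = "grid", zStep = 1)
  expect_equal(minConstriction(cyl)[["z"]], min(profileZ(cyl)))
  allBlocked <- new("PoreProfile", z = 0:1, radius = c(0, 0),
                    centerX = numeric(2), centerY = numeric(2),
                    blocked = c(TRUE, TRUE), meta = list())
  expect_error(minConstriction(allBlocked), "blocked-channel")
})

test_that("profile deltas localize and quantify radius changes", {
  a <- poreProfile(cylinderFixture(axisLength = 20, baseRadius = 4),
                   search = "grid", zStep = 1)
  self <- profileDelta(a, a)
  expect_true(all(abs(self$delta) < 1e-12))

  b <- poreProfile(cylinderFixture(axisLength = 20, baseRadius = 4.4),
                   search = "grid", zStep = 1)
  d <- profileDelta(a, b)
  expect_true(all(abs(d$delta - 0.4) <= 0.05))
  expect_equal(d$meanDelta, 0.4, tolerance = 0.05)

  hg <- poreProfile(hourglassFixture(), search = "grid", zStep = 0.5)
  hgWide <- poreProfile(hourglassFixture(constrictionRadius = 2.4),
                        search = "grid", zStep = 0.5)
  dh <- profileDelta(hg, hgWide)
  expect_equal(dh$deltaAtConstriction, 1.0, tolerance = 0.1)
  # the widening is localized: far from the constriction nothing changes
  far <- abs(dh$z - 20) > 15
  expect_true(all(abs(dh$delta[far]) < 0.1))

  offGrid <- new("PoreProfile", z = c(100, 101), radius = c(1, 1),
                 centerX = numeric(2), centerY = numeric(2),
                 blocked = c(FALSE, FALSE), meta = list())
  expect_error(profileDelta(a, offGrid), "no-overlap")
})

test_that("pore-lining residues are the wall residues, monotone in cutoff", {
  st <- cylinderFixture(axisLength = 20, baseRadius = 4)
  pr <- poreProfile(st, search = "grid", zStep = 1)
  lining <- poreLiningResidues(st, pr, contactCutoff = 1.5)
  # every ring touches the inscribed spheres of its own plane
  expect_equal(sort(lining$resNo), sort(unique(atomTable(st)$resNo)))
  tight <- poreLiningResidues(st, pr, contactCutoff = 0)
  expect_true(all(paste(tight$chain, tight$resNo) %in%
                    paste(lining$chain, lining$resNo)))
})

test_that("lining detection matches a brute-force distance-scan oracle", {
  st <- hourglassFixture(axisLength = 20, constrictionZ = 10,
                         atomSpacing = 2, nPerRing = 8)
  pr <- poreProfile(st, search = "grid", zStep = 2)
  cutoff <- 1.5
  a <- atomTable(st)
  cap <- pr@meta$captureRadius
  hit <- rep(FALSE, nrow(a))
  for (p in seq_along(profileZ(pr))) {
    if (pr@blocked[p] || profileRadius(pr)[p] >= cap) next
    for (i in seq_len(nrow(a))) {
      d <- sqrt((a$x[i] - pr@centerX[p])^2 + (a$y[i] - pr@centerY[p])^2 +
                  (a$z[i] - profileZ(pr)[p])^2) - a$vdw[i] - profileRadius(pr)[p]
      if (d <= cutoff) hit[i] <- TRUE
    }
  }
  oracle <- unique(a[hit, c("chain", "resNo", "resName")])
  oracle <- oracle[order(oracle$chain, oracle$resNo), ]
  rownames(oracle) <- NULL
  expect_identical(poreLiningResidues(st, pr, cutoff), oracle)
})

test_that("hydropathy ratios count the constructed labels", {
  # 23 rings cycling hydrophobic/hydrophilic labels: LEU,SER,VAL,ASN ->
  # per cycle 2 hydrophobic (L, V) and 2 hydrophilic (S, N)
  st <- makeChannelStructure(axisLength = 22, baseRadius = 4,
                             residueLabels = c("LEU", "SER", "VAL", "ASN"))
  pr <- poreProfile(st, search = "grid", zStep = 1)
  lining <- poreLiningResidues(st, pr)
  hr <- hydropathyRatio(st, lining)
  expect_equal(hr@nHydrophobic + hr@nHydrophilic, 23)
  expect_equal(hr@ratio, hr@nHydrophobic / hr@nHydrophilic)

  # explicit count fixture: 9 hydrophobic vs 14 hydrophilic -> 0.643
  res <- data.frame(chain = "A", resNo = 1:23,
                    resName = c(rep("LEU", 9), rep("SER", 14)))
  stAll <- makeChannelStructure(axisLength = 22, baseRadius = 4)
  hr2 <- hydropathyRatio(stAll, res)
  expect_equal(hr2@ratio, 9 / 14, tolerance = 1e-12)
  expect_equal(round(hr2@ratio, 3), 0.643)

  # all hydrophobic -> infinity flag with counts intact
  resH <- data.frame(chain = "A", resNo = 1:4, resName = "VAL")
  hrInf <- hydropathyRatio(stAll, resH)
  expect_identical(hrInf@ratio, Inf)
  expect_equal(hrInf@nHydrophilic, 0L)

  # Kyte-Doolittle threshold mode flips borderline residues
  resKD <- data.frame(chain = "A", resNo = 1:2, resName = c("TRP", "ILE"))
  expect_equal(hydropathyRatio(stAll, resKD, scale = "kd")@nHydrophobic, 1L)
  expect_equal(hydropathyRatio(stAll, resKD, scale = "binary")@nHydrophobic, 2L)
})

test_that("region split partitions planes and supports per-region ratios", {
  st <- hourglassFixture()
  pr <- poreProfile(st, search = "grid", zStep = 0.5)
  split <- splitRegions(pr, 20)
  z <- profileZ(pr)
  inUpper <- z >= 20
  inLower <- z < 20
  expect_true(all(xor(inUpper, inLower)))
  expect_false(split@upperEmpty)
  expect_false(split@lowerEmpty)

  lining <- poreLiningResidues(st, pr)
  whole <- hydropathyRatio(st, lining)
  up <- hydropathyRatio(st, lining, split = split, region = "upper")
  lo <- hydropathyRatio(st, lining, split = split, region = "lower")
  expect_equal(up@nHydrophobic + lo@nHydrophobic, whole@nHydrophobic)
  expect_equal(up@nHydrophilic + lo@nHydrophilic, whole@nHydrophilic)

  edge <- splitRegions(pr, min(z))
  expect_true(edge@lowerEmpty)
  expect_error(splitRegions(pr, max(z) + 5), "invalid-boundary")
})

test_that("profiles are invariant under rigid motion in principal-axis mode", {
  st <- hourglassFixture(axisLength = 30, constrictionZ = 12)
  p0 <- poreProfile(st, axis = "principal", search = "grid", zStep = 1)
  # rotate by an arbitrary rotation and translate
  th <- 0.7; ph <- 0.3
  Rz <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  Rx <- matrix(c(1, 0, 0, 0, cos(ph), -sin(ph), 0, sin(ph), cos(ph)), 3, 3)
  a <- atomTable(st)
  xyz <- as.matrix(a[, c("x", "y", "z")]) %*% t(Rz %*% Rx)
  a$x <- xyz[, 1] + 5; a$y <- xyz[, 2] - 3; a$z <- xyz[, 3] + 11
  st2 <- new("ChannelStructure", atoms = a)
  p1 <- poreProfile(st2, axis = "principal", search = "grid", zStep = 1)
  expect_equal(profileRadius(p1), profileRadius(p0), tolerance = 1e-3)
})
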