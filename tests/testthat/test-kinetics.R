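# Estimator chain: exponential fits, permeability formulas, Arrhenius
# regression, percent reduction, strain comparison, pipeline behaviour.

test_that("shrinkage fit recovers the generating rate constant exactly at noise 0", {
  # choose pfTrue so the generating k is exactly 2.0 /s
  geom <- cellGeometry()
  cond <- shockConditions(1.4, 2.1, "sorbitol")
  pf <- 2.0 * geom@v0OverA / (geom@vW * 2.1e-3)
  p <- simulationParams(pfTrue = pf, conditions = cond, noiseSd = 0,
                        duration = 10)
  fit <- fitShrinkageRate(simulateShock(p))
  expect_equal(rateConstant(fit), 2.0, tolerance = 1e-6)
  # and the estimator chain inverts to Pf
  est <- waterPermeability(fit, geom, cond)
  expect_equal(permValue(est), pf, tolerance = 1e-6)
})

test_that("constant and pure-noise traces are rejected as degenerate", {
  cond <- shockConditions()
  flat <- shockTrace(time = seq(0, 10, 0.1), signal = rep(1, 101),
                     conditions = cond)
  expect_error(fitShrinkageRate(flat), "fit-degenerate")
  set.seed(1)
  noise <- shockTrace(time = seq(0, 10, 0.1),
                      signal = 1 + rnorm(101, sd = 0.05), conditions = cond)
  expect_error(fitShrinkageRate(noise), "fit-degenerate")
})

test_that("mean fitted k over noisy replicates is within 2% of truth", {
  p <- waterParams(noiseSd = 0.01, duration = 20)
  kTrue <- 6.78e-4 * p@geometry@vW * 2.1e-3 / p@geometry@v0OverA
  ks <- vapply(simulateReplicates(p, replicates = 50), function(tr)
    rateConstant(fitShrinkageRate(tr)), numeric(1))
  expect_lt(abs(mean(ks) / kTrue - 1), 0.02)
})

test_that("water permeability formula is linear and matches direct evaluation", {
  geom <- cellGeometry(v0OverA = 8.3e-5, vW = 18.07)
  cond <- shockConditions(1.4, 2.1, "sorbitol")
  # direct evaluation: k * v0a / (vW * osmOut[mol/cm^3])
  expect_equal(permValue(waterPermeability(0.309, geom, cond)),
               0.309 * 8.3e-5 / (18.07 * 2.1e-3), tolerance = 1e-12)
  expect_equal(permValue(waterPermeability(0.309, geom, cond)), 6.8e-4,
               tolerance = 0.01)
  expect_equal(permValue(waterPermeability(0, geom, cond)), 0)
  doubled <- cellGeometry(v0OverA = 2 * 8.3e-5, vW = 18.07)
  expect_equal(permValue(waterPermeability(0.309, doubled, cond)),
               2 * permValue(waterPermeability(0.309, geom, cond)))
})

test_that("re-swelling slope inverts the generator exactly at noise 0", {
  # Pgly chosen so the generating slope is exactly 5e-4 /s
  geom <- cellGeometry()
  pg <- glycerolParams()
  pg@pglyTrue <- 5e-4 * geom@v0OverA
  fit <- fitReswellingSlope(simulateShock(pg))
  expect_equal(slopeValue(fit), 5e-4, tolerance = 1e-6)
  est <- glycerolPermeability(fit, geom)
  expect_equal(permValue(est), pg@pglyTrue, tolerance = 1e-6)
  # direct formula evaluation
  expect_equal(permValue(glycerolPermeability(5e-4, geom)), 4.15e-8)
  expect_equal(permValue(glycerolPermeability(0, geom)), 0)
  # reverse flux yields a flagged estimate, not an error
  rev <- glycerolPermeability(-2e-4, geom)
  expect_true(rev@flagged)
  expect_lt(permValue(rev), 0)
})

test_that("slope recovery is scale equivariant and robust to noise", {
  pg <- glycerolParams(noiseSd = 0.01, seed = 3L)
  ms <- vapply(simulateReplicates(pg, replicates = 50), function(tr)
    slopeValue(fitReswellingSlope(tr)), numeric(1))
  mTrue <- 24.5e-8 / pg@geometry@v0OverA
  expect_lt(abs(mean(ms) / mTrue - 1), 0.05)

  # multiplying the signal by c > 0 leaves k and m unchanged
  tr <- simulateShock(glycerolParams())
  scaled <- shockTrace(traceTime(tr), 3.7 * traceSignal(tr),
                       traceTemperature(tr), "glycerol", tr@conditions)
  expect_equal(slopeValue(fitReswellingSlope(scaled)),
               slopeValue(fitReswellingSlope(tr)), tolerance = 1e-9)
  trw <- simulateShock(waterParams())
  scaledw <- shockTrace(traceTime(trw), 3.7 * traceSignal(trw),
                        traceTemperature(trw), "water", trw@conditions)
  expect_equal(rateConstant(fitShrinkageRate(scaledw)),
               rateConstant(fitShrinkageRate(trw)), tolerance = 1e-9)
})

test_that("water-only traces raise no-reswelling", {
  expect_error(fitReswellingSlope(simulateShock(waterParams())),
               "no-reswelling")
  # a glycerol-shock trace from a strain with zero glycerol permeability
  pg <- glycerolParams()
  pg@pglyTrue <- 0
  expect_error(fitReswellingSlope(simulateShock(pg)), "no-reswelling")
})

test_that("Arrhenius regression is exact on exact inputs", {
  temps <- c(10, 15, 20, 25, 30, 35)
  R <- 1.987e-3
  ea <- 6.93
  pRef <- 24.5e-8
  tRefK <- 23 + 273.15
  p <- pRef * exp(-ea / R * (1 / (temps + 273.15) - 1 / tRefK))
  res <- activationEnergy(temps, p)
  expect_equal(activationEnergyValue(res), ea, tolerance = 1e-6)
  expect_equal(res@r2, 1, tolerance = 1e-9)
  # back-substitution: the fitted line reproduces P at the reference T
  expect_equal(exp(res@lnPrefactor - ea / R / tRefK), pRef, tolerance = 1e-6)
  # identical permeabilities -> zero activation energy
  expect_equal(activationEnergyValue(activationEnergy(temps, rep(1e-4, 6))), 0)
  expect_error(activationEnergy(c(10, 20), c(1, 2)), "insufficient-design")
  expect_error(activationEnergy(temps, c(1, 2, 3, 4, 5, -1)), "invalid-input")
})

test_that("percent reduction reproduces the reported mutant comparisons", {
  expect_equal(round(percentReduction(24.5, 3.58)), 85)
  expect_equal(round(percentReduction(24.5, 7.84)), 68)
  expect_equal(percentReduction(12.8, 2.57), 79.9, tolerance = 0.001)
  expect_equal(percentReduction(10, 10), 0)
  a <- waterPermeability(0.3)
  b <- glycerolPermeability(5e-4)
  expect_error(percentReduction(a, b), "invalid-comparison")
  expect_error(percentReduction(0, 1), "invalid-comparison")
})

test_that("Welch comparison labels follow the significance thresholds", {
  same <- compareStrains(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same@statistic, 0)
  expect_identical(same@significanceLabel, "ns")
  far <- compareStrains(c(1, 2, 3), c(11.001, 12.002, 13.001))
  expect_lt(far@pValue, 0.001)
  expect_identical(far@significanceLabel, "***")
  # degenerate zero-variance cases
  expect_equal(compareStrains(c(1, 1, 1), c(1, 1, 1))@pValue, 1)
  expect_equal(compareStrains(c(1, 1, 1), c(2, 2, 2))@pValue, 0)
})

test_that("Welch p agrees with an exhaustive permutation oracle on small n", {
  a <- c(4.1, 5.0, 3.6, 4.4)
  b <- c(5.2, 6.1, 5.5, 4.9)
  obs <- compareStrains(a, b)
  pool <- c(a, b)
  welchT <- function(x, y) unname(t.test(x, y)$statistic)
  splits <- combn(8, 4)
  tref <- abs(welchT(a, b))
  perm <- apply(splits, 2, function(ix) abs(welchT(pool[ix], pool[-ix])))
  pPerm <- mean(perm >= tref - 1e-12)
  expect_lt(abs(pPerm - obs@pValue), 0.08)
})

test_that("pipeline aggregates a two-strain cohort deterministically", {
  mkCohort <- function() {
    traces <- list(); strain <- character()
    specs <- list(native = c(pf = 6.78e-4, pgly = 24.5e-8),
                  mutant = c(pf = 5.12e-4, pgly = 3.58e-8))
    for (s in names(specs)) {
      for (solute in c("sorbitol", "glycerol")) {
        p <- nativeParams(conditions = shockConditions(1.4, 2.1, solute),
                          noiseSd = 0.01, seed = 42L)
        p@pfTrue <- specs[[s]][["pf"]]
        p@pglyTrue <- specs[[s]][["pgly"]]
        reps <- simulateReplicates(p, replicates = 3)
        traces <- c(traces, reps)
        strain <- c(strain, rep(s, 3))
      }
    }
    runKineticsPipeline(traces, strain)
  }
  r1 <- mkCohort()
  r2 <- mkCohort()
  expect_identical(r1, r2)
  expect_named(r1$strains, c("native", "mutant"))
  expect_equal(permValue(r1$strains$native$pgly), 24.5e-8, tolerance = 0.05)
  expect_equal(permValue(r1$strains$mutant$pf), 5.12e-4, tolerance = 0.05)
  expect_identical(r1$comparisons$native_vs_mutant_Pgly@significanceLabel, "***")
})

test_that("pipeline survives a glycerol-incompetent strain and sparse designs", {
  p <- glycerolParams(noiseSd = 0.01, seed = 8L)
  p@pglyTrue <- 0
  traces <- simulateReplicates(p, replicates = 3)
  rep <- runKineticsPipeline(traces, rep("aqp_only", 3))
  expect_null(rep$strains$aqp_only$pgly)
  expect_true(any(grepl("no-reswelling", rep$warnings)))
  # a single temperature cannot support an Arrhenius fit -> warning, no error
  pw <- waterParams(noiseSd = 0.01)
  rep2 <- runKineticsPipeline(simulateReplicates(pw, replicates = 3),
                              rep("s", 3))
  expect_null(rep2$strains$s$eaWater)
  expect_true(any(grepl("eaWater not fitted", rep2$warnings)))
})

test_that("pipeline recovers the generating activation energy from a cohort", {
  p <- waterParams(noiseSd = 0.01, seed = 21L)
  ser <- simulateArrheniusSeries(p, c(10, 15, 20, 25, 30, 35), replicates = 3)
  ref <- simulateReplicates(p, replicates = 3)
  traces <- c(ser, ref)
  rep <- runKineticsPipeline(traces, rep("native", length(traces)))
  expect_equal(activationEnergyValue(rep$strains$native$eaWater), 9.80,
               tolerance = 0.05)
})
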