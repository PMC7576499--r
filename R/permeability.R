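# Conversion of fitted rates/slopes to permeability coefficients,
# Arrhenius activation energies, percent reductions and the Welch t-test
# strain comparison.

#' Osmotic water permeability from a shrinkage rate constant
#'
#' Implements the stopped-flow formula
#' \deqn{P_f = k \, (V_0/A) \, \frac{1}{V_w (osm_{out})_\infty}}
#' with the final external osmolarity converted to mol cm\eqn{^{-3}}.
#'
#' @param fit a [RateFit-class], or a bare non-negative rate constant (1/s)
#' @param geometry a [CellGeometry-class]
#' @param conditions a [ShockConditions-class]
#' @param temperature optional shock temperature (degC) recorded in the
#'   estimate
#' @return a [PermeabilityEstimate-class] of kind `"Pf"` (cm/s, n = 1)
#' @export
waterPermeability <- function(fit, geometry = cellGeometry(),
                              conditions = shockConditions(),
                              temperature = NA_real_) {
  k <- if (is(fit, "RateFit")) fit@k else as.numeric(fit)
  if (k < 0) stop("invalid-parameters: rate constant must be >= 0")
  if (conditions@osmOut <= 0)
    stop("invalid-conditions: non-positive osmolarity")
  new("PermeabilityEstimate", kind = "Pf",
      value = pfFromRate(k, geometry, conditions),
      sd = NA_real_, n = 1L, temperature = temperature, flagged = FALSE)
}

#' Glycerol permeability from a re-swelling slope
#'
#' \deqn{P_{gly} = m \, (V_0/A)} with `m` the linear re-swelling slope in
#' relative-volume units. A negative slope (reverse flux) yields a flagged
#' estimate rather than an error.
#'
#' @param fit a [SlopeFit-class], or a bare finite slope (1/s)
#' @inheritParams waterPermeability
#' @return a [PermeabilityEstimate-class] of kind `"Pgly"` (cm/s, n = 1)
#' @export
glycerolPermeability <- function(fit, geometry = cellGeometry(),
                                 temperature = NA_real_) {
  m <- if (is(fit, "SlopeFit")) fit@m else as.numeric(fit)
  if (!is.finite(m)) stop("invalid-parameters: slope must be finite")
  new("PermeabilityEstimate", kind = "Pgly",
      value = m * geometry@v0OverA, sd = NA_real_, n = 1L,
      temperature = temperature, flagged = m < 0)
}

# Aggregate per-trace estimates into one mean +/- SD estimate.
aggregateEstimates <- function(estimates) {
  stopifnot(length(estimates) >= 1L)
  kind <- unique(vapply(estimates, function(e) e@kind, character(1L)))
  stopifnot(length(kind) == 1L)
  vals <- vapply(estimates, permValue, numeric(1L))
  temp <- unique(vapply(estimates, function(e) e@temperature, numeric(1L)))
  new("PermeabilityEstimate", kind = kind, value = mean(vals),
      sd = if (length(vals) > 1L) sd(vals) else NA_real_,
      n = length(vals),
      temperature = if (length(temp) == 1L) temp else NA_real_,
      flagged = any(vapply(estimates, function(e) e@flagged, logical(1L))))
}

#' Arrhenius activation energy from a temperature series
#'
#' Ordinary least squares of \eqn{\ln P} against \eqn{1/T} (T in kelvin);
#' \eqn{E_a = -\mathrm{slope} \times R} with
#' R = 1.987e-3 kcal mol\eqn{^{-1}} K\eqn{^{-1}}.
#'
#' @param temperatures degC (at least 3 distinct values)
#' @param permeabilities matching positive permeabilities (cm/s), either
#'   bare numbers or [PermeabilityEstimate-class] objects
#' @return an [ArrheniusResult-class]
#' @export
activationEnergy <- function(temperatures, permeabilities) {
  p <- vapply(permeabilities, function(x)
    if (is(x, "PermeabilityEstimate")) x@value else as.numeric(x), numeric(1L))
  if (length(temperatures) != length(p))
    stop("invalid-input: temperatures and permeabilities differ in length")
  if (length(unique(temperatures)) < 3L)
    stop("insufficient-design: need at least 3 distinct temperatures")
  if (any(!is.finite(p) | p <= 0))
    stop("invalid-input: all permeabilities must be positive")
  tk <- celsiusToKelvin(temperatures)
  invT <- 1 / tk
  fit <- lm(log(p) ~ invT)
  new("ArrheniusResult",
      ea = -coef(fit)[[2L]] * RGAS_KCAL,
      lnPrefactor = coef(fit)[[1L]],
      r2 = suppressWarnings(summary(fit)$r.squared),  # exact inputs fit perfectly
      points = data.frame(temperatureK = tk, permeability = p))
}

#' Percent reduction of a mutant permeability relative to the native
#'
#' `100 * (native - mutant) / native`; both arguments may be
#' [PermeabilityEstimate-class] objects (of the same kind) or bare values.
#'
#' @param native,mutant permeabilities (native > 0)
#' @return percentage
#' @export
percentReduction <- function(native, mutant) {
  if (is(native, "PermeabilityEstimate") && is(mutant, "PermeabilityEstimate") &&
      native@kind != mutant@kind)
    stop("invalid-comparison: cannot compare permeabilities of different kinds")
  nv <- if (is(native, "PermeabilityEstimate")) native@value else as.numeric(native)
  mv <- if (is(mutant, "PermeabilityEstimate")) mutant@value else as.numeric(mutant)
  if (nv <= 0) stop("invalid-comparison: native permeability must be > 0")
  100 * (nv - mv) / nv
}

#' Compare two strains' replicate permeabilities (Welch t-test)
#'
#' Two-sided Welch (unequal-variance) t-test with the significance
#' labelling used in the field's bar plots: `***` for p < 0.001, `**` for
#' p < 0.01, `ns` otherwise. Two groups with zero variance and equal means
#' yield statistic 0, p = 1; zero variance with different means yields an
#' infinite statistic and p = 0.
#'
#' @param replicatesA,replicatesB numeric vectors (>= 3 values each)
#' @return a [StrainComparison-class]
#' @export
compareStrains <- function(replicatesA, replicatesB) {
  if (length(replicatesA) < 3L || length(replicatesB) < 3L)
    stop("invalid-input: each group needs at least 3 values")
  if (sd(replicatesA) == 0 && sd(replicatesB) == 0) {
    if (mean(replicatesA) == mean(replicatesB))
      return(new("StrainComparison", statistic = 0, pValue = 1,
                 significanceLabel = "ns"))
    return(new("StrainComparison", statistic = Inf, pValue = 0,
               significanceLabel = "***"))
  }
  tt <- t.test(replicatesA, replicatesB, var.equal = FALSE)
  p <- tt$p.value
  lab <- if (p < 0.001) "***" else if (p < 0.01) "**" else "ns"
  new("StrainComparison", statistic = unname(tt$statistic), pValue = p,
      significanceLabel = lab)
}
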