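# Trace-level estimators: single-exponential shrinkage fit and linear
# re-swelling slope fit.

movingAverage <- function(x, w) {
  if (w < 2L) return(x)
  sm <- as.numeric(stats::filter(x, rep(1 / w, w), sides = 2))
  # pad the filter's NA edges with the nearest smoothed value
  ok <- which(!is.na(sm))
  sm[seq_len(ok[1L] - 1L)] <- sm[ok[1L]]
  sm[seq.int(ok[length(ok)] + 1L, length.out = length(sm) - ok[length(ok)])] <-
    sm[ok[length(ok)]]
  sm
}

# robust high-frequency noise estimate (sd of first differences / sqrt(2))
noiseEstimate <- function(y) {
  stats::sd(diff(y)) / sqrt(2)
}

#' Fit the shrinkage phase to a single exponential
#'
#' Nonlinear least squares of `signal = baseline + amplitude * exp(-k*t)`
#' over the whole supplied trace (use the pre-minimum segment for glycerol
#' shocks). Starting values: `baseline0` is the last sample, `amplitude0`
#' the first sample minus `baseline0`, and `k0` the negated slope of a
#' log-linear fit to the first third of the decay.
#'
#' @param trace a [ShockTrace-class] (or the shrinkage segment of one)
#' @return a [RateFit-class]
#' @section Errors:
#' A trace whose net signal change is below three times the estimated
#' noise floor raises a `fit-degenerate` error; failure of the optimizer
#' raises `fit-failure` with the residual summary.
#' @export
fitShrinkageRate <- function(trace) {
  tt <- trace@time
  y <- trace@signal
  n <- length(y)
  noise <- noiseEstimate(y)
  headMean <- mean(head(y, max(3L, ceiling(0.02 * n))))
  tailMean <- mean(tail(y, max(3L, ceiling(0.05 * n))))
  amp0 <- headMean - tailMean
  if (abs(amp0) <= 3 * noise + .Machine$double.eps)
    stop("fit-degenerate: signal amplitude below the noise floor")

  b0 <- y[n]
  a0 <- y[1L] - b0
  third <- seq_len(max(5L, floor(n / 3)))
  z <- (y[third] - b0) / a0
  pos <- z > 0
  k0 <- if (sum(pos) >= 3L) {
    sl <- coef(lm(log(z[pos]) ~ tt[third][pos]))[[2L]]
    if (is.finite(sl) && sl < 0) -sl else 3 / max(tt)
  } else 3 / max(tt)

  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ b + A * exp(-k * tt),
                      start = list(b = b0, A = a0, k = k0),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) stop("fit-failure: exponential fit did not converge (",
                             conditionMessage(e), ")"))
  cf <- coef(fit)
  if (!is.finite(cf[["k"]]) || cf[["k"]] <= 0)
    stop("fit-failure: non-positive rate constant; residual rmse = ",
         format(sqrt(mean(residuals(fit)^2))))
  new("RateFit", k = cf[["k"]], amplitude = cf[["A"]], baseline = cf[["b"]],
      rmse = sqrt(mean(residuals(fit)^2)))
}

#' Fit the glycerol re-swelling slope
#'
#' Locates the global minimum of a smoothed copy of the signal (moving
#' average over `smoothFrac` of the samples), skips a guard gap of
#' `guardFrac` of the samples past the minimum, and fits ordinary least
#' squares on the raw signal over a window of `windowFrac` of the samples
#' (or to the trace end). The guard gap must at least cover the smoothing
#' half-window, because minimum positions within it are blurred across the
#' shrink/re-swell kink; the default (3%) does, for the default smoothing
#' (5%, half-window 2.5%).
#'
#' The raw slope (signal units/s) is converted to relative-volume units by
#' dividing by the estimated transduction span, obtained from a
#' single-exponential fit of the pre-minimum shrinkage phase:
#' `span = |amplitude| / (1 - osmIn/osmOut)`.
#'
#' @param trace a glycerol-shock [ShockTrace-class]
#' @param smoothFrac moving-average window, fraction of samples
#' @param guardFrac guard gap after the minimum, fraction of samples
#' @param windowFrac fit window, fraction of samples
#' @param minRise minimum net smoothed rise after the minimum (as a
#'   fraction of the shrink amplitude) for a re-swelling phase to be
#'   declared present
#' @return a [SlopeFit-class]; `m` is in relative-volume 1/s
#' @section Errors:
#' Traces without an interior minimum followed by a genuine rise raise a
#' `no-reswelling` error; windows shorter than 5 samples raise a `window`
#' error.
#' @export
fitReswellingSlope <- function(trace, smoothFrac = 0.05, guardFrac = 0.03,
                               windowFrac = 0.40, minRise = 0.02) {
  tt <- trace@time
  y <- trace@signal
  n <- length(y)
  w <- max(3L, round(smoothFrac * n))
  sm <- movingAverage(y, w)
  imin <- which.min(sm)
  shrinkAmp <- sm[1L] - sm[imin]
  rise <- sm[n] - sm[imin]
  if (imin <= 1L || imin >= n || rise < minRise * abs(shrinkAmp))
    stop("no-reswelling: trace has no interior minimum followed by a rise")

  i0 <- imin + max(1L, round(guardFrac * n))
  i1 <- min(n, i0 + round(windowFrac * n))
  if (i1 - i0 + 1L < 5L)
    stop("window: fewer than 5 samples available for the slope fit")
  win <- i0:i1
  fit <- lm(y[win] ~ tt[win])
  mRaw <- coef(fit)[[2L]]
  r2 <- suppressWarnings(summary(fit)$r.squared)  # noiseless fits are exact

  # un-do the fluorescence transduction scale using the shrinkage phase;
  # trim the smoothing half-window off the end, where the minimum position
  # is blurred across the shrink/re-swell transition
  imin <- max(10L, imin - ceiling(w / 2))
  pre <- shockTrace(time = tt[1:imin], signal = y[1:imin],
                    temperature = trace@temperature, shockKind = "water",
                    conditions = trace@conditions)
  preFit <- fitShrinkageRate(pre)
  vinf <- trace@conditions@osmIn / trace@conditions@osmOut
  span <- abs(preFit@amplitude) / (1 - vinf)
  new("SlopeFit", m = mRaw / span, window = as.integer(c(i0, i1)), r2 = r2)
}
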