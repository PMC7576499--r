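# Forward simulation of stopped-flow osmotic-shock experiments.
#
# Two generator modes:
#  * "exponential": the exact inverse of the estimation chain. Shrinkage is
#    a single exponential whose rate is back-computed from the Pf formula
#    k = Pf * Vw * (osm_out)_inf / (V0/A); glycerol shocks append a linear
#    re-swelling of slope m = Pgly / (V0/A) once the shrinkage transient
#    has decayed to 0.5% of its amplitude.
#  * "ode": a mechanistic two-state model (relative volume v, internal
#    permeant amount g per initial volume, osmolar units):
#        dv/dt = -(Pf*Vw/(V0/A)) * (C_out - C_in)          C_in = (s+g)/va
#        dg/dt =  (Pgly/(V0/A))  * (Cgly_out - g/va)
#    with va = v - (1 - activeFraction) the osmotically active volume, s
#    the conserved impermeant internal osmolarity, and C_out constant (the
#    bath is infinite). For a sorbitol shock the external solute is all
#    impermeant (Cgly_out = 0); for a glycerol shock the shock solution is
#    the permeant itself (Cgly_out = C_out).
#
# Both permeabilities scale with temperature by the Arrhenius factor
# exp(-Ea/R * (1/T - 1/Tref)).

arrheniusFactor <- function(ea, temperatureC, tRefC) {
  exp(-ea / RGAS_KCAL *
        (1 / celsiusToKelvin(temperatureC) - 1 / celsiusToKelvin(tRefC)))
}

# k <-> Pf under the initial-slope convention of the stopped-flow formula.
rateFromPf <- function(pf, geometry, conditions) {
  pf * geometry@vW * (conditions@osmOut * 1e-3) / geometry@v0OverA
}

pfFromRate <- function(k, geometry, conditions) {
  k * geometry@v0OverA / (geometry@vW * conditions@osmOut * 1e-3)
}

# Evaluate an expression with a private, restored RNG state.
withLocalSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(expr)
}

# Noiseless relative-volume trajectory; shared by both public simulators
# and by validation tests.
simulateVolume <- function(params, temperature) {
  pf <- params@pfTrue * arrheniusFactor(params@eaWater, temperature, params@tRef)
  pgly <- params@pglyTrue *
    arrheniusFactor(params@eaGlycerol, temperature, params@tRef)
  cond <- params@conditions
  geom <- params@geometry
  tt <- seq(0, params@duration, by = params@dt)
  glycerolShock <- cond@shockSolute == "glycerol"

  if (params@mode == "exponential") {
    vinf <- cond@osmIn / cond@osmOut
    k <- rateFromPf(pf, geom, cond)
    v <- vinf + (1 - vinf) * exp(-k * tt)
    if (glycerolShock && pgly > 0) {
      # switch to the linear re-swelling once the shrinkage transient has
      # decayed to 0.5% of its amplitude
      ts <- log(200) / k
      m <- pgly / geom@v0OverA
      lin <- tt > ts
      v[lin] <- vinf + (1 - vinf) / 200 + m * (tt[lin] - ts)
    }
  } else {
    a <- pf * geom@vW * 1e-3 / geom@v0OverA        # per osmol/L
    b <- pgly / geom@v0OverA
    s <- cond@osmIn
    cout <- cond@osmOut
    cgly <- if (glycerolShock) cond@osmOut else 0
    beta <- 1 - geom@activeFraction                 # osmotically dead volume
    deriv <- function(t, y, parms) {
      va <- y[1L] - beta
      list(c(-a * (cout - (s + y[2L]) / va),
             b * (cgly - y[2L] / va)))
    }
    sol <- deSolve::ode(c(v = 1, g = 0), tt, deriv, NULL,
                        rtol = 1e-10, atol = 1e-12)
    v <- sol[, 2L]
  }
  list(time = tt, v = v, pf = pf, pgly = pgly,
       shockKind = if (glycerolShock) "glycerol" else "water")
}

#' Simulate one stopped-flow shock trace
#'
#' Forward-simulates the fluorescence signal of a hyperosmotic shock:
#' cells equilibrated at `conditions@osmIn` osmol/L are shocked to
#' `conditions@osmOut` osmol/L of either an impermeant solute (sorbitol;
#' water efflux and shrinkage only) or the permeant glycerol (shrinkage
#' followed by re-swelling as glycerol and water re-enter). The signal is
#' linear in relative cell volume, `F = baseline + span * v`, with additive
#' i.i.d. Gaussian noise of standard deviation `noiseSd * span`.
#'
#' @param params a [SimulationParams-class]
#' @param temperature shock temperature, degC (0-45)
#' @param seed optional integer overriding `params@seed` for the noise
#' @return a [ShockTrace-class] of length `duration/dt + 1`
#' @examples
#' tr <- simulateShock(simulationParams(noiseSd = 0), temperature = 23)
#' @export
simulateShock <- function(params, temperature = params@tRef, seed = NULL) {
  validObject(params)
  if (temperature < 0 || temperature > 45)
    stop("invalid-parameters: temperature must lie within 0-45 degC")
  traceSeed <- if (is.null(seed)) params@seed else as.integer(seed)
  sim <- simulateVolume(params, temperature)
  signal <- params@baseline + params@span * sim$v
  if (params@noiseSd > 0) {
    noise <- withLocalSeed(traceSeed,
      rnorm(length(signal), sd = params@noiseSd * abs(params@span)))
    signal <- signal + noise
  }
  shockTrace(time = sim$time, signal = signal, temperature = temperature,
             shockKind = sim$shockKind, conditions = params@conditions,
             meta = list(mode = params@mode, seed = traceSeed,
                         temperature_C = temperature))
}

#' Simulate replicate traces at one temperature
#'
#' Replicate `r` uses seed `params@seed + r` (temperature index 0 of the
#' scheme used by [simulateArrheniusSeries()]).
#'
#' @inheritParams simulateShock
#' @param replicates number of traces
#' @return list of [ShockTrace-class]
#' @export
simulateReplicates <- function(params, temperature = params@tRef,
                               replicates = 10L) {
  lapply(seq_len(replicates), function(r)
    simulateShock(params, temperature, seed = params@seed + r))
}

#' Simulate a temperature series for Arrhenius analysis
#'
#' Generates `replicates` traces at each temperature; the trace for
#' replicate `r` at (0-based) temperature index `i` uses seed
#' `params@seed + 1000*i + r`, so the whole design is reproducible from a
#' single seed.
#'
#' @inheritParams simulateShock
#' @param temperatures vector of at least 3 distinct temperatures, degC
#' @param replicates traces per temperature
#' @return a flat list of [ShockTrace-class], each tagged with its
#'   temperature; names are `T<temp>_r<replicate>`
#' @export
simulateArrheniusSeries <- function(params, temperatures = c(10, 15, 20, 25, 30, 35),
                                    replicates = 3L) {
  if (length(unique(temperatures)) < 3L)
    stop("insufficient-design: need at least 3 distinct temperatures")
  out <- list()
  for (i in seq_along(temperatures)) {
    for (r in seq_len(replicates)) {
      tr <- simulateShock(params, temperatures[i],
                          seed = params@seed + 1000L * (i - 1L) + r)
      out[[sprintf("T%g_r%d", temperatures[i], r)]] <- tr
    }
  }
  out
}
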