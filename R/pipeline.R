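# Orchestration: from a collection of traces (grouped by strain) to the
# per-strain permeability / activation-energy / comparison report.

estimateTrace <- function(trace, geometry) {
  if (trace@shockKind == "water") {
    waterPermeability(fitShrinkageRate(trace), geometry, trace@conditions,
                      temperature = trace@temperature)
  } else {
    glycerolPermeability(fitReswellingSlope(trace), geometry,
                         temperature = trace@temperature)
  }
}

#' Run the full kinetics estimation pipeline over a trace cohort
#'
#' Groups traces by strain, shock kind and temperature, estimates a
#' permeability per trace (technical replicates are averaged within each
#' temperature before any downstream fit), reports the mean +/- SD at the
#' reference temperature, fits Arrhenius activation energies where at
#' least three temperatures are covered, and runs pairwise Welch t-tests
#' between strains on the reference-temperature replicate values.
#'
#' Traces that fail estimation (e.g. `no-reswelling` for a strain without
#' glycerol transport) are recorded as warnings in the report, never as a
#' pipeline failure; missing temperature coverage yields a partial report
#' with a warning entry.
#'
#' @param traces list of [ShockTrace-class]
#' @param strain character vector of strain labels, one per trace
#' @param geometry a [CellGeometry-class]
#' @param tRef reference temperature (degC) for the headline estimates
#' @return a list with components `strains` (per-strain list with `pf`,
#'   `pgly`, `eaWater`, `eaGlycerol`, `pfReplicates`, `pglyReplicates`),
#'   `comparisons` (pairwise [StrainComparison-class] per kind) and
#'   `warnings` (character)
#' @export
runKineticsPipeline <- function(traces, strain, geometry = cellGeometry(),
                                tRef = 23) {
  stopifnot(length(traces) == length(strain))
  warningsLog <- character()
  note <- function(...) warningsLog <<- c(warningsLog, sprintf(...))

  perStrain <- list()
  for (s in unique(strain)) {
    idx <- which(strain == s)
    block <- list(pf = NULL, pgly = NULL, eaWater = NULL, eaGlycerol = NULL,
                  pfReplicates = numeric(), pglyReplicates = numeric())
    for (kind in c("water", "glycerol")) {
      kidx <- idx[vapply(traces[idx], function(tr) tr@shockKind == kind,
                         logical(1L))]
      if (!length(kidx)) next
      temps <- vapply(traces[kidx], traceTemperature, numeric(1L))
      byTempMeans <- list()
      for (tC in sort(unique(temps))) {
        ests <- list()
        for (i in kidx[temps == tC]) {
          e <- tryCatch(estimateTrace(traces[[i]], geometry),
                        error = function(err) {
                          note("strain %s, %s shock at %g degC: %s",
                               s, kind, tC, conditionMessage(err))
                          NULL
                        })
          if (!is.null(e)) ests[[length(ests) + 1L]] <- e
        }
        if (!length(ests)) next
        agg <- aggregateEstimates(ests)
        byTempMeans[[as.character(tC)]] <- agg
        if (isTRUE(all.equal(tC, tRef))) {
          vals <- vapply(ests, permValue, numeric(1L))
          if (kind == "water") {
            block$pf <- agg
            block$pfReplicates <- vals
          } else {
            block$pgly <- agg
            block$pglyReplicates <- vals
          }
        }
      }
      tempsCovered <- as.numeric(names(byTempMeans))
      eaSlot <- if (kind == "water") "eaWater" else "eaGlycerol"
      if (length(tempsCovered) >= 3L) {
        block[[eaSlot]] <- activationEnergy(
          tempsCovered, lapply(byTempMeans, permValue))
      } else if (length(tempsCovered) >= 1L) {
        note("strain %s: only %d temperature(s) with %s-shock estimates; %s not fitted",
             s, length(tempsCovered), kind, eaSlot)
      }
    }
    perStrain[[s]] <- block
  }

  comparisons <- list()
  ss <- names(perStrain)
  if (length(ss) >= 2L) {
    for (i in seq_len(length(ss) - 1L)) for (j in seq.int(i + 1L, length(ss))) {
      for (kind in c("pfReplicates", "pglyReplicates")) {
        a <- perStrain[[ss[i]]][[kind]]
        b <- perStrain[[ss[j]]][[kind]]
        if (length(a) >= 3L && length(b) >= 3L) {
          key <- sprintf("%s_vs_%s_%s", ss[i], ss[j],
                         if (kind == "pfReplicates") "Pf" else "Pgly")
          comparisons[[key]] <- compareStrains(a, b)
        }
      }
    }
  }
  list(strains = perStrain, comparisons = comparisons,
       warnings = warningsLog)
}
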