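# show() methods and accessors.

setMethod("show", "ShockTrace", function(object) {
  cat(sprintf("ShockTrace: %s shock, %d samples over %.3g s, %.3g degC\n",
              object@shockKind, length(object@time),
              max(object@time), object@temperature))
  cat(sprintf("  conditions: %.3g -> %.3g osmol/L (%s)\n",
              object@conditions@osmIn, object@conditions@osmOut,
              object@conditions@shockSolute))
  if (length(object@meta))
    cat("  meta:", paste(names(object@meta), unlist(lapply(object@meta, format)),
                         sep = "=", collapse = ", "), "\n")
})

setMethod("show", "PermeabilityEstimate", function(object) {
  cat(sprintf("%s = %.4g", object@kind, object@value))
  if (is.finite(object@sd)) cat(sprintf(" +/- %.3g", object@sd))
  cat(sprintf(" cm/s (n = %d", object@n))
  if (is.finite(object@temperature))
    cat(sprintf(", %.3g degC", object@temperature))
  cat(")")
  if (object@flagged) cat("  [flagged: reverse flux]")
  cat("\n")
})

setMethod("show", "ArrheniusResult", function(object) {
  cat(sprintf("ArrheniusResult: Ea = %.4g kcal/mol (%d temperatures, r2 = %.4f)\n",
              object@ea, nrow(object@points), object@r2))
})

setMethod("show", "StrainComparison", function(object) {
  cat(sprintf("Welch t-test: t = %.4g, p = %.3g  [%s]\n",
              object@statistic, object@pValue, object@significanceLabel))
})

setMethod("show", "ChannelStructure", function(object) {
  a <- object@atoms
  cat(sprintf("ChannelStructure: %d atoms, %d residues, chains %s\n",
              nrow(a), length(unique(paste(a$chain, a$resNo))),
              paste(unique(a$chain), collapse = ",")))
  if (nrow(a))
    cat(sprintf("  z range: %.2f .. %.2f A; vdw assigned: %s\n",
                min(a$z), max(a$z), !anyNA(a$vdw)))
})

setMethod("show", "PoreProfile", function(object) {
  cat(sprintf("PoreProfile: %d planes, z %.2f .. %.2f A (step %.3g)\n",
              length(object@z), min(object@z), max(object@z),
              if (length(object@z) > 1L) object@z[2L] - object@z[1L] else NA))
  ok <- !object@blocked
  if (any(ok))
    cat(sprintf("  radius: min %.3f at z = %.2f; %d blocked plane(s)\n",
                min(object@radius[ok]),
                object@z[ok][which.min(object@radius[ok])],
                sum(object@blocked)))
})

setMethod("show", "HydropathyRatio", function(object) {
  cat(sprintf("HydropathyRatio (%s, %s): %d hydrophobic / %d hydrophilic = %s\n",
              object@region, object@scaleName, object@nHydrophobic,
              object@nHydrophilic,
              if (is.finite(object@ratio)) sprintf("%.3f", object@ratio) else "Inf"))
})

setMethod("show", "ChannelAlignment", function(object) {
  cat(sprintf("ChannelAlignment: %d sequences x %d columns, %d channel columns\n",
              length(object@sequences),
              if (length(object@sequences)) Biostrings::width(object@sequences)[1L] else 0L,
              length(object@channelColumns)))
  cat(sprintf("  reference: %s\n", object@reference))
})

setMethod("show", "MutationSpec", function(object) {
  cat(sprintf("%s%d%s\n", object@wildType, object@position, object@mutant))
})

# Accessors -------------------------------------------------------------

#' Accessors for aquaflux objects
#'
#' Small, read-only accessors so user code never reaches into slots.
#'
#' @param x an aquaflux S4 object
#' @return the requested component
#' @name accessors
NULL

#' @rdname accessors
#' @export
traceTime <- function(x) { stopifnot(is(x, "ShockTrace")); x@time }

#' @rdname accessors
#' @export
traceSignal <- function(x) { stopifnot(is(x, "ShockTrace")); x@signal }

#' @rdname accessors
#' @export
traceTemperature <- function(x) { stopifnot(is(x, "ShockTrace")); x@temperature }

#' @rdname accessors
#' @export
shockKind <- function(x) { stopifnot(is(x, "ShockTrace")); x@shockKind }

#' @rdname accessors
#' @export
rateConstant <- function(x) { stopifnot(is(x, "RateFit")); x@k }

#' @rdname accessors
#' @export
slopeValue <- function(x) { stopifnot(is(x, "SlopeFit")); x@m }

#' @rdname accessors
#' @export
permValue <- function(x) { stopifnot(is(x, "PermeabilityEstimate")); x@value }

#' @rdname accessors
#' @export
permSd <- function(x) { stopifnot(is(x, "PermeabilityEstimate")); x@sd }

#' @rdname accessors
#' @export
activationEnergyValue <- function(x) { stopifnot(is(x, "ArrheniusResult")); x@ea }

#' @rdname accessors
#' @export
atomTable <- function(x) { stopifnot(is(x, "ChannelStructure")); x@atoms }

#' @rdname accessors
#' @export
profileZ <- function(x) { stopifnot(is(x, "PoreProfile")); x@z }

#' @rdname accessors
#' @export
profileRadius <- function(x) { stopifnot(is(x, "PoreProfile")); x@radius }

#' @rdname accessors
#' @export
alignedSequences <- function(x) { stopifnot(is(x, "ChannelAlignment")); x@sequences }

#' @rdname accessors
#' @export
channelColumns <- function(x) { stopifnot(is(x, "ChannelAlignment")); x@channelColumns }

#' @rdname accessors
#' @export
columnClasses <- function(x) { stopifnot(is(x, "ChannelAlignment")); x@columnClasses }
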