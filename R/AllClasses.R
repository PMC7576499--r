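# S4 classes for the kinetics, simulation, structure and conservation
# layers. Validity methods enforce the physical invariants; constructors
# (lower camelCase, same name with a lowercase initial where exported)
# supply defaults.

#' Shock conditions: osmolarities of the stopped-flow experiment
#'
#' Describes one hyperosmotic shock: the osmolarity the cells were
#' equilibrated in (initial internal osmolarity), the final external
#' osmolarity after mixing, and the identity of the shock solute
#' (impermeant sorbitol or permeant glycerol).
#'
#' @slot osmIn initial internal osmolarity, osmol/L
#' @slot osmOut final external osmolarity after the shock, osmol/L
#' @slot shockSolute `"sorbitol"` or `"glycerol"`
#' @exportClass ShockConditions
setClass("ShockConditions", representation(
  osmIn = "numeric", osmOut = "numeric", shockSolute = "character"))

setValidity("ShockConditions", function(object) {
  msg <- character()
  if (length(object@osmIn) != 1L || !is.finite(object@osmIn) || object@osmIn <= 0)
    msg <- c(msg, "osmIn must be a single positive number (osmol/L)")
  if (length(object@osmOut) != 1L || !is.finite(object@osmOut) || object@osmOut <= 0)
    msg <- c(msg, "osmOut must be a single positive number (osmol/L)")
  if (length(msg) == 0L && object@osmOut <= object@osmIn)
    msg <- c(msg, "hyperosmotic shock requires osmOut > osmIn")
  if (!object@shockSolute %in% c("sorbitol", "glycerol"))
    msg <- c(msg, "shockSolute must be 'sorbitol' or 'glycerol'")
  if (length(msg)) msg else TRUE
})

#' @param osmIn,osmOut,shockSolute see slots
#' @rdname ShockConditions-class
#' @export
shockConditions <- function(osmIn = 1.4, osmOut = 2.1,
                            shockSolute = c("sorbitol", "glycerol")) {
  new("ShockConditions", osmIn = osmIn, osmOut = osmOut,
      shockSolute = match.arg(shockSolute))
}

#' Cell geometry of the yeast suspension
#'
#' @slot v0OverA initial cell volume to area ratio \eqn{V_0/A}, cm
#' @slot vW molar volume of water \eqn{V_w}, cm^3/mol
#' @slot activeFraction osmotically active volume fraction in (0, 1]
#' @exportClass CellGeometry
setClass("CellGeometry", representation(
  v0OverA = "numeric", vW = "numeric", activeFraction = "numeric"))

setValidity("CellGeometry", function(object) {
  msg <- character()
  if (object@v0OverA <= 0) msg <- c(msg, "v0OverA must be positive")
  if (object@vW <= 0) msg <- c(msg, "vW must be positive")
  if (object@activeFraction <= 0 || object@activeFraction > 1)
    msg <- c(msg, "activeFraction must lie in (0, 1]")
  if (length(msg)) msg else TRUE
})

#' @param v0OverA,vW,activeFraction see slots
#' @rdname CellGeometry-class
#' @export
cellGeometry <- function(v0OverA = V0A_DEFAULT, vW = VW_DEFAULT,
                         activeFraction = 1) {
  new("CellGeometry", v0OverA = v0OverA, vW = vW,
      activeFraction = activeFraction)
}

#' One stopped-flow fluorescence trace
#'
#' @slot time seconds, strictly increasing, starting at 0
#' @slot signal fluorescence (arbitrary units, linear in relative volume)
#' @slot temperature degrees Celsius
#' @slot shockKind `"water"` or `"glycerol"`
#' @slot conditions a [ShockConditions-class]
#' @slot meta list of provenance fields (mode, seed, ...)
#' @exportClass ShockTrace
setClass("ShockTrace", representation(
  time = "numeric", signal = "numeric", temperature = "numeric",
  shockKind = "character", conditions = "ShockConditions", meta = "list"))

setValidity("ShockTrace", function(object) {
  msg <- character()
  n <- length(object@time)
  if (n < 10L) msg <- c(msg, "trace must have at least 10 samples")
  if (length(object@signal) != n)
    msg <- c(msg, "time and signal lengths differ")
  if (n && object@time[1L] != 0) msg <- c(msg, "time must start at 0")
  if (n > 1L && any(diff(object@time) <= 0))
    msg <- c(msg, "time must be strictly increasing")
  if (!all(is.finite(object@time)) || !all(is.finite(object@signal)))
    msg <- c(msg, "all values must be finite")
  if (!object@shockKind %in% c("water", "glycerol"))
    msg <- c(msg, "shockKind must be 'water' or 'glycerol'")
  if (length(msg)) msg else TRUE
})

#' @param time,signal,temperature,shockKind,conditions,meta see slots
#' @rdname ShockTrace-class
#' @export
shockTrace <- function(time, signal, temperature = 23,
                       shockKind = c("water", "glycerol"),
                       conditions = shockConditions(), meta = list()) {
  new("ShockTrace", time = as.numeric(time), signal = as.numeric(signal),
      temperature = temperature, shockKind = match.arg(shockKind),
      conditions = conditions, meta = meta)
}

#' Parameters of the forward shock simulation
#'
#' Houses the generating ("true") permeabilities and activation energies,
#' the geometry and shock conditions, sampling grid, noise level and mode.
#' Defaults are the conditions of the native VvTnNIP1;1 strain: water
#' permeability 6.78e-4 cm/s and glycerol permeability 24.5e-8 cm/s at the
#' 23 degC reference temperature, activation energies 9.80 (water) and 6.93
#' (glycerol) kcal/mol, 1.4 -> 2.1 osmol/L shock.
#'
#' @slot pfTrue osmotic water permeability at `tRef`, cm/s
#' @slot pglyTrue glycerol permeability at `tRef`, cm/s (0 allowed)
#' @slot eaWater,eaGlycerol Arrhenius activation energies, kcal/mol
#' @slot tRef reference temperature for the permeabilities, degC
#' @slot geometry a [CellGeometry-class]
#' @slot conditions a [ShockConditions-class]
#' @slot duration,dt acquisition window and sampling step, s
#' @slot noiseSd additive Gaussian noise, as a fraction of the signal span
#' @slot mode `"exponential"` (exact inverse of the estimator) or `"ode"`
#'   (mechanistic volume/solute model)
#' @slot baseline,span linear fluorescence transduction
#'   `F = baseline + span * v`
#' @slot seed integer seed for the trace noise
#' @exportClass SimulationParams
setClass("SimulationParams", representation(
  pfTrue = "numeric", pglyTrue = "numeric",
  eaWater = "numeric", eaGlycerol = "numeric", tRef = "numeric",
  geometry = "CellGeometry", conditions = "ShockConditions",
  duration = "numeric", dt = "numeric", noiseSd = "numeric",
  mode = "character", baseline = "numeric", span = "numeric",
  seed = "integer"))

setValidity("SimulationParams", function(object) {
  msg <- character()
  if (object@pfTrue < 0) msg <- c(msg, "invalid-parameters: pfTrue must be >= 0")
  if (object@pglyTrue < 0) msg <- c(msg, "invalid-parameters: pglyTrue must be >= 0")
  if (object@duration <= 0) msg <- c(msg, "invalid-parameters: duration must be > 0")
  if (object@dt <= 0 || object@dt >= object@duration)
    msg <- c(msg, "invalid-parameters: need 0 < dt < duration")
  if (object@noiseSd < 0) msg <- c(msg, "invalid-parameters: noiseSd must be >= 0")
  if (!object@mode %in% c("exponential", "ode"))
    msg <- c(msg, "mode must be 'exponential' or 'ode'")
  if (object@span == 0) msg <- c(msg, "span must be nonzero")
  if (length(msg)) msg else TRUE
})

#' @param pfTrue,pglyTrue,eaWater,eaGlycerol,tRef,geometry,conditions see slots
#' @param duration,dt,noiseSd,mode,baseline,span,seed see slots
#' @rdname SimulationParams-class
#' @export
simulationParams <- function(pfTrue = 6.78e-4, pglyTrue = 24.5e-8,
                             eaWater = 9.80, eaGlycerol = 6.93, tRef = 23,
                             geometry = cellGeometry(),
                             conditions = shockConditions(),
                             duration = 60, dt = 0.01, noiseSd = 0.01,
                             mode = c("exponential", "ode"),
                             baseline = 0, span = 1, seed = 1L) {
  new("SimulationParams", pfTrue = pfTrue, pglyTrue = pglyTrue,
      eaWater = eaWater, eaGlycerol = eaGlycerol, tRef = tRef,
      geometry = geometry, conditions = conditions, duration = duration,
      dt = dt, noiseSd = noiseSd, mode = match.arg(mode),
      baseline = baseline, span = span, seed = as.integer(seed))
}

# Fit results -----------------------------------------------------------

#' Single-exponential shrinkage fit
#' @slot k rate constant, 1/s
#' @slot amplitude,baseline signal units
#' @slot rmse root-mean-square residual, signal units
#' @exportClass RateFit
setClass("RateFit", representation(
  k = "numeric", amplitude = "numeric", baseline = "numeric",
  rmse = "numeric"))

setValidity("RateFit", function(object) {
  if (object@k <= 0) "k must be > 0 on a successful fit" else TRUE
})

#' Linear re-swelling slope fit
#' @slot m slope in relative-volume units, 1/s
#' @slot window integer index interval of the fitted region
#' @slot r2 coefficient of determination of the linear fit
#' @exportClass SlopeFit
setClass("SlopeFit", representation(
  m = "numeric", window = "integer", r2 = "numeric"))

setValidity("SlopeFit", function(object) {
  msg <- character()
  if (length(object@window) != 2L || diff(object@window) + 1L < 5L)
    msg <- c(msg, "window error: fit window must span at least 5 samples")
  if (length(msg)) msg else TRUE
})

#' Permeability coefficient with replicate statistics
#' @slot kind `"Pf"` or `"Pgly"`
#' @slot value,sd cm/s
#' @slot n replicate count
#' @slot temperature degC (NA when unknown)
#' @slot flagged TRUE when the estimate came from a negative slope
#'   (reverse flux) and should be interpreted with care
#' @exportClass PermeabilityEstimate
setClass("PermeabilityEstimate", representation(
  kind = "character", value = "numeric", sd = "numeric", n = "integer",
  temperature = "numeric", flagged = "logical"))

setValidity("PermeabilityEstimate", function(object) {
  msg <- character()
  if (!object@kind %in% c("Pf", "Pgly"))
    msg <- c(msg, "kind must be 'Pf' or 'Pgly'")
  if (!object@flagged && object@value < 0)
    msg <- c(msg, "value must be >= 0 unless flagged")
  if (object@n < 1L) msg <- c(msg, "n must be >= 1")
  if (length(msg)) msg else TRUE
})

#' Arrhenius regression result
#' @slot ea activation energy, kcal/mol
#' @slot lnPrefactor intercept of ln P vs 1/T
#' @slot r2 coefficient of determination
#' @slot points data.frame with columns `temperatureK`, `permeability`
#' @exportClass ArrheniusResult
setClass("ArrheniusResult", representation(
  ea = "numeric", lnPrefactor = "numeric", r2 = "numeric",
  points = "data.frame"))

setValidity("ArrheniusResult", function(object) {
  msg <- character()
  if (nrow(object@points) < 3L) msg <- c(msg, "need at least 3 points")
  if (anyDuplicated(object@points$temperatureK))
    msg <- c(msg, "temperatures must be distinct")
  if (length(msg)) msg else TRUE
})

#' Two-strain comparison (Welch t-test)
#' @slot statistic t statistic
#' @slot pValue two-sided p value
#' @slot significanceLabel `"ns"`, `"**"` (p < 0.01) or `"***"` (p < 0.001)
#' @exportClass StrainComparison
setClass("StrainComparison", representation(
  statistic = "numeric", pValue = "numeric", significanceLabel = "character"))

setValidity("StrainComparison", function(object) {
  if (object@pValue < 0 || object@pValue > 1) "pValue must lie in [0, 1]" else TRUE
})

# Structure layer -------------------------------------------------------

#' Channel protein structure (atom table)
#'
#' A thin container around an atom table sufficient for pore profiling:
#' serial, element, residue name/number, chain and Cartesian coordinates
#' in Angstrom, plus a van der Waals radius column (NA until assigned with
#' [assignVdwRadii()]).
#'
#' @slot atoms data.frame with columns `serial`, `element`, `resName`,
#'   `resNo`, `chain`, `x`, `y`, `z`, `vdw`
#' @exportClass ChannelStructure
setClass("ChannelStructure", representation(atoms = "data.frame"))

setValidity("ChannelStructure", function(object) {
  a <- object@atoms
  need <- c("serial", "element", "resName", "resNo", "chain",
            "x", "y", "z", "vdw")
  if (!all(need %in% names(a)))
    return(paste("atoms must have columns:", paste(need, collapse = ", ")))
  msg <- character()
  if (nrow(a)) {
    if (!all(is.finite(a$x) & is.finite(a$y) & is.finite(a$z)))
      msg <- c(msg, "coordinates must be finite")
    if (!all(a$resNo >= 1)) msg <- c(msg, "residue numbers must be positive")
    if (!all(is.na(a$vdw) | a$vdw > 0))
      msg <- c(msg, "assigned vdw radii must be positive")
  }
  if (length(msg)) msg else TRUE
})

#' Pore radius profile along the channel axis
#' @slot z axial coordinate, Angstrom, ascending
#' @slot radius largest-inscribed-sphere radius per plane, Angstrom
#' @slot centerX,centerY in-plane sphere center per plane
#' @slot blocked TRUE where the search found overlap everywhere
#' @slot meta list (axis, zStep, captureRadius, search, seed)
#' @exportClass PoreProfile
setClass("PoreProfile", representation(
  z = "numeric", radius = "numeric", centerX = "numeric",
  centerY = "numeric", blocked = "logical", meta = "list"))

setValidity("PoreProfile", function(object) {
  n <- length(object@z)
  msg <- character()
  if (length(object@radius) != n || length(object@centerX) != n ||
      length(object@centerY) != n || length(object@blocked) != n)
    msg <- c(msg, "all profile vectors must have equal length")
  if (n > 1L && any(diff(object@z) <= 0))
    msg <- c(msg, "z must be ascending")
  if (any(object@radius[!object@blocked] < 0))
    msg <- c(msg, "radius must be >= 0 where not blocked")
  if (length(msg)) msg else TRUE
})

#' Axial split of a pore profile at the ar/R constriction
#' @slot boundaryZ ar/R constriction position, Angstrom
#' @slot upper,lower z-intervals (periplasmic side = larger z)
#' @slot upperEmpty,lowerEmpty TRUE when a side contains no profiled plane
#' @exportClass PoreRegionSplit
setClass("PoreRegionSplit", representation(
  boundaryZ = "numeric", upper = "numeric", lower = "numeric",
  upperEmpty = "logical", lowerEmpty = "logical"))

#' Hydrophobicity/hydrophilicity ratio of pore-lining residues
#' @slot ratio nHydrophobic / nHydrophilic (Inf when no hydrophilic residue)
#' @slot nHydrophobic,nHydrophilic counts
#' @slot region `"whole"`, `"upper"` or `"lower"`
#' @slot scaleName classification used (`"binary"` or `"kd"`)
#' @exportClass HydropathyRatio
setClass("HydropathyRatio", representation(
  ratio = "numeric", nHydrophobic = "integer", nHydrophilic = "integer",
  region = "character", scaleName = "character"))

setValidity("HydropathyRatio", function(object) {
  if (object@nHydrophilic > 0L &&
      !isTRUE(all.equal(object@ratio,
                        object@nHydrophobic / object@nHydrophilic)))
    "ratio must equal nHydrophobic/nHydrophilic" else TRUE
})

# Conservation layer ----------------------------------------------------

#' Aligned channel homologs with a channel-column mask
#' @slot sequences an aligned [Biostrings::AAStringSet] (gap `-`)
#' @slot channelColumns 1-based alignment column indices lining the pore
#' @slot reference name of the sequence anchoring ungapped numbering
#' @slot columnClasses generator ground-truth class per channel column
#'   (`character(0)` for alignments read from file)
#' @exportClass ChannelAlignment
setClass("ChannelAlignment", representation(
  sequences = "AAStringSet", channelColumns = "integer",
  reference = "character", columnClasses = "character"))

setValidity("ChannelAlignment", function(object) {
  msg <- character()
  w <- Biostrings::width(object@sequences)
  if (length(w) && length(unique(w)) != 1L)
    msg <- c(msg, "aligned sequences must have equal lengths")
  if (length(w) && length(object@channelColumns) &&
      (min(object@channelColumns) < 1L || max(object@channelColumns) > w[1L]))
    msg <- c(msg, "channelColumns out of alignment range")
  if (!object@reference %in% names(object@sequences))
    msg <- c(msg, "reference sequence not present in alignment")
  if (length(object@columnClasses) &&
      length(object@columnClasses) != length(object@channelColumns))
    msg <- c(msg, "columnClasses must match channelColumns in length")
  if (length(msg)) msg else TRUE
})

#' @param sequences,channelColumns,reference,columnClasses see slots
#' @rdname ChannelAlignment-class
#' @export
channelAlignment <- function(sequences, channelColumns,
                             reference = names(sequences)[1L],
                             columnClasses = character()) {
  if (!methods::is(sequences, "AAStringSet"))
    sequences <- Biostrings::AAStringSet(sequences)
  new("ChannelAlignment", sequences = sequences,
      channelColumns = as.integer(channelColumns), reference = reference,
      columnClasses = columnClasses)
}

#' ar/R point-mutation specification (e.g. W86T)
#' @slot wildType,mutant one-letter amino acid codes
#' @slot position 1-based ungapped position in the reference sequence
#' @exportClass MutationSpec
setClass("MutationSpec", representation(
  wildType = "character", position = "integer", mutant = "character"))

setValidity("MutationSpec", function(object) {
  msg <- character()
  if (!object@wildType %in% AA1 || !object@mutant %in% AA1)
    msg <- c(msg, "residues must be one of the 20 amino-acid letters")
  if (object@position < 1L) msg <- c(msg, "position must be >= 1")
  if (length(msg)) msg else TRUE
})
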