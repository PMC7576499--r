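# Shared fixture builders. All synthetic, generated at test time.

nativeParams <- function(...) {
  args <- utils::modifyList(
    list(pfTrue = 6.78e-4, pglyTrue = 24.5e-8, eaWater = 9.80,
         eaGlycerol = 6.93, tRef = 23),
    list(...))
  do.call(simulationParams, args)
}

waterParams <- function(noiseSd = 0, seed = 1L, mode = "exponential", ...) {
  nativeParams(conditions = shockConditions(1.4, 2.1, "sorbitol"),
               noiseSd = noiseSd, seed = seed, mode = mode, ...)
}

glycerolParams <- function(noiseSd = 0, seed = 1L, mode = "exponential", ...) {
  nativeParams(conditions = shockConditions(1.4, 2.1, "glycerol"),
               noiseSd = noiseSd, seed = seed, mode = mode, ...)
}

cylinderFixture <- function(axisLength = 20, baseRadius = 4, ...) {
  makeChannelStructure(axisLength = axisLength, baseRadius = baseRadius, ...)
}

hourglassFixture <- function(axisLength = 40, baseRadius = 4,
                             constrictionRadius = 1.4, constrictionZ = 20, ...) {
  makeChannelStructure(axisLength = axisLength, baseRadius = baseRadius,
                       constrictionRadius = constrictionRadius,
                       constrictionZ = constrictionZ, ...)
}
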