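# Run configuration (YAML) and the end-to-end pipeline driver.

CONFIG_KEYS <- c("seed", "mode", "noise_sd", "geometry", "osmolarity",
                 "temperatures", "replicates", "reference_temperature",
                 "reference_replicates", "duration", "dt", "strains",
                 "pore", "conservation")

#' Read and validate a run configuration
#'
#' YAML with the keys: `seed`, `mode`, `noise_sd`, `geometry`
#' (`v0_over_a`, `vw`, `active_fraction`), `osmolarity` (`osm_in`,
#' `osm_out`), `temperatures`, `replicates`, `reference_temperature`,
#' `reference_replicates`, `duration`, `dt`, `strains` (list of `name`,
#' `pf`, `pgly`, `ea_water`, `ea_glycerol`) and optional `pore` /
#' `conservation` stage blocks. Unknown top-level keys are rejected and
#' all physical constraints are checked before any computation.
#'
#' @param path YAML file (or a pre-parsed list)
#' @return validated config list
#' @export
readRunConfig <- function(path) {
  cfg <- if (is.character(path)) yaml::read_yaml(path) else path
  extra <- setdiff(names(cfg), CONFIG_KEYS)
  if (length(extra))
    stop("validation: unknown config key(s): ", paste(extra, collapse = ", "))
  defaults <- list(seed = 1L, mode = "exponential", noise_sd = 0.01,
                   geometry = list(v0_over_a = V0A_DEFAULT, vw = VW_DEFAULT,
                                   active_fraction = 1),
                   osmolarity = list(osm_in = 1.4, osm_out = 2.1),
                   temperatures = c(10, 15, 20, 25, 30, 35),
                   replicates = 3L, reference_temperature = 23,
                   reference_replicates = 10L, duration = 60, dt = 0.01,
                   strains = list(), pore = list(enabled = TRUE),
                   conservation = list(enabled = TRUE))
  # modifyList drops unnamed list entries (e.g. the strains array), so
  # merge defaults key by key
  for (k in names(defaults)) {
    if (is.null(cfg[[k]])) {
      cfg[[k]] <- defaults[[k]]
    } else if (is.list(defaults[[k]]) && is.list(cfg[[k]]) &&
               length(names(defaults[[k]]))) {
      cfg[[k]] <- utils::modifyList(defaults[[k]], cfg[[k]])
    }
  }
  if (cfg$osmolarity$osm_in <= 0 || cfg$osmolarity$osm_out <= 0)
    stop("validation: osmolarities must be positive")
  if (cfg$osmolarity$osm_out <= cfg$osmolarity$osm_in)
    stop("validation: hyperosmotic shock requires osm_out > osm_in")
  if (cfg$noise_sd < 0) stop("validation: noise_sd must be >= 0")
  if (!length(cfg$strains)) stop("validation: at least one strain required")
  for (s in cfg$strains) {
    need <- c("name", "pf", "pgly", "ea_water", "ea_glycerol")
    if (!all(need %in% names(s)))
      stop("validation: each strain needs ", paste(need, collapse = ", "))
    if (s$pf < 0 || s$pgly < 0)
      stop("validation: permeabilities must be >= 0 (strain ", s$name, ")")
  }
  cfg
}

strainParams <- function(cfg, s, solute) {
  simulationParams(
    pfTrue = s$pf, pglyTrue = s$pgly, eaWater = s$ea_water,
    eaGlycerol = s$ea_glycerol, tRef = cfg$reference_temperature,
    geometry = cellGeometry(cfg$geometry$v0_over_a, cfg$geometry$vw,
                            cfg$geometry$active_fraction),
    conditions = shockConditions(cfg$osmolarity$osm_in,
                                 cfg$osmolarity$osm_out, solute),
    duration = cfg$duration, dt = cfg$dt, noiseSd = cfg$noise_sd,
    mode = cfg$mode, seed = cfg$seed)
}

estimateToList <- function(e) {
  if (is.null(e)) return(NULL)
  list(kind = e@kind, value = e@value, sd = e@sd, n = e@n,
       temperature = e@temperature, flagged = e@flagged)
}

arrheniusToList <- function(a) {
  if (is.null(a)) return(NULL)
  list(ea_kcal_mol = a@ea, ln_prefactor = a@lnPrefactor, r2 = a@r2,
       temperatures_K = a@points$temperatureK,
       permeability = a@points$permeability)
}

#' Run the end-to-end demonstration pipeline
#'
#' Simulation -> trace files -> estimation -> report, plus the structural
#' (toy channel profiling + hydropathy) and conservation stages. All
#' randomness flows from the config seed; rerunning with the same config
#' reproduces every output byte for byte. A `manifest.json` records the
#' package version, per-stage status and md5 checksums of the outputs; a
#' failing stage is recorded there and its dependent stages are skipped.
#'
#' @param config path to a YAML config or a config list
#'   (see [readRunConfig()])
#' @param outDir output directory (created; must be empty or absent)
#' @return the manifest, invisibly
#' @export
runEndToEnd <- function(config, outDir) {
  cfg <- readRunConfig(config)
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(outDir, "traces"), showWarnings = FALSE)
  manifest <- list(package = "aquaflux",
                   version = as.character(utils::packageVersion("aquaflux")),
                   seed = cfg$seed, stages = list(), checksums = list())
  written <- character()
  runStage <- function(name, dependsOn = NULL, fn) {
    for (d in dependsOn) {
      if (!identical(manifest$stages[[d]], "ok")) {
        manifest$stages[[name]] <<- paste0("skipped (", d, " failed)")
        return(invisible(NULL))
      }
    }
    res <- tryCatch({ fn(); "ok" },
                    error = function(e) paste0("error: ", conditionMessage(e)))
    manifest$stages[[name]] <<- res
    invisible(NULL)
  }

  traces <- list(); strainOf <- character()
  runStage("simulate", NULL, function() {
    for (s in cfg$strains) {
      for (solute in c("sorbitol", "glycerol")) {
        p <- strainParams(cfg, s, solute)
        reps <- simulateReplicates(p, cfg$reference_temperature,
                                   cfg$reference_replicates)
        series <- simulateArrheniusSeries(p, cfg$temperatures, cfg$replicates)
        all <- c(reps, series)
        names(all)[seq_along(reps)] <- sprintf("ref_r%d", seq_along(reps))
        for (nm in names(all)) {
          f <- file.path(outDir, "traces",
                         sprintf("%s_%s_%s.csv", s$name, solute, nm))
          writeShockTrace(all[[nm]], f)
          written <<- c(written, f, paste0(f, ".json"))
        }
        traces <<- c(traces, all)
        strainOf <<- c(strainOf, rep(s$name, length(all)))
      }
    }
  })

  runStage("kinetics", "simulate", function() {
    geom <- cellGeometry(cfg$geometry$v0_over_a, cfg$geometry$vw,
                         cfg$geometry$active_fraction)
    rep <- runKineticsPipeline(traces, strainOf, geom,
                               tRef = cfg$reference_temperature)
    out <- list(strains = lapply(rep$strains, function(b) list(
                  Pf = estimateToList(b$pf), Pgly = estimateToList(b$pgly),
                  Ea_water = arrheniusToList(b$eaWater),
                  Ea_glycerol = arrheniusToList(b$eaGlycerol))),
                comparisons = lapply(rep$comparisons, function(cp) list(
                  statistic = cp@statistic, p_value = cp@pValue,
                  label = cp@significanceLabel)),
                warnings = rep$warnings)
    f <- file.path(outDir, "kinetics_report.json")
    jsonlite::write_json(out, f, auto_unbox = TRUE, digits = NA, pretty = TRUE)
    written <<- c(written, f)
  })

  runStage("pore", NULL, function() {
    if (!isTRUE(cfg$pore$enabled)) return()
    zStep <- cfg$pore$z_step %||% 0.5
    cyl <- makeChannelStructure(axisLength = 40, baseRadius = 4)
    hg <- makeChannelStructure(axisLength = 40, baseRadius = 4,
                               constrictionRadius = 1.4, constrictionZ = 20)
    for (nm in c("cylinder", "hourglass")) {
      st <- if (nm == "cylinder") cyl else hg
      pr <- poreProfile(st, zStep = zStep,
                        search = cfg$pore$search %||% "anneal",
                        seed = cfg$seed)
      f <- file.path(outDir, sprintf("pore_profile_%s.tsv", nm))
      writePoreProfile(pr, f)
      written <<- c(written, f)
      lining <- poreLiningResidues(st, pr)
      cons <- minConstriction(pr)
      hr <- hydropathyRatio(st, lining)
      split <- splitRegions(pr, cons[["z"]])
      hrUp <- hydropathyRatio(st, lining, split = split, region = "upper")
      rep <- list(constriction_z_A = cons[["z"]],
                  constriction_radius_A = cons[["radius"]],
                  n_lining_residues = nrow(lining),
                  hydropathy = list(
                    whole = list(ratio = hr@ratio, n_hydrophobic = hr@nHydrophobic,
                                 n_hydrophilic = hr@nHydrophilic),
                    upper = list(ratio = hrUp@ratio, n_hydrophobic = hrUp@nHydrophobic,
                                 n_hydrophilic = hrUp@nHydrophilic)))
      f <- file.path(outDir, sprintf("pore_report_%s.json", nm))
      jsonlite::write_json(rep, f, auto_unbox = TRUE, digits = NA, pretty = TRUE)
      written <<- c(written, f)
    }
  })

  runStage("conserve", NULL, function() {
    if (!isTRUE(cfg$conservation$enabled)) return()
    nCols <- cfg$conservation$n_cols %||% 60L
    aln <- makeAlignment(nSeqs = cfg$conservation$n_seqs %||% 4L,
                         nCols = nCols,
                         channelCols = seq_len(min(cfg$conservation$n_channel_cols %||% 29L,
                                                   nCols)),
                         seed = cfg$seed)
    f <- file.path(outDir, "alignment.fasta")
    writeChannelAlignment(aln, f)
    cls <- classifyChannelColumns(aln)
    f2 <- file.path(outDir, "conservation_counts.json")
    jsonlite::write_json(list(identical = cls$identical, similar = cls$similar,
                              dissimilar = cls$dissimilar,
                              n_excluded = cls$nExcluded),
                         f2, auto_unbox = TRUE, digits = NA, pretty = TRUE)
    f3 <- file.path(outDir, "conservation_columns.tsv")
    write.table(data.frame(column = names(cls$perColumn),
                           class = unname(cls$perColumn)),
                f3, sep = "\t", row.names = FALSE, quote = FALSE)
    written <<- c(written, f, paste0(f, ".json"), f2, f3)
  })

  manifest$checksums <- as.list(tools::md5sum(sort(unique(written))))
  names(manifest$checksums) <- basename(sort(unique(written)))
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
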