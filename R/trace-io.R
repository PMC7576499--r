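# File formats: trace CSV + JSON sidecar, aligned FASTA + channel-column
# JSON, pore-profile TSV.

#' Write / read a shock trace as CSV with a JSON metadata sidecar
#'
#' The CSV has header `time_s,signal`; the sidecar `<path>.json` records
#' `temperature_C`, `shock_kind`, `osm_in_osmolar`, `osm_out_osmolar`,
#' `shock_solute`, `seed` and `mode`.
#'
#' @param trace a [ShockTrace-class]
#' @param path CSV file path
#' @return `path` invisibly (write); a [ShockTrace-class] (read)
#' @export
writeShockTrace <- function(trace, path) {
  write.csv(data.frame(time_s = trace@time, signal = trace@signal),
            path, row.names = FALSE, quote = FALSE)
  meta <- list(temperature_C = trace@temperature,
               shock_kind = trace@shockKind,
               osm_in_osmolar = trace@conditions@osmIn,
               osm_out_osmolar = trace@conditions@osmOut,
               shock_solute = trace@conditions@shockSolute,
               seed = trace@meta$seed %||% NA,
               mode = trace@meta$mode %||% NA)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' @param path CSV file written by [writeShockTrace()]
#' @rdname writeShockTrace
#' @export
readShockTrace <- function(path) {
  d <- read.csv(path)
  metaPath <- paste0(path, ".json")
  if (!file.exists(metaPath))
    stop("missing metadata sidecar: ", metaPath)
  m <- jsonlite::read_json(metaPath, simplifyVector = TRUE)
  shockTrace(time = d$time_s, signal = d$signal,
             temperature = m$temperature_C, shockKind = m$shock_kind,
             conditions = shockConditions(m$osm_in_osmolar, m$osm_out_osmolar,
                                          m$shock_solute),
             meta = list(mode = m$mode, seed = m$seed,
                         temperature_C = m$temperature_C))
}

#' Write / read a channel alignment as aligned FASTA + column JSON
#'
#' The alignment goes to `path` as aligned FASTA; the channel columns (and
#' ground-truth column classes if present) to `<path>.json`.
#'
#' @param alignment a [ChannelAlignment-class]
#' @param path FASTA file path
#' @return `path` invisibly (write); a [ChannelAlignment-class] (read)
#' @export
writeChannelAlignment <- function(alignment, path) {
  Biostrings::writeXStringSet(alignment@sequences, path)
  meta <- list(channel_columns = alignment@channelColumns,
               reference = alignment@reference)
  if (length(alignment@columnClasses))
    meta$column_classes <- alignment@columnClasses
  jsonlite::write_json(meta, paste0(path, ".json"), digits = NA,
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' @rdname writeChannelAlignment
#' @export
readChannelAlignment <- function(path) {
  seqs <- Biostrings::readAAStringSet(path)
  m <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  channelAlignment(seqs, m$channel_columns, reference = m$reference,
                   columnClasses = m$column_classes %||% character())
}

#' Write / read a pore profile as TSV
#'
#' Columns: `z_A`, `radius_A`, `cx`, `cy`, `blocked`.
#'
#' @param profile a [PoreProfile-class]
#' @param path TSV file path
#' @return `path` invisibly (write); a [PoreProfile-class] (read)
#' @export
writePoreProfile <- function(profile, path) {
  d <- data.frame(z_A = profile@z, radius_A = profile@radius,
                  cx = profile@centerX, cy = profile@centerY,
                  blocked = profile@blocked)
  write.table(d, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname writePoreProfile
#' @export
readPoreProfile <- function(path) {
  d <- read.delim(path)
  new("PoreProfile", z = d$z_A, radius = d$radius_A, centerX = d$cx,
      centerY = d$cy, blocked = as.logical(d$blocked), meta = list())
}
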