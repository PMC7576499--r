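# PDB input/output (via bio3d) and van der Waals radius assignment.

#' Read a channel structure from a PDB file
#'
#' Parses ATOM (and optionally HETATM) records into a
#' [ChannelStructure-class]. Alternate locations are resolved by keeping
#' the highest-occupancy conformer of each atom (ties: first in file).
#' Coordinate fields are pre-validated so a malformed record is reported
#' with its line number.
#'
#' @param path PDB file
#' @param includeHetatm keep HETATM records (waters etc.)? Default drops
#'   them.
#' @return a [ChannelStructure-class] with `vdw = NA` (see
#'   [assignVdwRadii()])
#' @export
readStructure <- function(path, includeHetatm = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  isAtom <- grepl("^ATOM  |^HETATM", lines)
  if (!any(isAtom)) stop("empty-structure: no ATOM records in ", path)
  bad <- which(isAtom & nchar(lines) < 54)
  if (!length(bad)) {
    coords <- substr(lines[isAtom], 31, 54)
    ok <- grepl("^[ 0-9.+-]+$", coords)
    if (any(!ok)) bad <- which(isAtom)[!ok]
  }
  if (length(bad))
    stop("parse error at line ", bad[1L], ": malformed ATOM record")

  pdb <- suppressWarnings(bio3d::read.pdb(path, verbose = FALSE,
                                          rm.alt = FALSE))
  a <- pdb$atom
  if (!includeHetatm) a <- a[a$type == "ATOM", , drop = FALSE]
  if (!nrow(a)) stop("empty-structure: no ATOM records in ", path)

  # altloc: keep the highest-occupancy conformer per atom site
  alt <- a$alt
  alt[is.na(alt)] <- ""
  if (any(alt != "")) {
    key <- paste(a$chain, a$resno, a$resid, a$elety)
    occ <- a$o
    occ[is.na(occ)] <- 1
    keep <- unlist(lapply(split(seq_len(nrow(a)), key), function(ix) {
      if (length(ix) == 1L) return(ix)
      ix[which.max(occ[ix])]
    }), use.names = FALSE)
    a <- a[sort(keep), , drop = FALSE]
  }

  element <- a$elesy
  blank <- is.na(element) | element == ""
  element[blank] <- substr(gsub("[^A-Za-z].*", "", a$elety[blank]), 1L, 1L)
  atoms <- data.frame(
    serial = a$eleno, element = toupper(element), resName = a$resid,
    resNo = a$resno, chain = ifelse(is.na(a$chain), "A", a$chain),
    x = a$x, y = a$y, z = a$z, vdw = NA_real_, stringsAsFactors = FALSE)
  new("ChannelStructure", atoms = atoms)
}

#' Write a channel structure as a minimal PDB file
#'
#' ATOM records only, occupancy and B-factor 0.0, element column set.
#'
#' @param structure a [ChannelStructure-class]
#' @param path output file
#' @return `path`, invisibly
#' @export
writeStructure <- function(structure, path) {
  a <- structure@atoms
  bio3d::write.pdb(file = path,
                   xyz = as.numeric(t(as.matrix(a[, c("x", "y", "z")]))),
                   type = rep("ATOM", nrow(a)),
                   resno = a$resNo, resid = a$resName, chain = a$chain,
                   eleno = a$serial, elety = paste0(a$element, seq_len(nrow(a)) %% 10),
                   o = rep(0, nrow(a)), b = rep(0, nrow(a)),
                   elesy = a$element)
  invisible(path)
}

#' Assign van der Waals radii by element
#'
#' @param structure a [ChannelStructure-class]
#' @param radiusSet named vector of radii per element symbol (Angstrom);
#'   defaults to C 1.70, N 1.55, O 1.52, S 1.80, H 1.20
#' @param unknown `"default"` assigns 1.70 A with a warning for elements
#'   missing from `radiusSet`; `"error"` raises an unknown-element error
#' @return the structure with its `vdw` column filled
#' @export
assignVdwRadii <- function(structure, radiusSet = DEFAULT_VDW_SET,
                           unknown = c("default", "error")) {
  unknown <- match.arg(unknown)
  a <- structure@atoms
  r <- radiusSet[a$element]
  if (anyNA(r)) {
    missing <- unique(a$element[is.na(r)])
    if (unknown == "error")
      stop("unknown-element: no radius for ", paste(missing, collapse = ", "))
    warning("assigning default radius ", VDW_FALLBACK, " A to element(s): ",
            paste(missing, collapse = ", "))
    r[is.na(r)] <- VDW_FALLBACK
  }
  a$vdw <- unname(r)
  new("ChannelStructure", atoms = a)
}
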