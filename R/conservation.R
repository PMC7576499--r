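# Alignment-based channel-residue analysis: pairwise identity, column
# conservation classes, reference-position mapping and ar/R mutation
# bookkeeping.

alignmentMatrix <- function(alignment) {
  mat <- do.call(rbind, strsplit(as.character(alignment@sequences), ""))
  rownames(mat) <- names(alignment@sequences)
  mat
}

#' Pairwise percent identity of two aligned sequences
#'
#' `100 * matches / columns` where columns with a gap in either sequence
#' are excluded from both numerator and denominator.
#'
#' @param a,b aligned sequences of equal length (character strings or
#'   `AAString`); gap character `-`
#' @return percentage in `[0, 100]`
#' @export
pairwiseIdentity <- function(a, b) {
  ca <- strsplit(as.character(a), "")[[1L]]
  cb <- strsplit(as.character(b), "")[[1L]]
  if (length(ca) != length(cb))
    stop("aligned sequences must have equal lengths")
  use <- ca != "-" & cb != "-"
  if (!any(use)) stop("undefined-identity: no gap-free column pair")
  100 * sum(ca[use] == cb[use]) / sum(use)
}

#' Classify channel alignment columns as identical / similar / dissimilar
#'
#' Per channel column: \emph{identical} when every sequence carries the
#' same residue; \emph{similar} when not identical but every residue pair
#' scores positively under the similarity rule; \emph{dissimilar}
#' otherwise. Any gap makes a column dissimilar; a column consisting only
#' of gaps is flagged and excluded from the counts (with a warning).
#'
#' Two similarity rules are provided: `"blosum62"` (all pairwise BLOSUM62
#' scores > 0; the default) and `"groups"` (all residues within one
#' physicochemical group: `{ILVMA} {FWY} {ST} {DE} {KRH} {NQ} {GP} {C}`).
#'
#' @param alignment a [ChannelAlignment-class]
#' @param rule `"blosum62"` or `"groups"`
#' @return list with `identical`, `similar`, `dissimilar` counts,
#'   `perColumn` (named character vector of labels per channel column;
#'   all-gap columns labelled `"excluded"`) and `nExcluded`
#' @export
classifyChannelColumns <- function(alignment, rule = c("blosum62", "groups")) {
  rule <- match.arg(rule)
  if (length(alignment@sequences) < 2L)
    stop("need at least 2 sequences")
  mat <- alignmentMatrix(alignment)
  b62 <- if (rule == "blosum62") blosum62() else NULL
  labels <- character(length(alignment@channelColumns))
  names(labels) <- as.character(alignment@channelColumns)
  for (ci in seq_along(alignment@channelColumns)) {
    col <- mat[, alignment@channelColumns[ci]]
    if (all(col == "-")) { labels[ci] <- "excluded"; next }
    if (any(col == "-")) { labels[ci] <- "dissimilar"; next }
    u <- unique(col)
    if (length(u) == 1L) { labels[ci] <- "identical"; next }
    pairs <- utils::combn(u, 2L)
    similar <- if (rule == "blosum62") {
      all(b62[cbind(pairs[1L, ], pairs[2L, ])] > 0)
    } else {
      grp <- vapply(u, function(x)
        which(vapply(PHYSCHEM_GROUPS, function(g) x %in% g, logical(1L)))[1L],
        integer(1L))
      length(unique(grp)) == 1L
    }
    labels[ci] <- if (similar) "similar" else "dissimilar"
  }
  nExcluded <- sum(labels == "excluded")
  if (nExcluded)
    warning(nExcluded, " all-gap channel column(s) excluded from counts")
  list(identical = sum(labels == "identical"),
       similar = sum(labels == "similar"),
       dissimilar = sum(labels == "dissimilar"),
       perColumn = labels, nExcluded = nExcluded)
}

#' Parse mutation strings like "W86T"
#'
#' @param x character vector, e.g. `c("W86T", "V206I")`
#' @return list of [MutationSpec-class]
#' @export
parseMutations <- function(x) {
  lapply(x, function(s) {
    m <- regmatches(s, regexec("^([A-Z])([0-9]+)([A-Z])$", s))[[1L]]
    if (length(m) != 4L) stop("cannot parse mutation spec: ", s)
    new("MutationSpec", wildType = m[2L], position = as.integer(m[3L]),
        mutant = m[4L])
  })
}

#' Apply point mutations to an ungapped protein sequence
#'
#' Substitutions are applied sequentially (so a double mutant is the
#' composition of its two singles); each spec's wild-type residue is
#' validated against the sequence before substitution.
#'
#' @param sequence ungapped protein string (or `AAString`)
#' @param mutations character vector of specs (`"W86T"`) or a list of
#'   [MutationSpec-class]
#' @return the mutated sequence (character), same length as the input
#' @export
applyMutations <- function(sequence, mutations) {
  s <- strsplit(as.character(sequence), "")[[1L]]
  if (is.character(mutations)) mutations <- parseMutations(mutations)
  for (mu in mutations) {
    if (mu@position > length(s))
      stop("wild-type-validation: position ", mu@position,
           " beyond sequence length ", length(s))
    found <- s[mu@position]
    if (found != mu@wildType)
      stop("wild-type-validation: expected ", mu@wildType, " at position ",
           mu@position, " but found ", found)
    s[mu@position] <- mu@mutant
  }
  paste(s, collapse = "")
}

#' Map an alignment column to an ungapped reference position
#'
#' Counts the non-gap reference residues up to and including the column.
#' When the reference carries a gap at the column, the nearest preceding
#' reference position is returned with attribute `gapped = TRUE`.
#'
#' @param alignment a [ChannelAlignment-class]
#' @param column 1-based alignment column
#' @return integer reference position with attribute `gapped`
#' @export
mapColumnToReference <- function(alignment, column) {
  ref <- strsplit(as.character(alignment@sequences[[alignment@reference]]),
                  "")[[1L]]
  if (column < 1L || column > length(ref))
    stop("column out of range")
  pos <- sum(ref[seq_len(column)] != "-")
  if (pos == 0L)
    stop("no-anchor: column precedes every reference residue")
  structure(as.integer(pos), gapped = ref[column] == "-")
}
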