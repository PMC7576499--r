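# Procedural aligned-homolog generator with per-column ground truth, the
# fixture source for the conservation module.

# letter pairs scoring <= 0 under BLOSUM62 (distinct letters only)
dissimilarPairs <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      b <- blosum62()[AA1, AA1]
      idx <- which(b <= 0 & upper.tri(b), arr.ind = TRUE)
      cache <<- cbind(AA1[idx[, 1L]], AA1[idx[, 2L]])
    }
    cache
  }
})

#' Generate a synthetic channel alignment with known column classes
#'
#' Builds `nSeqs` gapless aligned sequences. Each channel column is drawn
#' as one of three conservation classes with probabilities
#' `classProbs`:
#' \describe{
#'   \item{identical}{every sequence carries the same residue.}
#'   \item{similar}{residues are drawn (at least two distinct) from one
#'     similarity group within which every pair scores > 0 under BLOSUM62
#'     (`{ILVM}`, `{FWY}`, `{ST}`, `{DE}`, `{KR}`).}
#'   \item{dissimilar}{two residues from different groups with a BLOSUM62
#'     score <= 0 are both guaranteed to appear.}
#' }
#' Non-channel columns are identical across sequences. The realized class
#' of every channel column is recorded in the returned object as ground
#' truth, so a column classifier can be validated by round trip.
#'
#' @param nSeqs number of sequences (>= 2)
#' @param nCols alignment length
#' @param channelCols 1-based channel column indices
#' @param classProbs named probabilities over
#'   `c("identical", "similar", "dissimilar")`; must sum to 1
#' @param seed integer seed
#' @return a [ChannelAlignment-class] with ground-truth `columnClasses`
#' @export
makeAlignment <- function(nSeqs = 4L, nCols = 60L,
                          channelCols = seq_len(min(29L, nCols)),
                          classProbs = c(identical = 0.5, similar = 0.3,
                                         dissimilar = 0.2),
                          seed = 0L) {
  if (nSeqs < 2L) stop("invalid-spec: need at least 2 sequences")
  if (length(channelCols) &&
      (min(channelCols) < 1L || max(channelCols) > nCols))
    stop("invalid-spec: channelCols must lie within [1, nCols]")
  probs <- classProbs[c("identical", "similar", "dissimilar")]
  if (anyNA(probs) || abs(sum(probs) - 1) > 1e-8)
    stop("invalid-spec: classProbs must cover the three classes and sum to 1")

  withLocalSeed(seed, {
    mat <- matrix("", nrow = nSeqs, ncol = nCols)
    for (j in seq_len(nCols)) mat[, j] <- sample(AA1, 1L)
    classes <- character(length(channelCols))
    for (ci in seq_along(channelCols)) {
      j <- channelCols[ci]
      cls <- sample(names(probs), 1L, prob = probs)
      classes[ci] <- cls
      if (cls == "identical") {
        mat[, j] <- sample(AA1, 1L)
      } else if (cls == "similar") {
        grp <- GENERATOR_SIMILAR_GROUPS[[sample(length(GENERATOR_SIMILAR_GROUPS), 1L)]]
        col <- sample(grp, nSeqs, replace = TRUE)
        if (length(unique(col)) == 1L)   # force at least two distinct
          col[2L] <- sample(setdiff(grp, col[1L]), 1L)
        mat[, j] <- col
      } else {
        pp <- dissimilarPairs()
        pair <- pp[sample(nrow(pp), 1L), ]
        col <- sample(pair, nSeqs, replace = TRUE)
        col[sample(nSeqs, 2L)] <- pair    # both members present
        mat[, j] <- col
      }
    }
    seqs <- Biostrings::AAStringSet(apply(mat, 1L, paste, collapse = ""))
    names(seqs) <- sprintf("seq%d", seq_len(nSeqs))
    channelAlignment(seqs, channelCols, reference = "seq1",
                     columnClasses = classes)
  })
}
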