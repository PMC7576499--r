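# Alignment generation and conservation analysis: ground-truth round
# trips, identity arithmetic, mutation bookkeeping, column mapping.

test_that("degenerate class probabilities give an all-identical alignment", {
  aln <- makeAlignment(nSeqs = 5, nCols = 40, channelCols = 1:29,
                       classProbs = c(identical = 1, similar = 0,
                                      dissimilar = 0), seed = 2)
  seqs <- as.character(alignedSequences(aln))
  expect_true(all(seqs == seqs[1]))
  cls <- classifyChannelColumns(aln)
  expect_equal(cls$identical, 29)
  expect_equal(cls$similar + cls$dissimilar, 0)
})

test_that("classifier reproduces the generator's ground truth per column", {
  for (seed in c(1, 17, 101)) {
    aln <- makeAlignment(nSeqs = 4, nCols = 60, channelCols = 11:39,
                         seed = seed)
    gt <- columnClasses(aln)
    expect_length(gt, 29)
    cls <- classifyChannelColumns(aln)
    expect_identical(unname(cls$perColumn), gt)
    expect_equal(cls$identical + cls$similar + cls$dissimilar, 29)
  }
})

test_that("pairwise identity matches hand counts and an independent oracle", {
  expect_equal(pairwiseIdentity("ACDE", "ACDE"), 100)
  expect_equal(pairwiseIdentity("AC-DE", "AG-DE"), 75)
  expect_error(pairwiseIdentity("----", "AAAA"), "undefined-identity")

  oracle <- function(a, b) {
    ca <- strsplit(a, "")[[1]]; cb <- strsplit(b, "")[[1]]
    num <- 0; den <- 0
    for (i in seq_along(ca)) {
      if (ca[i] != "-" && cb[i] != "-") {
        den <- den + 1
        if (ca[i] == cb[i]) num <- num + 1
      }
    }
    100 * num / den
  }
  set.seed(42)
  alphabet <- c(LETTERS[1:6], "-")
  for (rep in 1:20) {
    a <- paste(sample(alphabet, 30, TRUE), collapse = "")
    b <- paste(sample(alphabet, 30, TRUE), collapse = "")
    if (grepl("[^-]", a) && grepl("[^-]", b)) {
      expect_equal(pairwiseIdentity(a, b), oracle(a, b))
      expect_equal(pairwiseIdentity(a, b), pairwiseIdentity(b, a))
      expect_gte(pairwiseIdentity(a, b), 0)
      expect_lte(pairwiseIdentity(a, b), 100)
    }
  }
})

test_that("column classification follows the substitution rule and gap policy", {
  aln <- channelAlignment(c(s1 = "IWA-G", s2 = "LWAAG", s3 = "VWACT"),
                          channelColumns = 1:5)
  cls <- classifyChannelColumns(aln)
  # {I,L,V} all score > 0 under BLOSUM62 -> similar
  expect_identical(unname(cls$perColumn[1]), "similar")
  expect_identical(unname(cls$perColumn[2]), "identical")
  expect_identical(unname(cls$perColumn[4]), "dissimilar")  # gap present
  # {G, G, T}: G/T scores <= 0 -> dissimilar
  expect_identical(unname(cls$perColumn[5]), "dissimilar")

  allGap <- channelAlignment(c(s1 = "A-C", s2 = "G-T"), channelColumns = 1:3)
  expect_warning(cls2 <- classifyChannelColumns(allGap), "all-gap")
  expect_equal(cls2$nExcluded, 1)
  expect_equal(cls2$identical + cls2$similar + cls2$dissimilar, 2)
})

test_that("mutations apply, validate and invert like the ar/R specs", {
  s <- paste(rep("A", 250), collapse = "")
  substr(s, 86, 86) <- "W"
  substr(s, 206, 206) <- "V"
  m1 <- applyMutations(s, "W86T")
  expect_identical(substr(m1, 86, 86), "T")
  expect_identical(nchar(m1), nchar(s))
  double <- applyMutations(s, c("W86T", "V206I"))
  expect_identical(substr(double, 206, 206), "I")
  # identity and inversion
  expect_identical(applyMutations(s, character(0)), s)
  expect_identical(applyMutations(double, c("T86W", "I206V")), s)
  # wild-type validation
  expect_error(applyMutations(s, "V100I"), "wild-type-validation")
})

test_that("alignment columns map onto ungapped reference numbering", {
  aln <- channelAlignment(c(ref = "A-CD", other = "AGCD"),
                          channelColumns = 1:4, reference = "ref")
  expect_equal(as.integer(mapColumnToReference(aln, 3)), 2)
  expect_equal(as.integer(mapColumnToReference(aln, 4)), 3)
  # a gap column returns the preceding position, flagged
  m2 <- mapColumnToReference(aln, 2)
  expect_equal(as.integer(m2), 1)
  expect_true(attr(m2, "gapped"))
  # gapless reference: column k -> position k
  aln2 <- channelAlignment(c(ref = "MKWV"), channelColumns = 1:4)
  for (k in 1:4) expect_equal(as.integer(mapColumnToReference(aln2, k)), k)
  # column before any reference residue
  aln3 <- channelAlignment(c(ref = "--AB", x = "CDAB"), channelColumns = 1:4,
                           reference = "ref")
  expect_error(mapColumnToReference(aln3, 1), "no-anchor")

  # independent cumulative-count oracle on random gapped references
  set.seed(7)
  for (rep in 1:10) {
    chars <- sample(c("A", "C", "-"), 25, TRUE, prob = c(0.4, 0.4, 0.2))
    if (chars[1] == "-") chars[1] <- "A"
    refStr <- paste(chars, collapse = "")
    alnR <- channelAlignment(c(ref = refStr), channelColumns = 1)
    for (col in sample(25, 5)) {
      expected <- sum(chars[1:col] != "-")
      expect_equal(as.integer(mapColumnToReference(alnR, col)), expected)
    }
  }
})

test_that("mutation strings parse and validate", {
  specs <- parseMutations(c("W86T", "V206I"))
  expect_length(specs, 2)
  expect_identical(specs[[1]]@wildType, "W")
  expect_identical(specs[[1]]@position, 86L)
  expect_identical(specs[[1]]@mutant, "T")
  expect_error(parseMutations("W86"), "cannot parse")
  expect_error(parseMutations("X86T"), "amino-acid")
})
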