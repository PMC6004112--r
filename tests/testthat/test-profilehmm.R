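test_that("profile building follows the occupancy and pseudocount rules", {
  # degenerate consensus: no smoothing, deterministic emissions
  p <- buildProfile(c(a = "ACGT", b = "ACGT", c = "ACGT", d = "ACGT"),
                    "t", "order", pseudocount = 0)
  expect_identical(nMatchStates(p), 4L)
  expect_equal(diag(p@matchEmissions[, c("A", "C", "G", "T")]),
               rep(1, 4))

  # gap fraction exactly at the threshold is NOT a match column
  p2 <- buildProfile(c(a = "AC", b = "A-"), "t", "order")
  expect_identical(nMatchStates(p2), 1L)

  # Laplace pseudocount arithmetic
  p3 <- buildProfile(c(a = "AAA", b = "AAC", c = "AAG"), "t", "order",
                     pseudocount = 1)
  expect_equal(unname(p3@matchEmissions[3L, "A"]), 2 / 7)

  expect_error(buildProfile(c(a = "A-", b = "-A"), "t", "order"),
               "zero match columns")
  expect_error(buildProfile(c(a = "ACGT"), "t", "order"), ">= 2 rows")
})

test_that("per-state transition distributions are normalized", {
  for (p in c(compactOrderProfiles(), list(toyProfile(3L)))) {
    tr <- p@transitions
    expect_equal(rowSums(tr[, c("MM", "MI", "MD"), drop = FALSE]),
                 rep(1, nMatchStates(p)))
    expect_equal(rowSums(tr[, c("IM", "II"), drop = FALSE]),
                 rep(1, nMatchStates(p)))
    expect_equal(rowSums(tr[, c("DM", "DD"), drop = FALSE]),
                 rep(1, nMatchStates(p)))
  }
})

test_that("forward equals exhaustive path enumeration on small profiles", {
  # hand-parameterized toy profiles, all query lengths <= 4, vs the
  # brute-force oracle written independently of the DP
  queries <- c("A", "T", "CG", "AN", "ACG", "TTAG", "NCGT")
  worst <- 0
  for (M in 1:3) {
    for (rep in 1:3) {
      p <- toyProfile(M, seed = 100 * M + rep)
      for (q in queries)
        worst <- max(worst, abs(forwardBits(p, q) - oracleForwardBits(p, q)))
    }
  }
  # and an estimated profile, not just hand-set parameters
  pb <- buildProfile(c(a = "AC-", b = "ACG", c = "A-G"), "t", "order")
  for (q in queries)
    worst <- max(worst, abs(forwardBits(pb, q) - oracleForwardBits(pb, q)))
  expect_lt(worst, 1e-9)
})

test_that("forward scoring is directional and locally flank-stable", {
  profs <- compactOrderProfiles()
  set.seed(31)
  for (p in profs) {
    cons <- consensusSequence(p)
    rc <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(cons)))
    expect_gt(forwardBits(p, cons), forwardBits(p, rc))
    # background flanks on a full-coverage query shift the score < 1 bit
    fl <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                            collapse = "")
    padded <- paste0(fl(20), cons, fl(20))
    expect_lt(abs(forwardBits(p, padded) - forwardBits(p, cons)), 1)
  }
  expect_error(forwardBits(profs[[1L]], ""), "non-empty")
})

test_that("Gumbel calibration yields reproducible, monotone E-values", {
  p <- compactOrderProfiles()[[1L]]
  cal <- calibrateEvalue(p, nShuffles = 150L, seed = 42L)
  expect_s4_class(cal, "EvalueCalibration")
  # survival at the location parameter is 1 - exp(-1)
  expect_equal(evalue(cal, cal@mu, nTargets = 1L), 1 - exp(-1),
               tolerance = 1e-12)
  # strictly decreasing above the saturation point of the lower tail
  grid <- seq(cal@mu, cal@mu + 30, length.out = 40)
  expect_true(all(diff(evalue(cal, grid)) < 0))
  expect_equal(evalue(cal, cal@mu - 50), 1)   # lower tail saturates at 1
  # determinism: same seed, bit-identical parameters
  cal2 <- calibrateEvalue(p, nShuffles = 150L, seed = 42L)
  expect_identical(c(cal@mu, cal@lambda), c(cal2@mu, cal2@lambda))
  expect_error(calibrateEvalue(p, nShuffles = 50L), ">= 100")
})

test_that("scanning is deterministic, sorted, and tie-stable", {
  profs <- compactOrderProfiles()
  q <- consensusSequence(profs[[1L]])
  one <- scanQuery(q, profs[1L])
  expect_identical(nrow(one), 1L)

  # two identical profiles under different names: equal scores,
  # name-lexicographic order
  pa <- profs[[1L]]; pb <- profs[[1L]]
  pa@name <- "zeta"; pb@name <- "alpha"
  hits <- scanQuery(q, list(pa, pb))
  expect_equal(hits$bit_score[1L], hits$bit_score[2L])
  expect_identical(hits$profile_name, c("alpha", "zeta"))

  # pure function of (profiles, query)
  s1 <- scanQueries(c(x = q), profs)
  s2 <- scanQueries(c(x = q), profs)
  expect_identical(s1, s2)
})

test_that("reads are routed to their source profile on simulated sets", {
  spec <- compactSpec(seed = 303L)
  refs <- compactRefs()
  sim <- sampleReads(refs, spec, nReads = 120L, seed = 304L)
  hits <- scanQueries(sim$reads, compactOrderProfiles())
  top <- hits[!duplicated(hits$query_id), ]
  expect_gte(mean(top$profile_name == sim$truth$order_label), 0.95)
})

test_that("profiles round-trip through JSON-lines serialization", {
  profs <- compactOrderProfiles()
  f <- withr::local_tempfile(fileext = ".jsonl")
  writeProfiles(profs, f)
  back <- readProfiles(f)
  expect_identical(length(back), length(profs))
  q <- consensusSequence(profs[[2L]])
  for (i in seq_along(profs)) {
    expect_identical(profileName(back[[i]]), profileName(profs[[i]]))
    expect_equal(forwardBits(back[[i]], q), forwardBits(profs[[i]], q))
    expect_true(isCalibrated(back[[i]]))
  }
})

test_that("viterbi placement reconstructs the source region of a read", {
  refs <- compactRefs()
  prof <- compactOrderProfiles()[["Coleoptera"]]
  spec <- compactSpec(seed = 77L,
                      errorModel = errorModel(baseSubRate = 0,
                                              homopolymerIndelRate = 0,
                                              readLength = 120L))
  sim <- sampleReads(refs, spec, nReads = 10L, seed = 78L)
  keep <- sim$truth$order_label == "Coleoptera"
  for (i in which(keep)) {
    placed <- alignToProfile(prof, as.character(sim$reads[[i]]))
    expect_identical(nchar(placed), prof@sourceWidth)
    # the placed bases spell the read, in order, without errors applied
    expect_identical(gsub("-", "", placed), as.character(sim$reads[[i]]))
  }
})
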