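test_that("site exponential entropy is the Hill number of order 1", {
  expect_identical(siteExpEntropy(c("A", "A", "A", "A")), 1)
  expect_equal(siteExpEntropy(c("A", "C", "G", "T")), 4)
  expect_equal(siteExpEntropy(c("A", "A", "C", "C")), 2)
  expect_true(is.na(siteExpEntropy(c("-", "-"))))      # all-gap column
  # bounds over random columns, gaps and N excluded
  set.seed(5)
  for (i in 1:40) {
    col <- sample(c("A", "C", "G", "T", "-", "N"), 12, TRUE)
    d <- siteExpEntropy(col)
    if (!is.na(d)) {
      expect_gte(d, 1)
      expect_lte(d, 4)
    }
  }
})

test_that("the GC track averages over sequences then smooths over sites", {
  allG <- c(a = "GGGG", b = "GGGG")
  expect_equal(gcTrack(allG, window = 2), rep(100, 4))
  allA <- c(a = "AAAA", b = "AAAA")
  expect_equal(gcTrack(allA, window = 2), rep(0, 4))
  # alternating G/A columns, window 2: all interior sites average to 50
  alt <- c(a = "GAGAGAGA", b = "GAGAGAGA")
  expect_equal(gcTrack(alt, window = 2)[1:7], rep(50, 7))
})

test_that("region slicing uses 1-based inclusive bounds", {
  prof <- data.frame(site = 1:650, d_reads = 1, d_ref = 1, gc_ref = 50,
                     complete = TRUE)
  expect_identical(nrow(sliceRegion(prof, "five_prime")), 400L)
  expect_identical(nrow(sliceRegion(prof, "three_prime")), 451L)
  short <- prof[1:300, ]
  expect_warning(out <- sliceRegion(short, "five_prime"), "truncated")
  expect_identical(nrow(out), 300L)
})

test_that("sequential ANOVA arithmetic conserves variance", {
  set.seed(9)
  for (i in 1:20) {
    ss <- stats::runif(3, 0.1, 100)
    names(ss) <- c("GCref", "Dref", "Residuals")
    df <- c(1, 1, sample(50:600, 1))
    tab <- anovaFromDecomposition(ss, df)
    expect_equal(sum(tab$sum_sq), sum(ss))
    expect_equal(sum(tab$explained_pct), 100, tolerance = 1e-9)
    expect_equal(tab$mean_sq, tab$sum_sq / tab$df)
    expect_equal(tab$f_value[1:2], (ss[1:2] / df[1:2]) / (ss[3] / df[3]),
                 ignore_attr = TRUE)
    expect_true(is.na(tab$f_value[3]))
  }
})

test_that("the linear model recovers simulated diversity effects", {
  set.seed(77)
  n <- 564
  rows <- data.frame(d_ref = stats::runif(n, 1, 3),
                     gc_ref = stats::runif(n, 20, 60))
  rows$d_reads <- 1.0 * rows$d_ref + 0.02 * rows$gc_ref +
    stats::rnorm(n, 0, 0.2)
  mod <- fitGcModel(rows)
  est <- summary(mod$fit)$coefficients
  expect_lt(abs(est["d_ref", 1] - 1.0), 3 * est["d_ref", 2])
  expect_lt(abs(est["gc_ref", 1] - 0.02), 3 * est["gc_ref", 2])
  expect_identical(mod$anova$term, c("gc_ref", "d_ref", "Residuals"))

  # swapping the sequential order changes term SS, never the residual
  swapped <- fitGcModel(rows, termOrder = c("d_ref", "gc_ref"))
  expect_false(isTRUE(all.equal(
    mod$anova$sum_sq[mod$anova$term == "gc_ref"],
    swapped$anova$sum_sq[swapped$anova$term == "gc_ref"])))
  expect_equal(mod$anova$sum_sq[mod$anova$term == "Residuals"],
               swapped$anova$sum_sq[swapped$anova$term == "Residuals"])
})

test_that("degenerate fits are handled: perfect fit and collinearity", {
  n <- 60
  rows <- data.frame(d_ref = seq(1, 3, length.out = n), gc_ref = 40)
  rows$d_reads <- rows$d_ref
  expect_warning(mod <- fitGcModel(rows), "constant")
  tab <- mod$anova
  expect_equal(tab$explained_pct[tab$term == "d_ref"], 100, tolerance = 1e-6)
  expect_lt(tab$sum_sq[tab$term == "Residuals"], 1e-20)
  expect_equal(tab$sum_sq[tab$term == "gc_ref"], 0)

  rows2 <- data.frame(d_ref = stats::runif(n, 1, 3))
  rows2$gc_ref <- 2 * rows2$d_ref          # genuinely collinear
  rows2$d_reads <- rows2$d_ref + stats::rnorm(n, 0, 0.1)
  expect_error(fitGcModel(rows2), "collinear")
  expect_error(fitGcModel(rows[1:2, ]), ">= 3")
})

test_that("with no GC effect the GCref term is usually non-significant", {
  # null simulation at the row level: d_reads depends on d_ref only. The
  # GC term is tested in the model-formula order (d_ref first), where its
  # sequential F is the valid added-contribution test; tested first, it
  # would absorb chance covariance with the strong diversity effect.
  set.seed(1234)
  n <- 564
  pvals <- replicate(400, {
    rows <- data.frame(d_ref = stats::runif(n, 1, 3),
                       gc_ref = stats::runif(n, 20, 60))
    rows$d_reads <- rows$d_ref + stats::rnorm(n, 0, 0.3)
    tab <- fitGcModel(rows, termOrder = c("d_ref", "gc_ref"))$anova
    tab$p_value[tab$term == "gc_ref"]
  })
  expect_gte(mean(pvals > 0.05), 0.92)
  expect_lte(mean(pvals > 0.05), 0.98)
})

test_that("the end-to-end diagnostic runs on profile-aligned reads", {
  refs <- compactRefs()
  prof <- compactOrderProfiles()[["Coleoptera"]]
  tx <- taxonomy(refs)
  ids <- tx$id[tx$order_label == "Coleoptera"]
  refAln <- codonAlign(setNames(as.character(refSequences(refs)), tx$id)[ids])
  spec <- compactSpec(seed = 91L)
  sim <- sampleReads(refs, spec, nReads = 120L, seed = 92L)
  reads <- sim$reads[sim$truth$order_label == "Coleoptera"]
  diag <- gcDiversityDiagnostic(reads, prof, refAln,
                                region = "five_prime", fiveEnd = 120L,
                                window = 20L)
  expect_identical(nrow(diag$profileTable), alignmentWidth(refAln))
  expect_true(all(c("gc_ref", "d_ref", "Residuals") %in% diag$anova$term))
  expect_equal(sum(diag$anova$explained_pct), 100, tolerance = 1e-6)
})
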