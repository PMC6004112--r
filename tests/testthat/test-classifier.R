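test_that("log Bayes factor matches direct arithmetic", {
  expect_equal(lnBayesFactor(c(10, 5, 3)), 10 - log(exp(5) + exp(3)),
               tolerance = 1e-12)
  expect_equal(lnBayesFactor(c(10, 5, 3)), 4.873072, tolerance = 1e-6)
  expect_identical(lnBayesFactor(c(7, 7)), 0)        # equal competitors
  expect_identical(lnBayesFactor(42), Inf)           # single hit
  expect_error(lnBayesFactor(c(3, 10)), "decreasing")
  expect_error(lnBayesFactor(numeric(0)), "non-empty")
})

test_that("log-sum-exp path agrees with the naive two-pass computation", {
  set.seed(19)
  for (i in 1:50) {
    n <- sample(2:8, 1)
    s <- sort(stats::runif(n, -50, 500), decreasing = TRUE)
    expect_equal(lnBayesFactor(s), naiveLnBF(s), tolerance = 1e-9)
  }
})

test_that("raising a competitor score never raises the Bayes factor", {
  set.seed(23)
  for (i in 1:25) {
    s <- sort(stats::runif(4, 0, 60), decreasing = TRUE)
    j <- sample(2:4, 1)
    bumped <- sort(replace(s, j, s[j] + stats::runif(1, 0, s[1] - s[j])),
                   decreasing = TRUE)
    expect_lte(lnBayesFactor(bumped), lnBayesFactor(s))
  }
})

test_that("the three-way decision rule gates on e-value then Bayes factor", {
  mkhits <- function(scores, evalues)
    data.frame(query_id = "q", profile_name = paste0("p", seq_along(scores)),
               bit_score = scores, evalue = evalues)
  # gate 1: insignificant best hit
  a <- classify(mkhits(10, 0.5), evalueThreshold = 0.01)
  expect_identical(a$category, "Unclassified")
  expect_true(is.na(a$taxon))
  # gate 2: Bayes factor over the significant competitors
  b <- classify(mkhits(c(10, 5, 3), c(1e-30, 1e-10, 1e-8)),
                evalueThreshold = 10, bfThreshold = 3.0)
  expect_identical(b$category, "Good")
  expect_identical(b$taxon, "p1")
  expect_equal(b$ln_bf, 4.873072, tolerance = 1e-6)
  # an exact tie cannot pass
  d <- classify(mkhits(c(7, 7), c(1e-10, 1e-10)))
  expect_identical(d$category, "Ambiguous")
  expect_equal(d$ln_bf, 0)
  # no hits at all
  expect_message(e <- classify(NULL), "Unclassified")
  expect_identical(e$category, "Unclassified")
  # nats variant shrinks the Bayes factor by ln 2 per bit
  f <- classify(mkhits(c(10, 5), c(1e-30, 1e-10)), units = "nats")
  expect_equal(f$ln_bf, 5 * log(2), tolerance = 1e-9)
})

test_that("hit tables are filtered to the best hit's order", {
  tab <- data.frame(
    query_id = "q1", subject_id = paste0("s", 1:10),
    subject_order_label = c("Coleoptera", "Coleoptera", "Diptera",
                            "Coleoptera", "Diptera", "Coleoptera",
                            "Orthoptera", "Coleoptera", "Coleoptera",
                            "Diptera"),
    bit_score = seq(100, 91), rank_position = 1:10)
  out <- filterHitsByBestOrder(tab)
  expect_identical(nrow(out), 6L)
  expect_true(all(out$subject_order_label == "Coleoptera"))

  same <- tab; same$subject_order_label <- "Coleoptera"
  expect_identical(filterHitsByBestOrder(same), same)

  noLab <- tab; noLab$subject_order_label[1L] <- NA
  expect_warning(out2 <- filterHitsByBestOrder(noLab), "dropped")
  expect_identical(nrow(out2), 0L)
})

test_that("assignment partitions queries and respects thresholds", {
  refs <- compactRefs()
  profs <- compactSpeciesProfiles()
  spec <- compactSpec(seed = 401L,
                      errorModel = errorModel(baseSubRate = 0,
                                              homopolymerIndelRate = 0,
                                              readLength = 120L))
  sim <- sampleReads(refs, spec, nReads = 100L, seed = 402L)
  res <- assignAll(sim$reads, profs)
  asn <- res$assignments

  # exhaustive, mutually exclusive partition
  expect_identical(nrow(asn), 100L)
  expect_identical(sum(table(asn$category)), 100L)
  expect_true(all(asn$category %in% c("Good", "Ambiguous", "Unclassified")))

  # error-free reads from profiled taxa are all correctly Good
  expect_true(all(asn$category == "Good"))
  expect_identical(asn$taxon, sim$truth$species_label)

  # abundance counts tally the Good assignments
  expect_identical(sum(res$abundance$count), sum(asn$category == "Good"))

  # a stricter Bayes-factor threshold can only shrink the Good set
  harsher <- assignAll(sim$reads, profs, bfThreshold = 50)$assignments
  expect_lte(sum(harsher$category == "Good"), sum(asn$category == "Good"))

  # zero queries: empty, well-formed outputs
  z <- assignAll(character(0), profs)
  expect_identical(nrow(z$assignments), 0L)
  expect_identical(nrow(z$abundance), 0L)
})

test_that("a single-profile collection can only yield Good or Unclassified", {
  profs <- compactSpeciesProfiles()[1L]
  refs <- compactRefs()
  sim <- sampleReads(refs, compactSpec(seed = 55L), nReads = 40L, seed = 56L)
  res <- assignAll(sim$reads, profs)
  expect_true(all(res$assignments$category %in% c("Good", "Unclassified")))
  sig <- res$assignments$best_evalue <= 10
  expect_true(all(res$assignments$category[sig] == "Good"))
  expect_true(all(is.infinite(res$assignments$ln_bf[sig])))
})

test_that("reads from an unprofiled, highly divergent taxon are rejected", {
  profs <- compactOrderProfiles()
  alien <- communitySpec(
    data.frame(order_label = "Alien", n_species = 1L, biomass_g = 1,
               bias_multiplier = 1),
    ancestorLengthCodons = 60L, orderDivergence = 0.35, seed = 611L,
    errorModel = errorModel(baseSubRate = 0.01, readLength = 120L))
  sim <- sampleReads(evolveReferences(alien), alien, nReads = 60L)
  res <- assignAll(sim$reads, profs)
  rejected <- res$assignments$category %in% c("Unclassified", "Ambiguous")
  expect_gte(mean(rejected), 0.8)
})
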