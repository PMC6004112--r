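pairIdentity <- function(a, b) {
  x <- strsplit(a, "")[[1L]]
  y <- strsplit(b, "")[[1L]]
  mean(x == y)
}

test_that("reference evolution is deterministic and divergence-ordered", {
  spec <- compactSpec(seed = 500L)
  r1 <- evolveReferences(spec)
  r2 <- evolveReferences(spec)
  expect_identical(as.character(refSequences(r1)),
                   as.character(refSequences(r2)))

  # realized identity decreases with the divergence parameter
  divs <- c(0.02, 0.05, 0.1, 0.2, 0.3)
  meanIdent <- sapply(seq_along(divs), function(i) {
    ids <- replicate(20, {
      sp <- compactSpec(seed = 1000L + i * 20 + sample.int(1e6, 1),
                        orderDivergence = divs[i])
      refs <- evolveReferences(sp)
      seqs <- as.character(refSequences(refs))
      tx <- taxonomy(refs)
      pairIdentity(seqs[match(tx$id[tx$order_label == "Coleoptera"][1],
                              names(seqs))],
                   seqs[match(tx$id[tx$order_label == "Diptera"][1],
                              names(seqs))])
    })
    mean(ids)
  })
  expect_lt(cor(divs, meanIdent, method = "spearman"), -0.9)
})

test_that("zero divergence tiers produce identical sequences", {
  sp <- compactSpec(seed = 42L, speciesDivergence = 0,
                    individualDivergence = 0)
  refs <- evolveReferences(sp)
  tx <- taxonomy(refs)
  seqs <- setNames(as.character(refSequences(refs)), tx$id)
  for (ord in unique(tx$order_label)) {
    within <- seqs[tx$order_label == ord]
    expect_identical(length(unique(within)), 1L)
  }
})

test_that("references are in-frame, stop-free coding sequences", {
  refs <- compactRefs()
  for (s in as.character(refSequences(refs))) {
    expect_identical(nchar(s) %% 3L, 0L)
    aa <- translateCodons(s, 0L, "invertebrate_mito")
    expect_false(grepl("*", aa, fixed = TRUE))
  }
})

test_that("read sampling respects weights, labels, and edge cases", {
  refs <- compactRefs()
  # equalized biomass, unit bias: species counts uniform up to
  # multinomial noise
  spec0 <- compactSpec(seed = 700L,
                       errorModel = errorModel(baseSubRate = 0,
                                               homopolymerIndelRate = 0,
                                               readLength = 60L))
  sim <- sampleReads(refs, spec0, nReads = 10000L, equalizeBiomass = TRUE,
                     seed = 701L)
  counts <- table(sim$truth$species_label)
  expect_identical(length(counts), 5L)    # 3 + 1 + 1 species
  expect_gt(stats::chisq.test(counts, p = rep(1 / 5, 5))$p.value, 0.01)

  # truth and FASTA ids are bijective
  expect_identical(sort(names(sim$reads)), sort(sim$truth$read_id))
  expect_identical(anyDuplicated(sim$truth$read_id), 0L)
  expect_true(all(sim$truth$strand %in% c("5p", "3p")))

  # biomass weighting: the heaviest taxon dominates when not equalized
  simW <- sampleReads(refs, spec0, nReads = 2000L, seed = 702L)
  byOrder <- table(simW$truth$order_label)
  expect_identical(names(which.max(byOrder)), "Coleoptera")

  # amplification bias multiplies the sampling weight
  biased <- compactSpec(seed = 700L)
  biased$taxa$bias_multiplier <- c(1, 20, 1)
  simB <- sampleReads(refs, biased, nReads = 2000L, equalizeBiomass = TRUE,
                      seed = 703L)
  expect_identical(names(which.max(table(simB$truth$order_label))),
                   "Diptera")

  empty <- sampleReads(refs, spec0, nReads = 0L)
  expect_identical(length(empty$reads), 0L)
  expect_identical(nrow(empty$truth), 0L)
})

test_that("the GC-dependent error component raises substitution rates", {
  refs <- compactRefs()
  base <- compactSpec(seed = 800L,
                      errorModel = errorModel(baseSubRate = 0.01,
                                              gcSubSlope = 0,
                                              homopolymerIndelRate = 0,
                                              readLength = 120L))
  gcy <- compactSpec(seed = 800L,
                     errorModel = errorModel(baseSubRate = 0.01,
                                             gcSubSlope = 0.2,
                                             homopolymerIndelRate = 0,
                                             readLength = 120L))
  errRate <- function(spec) {
    sim <- sampleReads(refs, spec, nReads = 300L, seed = 801L)
    seqs <- setNames(as.character(refSequences(refs)),
                     taxonomy(refs)$id)
    mean(sapply(seq_len(300L), function(i) {
      tr <- sim$truth[i, ]
      src <- substr(seqs[[tr$ref_id]], tr$start, tr$start + 119L)
      1 - pairIdentity(as.character(sim$reads[[i]]), src)
    }))
  }
  expect_gt(errRate(gcy), errRate(base))
})

test_that("simulation outputs round-trip through the on-disk formats", {
  refs <- compactRefs()
  spec <- compactSpec(seed = 900L)
  sim <- sampleReads(refs, spec, nReads = 25L, seed = 901L)
  dir <- withr::local_tempdir()
  paths <- writeSimulation(refs, sim, spec, dir)
  expect_true(all(file.exists(paths)))
  back <- readTaxonSet(paths[["references"]], paths[["taxonomy"]])
  expect_identical(as.character(refSequences(back)),
                   as.character(refSequences(refs)))
  reads <- readFasta(paths[["reads"]])
  expect_identical(length(reads), 25L)
  echo <- jsonlite::fromJSON(paths[["spec"]])
  expect_identical(echo$seed, 900L)
  expect_identical(echo$errorModel$readLength, 120L)
})
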