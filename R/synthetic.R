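## Mock-community simulator: star-tree coding references with
## codon-position-weighted substitution, biomass x amplification-bias
## weighted read sampling, and a pyrosequencing-style error model with a
## GC-dependent substitution component and homopolymer indels.

#' Read error model
#'
#' @param baseSubRate baseline per-base substitution probability.
#' @param gcSubSlope extra substitution probability per unit window-GC
#'   fraction (the GC-dependent error component).
#' @param homopolymerIndelRate per-run indel probability at homopolymers
#'   of length >= 3 (454-style).
#' @param readLength target read length in bases (>= 50).
#' @return a list of class `ErrorModel`.
#' @export
errorModel <- function(baseSubRate = 0.005, gcSubSlope = 0,
                       homopolymerIndelRate = 0.005, readLength = 250L) {
  rates <- c(baseSubRate, gcSubSlope, homopolymerIndelRate)
  if (any(rates < 0 | rates >= 0.5))
    stop("error rates must lie in [0, 0.5)")
  if (readLength < 50L) stop("readLength must be >= 50")
  structure(list(baseSubRate = baseSubRate, gcSubSlope = gcSubSlope,
                 homopolymerIndelRate = homopolymerIndelRate,
                 readLength = as.integer(readLength)),
            class = "ErrorModel")
}

#' Mock community specification
#'
#' Describes a multi-taxon coding-sequence community: per order, a number
#' of species, a biomass and a PCR amplification-bias multiplier; global
#' divergence tiers (order / species / individual, substitutions per
#' site); and a read error model. Defaults emulate a terrestrial
#' invertebrate pitfall-trap community barcoded at a ~650 bp mitochondrial
#' coding fragment.
#'
#' @param taxa `data.frame` with columns `order_label`, `n_species`,
#'   `biomass_g`, `bias_multiplier`.
#' @param ancestorLengthCodons length of the root coding sequence in
#'   codons (default 219, ~657 nt).
#' @param orderDivergence,speciesDivergence,individualDivergence expected
#'   substitutions per site on the star-tree branches of each tier.
#' @param nIndividuals reference individuals simulated per species
#'   (default 3; profile building needs >= 2).
#' @param errorModel an [errorModel()].
#' @param seed integer seed all downstream randomness derives from.
#' @return a list of class `CommunitySpec`.
#' @export
communitySpec <- function(taxa,
                          ancestorLengthCodons = 219L,
                          orderDivergence = 0.2,
                          speciesDivergence = 0.05,
                          individualDivergence = 0.005,
                          nIndividuals = 3L,
                          errorModel = hsta::errorModel(),
                          seed = 1L) {
  need <- c("order_label", "n_species", "biomass_g", "bias_multiplier")
  if (!all(need %in% colnames(taxa)))
    stop("taxa must have columns: ", paste(need, collapse = ", "))
  if (any(taxa$biomass_g <= 0)) stop("biomass_g must be positive")
  if (any(taxa$bias_multiplier <= 0)) stop("bias_multiplier must be positive")
  div <- c(orderDivergence, speciesDivergence, individualDivergence)
  if (any(div < 0 | div >= 1)) stop("divergences must lie in [0, 1)")
  if (nIndividuals < 2L) stop("nIndividuals must be >= 2")
  structure(list(taxa = taxa,
                 ancestorLengthCodons = as.integer(ancestorLengthCodons),
                 orderDivergence = orderDivergence,
                 speciesDivergence = speciesDivergence,
                 individualDivergence = individualDivergence,
                 nIndividuals = as.integer(nIndividuals),
                 errorModel = errorModel,
                 seed = as.integer(seed)),
            class = "CommunitySpec")
}

#' A three-order, seven-species example community
#'
#' The default study condition for end-to-end checks: the three most
#' abundant orders of the packaged mock community (a carabid-dominated
#' beetle order with seven species, plus flies and grasshoppers at their
#' measured biomasses), unbiased amplification.
#'
#' @param seed integer seed.
#' @param ... overrides passed on to [communitySpec()].
#' @return a `CommunitySpec`.
#' @export
exampleCommunitySpec <- function(seed = 1L, ...) {
  taxa <- data.frame(
    order_label = c("Coleoptera", "Diptera", "Orthoptera"),
    n_species = c(7L, 1L, 1L),
    biomass_g = c(22.89, 4.12, 2.44),
    bias_multiplier = c(1, 1, 1))
  communitySpec(taxa, seed = seed, ...)
}

nonStopCodons <- function() {
  tab <- geneticCodeTable("invertebrate_mito")
  names(tab)[tab != "*"]
}

## per-codon-position substitution weights: 3rd = 4 x 1st, 1st = 2 x 2nd
CODON_POS_WEIGHTS <- c(2, 1, 8) / mean(c(2, 1, 8))

mutateCoding <- function(seq, divergence, stops) {
  if (divergence == 0) return(seq)
  chars <- strsplit(seq, "", fixed = TRUE)[[1L]]
  n <- length(chars)
  p <- pmin(0.75, divergence * CODON_POS_WEIGHTS[((seq_len(n) - 1L) %% 3L) + 1L])
  hit <- runif(n) < p
  if (any(hit))
    chars[hit] <- vapply(chars[hit], function(b)
      sample(setdiff(DNA_BASES4, b), 1L), character(1))
  ## repair any stop codons introduced by substitution
  repeat {
    starts <- seq(1L, n, 3L)
    cods <- vapply(starts, function(s)
      paste(chars[s:(s + 2L)], collapse = ""), character(1))
    bad <- which(cods %in% stops)
    if (!length(bad)) break
    for (b in bad) {
      pos <- starts[b] + sample(0:2, 1L)
      chars[pos] <- sample(setdiff(DNA_BASES4, chars[pos]), 1L)
    }
  }
  paste(chars, collapse = "")
}

#' Simulate a star-tree reference set
#'
#' Draws a random in-frame, stop-free ancestor (invertebrate mitochondrial
#' code), then evolves order ancestors, species ancestors and individual
#' reference sequences along star trees with codon-position-weighted
#' substitution (3rd position 4x the 1st, 1st 2x the 2nd). Deterministic
#' given `spec$seed`.
#'
#' @param spec a [communitySpec()].
#' @return a [TaxonSet-class]; ids are `order_spNN_indNN`, species labels
#'   `order_spNN`.
#' @export
evolveReferences <- function(spec) {
  stopifnot(inherits(spec, "CommunitySpec"))
  codons <- nonStopCodons()
  stops <- setdiff(names(geneticCodeTable("invertebrate_mito")), codons)
  withPrivateSeed(spec$seed, {
    root <- paste(sample(codons, spec$ancestorLengthCodons, replace = TRUE),
                  collapse = "")
    seqs <- character(0); ids <- character(0)
    ord <- character(0); spp <- character(0)
    for (t in seq_len(nrow(spec$taxa))) {
      orderAnc <- mutateCoding(root, spec$orderDivergence, stops)
      olab <- spec$taxa$order_label[t]
      for (s in seq_len(spec$taxa$n_species[t])) {
        spAnc <- mutateCoding(orderAnc, spec$speciesDivergence, stops)
        slab <- sprintf("%s_sp%02d", olab, s)
        for (i in seq_len(spec$nIndividuals)) {
          seqs <- c(seqs, mutateCoding(spAnc, spec$individualDivergence,
                                       stops))
          ids <- c(ids, sprintf("%s_ind%02d", slab, i))
          ord <- c(ord, olab); spp <- c(spp, slab)
        }
      }
    }
    TaxonSet(setNames(seqs, ids),
             data.frame(id = ids, order_label = ord, species_label = spp,
                        stringsAsFactors = FALSE))
  })
}

movingMean <- function(x, window) {
  n <- length(x)
  lo <- pmax(1L, seq_len(n) - (window - 1L) %/% 2L)
  hi <- pmin(n, seq_len(n) + window %/% 2L)
  cs <- cumsum(x)
  (cs[hi] - c(0, cs)[lo]) / (hi - lo + 1L)
}

applyReadErrors <- function(frag, em) {
  chars <- strsplit(frag, "", fixed = TRUE)[[1L]]
  n <- length(chars)
  gcwin <- movingMean(as.numeric(chars %in% c("G", "C")), 100L)
  p <- pmin(0.95, em$baseSubRate + em$gcSubSlope * gcwin)
  hit <- runif(n) < p
  if (any(hit))
    chars[hit] <- vapply(chars[hit], function(b)
      sample(setdiff(DNA_BASES4, b), 1L), character(1))
  if (em$homopolymerIndelRate > 0) {
    r <- rle(chars)
    runs <- which(r$lengths >= 3L)
    if (length(runs)) {
      ends <- cumsum(r$lengths)
      edit <- runs[runif(length(runs)) < em$homopolymerIndelRate]
      for (k in rev(edit)) {           # right-to-left keeps positions valid
        pos <- ends[k]
        if (runif(1) < 0.5)
          chars <- append(chars, chars[pos], after = pos)   # +1 copy
        else
          chars <- chars[-pos]                              # -1 copy
      }
    }
  }
  paste(chars, collapse = "")
}

#' Sample biomass-weighted reads from a reference set
#'
#' Read counts are multinomial over species with weights
#' `within-order biomass share x bias_multiplier` (bias only when
#' `equalizeBiomass = TRUE`, emulating a biomass-equalised sample). Each
#' read is a random-start fragment of a randomly chosen conspecific
#' reference, pushed through the error model: substitutions at rate
#' `baseSubRate + gcSubSlope x (100 bp window GC fraction)` and
#' homopolymer indels. Reads are labelled `5p`/`3p` by which half of the
#' reference their midpoint covers.
#'
#' @param refs a [TaxonSet-class] from [evolveReferences()].
#' @param spec the [communitySpec()] used to generate `refs`.
#' @param nReads number of reads to draw.
#' @param equalizeBiomass if `TRUE`, weights use the bias multipliers
#'   only.
#' @param seed integer seed (default `spec$seed + 1`).
#' @return list: `reads` ([Biostrings::DNAStringSet]) and `truth`
#'   (`data.frame`: `read_id`, `order_label`, `species_label`, `ref_id`,
#'   `strand`, `start`).
#' @export
sampleReads <- function(refs, spec, nReads, equalizeBiomass = FALSE,
                        seed = spec$seed + 1L) {
  stopifnot(inherits(spec, "CommunitySpec"))
  em <- spec$errorModel
  tx <- taxonomy(refs)
  if (nReads == 0L)
    return(list(reads = Biostrings::DNAStringSet(),
                truth = data.frame(read_id = character(0),
                                   order_label = character(0),
                                   species_label = character(0),
                                   ref_id = character(0),
                                   strand = character(0),
                                   start = integer(0))))
  sp <- unique(tx[, c("order_label", "species_label")])
  t2 <- spec$taxa[match(sp$order_label, spec$taxa$order_label), ]
  w <- t2$bias_multiplier *
    (if (equalizeBiomass) 1 else t2$biomass_g / t2$n_species)
  seqs <- setNames(as.character(refSequences(refs)), tx$id)
  withPrivateSeed(seed, {
    pick <- sample(nrow(sp), nReads, replace = TRUE, prob = w / sum(w))
    reads <- character(nReads); meta <- vector("list", nReads)
    for (i in seq_len(nReads)) {
      slab <- sp$species_label[pick[i]]
      cands <- tx$id[tx$species_label == slab]
      rid <- if (length(cands) == 1L) cands else sample(cands, 1L)
      ref <- seqs[[rid]]
      L <- nchar(ref)
      rl <- min(em$readLength, L)
      start <- if (L == rl) 1L else sample.int(L - rl + 1L, 1L)
      frag <- substr(ref, start, start + rl - 1L)
      strand <- if (start + rl / 2 <= L / 2) "5p" else "3p"
      reads[i] <- applyReadErrors(frag, em)
      meta[[i]] <- data.frame(read_id = sprintf("read%06d", i),
                              order_label = sp$order_label[pick[i]],
                              species_label = slab, ref_id = rid,
                              strand = strand, start = start,
                              stringsAsFactors = FALSE)
    }
    truth <- do.call(rbind, meta)
    list(reads = Biostrings::DNAStringSet(setNames(reads, truth$read_id)),
         truth = truth)
  })
}

#' Write simulator outputs to disk
#'
#' Reads FASTA, references FASTA, taxonomy TSV, truth TSV, and a JSON echo
#' of the specification.
#'
#' @param refs a [TaxonSet-class].
#' @param sim list from [sampleReads()].
#' @param spec the [communitySpec()].
#' @param dir output directory (created if needed).
#' @return named character vector of the five written paths, invisibly.
#' @export
writeSimulation <- function(refs, sim, spec, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(reads = file.path(dir, "reads.fasta"),
             references = file.path(dir, "references.fasta"),
             taxonomy = file.path(dir, "taxonomy.tsv"),
             truth = file.path(dir, "truth.tsv"),
             spec = file.path(dir, "spec.json"))
  writeFasta(sim$reads, paths[["reads"]])
  writeFasta(refSequences(refs), paths[["references"]])
  writeTaxonomyTsv(taxonomy(refs), paths[["taxonomy"]])
  write.table(sim$truth, paths[["truth"]], sep = "\t", quote = FALSE,
              row.names = FALSE)
  specEcho <- spec
  specEcho$errorModel <- unclass(specEcho$errorModel)
  jsonlite::write_json(unclass(specEcho), paths[["spec"]],
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(paths)
}
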