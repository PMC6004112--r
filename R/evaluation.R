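#' Read an expected-community table
#'
#' TSV with header columns `name`, `rank`, `biomass_g`. The packaged
#' fixture `mock_community_biomass.tsv` (see
#' `system.file("extdata", package = "hsta")`) describes a pitfall-trap
#' soil-litter mock community: 11 order/class-level taxa and 7 carabid
#' beetle species with their measured biomasses.
#'
#' @param path path to the TSV; defaults to the packaged fixture.
#' @return `data.frame` with columns `name`, `rank`, `biomass_g`.
#' @export
readExpectedCommunity <- function(path = system.file(
    "extdata", "mock_community_biomass.tsv", package = "hsta")) {
  x <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("name", "rank", "biomass_g")
  if (!all(need %in% colnames(x)))
    stop("expected-community table needs columns: ",
         paste(need, collapse = ", "))
  if (any(x$biomass_g <= 0)) stop("biomass must be positive")
  if (anyDuplicated(paste(x$rank, x$name)))
    stop("duplicate taxon name within a rank")
  x[, need]
}

#' Detection ratio of expected taxa
#'
#' Fraction of the expected taxa at `rank` that received at least one
#' Good-assigned read, plus the found/missing name lists. Reported as a
#' fraction in `[0, 1]`.
#'
#' @param abundance `data.frame` from [assignAll()] (`taxon`, `rank`,
#'   `strand`, `count`); counts are summed over strands.
#' @param expected `data.frame` from [readExpectedCommunity()].
#' @param rank rank to evaluate (must be present in both tables).
#' @return list: `ratio`, `found`, `missing`, `n_expected`.
#' @export
detectionRatio <- function(abundance, expected, rank) {
  exp_taxa <- expected$name[expected$rank == rank]
  if (!length(exp_taxa)) stop("no expected taxa at rank '", rank, "'")
  ab <- abundance[abundance$rank == rank, , drop = FALSE]
  counts <- tapply(ab$count, ab$taxon, sum)
  found <- exp_taxa[exp_taxa %in% names(counts)[counts > 0]]
  list(ratio = length(found) / length(exp_taxa),
       found = found,
       missing = setdiff(exp_taxa, found),
       n_expected = length(exp_taxa))
}

#' Pearson correlation of read abundance with biomass
#'
#' Computed on raw Good-read counts (no normalisation) over the expected
#' taxa that were detected; undefined (returned as `NA` with a message)
#' when fewer than two taxa were detected, matching the convention of
#' reporting correlations only when more than one taxon was classified.
#'
#' @inheritParams detectionRatio
#' @return Pearson r, or `NA_real_`.
#' @export
biomassCorrelation <- function(abundance, expected, rank) {
  exp_tab <- expected[expected$rank == rank, , drop = FALSE]
  ab <- abundance[abundance$rank == rank, , drop = FALSE]
  counts <- tapply(ab$count, ab$taxon, sum)
  exp_tab$count <- as.numeric(counts[exp_tab$name])
  exp_tab$count[is.na(exp_tab$count)] <- 0
  det <- exp_tab[exp_tab$count > 0, , drop = FALSE]
  if (nrow(det) < 2L) {
    message("fewer than two detected taxa at rank '", rank,
            "': correlation undefined")
    return(NA_real_)
  }
  cor(det$count, det$biomass_g, method = "pearson")
}

#' Per-strand read-count ratio of a species pair
#'
#' Ratio of taxon A's to taxon B's Good-read counts at the 5' and 3'
#' strata, and their arithmetic mean — the read-abundance analogue of a
#' per-pair biomass or qPCR signal ratio.
#'
#' @param abundance `data.frame` with columns `taxon`, `strand`
#'   (containing `"5p"` and `"3p"`), `count`.
#' @param taxonA numerator taxon.
#' @param taxonB denominator taxon.
#' @return `data.frame` row: `numerator_taxon`, `denominator_taxon`,
#'   `ratio_5p`, `ratio_3p`, `mean_ratio`. A zero denominator yields an
#'   infinite ratio with a warning.
#' @examples
#' ab <- data.frame(taxon = rep(c("CC1", "LL1"), 2),
#'                  strand = rep(c("5p", "3p"), each = 2),
#'                  count = c(231.35, 1, 103.55, 1))
#' pairRatioReport(ab, "CC1", "LL1")$mean_ratio  # 167.45
#' @export
pairRatioReport <- function(abundance, taxonA, taxonB) {
  get <- function(tx, st) {
    v <- abundance$count[abundance$taxon == tx & abundance$strand == st]
    if (!length(v)) 0 else sum(v)
  }
  r5 <- get(taxonA, "5p") / get(taxonB, "5p")
  r3 <- get(taxonA, "3p") / get(taxonB, "3p")
  if (!is.finite(r5) || !is.finite(r3))
    warning("zero denominator count: infinite/undefined ratio for pair ",
            taxonA, "/", taxonB)
  data.frame(numerator_taxon = taxonA, denominator_taxon = taxonB,
             ratio_5p = r5, ratio_3p = r3, mean_ratio = (r5 + r3) / 2,
             stringsAsFactors = FALSE)
}

#' Full evaluation report for a pipeline run
#'
#' Bundles the detection ratios, biomass correlation and optional
#' species-pair ratio for one assignment result.
#'
#' @param abundance abundance table from [assignAll()].
#' @param expected expected community (see [readExpectedCommunity()]).
#' @param rank rank to evaluate.
#' @param pair optional character vector `c(taxonA, taxonB)` for a
#'   per-strand ratio report.
#' @return list: `detection`, `pearson_r`, and `ratio` when `pair` is
#'   given.
#' @export
evaluationReport <- function(abundance, expected, rank, pair = NULL) {
  out <- list(detection = detectionRatio(abundance, expected, rank),
              pearson_r = suppressMessages(
                biomassCorrelation(abundance, expected, rank)))
  if (!is.null(pair))
    out$ratio <- pairRatioReport(abundance, pair[1L], pair[2L])
  out
}
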