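#' Build per-taxon profiles from a labelled reference set
#'
#' Groups the references by `rank` label, codon-aligns each group
#' (protein-guided back-alignment, see [codonAlign()]) and builds one
#' profile per taxon. Rank collections are kept separate by design: order
#' profiles and species profiles are scanned independently, giving one
#' assignment per rank. Groups with fewer than two sequences cannot
#' support a profile and are skipped with a warning.
#'
#' @param refs a [TaxonSet-class].
#' @param rank `"order"` or `"species"`.
#' @param protMsas optional named list of externally aligned protein MSAs,
#'   one per taxon label.
#' @param calibrate attach Gumbel E-value calibrations (default `TRUE`).
#' @param nShuffles,seed calibration parameters (see
#'   [calibrateProfiles()]).
#' @param ... passed to [buildProfile()] (`occupancyThreshold`,
#'   `pseudocount`, `background`).
#' @return named list of [ProfileHMM-class] objects.
#' @export
buildTaxonProfiles <- function(refs, rank = c("order", "species"),
                               protMsas = NULL, calibrate = TRUE,
                               nShuffles = 200L, seed = 1L, ...) {
  rank <- match.arg(rank)
  tx <- taxonomy(refs)
  labels <- if (rank == "order") tx$order_label else tx$species_label
  keep <- !is.na(labels)
  seqs <- setNames(as.character(refSequences(refs)), tx$id)[keep]
  labels <- labels[keep]
  groups <- split(names(seqs), labels)
  profiles <- list()
  for (lab in names(groups)) {
    ids <- groups[[lab]]
    if (length(ids) < 2L) {
      warning("taxon '", lab, "' has fewer than 2 sequences; skipped")
      next
    }
    aln <- codonAlign(seqs[ids],
                      protMsa = if (is.null(protMsas)) NULL else
                        protMsas[[lab]])
    profiles[[lab]] <- buildProfile(aln, name = lab, rank = rank, ...)
  }
  if (!length(profiles)) stop("no taxon had enough sequences for a profile")
  if (calibrate)
    profiles <- setNames(calibrateProfiles(profiles, nShuffles, seed),
                         names(profiles))
  profiles
}

#' Run manifest
#'
#' JSON record of a pipeline stage: package version, timestamp, seeds,
#' thresholds and md5 digests of the input files, so that two runs with
#' identical configuration and inputs are provably identical.
#'
#' @param stage stage name.
#' @param params named list of parameters/thresholds to echo.
#' @param inputs character vector of input file paths to digest.
#' @param path output JSON path, or `NULL` to return the record only.
#' @return the manifest list, invisibly.
#' @export
writeManifest <- function(stage, params = list(), inputs = character(0),
                          path = NULL) {
  digests <- if (length(inputs))
    as.list(tools::md5sum(inputs)) else list()
  man <- list(stage = stage,
              package = "hsta",
              version = as.character(packageVersion("hsta")),
              parameters = params,
              input_md5 = digests)
  if (!is.null(path))
    jsonlite::write_json(man, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  invisible(man)
}
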