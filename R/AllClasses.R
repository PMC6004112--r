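#' @useDynLib hsta, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @import methods
#' @importClassesFrom Biostrings DNAStringSet AAStringSet XStringSet
#' @importFrom stats anova coef cor lm optim pf rbinom runif sd setNames
#' @importFrom utils read.delim write.table packageVersion
NULL

DNA_BASES4 <- c("A", "C", "G", "T")

#' Labelled reference sequence collection
#'
#' A set of nucleotide reference sequences, each tagged with an order-rank
#' taxon label and, optionally, a species label. This is the unit on which
#' reference databases for profile building are assembled.
#'
#' @slot sequences a [Biostrings::DNAStringSet] of ungapped reference
#'   sequences; names are the record ids and must be unique.
#' @slot taxonomy a `data.frame` with columns `id`, `order_label` and
#'   `species_label` (`NA` where unknown), one row per sequence, in the
#'   same order as `sequences`.
#'
#' @seealso [TaxonSet()], [readTaxonomyTsv()]
#' @export
setClass("TaxonSet",
  representation(sequences = "DNAStringSet", taxonomy = "data.frame"))

setValidity("TaxonSet", function(object) {
  ids <- names(object@sequences)
  msg <- character(0)
  if (is.null(ids) || anyNA(ids) || any(ids == ""))
    msg <- c(msg, "all sequences must be named")
  if (anyDuplicated(ids))
    msg <- c(msg, "sequence ids must be unique")
  if (any(Biostrings::width(object@sequences) == 0L))
    msg <- c(msg, "sequences must be non-empty")
  tx <- object@taxonomy
  need <- c("id", "order_label", "species_label")
  if (!all(need %in% colnames(tx)))
    msg <- c(msg, "taxonomy must have columns id, order_label, species_label")
  else {
    if (!identical(as.character(tx$id), as.character(ids)))
      msg <- c(msg, "taxonomy ids must match sequence names, in order")
    if (anyNA(tx$order_label) || any(tx$order_label == ""))
      msg <- c(msg, "order_label must be non-empty for every record")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a TaxonSet
#'
#' @param sequences a [Biostrings::DNAStringSet] (or named character vector)
#'   of ungapped nucleotide sequences.
#' @param taxonomy a `data.frame` with columns `id`, `order_label` and
#'   optionally `species_label`, covering every sequence id.
#' @return a [TaxonSet-class] object.
#' @examples
#' seqs <- c(rec1 = "ATGAAATTT", rec2 = "ATGCCCGGG")
#' tax <- data.frame(id = c("rec1", "rec2"),
#'                   order_label = c("Coleoptera", "Diptera"))
#' ts <- TaxonSet(seqs, tax)
#' orderLabels(ts)
#' @export
TaxonSet <- function(sequences, taxonomy) {
  if (is.character(sequences))
    sequences <- Biostrings::DNAStringSet(sequences)
  if (!"species_label" %in% colnames(taxonomy))
    taxonomy$species_label <- NA_character_
  taxonomy$id <- as.character(taxonomy$id)
  ids <- names(sequences)
  missing <- setdiff(ids, taxonomy$id)
  if (length(missing))
    stop("sequence id(s) missing from taxonomy: ",
         paste(missing, collapse = ", "))
  taxonomy <- taxonomy[match(ids, taxonomy$id),
                       c("id", "order_label", "species_label"),
                       drop = FALSE]
  rownames(taxonomy) <- NULL
  new("TaxonSet", sequences = sequences, taxonomy = taxonomy)
}

#' @describeIn TaxonSet the underlying [Biostrings::DNAStringSet].
#' @param x a `TaxonSet`.
#' @export
refSequences <- function(x) x@sequences

#' @describeIn TaxonSet the taxonomy `data.frame`.
#' @export
taxonomy <- function(x) x@taxonomy

#' @describeIn TaxonSet order labels, named by record id.
#' @export
orderLabels <- function(x) setNames(x@taxonomy$order_label, x@taxonomy$id)

#' @describeIn TaxonSet species labels (`NA` where absent), named by id.
#' @export
speciesLabels <- function(x) setNames(x@taxonomy$species_label, x@taxonomy$id)

setMethod("show", "TaxonSet", function(object) {
  cat("TaxonSet with", length(object@sequences), "sequences;",
      length(unique(object@taxonomy$order_label)), "order label(s),",
      length(unique(stats::na.omit(object@taxonomy$species_label))),
      "species label(s)\n")
})

#' @export
setMethod("length", "TaxonSet", function(x) length(x@sequences))

#' Codon-resolved nucleotide alignment
#'
#' A nucleotide multiple alignment whose columns come in codon triplets
#' threaded through a protein alignment (a "back-alignment"): every aligned
#' protein residue is expanded to its source codon and every protein gap to
#' `---`, so the reading frame is preserved column-for-column.
#'
#' @slot nucleotide gapped [Biostrings::DNAStringSet]; all rows equal width.
#' @slot protein the gapped [Biostrings::AAStringSet] the codons were
#'   threaded through; nucleotide width equals `3 *` protein width.
#'
#' @seealso [backAlign()]
#' @export
setClass("CodonAlignment",
  representation(nucleotide = "DNAStringSet", protein = "AAStringSet"))

setValidity("CodonAlignment", function(object) {
  wn <- Biostrings::width(object@nucleotide)
  wp <- Biostrings::width(object@protein)
  msg <- character(0)
  if (length(object@nucleotide) != length(object@protein))
    msg <- c(msg, "nucleotide and protein row counts differ")
  if (length(unique(wn)) > 1L) msg <- c(msg, "nucleotide rows differ in width")
  if (length(unique(wp)) > 1L) msg <- c(msg, "protein rows differ in width")
  if (length(wn) && length(wp) && wn[1L] != 3L * wp[1L])
    msg <- c(msg, "nucleotide width must be 3 x protein width")
  if (!identical(names(object@nucleotide), names(object@protein)))
    msg <- c(msg, "row names must match between nucleotide and protein")
  if (length(wn) && wn[1L] %% 3L == 0L) {
    rows <- as.character(object@nucleotide)
    for (r in rows) {
      cod <- substring(r, seq(1L, nchar(r), 3L), seq(3L, nchar(r), 3L))
      bad <- grepl("-", cod) & cod != "---"
      if (any(bad)) {
        msg <- c(msg, "gaps must occur as whole codon triplets")
        break
      }
    }
  }
  if (length(msg)) msg else TRUE
})

#' @describeIn CodonAlignment the gapped nucleotide rows.
#' @param x a `CodonAlignment`.
#' @export
nucAlignment <- function(x) x@nucleotide

#' @describeIn CodonAlignment the guiding protein alignment.
#' @export
protAlignment <- function(x) x@protein

#' @describeIn CodonAlignment number of nucleotide alignment columns.
#' @export
alignmentWidth <- function(x) {
  w <- Biostrings::width(x@nucleotide)
  if (length(w)) w[1L] else 0L
}

setMethod("show", "CodonAlignment", function(object) {
  cat("CodonAlignment:", length(object@nucleotide), "rows x",
      alignmentWidth(object), "nucleotide columns (",
      alignmentWidth(object) %/% 3L, "codons )\n")
})

#' Gumbel significance calibration for a profile
#'
#' Location/scale of a Gumbel (type-I extreme value) distribution fitted by
#' maximum likelihood to forward bit scores of random background sequences,
#' used to convert bit scores into E-values.
#'
#' @slot profileName name of the calibrated profile.
#' @slot mu Gumbel location (bits).
#' @slot lambda Gumbel rate (1/scale), strictly positive.
#' @slot nShuffles number of background sequences scored.
#' @slot seed integer seed the calibration is reproducible from.
#'
#' @seealso [calibrateEvalue()], [evalue()]
#' @export
setClass("EvalueCalibration",
  representation(profileName = "character", mu = "numeric",
                 lambda = "numeric", nShuffles = "integer", seed = "integer"))

setValidity("EvalueCalibration", function(object) {
  msg <- character(0)
  if (length(object@lambda) != 1L || !is.finite(object@lambda) ||
      object@lambda <= 0)
    msg <- c(msg, "lambda must be a single positive finite number")
  if (length(object@mu) != 1L || !is.finite(object@mu))
    msg <- c(msg, "mu must be a single finite number")
  if (length(msg)) msg else TRUE
})

setMethod("show", "EvalueCalibration", function(object) {
  cat(sprintf(
    "EvalueCalibration for '%s': mu = %.3f bits, lambda = %.4f (%d shuffles, seed %d)\n",
    object@profileName, object@mu, object@lambda, object@nShuffles,
    object@seed))
})

#' Nucleotide profile hidden Markov model
#'
#' Plan-7-style match/insert/delete model over `{A,C,G,T}` with uniform
#' local (fragment) entry and exit, built from a multiple alignment and
#' scored against queries with the forward algorithm in bits.
#'
#' Probabilities are stored on the probability scale; log-odds are formed
#' against `background` at scoring time. `transitions` has one row per
#' match node and columns `MM, MI, MD, IM, II, DM, DD`; each of the three
#' per-state triples (`MM+MI+MD`, `IM+II`, `DM+DD`) sums to 1.
#'
#' @slot name taxon name the profile represents.
#' @slot rank taxonomic rank of the label, `"order"` or `"species"`.
#' @slot M number of match states.
#' @slot matchEmissions `M x 4` matrix of match emission probabilities
#'   (columns A, C, G, T).
#' @slot insertEmissions `M x 4` matrix of insert emission probabilities.
#' @slot transitions `M x 7` matrix of transition probabilities.
#' @slot background length-4 background base distribution.
#' @slot matchColumns 1-based source-alignment columns that became match
#'   states.
#' @slot sourceWidth number of columns of the training alignment.
#' @slot calibration an [EvalueCalibration-class], or an empty list before
#'   calibration.
#'
#' @seealso [buildProfile()], [forwardBits()], [scanQueries()]
#' @export
setClass("ProfileHMM",
  representation(name = "character", rank = "character", M = "integer",
                 matchEmissions = "matrix", insertEmissions = "matrix",
                 transitions = "matrix", background = "numeric",
                 matchColumns = "integer", sourceWidth = "integer",
                 calibration = "ANY"))

TRANS_NAMES <- c("MM", "MI", "MD", "IM", "II", "DM", "DD")

setValidity("ProfileHMM", function(object) {
  msg <- character(0)
  M <- object@M
  if (M < 1L) msg <- c(msg, "M must be >= 1")
  if (!identical(dim(object@matchEmissions), c(M, 4L)))
    msg <- c(msg, "matchEmissions must be M x 4")
  if (!identical(dim(object@insertEmissions), c(M, 4L)))
    msg <- c(msg, "insertEmissions must be M x 4")
  if (!identical(dim(object@transitions), c(M, 7L)))
    msg <- c(msg, "transitions must be M x 7")
  if (length(object@background) != 4L ||
      abs(sum(object@background) - 1) > 1e-9)
    msg <- c(msg, "background must be 4 probabilities summing to 1")
  if (identical(dim(object@transitions), c(M, 7L))) {
    tr <- object@transitions
    ok <- abs(rowSums(tr[, 1:3, drop = FALSE]) - 1) < 1e-9 &
          abs(rowSums(tr[, 4:5, drop = FALSE]) - 1) < 1e-9 &
          abs(rowSums(tr[, 6:7, drop = FALSE]) - 1) < 1e-9
    if (!all(ok))
      msg <- c(msg, "per-state transition distributions must sum to 1")
  }
  if (identical(dim(object@matchEmissions), c(M, 4L)) &&
      any(abs(rowSums(object@matchEmissions) - 1) > 1e-9))
    msg <- c(msg, "match emission rows must sum to 1")
  if (!object@rank %in% c("order", "species"))
    msg <- c(msg, "rank must be 'order' or 'species'")
  if (length(msg)) msg else TRUE
})

#' @describeIn ProfileHMM taxon name of the profile.
#' @param x a `ProfileHMM`.
#' @export
profileName <- function(x) x@name

#' @describeIn ProfileHMM taxonomic rank of the profile label.
#' @export
profileRank <- function(x) x@rank

#' @describeIn ProfileHMM number of match states.
#' @export
nMatchStates <- function(x) x@M

#' @describeIn ProfileHMM the stored [EvalueCalibration-class], or `NULL`.
#' @export
profileCalibration <- function(x) {
  if (is(x@calibration, "EvalueCalibration")) x@calibration else NULL
}

#' @describeIn ProfileHMM `TRUE` once an E-value calibration is attached.
#' @export
isCalibrated <- function(x) is(x@calibration, "EvalueCalibration")

setMethod("show", "ProfileHMM", function(object) {
  cat(sprintf("ProfileHMM '%s' (rank %s): %d match states%s\n",
              object@name, object@rank, object@M,
              if (isCalibrated(object)) ", calibrated" else ""))
})
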