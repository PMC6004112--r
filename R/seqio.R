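#' Read a nucleotide FASTA file
#'
#' Thin wrapper over [Biostrings::readDNAStringSet()] that enforces the
#' contracts the rest of the pipeline relies on: unique, non-empty record
#' ids (the first whitespace-delimited token of the header) and non-empty
#' sequences. CRLF and LF files are equivalent.
#'
#' @param path path to a FASTA file.
#' @return a named [Biostrings::DNAStringSet].
#' @export
readFasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  x <- Biostrings::readDNAStringSet(path)
  names(x) <- sub("\\s.*$", "", names(x))
  if (anyDuplicated(names(x)))
    stop("duplicate FASTA id(s): ",
         paste(unique(names(x)[duplicated(names(x))]), collapse = ", "))
  if (any(Biostrings::width(x) == 0L))
    stop("empty sequence in FASTA: ",
         paste(names(x)[Biostrings::width(x) == 0L], collapse = ", "))
  x
}

#' Write sequences to FASTA
#'
#' @param x a named [Biostrings::XStringSet] or character vector.
#' @param path output path.
#' @param width line-wrap width (default 60).
#' @return `path`, invisibly.
#' @export
writeFasta <- function(x, path, width = 60L) {
  if (is.character(x)) x <- Biostrings::BStringSet(x)
  Biostrings::writeXStringSet(x, path, width = width)
  invisible(path)
}

#' Read a taxonomy map
#'
#' Tab-separated file `id<TAB>order_label[<TAB>species_label]`, no header.
#'
#' @param path path to the TSV.
#' @return `data.frame` with columns `id`, `order_label`, `species_label`.
#' @export
readTaxonomyTsv <- function(path) {
  if (!file.exists(path)) stop("taxonomy file not found: ", path)
  tx <- read.delim(path, header = FALSE, sep = "\t",
                   colClasses = "character", quote = "",
                   blank.lines.skip = TRUE)
  if (ncol(tx) < 2L)
    stop("taxonomy TSV must have at least two columns (id, order_label)")
  if (ncol(tx) == 2L) tx$V3 <- NA_character_
  tx <- tx[, 1:3]
  colnames(tx) <- c("id", "order_label", "species_label")
  tx$species_label[!is.na(tx$species_label) & tx$species_label == ""] <-
    NA_character_
  if (anyDuplicated(tx$id))
    stop("duplicate id(s) in taxonomy: ",
         paste(unique(tx$id[duplicated(tx$id)]), collapse = ", "))
  if (any(is.na(tx$order_label) | tx$order_label == ""))
    stop("empty order_label in taxonomy")
  tx
}

#' Write a taxonomy map
#'
#' @param taxonomy `data.frame` with columns `id`, `order_label`,
#'   `species_label`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeTaxonomyTsv <- function(taxonomy, path) {
  out <- taxonomy[, c("id", "order_label", "species_label")]
  out$species_label[is.na(out$species_label)] <- ""
  write.table(out, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Load a reference set from FASTA + taxonomy TSV
#'
#' @param fastaPath nucleotide FASTA of reference sequences.
#' @param taxonomyPath taxonomy TSV (see [readTaxonomyTsv()]).
#' @return a [TaxonSet-class]. Errors if any FASTA id is missing from the
#'   taxonomy map.
#' @export
readTaxonSet <- function(fastaPath, taxonomyPath) {
  TaxonSet(readFasta(fastaPath), readTaxonomyTsv(taxonomyPath))
}

## genetic-code tables come from Biostrings (NCBI tables 1 and 5)
geneticCodeTable <- function(code = c("invertebrate_mito", "standard")) {
  code <- match.arg(code)
  id <- if (code == "invertebrate_mito") "5" else "1"
  Biostrings::getGeneticCode(id)
}

#' Translate a nucleotide sequence
#'
#' Codon-by-codon translation of the in-frame part of `seq`; any trailing
#' partial codon is dropped. Codons containing `N` translate to `X`. Stop
#' codons translate to `*`. coxI is mitochondrial, so the invertebrate
#' mitochondrial code (NCBI table 5) is the default; the standard code is
#' selectable.
#'
#' @param seq a nucleotide string over `A,C,G,T,N`.
#' @param frame reading-frame offset, 0, 1 or 2.
#' @param code `"invertebrate_mito"` (default) or `"standard"`.
#' @return an amino-acid string.
#' @examples
#' translateCodons("ATGAAA")              # "MK"
#' translateCodons("ATGAAA", frame = 1)   # "W" under the mitochondrial code
#' @export
translateCodons <- function(seq, frame = 0L,
                            code = c("invertebrate_mito", "standard")) {
  seq <- toupper(as.character(seq))
  if (length(seq) != 1L || nchar(seq) == 0L)
    stop("seq must be a single non-empty nucleotide string")
  if (!frame %in% 0:2) stop("frame must be 0, 1 or 2")
  if (grepl("[^ACGTN]", seq))
    stop("seq contains characters outside {A,C,G,T,N}")
  body <- substr(seq, frame + 1L, nchar(seq))
  n <- nchar(body) %/% 3L
  if (n == 0L) return("")
  tab <- geneticCodeTable(code)
  cod <- substring(body, 3L * seq_len(n) - 2L, 3L * seq_len(n))
  aa <- tab[cod]
  aa[is.na(aa)] <- "X"   # codons containing N
  paste(aa, collapse = "")
}

#' Pick a reading frame by longest stop-free translation
#'
#' Returns the frame (0, 1 or 2) whose translation has the fewest internal
#' stop codons, preferring the longest stop-free run and, on ties, the
#' lowest frame. Reference sets rarely record their frame; this heuristic
#' recovers it for protein-coding barcodes.
#'
#' @inheritParams translateCodons
#' @return integer frame in `0:2`.
#' @export
chooseFrame <- function(seq, code = c("invertebrate_mito", "standard")) {
  code <- match.arg(code)
  stats <- vapply(0:2, function(f) {
    aa <- translateCodons(seq, f, code)
    c(stops = lengths(regmatches(aa, gregexpr("\\*", aa))),
      len = nchar(aa))
  }, numeric(2))
  frames <- order(stats["stops", ], -stats["len", ])
  as.integer(frames[1L] - 1L)
}
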