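#' Thread nucleotide sequences through a protein alignment
#'
#' Produces a codon-resolved nucleotide alignment ("back-alignment") from
#' ungapped nucleotide sequences and a protein multiple alignment of their
#' translations: each aligned residue is replaced by its source codon and
#' each protein gap by `---`. Ungapping any output row reproduces the
#' in-frame part of the input nucleotide sequence exactly.
#'
#' Input nucleotides are assumed in-frame (frame 0); pass `frames` when
#' they are not. Internal stop codons in the translation are tolerated
#' with a warning (reference sets may contain pseudogene-like entries) —
#' the codon is threaded like any other.
#'
#' @param nucs named character vector or [Biostrings::DNAStringSet] of
#'   ungapped nucleotide sequences.
#' @param protMsa gapped protein alignment as a named character vector or
#'   [Biostrings::AAStringSet]; ids must match `nucs` one-to-one.
#' @param frames optional named integer vector of per-record frame offsets
#'   (default 0 for all).
#' @param code genetic code used for the consistency warning on stops.
#' @return a [CodonAlignment-class].
#' @examples
#' backAlign(c(a = "ATGAAA"), c(a = "M-K"))
#' @export
backAlign <- function(nucs, protMsa, frames = NULL,
                      code = c("invertebrate_mito", "standard")) {
  code <- match.arg(code)
  if (is(nucs, "XStringSet")) nucs <- setNames(as.character(nucs), names(nucs))
  if (is(protMsa, "XStringSet"))
    protMsa <- setNames(as.character(protMsa), names(protMsa))
  if (is.null(names(nucs)) || is.null(names(protMsa)))
    stop("both nucs and protMsa must be named")
  if (!setequal(names(nucs), names(protMsa)) ||
      length(nucs) != length(protMsa))
    stop("ids of nucs and protMsa must match one-to-one")
  protMsa <- protMsa[names(nucs)]
  if (length(unique(nchar(protMsa))) > 1L)
    stop("protein alignment rows differ in length")

  rows <- character(length(nucs))
  for (i in seq_along(nucs)) {
    id <- names(nucs)[i]
    fr <- if (is.null(frames)) 0L else as.integer(frames[[id]])
    nuc <- toupper(nucs[[i]])
    body <- substr(nuc, fr + 1L, nchar(nuc))
    ncod <- nchar(body) %/% 3L
    body <- substr(body, 1L, 3L * ncod)   # drop trailing partial codon
    prot <- strsplit(protMsa[[i]], "", fixed = TRUE)[[1L]]
    nres <- sum(prot != "-")
    if (nres != ncod)
      stop("back-alignment length mismatch for '", id, "': ",
           nres, " aligned residues vs ", ncod, " in-frame codons")
    aa <- translateCodons(body, 0L, code)
    if (grepl("\\*", substr(aa, 1L, nchar(aa) - 1L)))
      warning("internal stop codon(s) in '", id,
              "'; threading codons anyway")
    codons <- substring(body, 3L * seq_len(ncod) - 2L, 3L * seq_len(ncod))
    out <- rep("---", length(prot))
    out[prot != "-"] <- codons
    rows[i] <- paste(out, collapse = "")
  }
  new("CodonAlignment",
      nucleotide = Biostrings::DNAStringSet(setNames(rows, names(nucs))),
      protein = Biostrings::AAStringSet(protMsa))
}

#' Remove gaps from alignment rows
#'
#' @param x a [CodonAlignment-class], [Biostrings::XStringSet] or character
#'   vector of gapped rows.
#' @return named character vector of ungapped sequences.
#' @export
ungapRows <- function(x) {
  if (is(x, "CodonAlignment")) x <- x@nucleotide
  if (is(x, "XStringSet")) x <- setNames(as.character(x), names(x))
  vapply(x, function(r) gsub("-", "", r, fixed = TRUE), character(1))
}

#' Serialize a codon alignment as gapped FASTA
#'
#' @param x a [CodonAlignment-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeCodonAlignment <- function(x, path) {
  writeFasta(x@nucleotide, path)
}
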