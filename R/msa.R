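## Progressive protein multiple alignment: UPGMA guide tree on k-mer
## distances, profile-profile Needleman-Wunsch with BLOSUM62 and a linear
## gap penalty. Deliberately modest -- it exists so that codon
## back-alignments can be produced without an external aligner; any
## protein MSA produced elsewhere is accepted by backAlign() unchanged.

blosumWithGap <- function() {
  e <- new.env()
  data("BLOSUM62", package = "Biostrings", envir = e)
  B <- e$BLOSUM62
  ab <- c(rownames(B), "-")
  S <- matrix(-4, length(ab), length(ab), dimnames = list(ab, ab))
  S[rownames(B), colnames(B)] <- B
  S["-", ] <- -4
  S[, "-"] <- -4
  S["-", "-"] <- 0
  S
}

kmerDistance <- function(seqs, k = 3L) {
  kms <- lapply(seqs, function(s) {
    n <- nchar(s)
    if (n < k) return(s)
    unique(substring(s, seq_len(n - k + 1L), seq_len(n - k + 1L) + k - 1L))
  })
  n <- length(seqs)
  D <- matrix(0, n, n)
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    shared <- length(intersect(kms[[i]], kms[[j]]))
    D[i, j] <- D[j, i] <-
      1 - shared / max(1L, min(length(kms[[i]]), length(kms[[j]])))
  }
  D
}

## P1, P2: character matrices (rows = sequences, cols = alignment columns)
profilePairAlign <- function(P1, P2, S, gap = -8) {
  ab <- rownames(S)
  freq <- function(P) {
    Fm <- matrix(0, ncol(P), length(ab), dimnames = list(NULL, ab))
    for (j in seq_len(ncol(P))) {
      tb <- table(factor(P[, j], levels = ab))
      Fm[j, ] <- as.numeric(tb) / nrow(P)
    }
    Fm
  }
  F1 <- freq(P1); F2 <- freq(P2)
  CS <- F1 %*% S %*% t(F2)            # column-pair substitution scores
  L1 <- ncol(P1); L2 <- ncol(P2)
  V <- matrix(0, L1 + 1L, L2 + 1L)
  V[, 1L] <- gap * (0:L1)
  V[1L, ] <- gap * (0:L2)
  TB <- matrix(0L, L1 + 1L, L2 + 1L)  # 1 diag, 2 up(P1 col), 3 left(P2 col)
  TB[, 1L] <- 2L; TB[1L, ] <- 3L; TB[1L, 1L] <- 0L
  for (i in seq_len(L1)) {
    for (j in seq_len(L2)) {
      d <- V[i, j] + CS[i, j]
      u <- V[i, j + 1L] + gap
      l <- V[i + 1L, j] + gap
      best <- max(d, u, l)
      V[i + 1L, j + 1L] <- best
      TB[i + 1L, j + 1L] <- if (best == d) 1L else if (best == u) 2L else 3L
    }
  }
  i <- L1 + 1L; j <- L2 + 1L
  cols1 <- integer(0); cols2 <- integer(0)   # 0 = gap column
  while (i > 1L || j > 1L) {
    mv <- TB[i, j]
    if (mv == 1L)      { cols1 <- c(i - 1L, cols1); cols2 <- c(j - 1L, cols2); i <- i - 1L; j <- j - 1L }
    else if (mv == 2L) { cols1 <- c(i - 1L, cols1); cols2 <- c(0L, cols2);     i <- i - 1L }
    else               { cols1 <- c(0L, cols1);     cols2 <- c(j - 1L, cols2); j <- j - 1L }
  }
  take <- function(P, idx) {
    out <- matrix("-", nrow(P), length(idx))
    nz <- idx > 0L
    out[, nz] <- P[, idx[nz], drop = FALSE]
    out
  }
  rbind(take(P1, cols1), take(P2, cols2))
}

#' Progressive protein multiple alignment
#'
#' Aligns amino-acid sequences progressively along a UPGMA guide tree
#' computed from shared 3-mer fractions, using profile-profile global
#' alignment with BLOSUM62 and a linear gap penalty. Intended for
#' within-taxon barcode translations, where sequences are closely related;
#' it is not a general-purpose aligner and an externally produced protein
#' MSA can be supplied to [backAlign()] instead.
#'
#' @param seqs named character vector or [Biostrings::AAStringSet] of
#'   ungapped amino-acid sequences.
#' @param gap linear gap penalty per column (default -8).
#' @return a gapped [Biostrings::AAStringSet] in input order.
#' @export
alignProteins <- function(seqs, gap = -8) {
  if (is(seqs, "XStringSet")) seqs <- setNames(as.character(seqs), names(seqs))
  if (is.null(names(seqs)) || anyDuplicated(names(seqs)))
    stop("seqs must have unique names")
  if (any(nchar(seqs) == 0L)) stop("empty protein sequence")
  n <- length(seqs)
  toMat <- function(s) matrix(strsplit(s, "", fixed = TRUE)[[1L]], nrow = 1L)
  if (n == 1L)
    return(Biostrings::AAStringSet(seqs))
  S <- blosumWithGap()
  profiles <- lapply(seqs, toMat)
  rowids <- as.list(names(seqs))
  if (n == 2L) {
    merged <- profilePairAlign(profiles[[1L]], profiles[[2L]], S, gap)
    ids <- c(rowids[[1L]], rowids[[2L]])
  } else {
    hc <- stats::hclust(stats::as.dist(kmerDistance(seqs)), method = "average")
    nodeP <- vector("list", nrow(hc$merge))
    nodeI <- vector("list", nrow(hc$merge))
    pick <- function(k) {
      if (k < 0L) list(P = profiles[[-k]], ids = rowids[[-k]])
      else list(P = nodeP[[k]], ids = nodeI[[k]])
    }
    for (m in seq_len(nrow(hc$merge))) {
      a <- pick(hc$merge[m, 1L]); b <- pick(hc$merge[m, 2L])
      nodeP[[m]] <- profilePairAlign(a$P, b$P, S, gap)
      nodeI[[m]] <- c(a$ids, b$ids)
    }
    merged <- nodeP[[nrow(hc$merge)]]
    ids <- nodeI[[nrow(hc$merge)]]
  }
  rows <- apply(merged, 1L, paste, collapse = "")
  names(rows) <- unlist(ids)
  Biostrings::AAStringSet(rows[names(seqs)])
}

#' Codon alignment of a nucleotide reference set
#'
#' Convenience pipeline: choose a reading frame per sequence (see
#' [chooseFrame()]), translate, align the proteins with [alignProteins()]
#' (or use `protMsa` if given), and thread the codons back with
#' [backAlign()].
#'
#' @param nucs named character vector or [Biostrings::DNAStringSet].
#' @param protMsa optional externally produced gapped protein MSA.
#' @param code genetic code (see [translateCodons()]).
#' @return a [CodonAlignment-class].
#' @export
codonAlign <- function(nucs, protMsa = NULL,
                       code = c("invertebrate_mito", "standard")) {
  code <- match.arg(code)
  if (is(nucs, "XStringSet")) nucs <- setNames(as.character(nucs), names(nucs))
  frames <- vapply(nucs, chooseFrame, integer(1), code = code)
  if (is.null(protMsa)) {
    aa <- mapply(function(s, f) {
      p <- translateCodons(s, f, code)
      sub("\\*$", "X", p)    # keep a trailing stop as a residue column
    }, nucs, frames)
    protMsa <- alignProteins(aa)
  }
  backAlign(nucs = trimToFrame(nucs, frames), protMsa = protMsa, code = code)
}

trimToFrame <- function(nucs, frames) {
  out <- mapply(function(s, f) {
    body <- substr(s, f + 1L, nchar(s))
    substr(body, 1L, 3L * (nchar(body) %/% 3L))
  }, nucs, frames)
  setNames(out, names(nucs))
}
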