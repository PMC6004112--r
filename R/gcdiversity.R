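#' Exponential entropy (Hill number of order 1) of an alignment column
#'
#' Gaps, `N` and any non-ACGT symbols are excluded before computing base
#' frequencies; the value is `exp` of the natural-log Shannon entropy —
#' the effective number of equally frequent bases, between 1 (monomorphic)
#' and 4 (uniform).
#'
#' @param column character vector of single characters (one alignment
#'   column).
#' @return numeric in `[1, 4]`, or `NA` if no usable characters remain.
#' @examples
#' siteExpEntropy(c("A", "A", "C", "C"))  # 2
#' @export
siteExpEntropy <- function(column) {
  column <- toupper(column)
  column <- column[column %in% DNA_BASES4]
  if (!length(column)) return(NA_real_)
  p <- as.numeric(table(factor(column, levels = DNA_BASES4)))
  p <- p[p > 0] / sum(p)
  exp(-sum(p * log(p)))
}

#' Per-site GC percentage track with moving-average smoothing
#'
#' Per column, the fraction of G/C among the non-gap reference characters
#' (i.e. averaged over sequences first), then a centred moving average
#' over `window` columns, truncated at the alignment edges, expressed in
#' percent.
#'
#' @param refAln reference alignment (anything [buildProfile()] accepts).
#' @param window smoothing window in columns (default 100).
#' @return numeric vector, one value in `[0, 100]` per column.
#' @export
gcTrack <- function(refAln, window = 100L) {
  if (window < 1L) stop("window must be >= 1")
  m <- alnToMatrix(refAln)
  if (!ncol(m)) stop("empty alignment")
  gc <- vapply(seq_len(ncol(m)), function(j) {
    col <- m[, j]
    col <- col[col %in% DNA_BASES4]
    if (!length(col)) return(NA_real_)
    mean(col %in% c("G", "C"))
  }, numeric(1))
  n <- length(gc)
  lo <- pmax(1L, seq_len(n) - (window - 1L) %/% 2L)
  hi <- pmin(n, seq_len(n) + window %/% 2L)
  cs <- cumsum(ifelse(is.na(gc), 0, gc))
  cn <- cumsum(!is.na(gc))
  sums <- cs[hi] - c(0, cs)[lo]
  cnts <- cn[hi] - c(0, cn)[lo]
  100 * sums / cnts
}

#' Per-site diversity profile of reads against references
#'
#' Joins, per alignment column, the exponential entropy of the read
#' alignment (`d_reads`), of the reference alignment (`d_ref`), and the
#' smoothed reference GC percentage (`gc_ref`). Both alignments must live
#' in the same coordinate system (reads are placed there by
#' [alignToProfile()]). Columns where either entropy is undefined (e.g.
#' all-gap in the reads) are flagged `complete = FALSE` and excluded from
#' model fitting.
#'
#' @param readsAln read alignment in reference coordinates.
#' @param refAln reference alignment.
#' @param window GC smoothing window (default 100).
#' @return `data.frame`: `site`, `d_reads`, `d_ref`, `gc_ref`, `complete`.
#' @export
diversityProfile <- function(readsAln, refAln, window = 100L) {
  mr <- alnToMatrix(readsAln)
  mf <- alnToMatrix(refAln)
  if (ncol(mr) != ncol(mf))
    stop("reads and reference alignments differ in width (",
         ncol(mr), " vs ", ncol(mf), ")")
  dReads <- apply(mr, 2L, siteExpEntropy)
  dRef <- apply(mf, 2L, siteExpEntropy)
  gc <- gcTrack(mf, window)
  out <- data.frame(site = seq_len(ncol(mf)), d_reads = dReads,
                    d_ref = dRef, gc_ref = gc)
  out$complete <- !(is.na(out$d_reads) | is.na(out$d_ref) | is.na(out$gc_ref))
  out
}

#' Slice a diversity profile into the 5' or 3' analysis region
#'
#' `five_prime` keeps alignment columns 1..`fiveEnd` (default 400,
#' 1-based inclusive); `three_prime` keeps columns `threeStart`..end
#' (default from 200). A profile shorter than the bound is truncated with
#' a warning.
#'
#' @param profile `data.frame` from [diversityProfile()], sorted by
#'   `site`.
#' @param region `"five_prime"` or `"three_prime"`.
#' @param fiveEnd,threeStart region bounds in alignment columns.
#' @return the sliced `data.frame`.
#' @export
sliceRegion <- function(profile, region = c("five_prime", "three_prime"),
                        fiveEnd = 400L, threeStart = 200L) {
  region <- match.arg(region)
  if (is.unsorted(profile$site)) stop("profile must be sorted by site")
  n <- max(profile$site)
  if (region == "five_prime") {
    if (n < fiveEnd)
      warning("alignment has only ", n, " columns; 5' region truncated")
    profile[profile$site <= fiveEnd, , drop = FALSE]
  } else {
    if (n < threeStart)
      warning("alignment has only ", n, " columns; 3' region is empty")
    profile[profile$site >= threeStart, , drop = FALSE]
  }
}

#' Sequential ANOVA table from a sum-of-squares decomposition
#'
#' Pure arithmetic shared by [fitGcModel()]: given per-term sequential
#' sums of squares and degrees of freedom (with the residual term last),
#' computes mean squares, F statistics against the residual mean square,
#' right-tail p-values and explained-variance percentages
#' (`100 * SS / total SS`).
#'
#' @param ss named numeric vector of sums of squares; the last element is
#'   the residual.
#' @param df integer vector of degrees of freedom, parallel to `ss`.
#' @return `data.frame`: `term`, `df`, `sum_sq`, `mean_sq`, `f_value`
#'   (`NA` for the residual), `p_value`, `explained_pct`.
#' @examples
#' anovaFromDecomposition(c(GCref = 4.518, Dref = 58.766,
#'                          Residuals = 123.808), c(1, 1, 562))
#' @export
anovaFromDecomposition <- function(ss, df) {
  if (length(ss) != length(df) || length(ss) < 2L)
    stop("ss and df must be parallel vectors with the residual last")
  ms <- ss / df
  resMS <- ms[length(ms)]
  f <- ms / resMS
  f[length(f)] <- NA_real_
  p <- pf(f, df, df[length(df)], lower.tail = FALSE)
  out <- data.frame(term = names(ss), df = as.integer(df),
                    sum_sq = as.numeric(ss), mean_sq = as.numeric(ms),
                    f_value = as.numeric(f), p_value = as.numeric(p),
                    explained_pct = 100 * as.numeric(ss) / sum(ss),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Fit the diversity ~ diversity + GC linear model
#'
#' Ordinary-least-squares fit of `d_reads` on an intercept plus the given
#' covariates, with a sequential (type I) ANOVA in the supplied term
#' order. The decomposition is order dependent by construction: term sums
#' of squares change with the order, the residual does not. The default
#' order is `(gc_ref, d_ref)`, matching the reported-table convention;
#' pass `c("d_ref", "gc_ref")` for the model-formula order.
#'
#' @param rows `data.frame` with columns `d_reads`, `d_ref`, `gc_ref`
#'   (e.g. from [diversityProfile()]); incomplete rows are dropped.
#' @param termOrder character vector of covariate columns in sequential
#'   order.
#' @return list with `fit` (the `lm` object) and `anova`
#'   (see [anovaFromDecomposition()]).
#' @export
fitGcModel <- function(rows, termOrder = c("gc_ref", "d_ref")) {
  if (!all(c("d_reads", termOrder) %in% colnames(rows)))
    stop("rows must contain d_reads and the terms: ",
         paste(termOrder, collapse = ", "))
  rows <- rows[stats::complete.cases(rows[, c("d_reads", termOrder)]), ,
               drop = FALSE]
  if (nrow(rows) < 3L) stop("need >= 3 complete rows to fit the model")
  fml <- stats::as.formula(paste("d_reads ~", paste(termOrder, collapse = " + ")))
  fit <- lm(fml, data = rows)
  aliased <- names(coef(fit))[is.na(coef(fit))]
  constant <- aliased[vapply(aliased, function(tm)
    tm %in% colnames(rows) && stats::var(rows[[tm]]) < 1e-12, logical(1))]
  if (length(setdiff(aliased, constant)))
    stop("collinear covariates (aliased): ",
         paste(setdiff(aliased, constant), collapse = ", "))
  if (length(constant))
    warning("constant covariate(s) carry no variance: ",
            paste(constant, collapse = ", "))
  av <- suppressWarnings(anova(fit))
  ss <- setNames(av[["Sum Sq"]], rownames(av))
  df <- av[["Df"]]
  tab <- anovaFromDecomposition(ss, df)
  if (length(constant)) {   # re-insert dropped constant terms as zero rows
    zero <- data.frame(term = constant, df = 0L, sum_sq = 0, mean_sq = NA_real_,
                       f_value = NA_real_, p_value = NA_real_,
                       explained_pct = 0, stringsAsFactors = FALSE)
    tab <- rbind(tab[tab$term != "Residuals", ], zero,
                 tab[tab$term == "Residuals", ])
    tab <- tab[order(match(tab$term, c(termOrder, "Residuals"))), ]
    rownames(tab) <- NULL
  }
  list(fit = fit, anova = tab)
}

#' Place reads into reference coordinates and run the GC/diversity model
#'
#' End-to-end diagnostic: aligns each read into the profile's source
#' coordinates via [alignToProfile()], computes the per-site diversity
#' profile against the profile's training alignment, slices the requested
#' region and fits the sequential-ANOVA linear model.
#'
#' @param reads character vector / [Biostrings::DNAStringSet] of reads
#'   assigned to the profile's taxon.
#' @param profile the taxon's [ProfileHMM-class].
#' @param refAln the training alignment the profile was built from.
#' @param region,fiveEnd,threeStart see [sliceRegion()].
#' @param window GC window (default 100).
#' @param termOrder see [fitGcModel()].
#' @return list: `profileTable` (all sites), `region` (sliced rows),
#'   `fit`, `anova`.
#' @export
gcDiversityDiagnostic <- function(reads, profile, refAln,
                                  region = c("five_prime", "three_prime"),
                                  fiveEnd = 400L, threeStart = 200L,
                                  window = 100L,
                                  termOrder = c("gc_ref", "d_ref")) {
  region <- match.arg(region)
  if (is(reads, "XStringSet"))
    reads <- setNames(as.character(reads), names(reads))
  aligned <- vapply(reads, function(s) alignToProfile(profile, s),
                    character(1))
  tab <- diversityProfile(aligned, refAln, window = window)
  sl <- sliceRegion(tab, region, fiveEnd = fiveEnd, threeStart = threeStart)
  mod <- fitGcModel(sl[sl$complete, , drop = FALSE], termOrder = termOrder)
  list(profileTable = tab, region = sl, fit = mod$fit, anova = mod$anova)
}
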