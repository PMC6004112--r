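logSumExp <- function(x) {
  if (!length(x)) return(-Inf)
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

#' Log Bayes factor of the best hit over its competitors
#'
#' For a descending vector of per-profile scores `S_1 >= S_2 >= ... >=
#' S_n`, returns `S_1 - ln(sum_{i=2}^{n} exp(S_i))`, computed with an
#' overflow-safe log-sum-exp. With a single hit there is no competitor and
#' the value is `+Inf`. Scores are used exactly as given: the canonical
#' rule applies natural exp/ln to bit scores as printed; pass
#' `units = "nats"` upstream (see [classify()]) for the variant that
#' converts bits to nats first.
#'
#' @param scores numeric vector sorted in decreasing order.
#' @return the log Bayes factor (natural-log scale).
#' @examples
#' lnBayesFactor(c(10, 5, 3))   # 10 - log(exp(5) + exp(3)) = 4.8732...
#' lnBayesFactor(c(7, 7))       # 0
#' lnBayesFactor(42)            # Inf
#' @export
lnBayesFactor <- function(scores) {
  if (!length(scores)) stop("scores must be non-empty")
  if (is.unsorted(rev(scores)))
    stop("scores must be sorted in decreasing order")
  if (length(scores) == 1L) return(Inf)
  scores[1L] - logSumExp(scores[-1L])
}

#' Three-way classification of a query's profile hits
#'
#' Implements the hidden-state taxa-assignment decision rule:
#' \describe{
#'   \item{Unclassified}{the best hit's E-value exceeds the significance
#'     gate (or there are no hits);}
#'   \item{Good}{the log Bayes factor of the best significant hit over the
#'     remaining significant hits exceeds `bfThreshold`; the query is
#'     assigned the best profile's taxon;}
#'   \item{Ambiguous}{significant, but the Bayes-factor test fails.}
#' }
#' The Bayes-factor sum runs over the hits passing the E-value gate. Ties
#' for best hit are broken by profile name (lexicographic); an exact tie
#' gives `ln(BF) = 0`, so the category does not depend on the tie-break.
#'
#' @param hits `data.frame` from [scanQuery()] (columns `query_id`,
#'   `profile_name`, `bit_score`, `evalue`), sorted by `bit_score`
#'   descending.
#' @param evalueThreshold significance gate on the E-value (default 10,
#'   the conventional reporting threshold; 0.01 mirrors the stricter
#'   inclusion threshold).
#' @param bfThreshold Bayes-factor threshold (default 3.0).
#' @param units `"bits"` (default: scores enter the Bayes factor as-is) or
#'   `"nats"` (bit scores are multiplied by `ln 2` first).
#' @param rank rank recorded in the output row.
#' @return one-row `data.frame`: `query_id`, `rank`, `category`, `taxon`
#'   (`NA` unless Good), `ln_bf`, `best_bit_score`, `best_evalue`.
#' @export
classify <- function(hits, evalueThreshold = 10, bfThreshold = 3.0,
                     units = c("bits", "nats"), rank = "order") {
  units <- match.arg(units)
  row <- function(cat, taxon = NA_character_, lbf = NA_real_,
                  qid = NA_character_, bs = NA_real_, ev = NA_real_)
    data.frame(query_id = qid, rank = rank, category = cat, taxon = taxon,
               ln_bf = lbf, best_bit_score = bs, best_evalue = ev,
               stringsAsFactors = FALSE)
  if (is.null(hits) || nrow(hits) == 0L) {
    message("query with no hits: Unclassified")
    return(row("Unclassified"))
  }
  if (is.unsorted(rev(hits$bit_score)))
    stop("hits must be sorted by bit_score descending")
  qid <- hits$query_id[1L]
  best <- hits[1L, ]
  if (is.na(best$evalue) || best$evalue > evalueThreshold)
    return(row("Unclassified", qid = qid, bs = best$bit_score,
               ev = best$evalue))
  sig <- hits[!is.na(hits$evalue) & hits$evalue <= evalueThreshold, ,
              drop = FALSE]
  scores <- sig$bit_score
  if (units == "nats") scores <- scores * log(2)
  lbf <- lnBayesFactor(scores)
  if (lbf > bfThreshold)
    row("Good", taxon = best$profile_name, lbf = lbf, qid = qid,
        bs = best$bit_score, ev = best$evalue)
  else
    row("Ambiguous", lbf = lbf, qid = qid, bs = best$bit_score,
        ev = best$evalue)
}

#' Filter a homology hit table to the best hit's order
#'
#' Keeps, per query, only the rows whose subject order label equals the
#' order label of the rank-1 (best) hit — the reference-selection rule
#' applied to retrieved top-10 hit lists before profile building. Rows
#' with a missing order label are dropped with a warning; if the best
#' hit's own label is missing the whole query is dropped with a warning.
#'
#' @param table `data.frame` with columns `query_id`, `subject_id`,
#'   `subject_order_label`, `bit_score`, `rank_position` (1 = best, at
#'   most 10 rows per query).
#' @return the filtered `data.frame`.
#' @export
filterHitsByBestOrder <- function(table) {
  need <- c("query_id", "subject_id", "subject_order_label",
            "bit_score", "rank_position")
  if (!all(need %in% colnames(table)))
    stop("hit table must have columns: ", paste(need, collapse = ", "))
  if (any(tabulate(factor(table$query_id)) > 10L))
    stop("more than 10 rows for a query in the hit table")
  keep <- lapply(split(table, table$query_id), function(h) {
    h <- h[order(h$rank_position), , drop = FALSE]
    if (h$rank_position[1L] != 1L)
      stop("query '", h$query_id[1L], "' lacks a rank_position-1 row")
    bad <- is.na(h$subject_order_label) | h$subject_order_label == ""
    if (bad[1L]) {
      warning("best hit of query '", h$query_id[1L],
              "' has no order label; query dropped")
      return(h[0L, , drop = FALSE])
    }
    if (any(bad))
      warning("dropping ", sum(bad), " unlabelled hit(s) for query '",
              h$query_id[1L], "'")
    h[!bad & h$subject_order_label == h$subject_order_label[1L], ,
      drop = FALSE]
  })
  out <- do.call(rbind, keep)
  rownames(out) <- NULL
  out[order(match(out$query_id, unique(table$query_id)),
            out$rank_position), , drop = FALSE]
}

#' Assign every query and tabulate Good abundances
#'
#' Scans each query against the profile collection, classifies it, and
#' counts Good assignments per taxon (optionally per strand stratum).
#'
#' @param queries named character vector or [Biostrings::DNAStringSet].
#' @param profiles list of calibrated [ProfileHMM-class] objects sharing
#'   one rank.
#' @param evalueThreshold,bfThreshold,units see [classify()].
#' @param strand optional character vector (parallel to `queries`) of
#'   strand/region labels, e.g. `"5p"`/`"3p"`; default a single `"all"`
#'   stratum.
#' @return list with `assignments` (one row per query) and `abundance`
#'   (columns `taxon`, `rank`, `strand`, `count`, Good reads only).
#' @export
assignAll <- function(queries, profiles, evalueThreshold = 10,
                      bfThreshold = 3.0, units = c("bits", "nats"),
                      strand = NULL) {
  units <- match.arg(units)
  if (is(queries, "XStringSet"))
    queries <- setNames(as.character(queries), names(queries))
  rank <- if (length(profiles)) profileRank(profiles[[1L]]) else "order"
  if (length(queries) == 0L) {
    return(list(
      assignments = data.frame(query_id = character(0), rank = character(0),
                               category = character(0), taxon = character(0),
                               ln_bf = numeric(0), best_bit_score = numeric(0),
                               best_evalue = numeric(0)),
      abundance = data.frame(taxon = character(0), rank = character(0),
                             strand = character(0), count = integer(0))))
  }
  if (is.null(names(queries))) names(queries) <- paste0("q", seq_along(queries))
  if (is.null(strand)) strand <- rep("all", length(queries))
  stopifnot(length(strand) == length(queries))
  hitsAll <- scanQueries(queries, profiles)
  byQuery <- split(hitsAll, factor(hitsAll$query_id, levels = names(queries)))
  rows <- lapply(byQuery, function(h)
    classify(h, evalueThreshold = evalueThreshold, bfThreshold = bfThreshold,
             units = units, rank = rank))
  assignments <- do.call(rbind, rows)
  good <- assignments$category == "Good"
  taxa <- vapply(profiles, profileName, character(1))
  grid <- expand.grid(taxon = sort(unique(taxa)),
                      strand = sort(unique(strand)),
                      stringsAsFactors = FALSE)
  grid$rank <- rank
  grid$count <- mapply(function(tx, st)
    sum(good & assignments$taxon == tx & strand == st, na.rm = TRUE),
    grid$taxon, grid$strand)
  list(assignments = assignments,
       abundance = grid[, c("taxon", "rank", "strand", "count")])
}

#' Write assignments and abundances as TSV
#'
#' @param result list from [assignAll()].
#' @param assignmentsPath,abundancePath output paths (either may be `NULL`
#'   to skip).
#' @return `result`, invisibly.
#' @export
writeAssignments <- function(result, assignmentsPath = NULL,
                             abundancePath = NULL) {
  if (!is.null(assignmentsPath))
    write.table(result$assignments, assignmentsPath, sep = "\t",
                quote = FALSE, row.names = FALSE)
  if (!is.null(abundancePath))
    write.table(result$abundance, abundancePath, sep = "\t",
                quote = FALSE, row.names = FALSE)
  invisible(result)
}
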