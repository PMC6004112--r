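alnToMatrix <- function(aln) {
  if (is(aln, "CodonAlignment")) aln <- aln@nucleotide
  if (is(aln, "XStringSet")) aln <- setNames(as.character(aln), names(aln))
  if (is.matrix(aln)) return(aln)
  if (!is.character(aln)) stop("unsupported alignment type")
  if (length(unique(nchar(aln))) > 1L)
    stop("alignment rows differ in length")
  m <- do.call(rbind, strsplit(toupper(aln), "", fixed = TRUE))
  rownames(m) <- names(aln)
  m
}

#' Build a nucleotide profile HMM from a multiple alignment
#'
#' Columns with a gap fraction strictly below `occupancyThreshold` become
#' match states (a column at exactly the threshold does not). Match
#' emissions are Laplace-smoothed column base counts converted to
#' probabilities; `N` characters are ignored in the counts. Transitions
#' are estimated from the observed match/insert/delete path of every row,
#' again with Laplace pseudocounts. Insert states emit the background
#' distribution.
#'
#' @param aln a [CodonAlignment-class], gapped [Biostrings::DNAStringSet],
#'   named character vector of equal-length rows, or character matrix.
#' @param name taxon name for the profile.
#' @param rank `"order"` or `"species"`.
#' @param occupancyThreshold match-column gap-fraction cutoff (default 0.5,
#'   strict `<`).
#' @param pseudocount Laplace pseudocount for emissions and transitions
#'   (default 1).
#' @param background length-4 background distribution over A,C,G,T
#'   (default uniform).
#' @return a [ProfileHMM-class] (uncalibrated).
#' @examples
#' p <- buildProfile(c(a = "ACGT", b = "ACGT", c = "ACGA"), "toy", "order")
#' nMatchStates(p)
#' @export
buildProfile <- function(aln, name, rank = c("order", "species"),
                         occupancyThreshold = 0.5, pseudocount = 1,
                         background = rep(0.25, 4)) {
  rank <- match.arg(rank)
  m <- alnToMatrix(aln)
  if (nrow(m) < 2L)
    stop("profile building needs an alignment with >= 2 rows")
  bad <- setdiff(unique(as.vector(m)), c(DNA_BASES4, "N", "-"))
  if (length(bad))
    stop("alignment contains unsupported characters: ",
         paste(bad, collapse = ", "))
  gapFrac <- colMeans(m == "-")
  matchCols <- which(gapFrac < occupancyThreshold)
  M <- length(matchCols)
  if (M == 0L) stop("alignment has zero match columns")

  em <- matrix(pseudocount, M, 4L, dimnames = list(NULL, DNA_BASES4))
  for (j in seq_len(M)) {
    tb <- table(factor(m[, matchCols[j]], levels = DNA_BASES4))
    em[j, ] <- em[j, ] + as.numeric(tb)
  }
  em <- em / rowSums(em)

  ## transition counts from the observed state path of each row
  cnt <- matrix(0, M, 7L, dimnames = list(NULL, TRANS_NAMES))
  isMatch <- logical(ncol(m)); isMatch[matchCols] <- TRUE
  node <- integer(ncol(m))                      # node index per match column
  node[matchCols] <- seq_len(M)
  for (r in seq_len(nrow(m))) {
    prev <- "B"; prevNode <- 0L
    for (j in seq_len(ncol(m))) {
      ch <- m[r, j]
      if (isMatch[j]) {
        cur <- if (ch == "-") "D" else "M"
        k <- node[j]
        if (prevNode >= 1L) {
          tn <- paste0(prev, cur)
          if (tn %in% TRANS_NAMES) cnt[prevNode, tn] <- cnt[prevNode, tn] + 1
        }
        prev <- cur; prevNode <- k
      } else if (ch != "-") {                   # insert-column residue
        if (prevNode >= 1L && prevNode < M) {
          if (prev != "D") {                    # plan 7 has no D->I
            tn <- paste0(prev, "I")
            cnt[prevNode, tn] <- cnt[prevNode, tn] + 1
            prev <- "I"
          }
        }
      }
    }
  }
  tr <- cnt + pseudocount
  ## with pseudocount 0, state classes never visited have zero counts:
  ## default them to the deterministic continue-to-next-match transition
  for (cols in list(c("MM", "MI", "MD"), c("IM", "II"), c("DM", "DD"))) {
    s <- rowSums(tr[, cols, drop = FALSE])
    if (any(s == 0)) {
      tr[s == 0, cols[1L]] <- 1
      s[s == 0] <- 1
    }
    tr[, cols] <- tr[, cols, drop = FALSE] / s
  }
  tr[M, ] <- c(1, 0, 0, 1, 0, 1, 0)             # last node exits to E

  background <- background / sum(background)
  ins <- matrix(background, M, 4L, byrow = TRUE,
                dimnames = list(NULL, DNA_BASES4))
  new("ProfileHMM", name = name, rank = rank, M = M,
      matchEmissions = em, insertEmissions = ins, transitions = tr,
      background = background, matchColumns = as.integer(matchCols),
      sourceWidth = ncol(m), calibration = list())
}

#' Consensus sequence of a profile
#'
#' @param profile a [ProfileHMM-class].
#' @return character string: per match state, the base of maximal emission
#'   probability (ties broken alphabetically).
#' @export
consensusSequence <- function(profile) {
  paste(DNA_BASES4[apply(profile@matchEmissions, 1L, which.max)],
        collapse = "")
}

encodeQuery <- function(seq) {
  seq <- toupper(as.character(seq))
  if (length(seq) != 1L || nchar(seq) == 0L)
    stop("query must be a single non-empty nucleotide string")
  x <- match(strsplit(seq, "", fixed = TRUE)[[1L]],
             c(DNA_BASES4, "N")) - 1L
  if (anyNA(x))
    stop("query contains characters outside {A,C,G,T,N}")
  as.integer(x)
}

profileLogOdds <- function(profile) {
  bg <- profile@background
  lm <- log2(sweep(profile@matchEmissions, 2L, bg, "/"))
  li <- log2(sweep(profile@insertEmissions, 2L, bg, "/"))
  lm <- cbind(lm, 0)   # 5th column: N emits at background, log-odds 0
  li <- cbind(li, 0)
  lt <- log2(profile@transitions)
  list(lm = lm, li = li, lt = lt)
}

#' Forward bit score of a query against a profile
#'
#' Log2 odds of the query under the profile's local (fragment) alignment
#' model versus the background model, summed over all alignments by the
#' forward algorithm. `N` in the query emits at background (log-odds 0).
#'
#' @param profile a [ProfileHMM-class].
#' @param seq nucleotide query string over `A,C,G,T,N`.
#' @return score in bits.
#' @export
forwardBits <- function(profile, seq) {
  lo <- profileLogOdds(profile)
  forward_bits_cpp(lo$lm, lo$li, lo$lt, encodeQuery(seq))
}

#' Align a query into profile match-state coordinates
#'
#' Viterbi alignment of the query to the profile; returns the query spelled
#' out over the profile's source-alignment columns, with `-` at deleted or
#' uncovered match columns and at non-match columns (inserted query bases
#' are dropped). This is how reads are carried into the reference
#' coordinate system for per-site diversity analysis.
#'
#' @param profile a [ProfileHMM-class].
#' @param seq nucleotide query string.
#' @return character string of length `profile@sourceWidth`.
#' @export
alignToProfile <- function(profile, seq) {
  lo <- profileLogOdds(profile)
  x <- encodeQuery(seq)
  pos <- viterbi_match_path_cpp(lo$lm, lo$li, lo$lt, x)
  chars <- rep("-", profile@sourceWidth)
  emitted <- pos > 0L
  chars[profile@matchColumns[emitted]] <-
    c(DNA_BASES4, "N")[x[pos[emitted]] + 1L]
  paste(chars, collapse = "")
}

gumbelNegLogLik <- function(par, x) {
  mu <- par[1L]; beta <- exp(par[2L])
  z <- (x - mu) / beta
  length(x) * log(beta) + sum(z + exp(-z))
}

#' Calibrate a Gumbel E-value model for a profile
#'
#' Scores `nShuffles` i.i.d. background sequences of consensus length with
#' [forwardBits()] and fits a Gumbel location/rate by maximum likelihood.
#' Deterministic given `seed`; the caller's RNG state is left untouched.
#'
#' @param profile a [ProfileHMM-class].
#' @param nShuffles number of background sequences (>= 100).
#' @param seed integer seed.
#' @return an [EvalueCalibration-class].
#' @export
calibrateEvalue <- function(profile, nShuffles = 200L, seed = 1L) {
  if (nShuffles < 100L) stop("nShuffles must be >= 100")
  len <- profile@M
  xs <- withPrivateSeed(seed, {
    lapply(seq_len(nShuffles), function(i)
      sample(0:3, len, replace = TRUE, prob = profile@background))
  })
  lo <- profileLogOdds(profile)
  scores <- forward_bits_many_cpp(lo$lm, lo$li, lo$lt, xs)
  beta0 <- sd(scores) * sqrt(6) / pi
  mu0 <- mean(scores) - 0.5772156649 * beta0
  fit <- optim(c(mu0, log(beta0)), gumbelNegLogLik, x = scores,
               method = "Nelder-Mead")
  lambda <- 1 / exp(fit$par[2L])
  if (!is.finite(lambda) || lambda <= 0)
    stop("degenerate Gumbel calibration (lambda <= 0) for profile '",
         profile@name, "'")
  new("EvalueCalibration", profileName = profile@name,
      mu = fit$par[1L], lambda = lambda,
      nShuffles = as.integer(nShuffles), seed = as.integer(seed))
}

withPrivateSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' E-value of a bit score under a Gumbel calibration
#'
#' `nTargets * P(S >= s)` under the fitted Gumbel null; strictly
#' decreasing in `s`.
#'
#' @param calibration an [EvalueCalibration-class].
#' @param bitScore score in bits (vectorized).
#' @param nTargets number of profiles scanned (default 1).
#' @return numeric E-value(s).
#' @export
evalue <- function(calibration, bitScore, nTargets = 1L) {
  p <- -expm1(-exp(-calibration@lambda * (bitScore - calibration@mu)))
  nTargets * p
}

#' Attach a calibration to a profile
#'
#' @param profile a [ProfileHMM-class].
#' @param calibration an [EvalueCalibration-class] (default: compute one).
#' @param nShuffles,seed passed to [calibrateEvalue()] when `calibration`
#'   is missing.
#' @return the calibrated profile.
#' @export
calibrateProfile <- function(profile, calibration = NULL,
                             nShuffles = 200L, seed = 1L) {
  if (is.null(calibration))
    calibration <- calibrateEvalue(profile, nShuffles, seed)
  profile@calibration <- calibration
  profile
}

#' Calibrate a list of profiles
#'
#' Each profile gets its own deterministic seed derived from `seed` and its
#' position in the list.
#'
#' @param profiles list of [ProfileHMM-class] objects.
#' @param nShuffles shuffles per profile.
#' @param seed base seed.
#' @return list of calibrated profiles.
#' @export
calibrateProfiles <- function(profiles, nShuffles = 200L, seed = 1L) {
  lapply(seq_along(profiles), function(i)
    calibrateProfile(profiles[[i]], nShuffles = nShuffles,
                     seed = seed + i))
}

#' Score a query against a profile collection
#'
#' One hit per profile, sorted by bit score descending with ties broken by
#' profile name; a pure function of its inputs.
#'
#' @param seq nucleotide query string.
#' @param profiles non-empty list of calibrated [ProfileHMM-class]
#'   objects.
#' @param queryId id recorded in the output (default `"query"`).
#' @return `data.frame` with columns `query_id`, `profile_name`,
#'   `bit_score`, `evalue`.
#' @export
scanQuery <- function(seq, profiles, queryId = "query") {
  if (length(profiles) < 1L) stop("at least one profile is required")
  n <- length(profiles)
  hits <- data.frame(
    query_id = queryId,
    profile_name = vapply(profiles, profileName, character(1)),
    bit_score = vapply(profiles, forwardBits, numeric(1), seq = seq),
    stringsAsFactors = FALSE)
  hits$evalue <- vapply(seq_len(n), function(i) {
    cal <- profileCalibration(profiles[[i]])
    if (is.null(cal)) NA_real_ else evalue(cal, hits$bit_score[i], n)
  }, numeric(1))
  hits[order(-hits$bit_score, hits$profile_name), , drop = FALSE]
}

#' Scan many queries against a profile collection
#'
#' @param queries named character vector or [Biostrings::DNAStringSet].
#' @param profiles list of calibrated [ProfileHMM-class] objects.
#' @return one `data.frame` of hits, grouped by query in input order.
#' @export
scanQueries <- function(queries, profiles) {
  if (is(queries, "XStringSet"))
    queries <- setNames(as.character(queries), names(queries))
  if (length(queries) == 0L)
    return(data.frame(query_id = character(0), profile_name = character(0),
                      bit_score = numeric(0), evalue = numeric(0)))
  if (is.null(names(queries))) names(queries) <- paste0("q", seq_along(queries))
  if (length(profiles) < 1L) stop("at least one profile is required")
  xs <- lapply(queries, encodeQuery)
  n <- length(profiles)
  ## score profile-by-profile in one compiled call each
  scores <- vapply(profiles, function(p) {
    lo <- profileLogOdds(p)
    forward_bits_many_cpp(lo$lm, lo$li, lo$lt, xs)
  }, numeric(length(queries)))
  scores <- matrix(scores, nrow = length(queries))
  evs <- vapply(seq_len(n), function(i) {
    cal <- profileCalibration(profiles[[i]])
    if (is.null(cal)) rep(NA_real_, length(queries))
    else evalue(cal, scores[, i], n)
  }, numeric(length(queries)))
  evs <- matrix(evs, nrow = length(queries))
  pnames <- vapply(profiles, profileName, character(1))
  out <- lapply(seq_along(queries), function(q) {
    h <- data.frame(query_id = names(queries)[q], profile_name = pnames,
                    bit_score = scores[q, ], evalue = evs[q, ],
                    stringsAsFactors = FALSE)
    h[order(-h$bit_score, h$profile_name), , drop = FALSE]
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

## --- profile JSON serialization (versioned) ---------------------------

PROFILE_SCHEMA_VERSION <- "1.0"

profileToList <- function(p) {
  cal <- profileCalibration(p)
  list(schema = PROFILE_SCHEMA_VERSION, name = p@name, rank = p@rank,
       M = p@M,
       match_emissions = unname(apply(p@matchEmissions, 1L, c,
                                      simplify = FALSE)),
       insert_emissions = unname(apply(p@insertEmissions, 1L, c,
                                       simplify = FALSE)),
       transitions = unname(apply(p@transitions, 1L, c, simplify = FALSE)),
       background = p@background,
       match_columns = p@matchColumns, source_width = p@sourceWidth,
       calibration = if (is.null(cal)) NULL else
         list(mu = cal@mu, lambda = cal@lambda,
              n_shuffles = cal@nShuffles, seed = cal@seed))
}

profileFromList <- function(l) {
  toMat <- function(x, nc) {
    m <- do.call(rbind, lapply(x, as.numeric))
    stopifnot(ncol(m) == nc)
    m
  }
  em <- toMat(l$match_emissions, 4L); colnames(em) <- DNA_BASES4
  ins <- toMat(l$insert_emissions, 4L); colnames(ins) <- DNA_BASES4
  tr <- toMat(l$transitions, 7L); colnames(tr) <- TRANS_NAMES
  cal <- if (is.null(l$calibration)) list() else
    new("EvalueCalibration", profileName = l$name,
        mu = l$calibration$mu, lambda = l$calibration$lambda,
        nShuffles = as.integer(l$calibration$n_shuffles),
        seed = as.integer(l$calibration$seed))
  new("ProfileHMM", name = l$name, rank = l$rank, M = as.integer(l$M),
      matchEmissions = em, insertEmissions = ins, transitions = tr,
      background = as.numeric(l$background),
      matchColumns = as.integer(l$match_columns),
      sourceWidth = as.integer(l$source_width), calibration = cal)
}

#' Write profiles to a JSON-lines file
#'
#' One JSON document per line, versioned; round-trips through
#' [readProfiles()].
#'
#' @param profiles list of [ProfileHMM-class] objects.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeProfiles <- function(profiles, path) {
  lines <- vapply(profiles, function(p)
    jsonlite::toJSON(profileToList(p), auto_unbox = TRUE, digits = NA),
    character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read profiles from a JSON-lines file
#'
#' @param path path written by [writeProfiles()].
#' @return list of [ProfileHMM-class] objects.
#' @export
readProfiles <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  lapply(lines, function(ln)
    profileFromList(jsonlite::fromJSON(ln, simplifyVector = FALSE)))
}
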