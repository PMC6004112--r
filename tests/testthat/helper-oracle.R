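# Independent brute-force oracle for the local-mode forward score: sums
# path probabilities over every explicit state path (flank loops x entry
# node x core path x exit position x trailing flank) by recursive
# enumeration, divided by the geometric null. Kept free of the package's
# dynamic-programming code on purpose; only profile slot layout is
# shared. Feasible for small M and short queries.
oracleForwardBits <- function(profile, seq) {
  x <- match(strsplit(toupper(seq), "", fixed = TRUE)[[1L]],
             c("A", "C", "G", "T", "N"))
  stopifnot(!anyNA(x))
  M <- profile@M
  L <- length(x)
  bg <- profile@background
  emOdds <- cbind(sweep(profile@matchEmissions, 2L, bg, "/"), 1)
  inOdds <- cbind(sweep(profile@insertEmissions, 2L, bg, "/"), 1)
  tr <- profile@transitions
  tNN <- L / (L + 2)                 # flank self-loop (= tCC)
  tNB <- 2 / (L + 2)                 # flank exit (= tCT)
  rnull <- L / (L + 1)               # null-model continuation
  entry <- tNB * 2 / (M * (M + 1))
  total <- 0
  go <- function(state, k, i, w) {
    if (state == "M") {
      if (k > M || i > L) return(invisible(NULL))
      w <- w * emOdds[k, x[i]]
      # exit to E here (prob 1), then C loops over the trailing residues
      total <<- total + w * tNN^(L - i) * tNB
      if (k < M) {
        go("M", k + 1L, i + 1L, w * tr[k, "MM"])
        go("I", k, i + 1L, w * tr[k, "MI"])
        go("D", k + 1L, i + 1L, w * tr[k, "MD"])
      }
    } else if (state == "I") {       # I_k exists for k < M
      if (i > L) return(invisible(NULL))
      w <- w * inOdds[k, x[i]]
      go("M", k + 1L, i + 1L, w * tr[k, "IM"])
      go("I", k, i + 1L, w * tr[k, "II"])
    } else {                         # D_k, silent; dead end at k = M
      if (k < M) {
        go("M", k + 1L, i, w * tr[k, "DM"])
        go("D", k + 1L, i, w * tr[k, "DD"])
      }
    }
    invisible(NULL)
  }
  for (i0 in seq_len(L))          # i0 - 1 leading N self-loops
    for (k0 in seq_len(M))
      go("M", k0, i0, entry * tNN^(i0 - 1))
  log2(total) - L * log2(rnull) - log2(1 - rnull)
}

# Two-pass extended-precision reimplementation of the log-Bayes-factor
# arithmetic (explicit exp/sum/log), used as the naive cross-check.
naiveLnBF <- function(scores) {
  if (length(scores) == 1L) return(Inf)
  scores[1L] - log(sum(exp(scores[-1L])))
}

# Deterministic toy profile with hand-set parameters (no estimation
# involved), for oracle equivalence at tiny sizes.
toyProfile <- function(M = 2L, seed = 42L) {
  set.seed(seed)
  em <- matrix(stats::runif(4 * M), M, 4)
  em <- em / rowSums(em)
  colnames(em) <- c("A", "C", "G", "T")
  ins <- matrix(0.25, M, 4, dimnames = list(NULL, colnames(em)))
  tr <- matrix(0, M, 7, dimnames = list(NULL,
    c("MM", "MI", "MD", "IM", "II", "DM", "DD")))
  for (k in seq_len(M)) {
    a <- stats::runif(3); a <- a / sum(a)
    b <- stats::runif(2); b <- b / sum(b)
    d <- stats::runif(2); d <- d / sum(d)
    tr[k, ] <- c(a, b, d)
  }
  tr[M, ] <- c(1, 0, 0, 1, 0, 1, 0)
  new("ProfileHMM", name = "toy", rank = "order", M = M,
      matchEmissions = em, insertEmissions = ins, transitions = tr,
      background = rep(0.25, 4), matchColumns = seq_len(M),
      sourceWidth = M, calibration = list())
}
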