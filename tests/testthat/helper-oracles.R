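# Independent scoring and exhaustive decoding used to cross-check the
# beam Viterbi. Deliberately written from first principles (plain dnorm,
# explicit enumeration), not via the package's HMM internals.

oracle_score_tables <- function(cand, mu = 3.8047, sd = 0.36,
                                cutoff = c(2, 6),
                                background = rep(1 / 20, 20)) {
  n <- nrow(cand$xyz)
  E <- t(apply(cand$amino_probs, 1, function(p) {
    g <- sqrt(p * background)
    g / sum(g)
  }))
  E <- matrix(E, nrow = n)
  D <- as.matrix(stats::dist(cand$xyz))
  Tm <- matrix(-Inf, n, n)
  for (s in seq_len(n)) {
    nb <- which(D[s, ] >= cutoff[1] & D[s, ] <= cutoff[2] & seq_len(n) != s)
    if (length(nb) > 0) {
      w <- stats::dnorm(D[s, nb], mu, sd)
      Tm[s, nb] <- log(w / sum(w))
    }
  }
  list(E = E, Tm = Tm)
}

oracle_path_score <- function(tables, aa, path) {
  E <- tables$E; Tm <- tables$Tm
  pi0 <- E[, aa[1]] / sum(E[, aa[1]])
  sc <- log(pi0[path[1]]) + log(E[path[1], aa[1]])
  for (t in seq_along(aa)[-1]) {
    sc <- sc + Tm[path[t - 1], path[t]] + log(E[path[t], aa[t]])
  }
  sc
}

# Exhaustive search over all injective state sequences of length |aa|.
oracle_best_path <- function(cand, aa, ...) {
  tables <- oracle_score_tables(cand, ...)
  n <- nrow(cand$xyz)
  L <- length(aa)
  best <- list(score = -Inf, path = NULL)
  rec <- function(path, score) {
    if (length(path) == L) {
      if (score > best$score) best <<- list(score = score, path = path)
      return(invisible(NULL))
    }
    t <- length(path)
    for (s in setdiff(seq_len(n), path)) {
      step <- tables$Tm[path[t], s] + log(tables$E[s, aa[t + 1]])
      if (is.finite(step)) rec(c(path, s), score + step)
    }
  }
  pi0 <- tables$E[, aa[1]] / sum(tables$E[, aa[1]])
  for (s in seq_len(n)) {
    sc <- log(pi0[s]) + log(tables$E[s, aa[1]])
    if (is.finite(sc)) rec(s, sc)
  }
  best
}

# Percentile by explicit linear interpolation between order statistics.
oracle_percentile <- function(v, p) {
  v <- sort(v)
  h <- (length(v) - 1) * p + 1
  lo <- floor(h)
  if (lo == length(v)) return(v[lo])
  v[lo] + (h - lo) * (v[lo + 1] - v[lo])
}
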