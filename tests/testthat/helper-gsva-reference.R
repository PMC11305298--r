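# Independent reference implementation of the gene set variation analysis
# statistic, written as plain loops from the published description. It is
# deliberately structured differently from the package implementation
# (scalar running sums instead of vectorized cumulative sums) so the two
# can only agree by computing the same statistic.
gsva_reference <- function(X, sets, bw_factor = 4, tau = 1) {
  p <- nrow(X)
  n <- ncol(X)

  # step 1: Gaussian-kernel CDF estimate per gene across samples
  Z <- matrix(NA_real_, p, n, dimnames = dimnames(X))
  for (i in seq_len(p)) {
    s <- stats::sd(X[i, ])
    if (s == 0) {
      for (j in seq_len(n)) Z[i, j] <- 0.5
    } else {
      h <- s / bw_factor
      for (j in seq_len(n)) {
        acc <- 0
        for (l in seq_len(n)) acc <- acc + stats::pnorm((X[i, j] - X[i, l]) / h)
        Z[i, j] <- acc / n
      }
    }
  }

  out <- matrix(NA_real_, length(sets), n,
                dimnames = list(names(sets), colnames(X)))
  for (j in seq_len(n)) {
    # step 2: decreasing rank order, symmetric weight about the middle
    o <- order(Z[, j], decreasing = TRUE)
    for (s in seq_along(sets)) {
      members <- which(rownames(X) %in% sets[[s]])
      K <- length(members)
      wsum <- 0
      for (pos in seq_len(p)) {
        if (o[pos] %in% members) wsum <- wsum + abs(pos - p / 2)^tau
      }
      # step 3: weighted KS-like walk; step 4: max deviation score
      running <- 0
      best_pos <- 0
      best_neg <- 0
      for (pos in seq_len(p)) {
        if (o[pos] %in% members) {
          running <- running + abs(pos - p / 2)^tau / wsum
        } else {
          running <- running - 1 / (p - K)
        }
        if (running > best_pos) best_pos <- running
        if (running < best_neg) best_neg <- running
      }
      out[s, j] <- best_pos + best_neg
    }
  }
  out
}

# random matrix + random collection used by the equivalence checks
random_gsva_case <- function(p = 50, n = 12, n_sets = 5) {
  X <- matrix(stats::rnorm(p * n), p, n,
              dimnames = list(sprintf("g%03d", seq_len(p)),
                              sprintf("s%02d", seq_len(n))))
  sets <- lapply(seq_len(n_sets), function(i) {
    sample(rownames(X), sample(5:min(15, p - 2), 1))
  })
  names(sets) <- sprintf("set%02d", seq_len(n_sets))
  list(X = X, sets = sets)
}
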