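#' Sample-level gene-set variation scores
#'
#' Computes per-set, per-sample enrichment scores following the gene set
#' variation analysis statistic: (1) each gene's expression is transformed
#' to a Gaussian-kernel cumulative density estimate across samples with
#' bandwidth `sd / bw_factor`; (2) within each sample the transformed
#' values are ranked decreasingly and symmetrized about the middle of the
#' list (`|position - p/2|`); (3) a weighted Kolmogorov-Smirnov-like
#' running sum walks down the ranked list with weight exponent `tau`;
#' (4) the score is the largest positive deviation plus the largest
#' negative deviation of the running sum, giving values in \[-1, 1\].
#'
#' Genes with zero variance contribute a flat density estimate (0.5).
#'
#' @param expr expression matrix or data frame (log2; >= 3 samples).
#' @param collection named list of feature-id vectors; each set is
#'   intersected with the matrix features and must be a strict subset of
#'   them.
#' @param bw_factor kernel bandwidth divisor (bandwidth = per-gene
#'   sd / `bw_factor`).
#' @param tau rank-weight exponent of the running sum.
#' @return a `gsva_scores` object: numeric matrix (sets x samples) with a
#'   `params` attribute.
#' @export
gsva_scores <- function(expr, collection, bw_factor = 4, tau = 1) {
  X <- as_expression_matrix(expr)
  p <- nrow(X)
  n <- ncol(X)
  if (n < 3) stop_insufficient("gene set variation scoring needs at least 3 samples")

  collection <- purrr::map(collection, function(m) intersect(unique(m), rownames(X)))
  empty <- lengths(collection) == 0
  if (any(empty)) {
    warn(paste0(sum(empty), " gene set(s) with no features on the matrix dropped"))
    collection <- collection[!empty]
  }
  if (!length(collection)) stop_insufficient("no usable gene sets")
  if (any(lengths(collection) >= p)) {
    stop_validation("a gene set equal to the whole feature universe is degenerate")
  }

  # (1) kernel-smoothed cumulative density per gene across samples
  Z <- matrix(0, p, n, dimnames = dimnames(X))
  sds <- apply(X, 1, stats::sd)
  for (i in seq_len(p)) {
    xi <- X[i, ]
    if (sds[i] == 0) {
      Z[i, ] <- 0.5
    } else {
      h <- sds[i] / bw_factor
      Z[i, ] <- rowMeans(stats::pnorm(outer(xi, xi, "-") / h))
    }
  }

  # (2) decreasing rank order and symmetric rank weights per sample
  ord <- apply(Z, 2, order, decreasing = TRUE)   # p x n, gene index by position
  w_pos <- abs(seq_len(p) - p / 2)               # weight at each position

  set_idx <- purrr::map(collection, function(m) match(m, rownames(X)))
  scores <- matrix(NA_real_, length(collection), n,
                   dimnames = list(names(collection), colnames(X)))

  for (j in seq_len(n)) {
    genes_sorted <- ord[, j]
    wj <- w_pos^tau
    for (s in seq_along(set_idx)) {
      inset <- genes_sorted %in% set_idx[[s]]
      K <- sum(inset)
      num <- cumsum(ifelse(inset, wj, 0)) / sum(wj[inset])
      den <- cumsum(!inset) / (p - K)
      v <- num - den
      scores[s, j] <- max(c(0, v)) + min(c(0, v))
    }
  }
  structure(scores, class = c("gsva_scores", class(scores)),
            params = list(bw_factor = bw_factor, tau = tau,
                          score_mode = "max_pos_plus_max_neg"))
}

#' @export
tidy.gsva_scores <- function(x, ...) {
  m <- unclass(x)
  attr(m, "params") <- NULL
  as_tibble(m, rownames = "set_name") %>%
    tidyr::pivot_longer(-"set_name", names_to = "sample_id", values_to = "score")
}

#' Paired lesional vs nonlesional contrast of gene-set scores
#'
#' For each gene set, a paired t-test on the per-patient difference of
#' scores between the week-0 lesional and nonlesional biopsies, with
#' Benjamini-Hochberg adjustment across sets. Zero-variance conventions
#' follow [paired_lesional_de()].
#'
#' @param scores a [gsva_scores()] matrix (sets x samples).
#' @param annot sample annotation covering the scored samples.
#' @return tibble per set: `set_name`, `n_pairs`, `delta` (LS - NL),
#'   `t_statistic`, `p_value`, `q_value`.
#' @export
gsva_differential <- function(scores, annot) {
  annot <- validate_annotation(annot)
  pairs <- baseline_pairs(annot)
  pairs <- pairs[pairs$ls_sample %in% colnames(scores) &
                   pairs$nl_sample %in% colnames(scores), ]
  if (nrow(pairs) < 2) stop_insufficient("need at least 2 scored LS/NL pairs")
  m <- unclass(scores)
  diffs <- m[, pairs$ls_sample, drop = FALSE] - m[, pairs$nl_sample, drop = FALSE]
  st <- row_paired_t(diffs)
  tibble(
    set_name = rownames(scores),
    n_pairs = st$n_pairs,
    delta = st$mean_delta,
    t_statistic = st$t_statistic,
    p_value = st$p_value,
    q_value = bh_adjust(st$p_value)
  )
}
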