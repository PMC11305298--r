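#' Simulate gene-set collections overlapping a planted signature
#'
#' Draws `n_sets` gene sets from a feature universe. Each set takes a
#' fraction `enriched_fraction` of its members from the planted signature
#' (rounded to the nearest count) and the remainder uniformly from the
#' non-signature features, so `enriched_fraction = 0` yields null sets and
#' `enriched_fraction = 1` yields sets fully contained in the signature.
#'
#' @param truth the `truth` component of [simulate_expression_cohort()]
#'   output (or any list with a `signature_features` character vector).
#' @param universe character vector of all feature ids.
#' @param n_sets number of sets to draw.
#' @param set_size_range integer length-2 vector, inclusive bounds on set
#'   size (sizes drawn uniformly).
#' @param enriched_fraction fraction in \[0, 1\] of each set drawn from the
#'   signature.
#' @param seed integer seed.
#' @return named list of character vectors (a gene-set collection).
#' @export
simulate_gene_sets <- function(truth, universe, n_sets = 50,
                               set_size_range = c(10, 50),
                               enriched_fraction = 0.5, seed = 1L) {
  set.seed(as.integer(seed))
  sig <- intersect(truth$signature_features, universe)
  bg <- setdiff(universe, sig)
  if (max(set_size_range) > length(universe)) {
    stop_validation("set size exceeds the feature universe")
  }
  if (enriched_fraction < 0 || enriched_fraction > 1) {
    stop_validation("enriched_fraction must be in [0, 1]")
  }
  sizes <- if (set_size_range[1] == set_size_range[2]) {
    rep(set_size_range[1], n_sets)
  } else {
    sample(seq(set_size_range[1], set_size_range[2]), n_sets, replace = TRUE)
  }
  sets <- purrr::map(seq_len(n_sets), function(i) {
    k_sig <- min(round(enriched_fraction * sizes[i]), length(sig))
    k_bg <- sizes[i] - k_sig
    if (k_bg > length(bg)) stop_validation("not enough background features for requested set size")
    c(if (k_sig > 0) sample(sig, k_sig) else character(),
      if (k_bg > 0) sample(bg, k_bg) else character())
  })
  names(sets) <- sprintf("GS%03d", seq_len(n_sets))
  sets
}
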