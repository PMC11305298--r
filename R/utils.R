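#' @importFrom rlang abort warn .data := %||%
#' @importFrom tibble tibble as_tibble
#' @importFrom dplyr %>%
NULL

# error helpers: all user-facing failures carry a psopd_error_* class so
# callers (and tests) can distinguish validation from insufficient data
stop_validation <- function(msg) {
  abort(msg, class = c("psopd_error_validation", "psopd_error"))
}

stop_insufficient <- function(msg) {
  abort(msg, class = c("psopd_error_insufficient_data", "psopd_error"))
}

ARM_LEVELS <- c("GUS", "ADA", "PBO_GUS", "HC")
TISSUE_LEVELS <- c("LS", "NL")

#' Coerce expression input to a numeric feature-by-sample matrix
#'
#' Accepts either a numeric matrix with feature ids as rownames and sample
#' ids as colnames, or a data frame whose first column holds feature ids
#' and remaining columns hold one sample each.
#'
#' @param expr matrix or data frame of log2 expression values.
#' @return numeric matrix (features x samples).
#' @keywords internal
as_expression_matrix <- function(expr) {
  if (is.matrix(expr)) {
    X <- expr
  } else if (is.data.frame(expr)) {
    ids <- as.character(expr[[1]])
    X <- as.matrix(expr[, -1, drop = FALSE])
    rownames(X) <- ids
  } else {
    stop_validation("`expr` must be a matrix or a data frame with feature ids in the first column")
  }
  if (!is.numeric(X)) stop_validation("expression values must be numeric")
  if (is.null(rownames(X)) || is.null(colnames(X))) {
    stop_validation("expression matrix needs feature ids as rownames and sample ids as colnames")
  }
  if (anyDuplicated(rownames(X))) {
    dup <- rownames(X)[duplicated(rownames(X))][1]
    stop_validation(paste0("duplicate feature id: ", dup))
  }
  if (anyDuplicated(colnames(X))) {
    dup <- colnames(X)[duplicated(colnames(X))][1]
    stop_validation(paste0("duplicate sample id: ", dup))
  }
  if (!all(is.finite(X))) stop_validation("expression matrix contains non-finite values")
  X
}

#' Validate a sample annotation table
#'
#' Enforces the biopsy-design invariants: required columns, known arm and
#' tissue labels, nonlesional biopsies only at week 0, at most one sample
#' per (patient, tissue, week) slot, and PASI within its 0-72 range.
#'
#' @param annot data frame with columns `sample_id`, `patient_id`, `arm`,
#'   `week`, `tissue`, `pasi` (and optionally `pasi100`).
#' @return the validated annotation as a tibble, with `pasi100` filled in
#'   as `FALSE` when absent.
#' @export
validate_annotation <- function(annot) {
  required <- c("sample_id", "patient_id", "arm", "week", "tissue", "pasi")
  missing <- setdiff(required, names(annot))
  if (length(missing)) {
    stop_validation(paste0("annotation is missing column(s): ", paste(missing, collapse = ", ")))
  }
  annot <- as_tibble(annot)
  if (!all(annot$arm %in% ARM_LEVELS)) {
    bad <- unique(annot$arm[!annot$arm %in% ARM_LEVELS])
    stop_validation(paste0("unknown arm label(s): ", paste(bad, collapse = ", ")))
  }
  if (!all(annot$tissue %in% TISSUE_LEVELS)) {
    bad <- unique(annot$tissue[!annot$tissue %in% TISSUE_LEVELS])
    stop_validation(paste0("unknown tissue label(s): ", paste(bad, collapse = ", ")))
  }
  if (any(annot$tissue == "NL" & annot$week != 0)) {
    bad <- annot$sample_id[annot$tissue == "NL" & annot$week != 0]
    stop_validation(paste0("nonlesional biopsies are only collected at week 0; offending sample(s): ",
                           paste(bad, collapse = ", ")))
  }
  key <- paste(annot$patient_id, annot$tissue, annot$week)
  if (anyDuplicated(key)) {
    dup_key <- key[duplicated(key)][1]
    ids <- annot$sample_id[key == dup_key]
    stop_validation(paste0("duplicate biopsy slot (patient/tissue/week); offending samples: ",
                           paste(ids, collapse = ", ")))
  }
  ok_pasi <- is.na(annot$pasi) | (annot$pasi >= 0 & annot$pasi <= 72)
  if (!all(ok_pasi)) stop_validation("`pasi` must lie in [0, 72]")
  if (is.null(annot[["pasi100"]])) annot$pasi100 <- FALSE
  annot
}

#' Signed linear fold change from a log2 difference
#'
#' Uses the signed-fold convention common in dermatology transcriptomics
#' tables: a log2 difference of -1 is reported as -2 (halving) rather than
#' 0.5, and a difference of 0 maps to +1.
#'
#' @param log2_delta numeric vector of log2 differences.
#' @return numeric vector of signed linear fold changes.
#' @export
#' @examples
#' signed_fold(c(-1, 0, 1, 2))
signed_fold <- function(log2_delta) {
  ifelse(log2_delta >= 0, 2^log2_delta, -(2^(-log2_delta)))
}

# vectorised paired t statistics on a features x pairs matrix of differences.
# zero-variance conventions: all-zero differences -> t = 0, p = 1;
# identical nonzero differences -> p = 0 with degenerate flag.
row_paired_t <- function(delta) {
  if (is.null(dim(delta))) delta <- matrix(delta, nrow = 1)
  n <- ncol(delta)
  if (n < 2) stop_insufficient("paired t needs at least 2 complete pairs")
  m <- rowMeans(delta)
  ss <- rowSums((delta - m)^2)
  se <- sqrt(ss / (n - 1)) / sqrt(n)
  zero_var <- se == 0
  t_raw <- m / ifelse(zero_var, NA_real_, se)
  t_stat <- ifelse(zero_var, ifelse(m == 0, 0, sign(m) * Inf), t_raw)
  p <- ifelse(zero_var, ifelse(m == 0, 1, 0),
              2 * stats::pt(-abs(t_raw), df = n - 1))
  tibble(
    n_pairs = n,
    mean_delta = unname(m),
    t_statistic = unname(t_stat),
    p_value = unname(p),
    degenerate = unname(zero_var & m != 0)
  )
}

# match a set of samples' columns in X, preserving order
expr_cols <- function(X, sample_ids) {
  idx <- match(sample_ids, colnames(X))
  if (anyNA(idx)) {
    stop_validation(paste0("sample(s) absent from expression matrix: ",
                           paste(sample_ids[is.na(idx)], collapse = ", ")))
  }
  X[, idx, drop = FALSE]
}

# week-0 LS/NL complete pairs for a set of patients; returns tibble with
# patient_id, ls_sample, nl_sample
baseline_pairs <- function(annot, patients = NULL) {
  base <- annot[annot$week == 0, , drop = FALSE]
  if (!is.null(patients)) base <- base[base$patient_id %in% patients, , drop = FALSE]
  ls <- base[base$tissue == "LS", c("patient_id", "sample_id")]
  nl <- base[base$tissue == "NL", c("patient_id", "sample_id")]
  names(ls)[2] <- "ls_sample"
  names(nl)[2] <- "nl_sample"
  dplyr::inner_join(ls, nl, by = "patient_id")
}
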