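#' Read a log2 expression matrix from TSV
#'
#' Expects a tab-separated file whose first column holds unique feature
#' ids and whose header row holds sample ids. With `linear_scale = TRUE`
#' values are assumed linear (all positive) and are log2-transformed on
#' ingest.
#'
#' @param path TSV file path.
#' @param linear_scale transform linear-scale intensities to log2.
#' @return numeric matrix (features x samples).
#' @export
read_expression_matrix <- function(path, linear_scale = FALSE) {
  header <- strsplit(readLines(path, n = 1), "\t", fixed = TRUE)[[1]]
  if (length(header) < 2) stop_validation("expression TSV needs an id column and at least one sample")
  ct <- readr::cols(.default = readr::col_double())
  ct$cols[[header[1]]] <- readr::col_character()
  # parse issues surface as a classed validation error below, not warnings
  df <- suppressWarnings(readr::read_tsv(path, col_types = ct, progress = FALSE))
  probs <- readr::problems(df)
  if (nrow(probs)) {
    stop_validation(paste0("malformed expression TSV at line ", probs$row[1],
                           ": ", probs$expected[1]))
  }
  X <- as_expression_matrix(df)
  if (linear_scale) {
    if (any(X <= 0)) stop_validation("linear-scale values must be positive for log2 transform")
    X <- log2(X)
  }
  X
}

#' Write an expression matrix to TSV
#'
#' @param expr matrix or data frame (see [as_expression_matrix()]).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_expression_matrix <- function(expr, path) {
  X <- as_expression_matrix(expr)
  df <- dplyr::bind_cols(tibble(feature_id = rownames(X)),
                         as_tibble(as.data.frame(X)))
  readr::write_tsv(df, path)
  invisible(path)
}

#' Read and validate a sample annotation TSV
#'
#' @param path TSV with columns `sample_id`, `patient_id`, `arm`, `week`,
#'   `tissue`, `pasi` and optionally `pasi100`, `pasi_improvement`.
#' @return validated annotation tibble.
#' @export
read_sample_annotation <- function(path) {
  df <- readr::read_tsv(path, col_types = readr::cols(), progress = FALSE)
  if ("pasi100" %in% names(df)) df$pasi100 <- as.logical(df$pasi100)
  validate_annotation(df)
}

#' @rdname read_sample_annotation
#' @param annot annotation tibble to write.
#' @export
write_sample_annotation <- function(annot, path) {
  readr::write_tsv(validate_annotation(annot), path)
  invisible(path)
}

#' Read a long-format serum panel TSV
#'
#' @param path TSV with columns `subject_id`, `group`, `week`, `analyte`,
#'   `concentration` and optionally `below_lloq`, `lloq`.
#' @return serum tibble.
#' @export
read_serum_panel <- function(path) {
  df <- readr::read_tsv(path, col_types = readr::cols(), progress = FALSE)
  if ("below_lloq" %in% names(df)) df$below_lloq <- as.logical(df$below_lloq)
  serum_checks(df)
}

#' @rdname read_serum_panel
#' @param panel serum tibble to write.
#' @export
write_serum_panel <- function(panel, path) {
  readr::write_tsv(serum_checks(panel), path)
  invisible(path)
}

#' Read a raw qPCR Ct table TSV
#'
#' @param path TSV with columns `gene`, `sample_id`, `replicate`, `ct`
#'   (annotation columns such as `patient_id`, `arm`, `week`, `tissue` are
#'   carried through).
#' @return Ct tibble.
#' @export
read_qpcr_table <- function(path) {
  df <- readr::read_tsv(path, col_types = readr::cols(), progress = FALSE)
  need <- c("gene", "sample_id", "replicate", "ct")
  missing <- setdiff(need, names(df))
  if (length(missing)) {
    stop_validation(paste0("qPCR table missing column(s): ", paste(missing, collapse = ", ")))
  }
  df
}

#' @rdname read_qpcr_table
#' @param ct_table Ct tibble to write.
#' @export
write_qpcr_table <- function(ct_table, path) {
  readr::write_tsv(ct_table, path)
  invisible(path)
}
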