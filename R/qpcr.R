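#' Delta-Ct normalization of a raw qPCR table
#'
#' Normalizes each gene's cycle threshold against a reference gene
#' measured in the same sample: `delta_ct = ct - reference_ct` and
#' `log2 normalized expression = -delta_ct`. Technical replicates are
#' aggregated by the median (configurable to the mean); undetermined
#' (missing) Ct values are dropped before aggregation. Samples lacking
#' the reference gene are removed with a warning, and genes missing in
#' more than half of the samples are flagged.
#'
#' @param ct_table tibble with columns `gene`, `sample_id`, `replicate`,
#'   `ct` (extra annotation columns are carried through).
#' @param reference_gene normalizer gene name (default beta-actin).
#' @param aggregate replicate aggregation, `"median"` or `"mean"`.
#' @return tibble per (gene, sample): `gene`, `sample_id`, carried
#'   annotation, `ct`, `reference_ct`, `delta_ct`, `log2_expression`;
#'   genes failing the missingness check are listed in the
#'   `flagged_genes` attribute.
#' @export
normalize_delta_ct <- function(ct_table, reference_gene = "ACTB",
                               aggregate = c("median", "mean")) {
  aggregate <- match.arg(aggregate)
  agg <- if (aggregate == "median") stats::median else mean
  need <- c("gene", "sample_id", "replicate", "ct")
  missing <- setdiff(need, names(ct_table))
  if (length(missing)) {
    stop_validation(paste0("ct table missing column(s): ", paste(missing, collapse = ", ")))
  }
  ct_table <- as_tibble(ct_table)
  extra <- setdiff(names(ct_table), c(need))

  per <- ct_table %>%
    dplyr::group_by(dplyr::across(dplyr::all_of(c("gene", "sample_id", extra)))) %>%
    dplyr::summarise(ct = if (all(is.na(.data$ct))) NA_real_ else
      agg(.data$ct[!is.na(.data$ct)]), .groups = "drop")

  ref <- per[per$gene == reference_gene & !is.na(per$ct),
             c("sample_id", "ct")]
  names(ref)[2] <- "reference_ct"
  no_ref <- setdiff(unique(per$sample_id), ref$sample_id)
  if (length(no_ref)) {
    warn(paste0("dropping ", length(no_ref),
                " sample(s) without reference gene ", reference_gene, ": ",
                paste(utils::head(no_ref, 5), collapse = ", ")))
  }
  res <- per[per$gene != reference_gene & per$sample_id %in% ref$sample_id, ] %>%
    dplyr::left_join(ref, by = "sample_id") %>%
    dplyr::mutate(delta_ct = .data$ct - .data$reference_ct,
                  log2_expression = -.data$delta_ct)

  miss_rate <- res %>%
    dplyr::group_by(.data$gene) %>%
    dplyr::summarise(rate = mean(is.na(.data$ct)), .groups = "drop")
  flagged <- miss_rate$gene[miss_rate$rate > 0.5]
  if (length(flagged)) {
    warn(paste0("gene(s) missing in >50% of samples: ", paste(flagged, collapse = ", ")))
  }
  attr(res, "flagged_genes") <- flagged
  res
}

#' Signed, capped fold change from a mean log2 ratio
#'
#' Converts a mean log2 ratio to the signed-fold convention (-2 means
#' halving, +1 means no change) and caps extreme values at `cap` (the
#' published tables cap at +/-1000).
#'
#' @param mean_log2_ratio numeric vector of log2 ratios.
#' @param cap absolute cap on the linear fold change.
#' @return tibble: `log2_ratio`, `fold_change`, `capped`.
#' @export
#' @examples
#' signed_fold_change(c(1, -1, -11))
signed_fold_change <- function(mean_log2_ratio, cap = 1000) {
  if (any(!is.finite(mean_log2_ratio))) stop_validation("log2 ratios must be finite")
  fc <- signed_fold(mean_log2_ratio)
  capped <- abs(fc) > cap
  fc[capped] <- sign(fc[capped]) * cap
  tibble(log2_ratio = mean_log2_ratio, fold_change = fc, capped = capped)
}

#' Fold-change contrasts from a normalized qPCR table
#'
#' Computes, per gene, (a) the baseline lesional vs nonlesional signed
#' fold change across week-0 pairs and (b) the per-arm, per-week lesional
#' fold change versus baseline, from the mean difference of log2
#' normalized expression (equivalently the negative mean delta-delta-Ct).
#' Requires the annotation columns `patient_id`, `arm`, `week`, `tissue`
#' on the normalized table (carried through [normalize_delta_ct()]).
#'
#' @param norm_table output of [normalize_delta_ct()] with annotation
#'   columns.
#' @param cap fold-change cap, see [signed_fold_change()].
#' @return tibble: `gene`, `comparison`, `arm`, `week`, `n`,
#'   `mean_log2_ratio`, `fold_change`, `capped`.
#' @export
qpcr_fold_changes <- function(norm_table, cap = 1000) {
  need <- c("gene", "sample_id", "patient_id", "arm", "week", "tissue",
            "log2_expression")
  missing <- setdiff(need, names(norm_table))
  if (length(missing)) {
    stop_validation(paste0("normalized table missing column(s): ",
                           paste(missing, collapse = ", ")))
  }
  tab <- norm_table[!is.na(norm_table$log2_expression), ]
  rows <- list()

  # baseline LS vs NL, paired within patient
  b <- tab[tab$week == 0, ]
  wide <- tidyr::pivot_wider(b[, c("gene", "patient_id", "tissue", "log2_expression")],
                             names_from = "tissue", values_from = "log2_expression")
  if (all(c("LS", "NL") %in% names(wide))) {
    wide <- wide[stats::complete.cases(wide), ]
    base <- wide %>%
      dplyr::group_by(.data$gene) %>%
      dplyr::summarise(mean_log2_ratio = mean(.data$LS - .data$NL),
                       n = dplyr::n(), .groups = "drop")
    fc <- signed_fold_change(base$mean_log2_ratio, cap)
    rows[[1]] <- dplyr::bind_cols(
      base[, c("gene", "n")],
      tibble(comparison = "LS vs NL (baseline)", arm = NA_character_,
             week = 0, mean_log2_ratio = base$mean_log2_ratio,
             fold_change = fc$fold_change, capped = fc$capped))
  }

  # per arm/week LS vs baseline LS, paired within patient
  ls <- tab[tab$tissue == "LS", ]
  ls0 <- ls[ls$week == 0, c("gene", "patient_id", "log2_expression")]
  names(ls0)[3] <- "baseline"
  lst <- ls[ls$week > 0, ]
  if (nrow(lst)) {
    joined <- dplyr::inner_join(lst, ls0, by = c("gene", "patient_id"))
    per <- joined %>%
      dplyr::group_by(.data$gene, .data$arm, .data$week) %>%
      dplyr::summarise(mean_log2_ratio = mean(.data$log2_expression - .data$baseline),
                       n = dplyr::n(), .groups = "drop")
    fc <- signed_fold_change(per$mean_log2_ratio, cap)
    rows[[length(rows) + 1]] <- dplyr::bind_cols(
      per[, c("gene", "n", "arm", "week", "mean_log2_ratio")],
      tibble(comparison = "LS vs baseline",
             fold_change = fc$fold_change, capped = fc$capped))
  }
  dplyr::bind_rows(rows) %>%
    dplyr::select("gene", "comparison", "arm", "week", "n",
                  "mean_log2_ratio", "fold_change", "capped")
}
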