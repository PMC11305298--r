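#' Read a gene-set collection from a GMT file
#'
#' Standard tab-separated GMT: set name, description, then one member per
#' field. Duplicate members within a set are removed with a warning; sets
#' with no members are skipped with a warning; duplicate set names are an
#' error.
#'
#' @param path GMT file path.
#' @return named list of character vectors; per-set descriptions in the
#'   `descriptions` attribute.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  names_v <- vapply(fields, `[[`, character(1), 1)
  if (anyDuplicated(names_v)) {
    stop_validation(paste0("duplicate gene-set name: ",
                           names_v[duplicated(names_v)][1]))
  }
  sets <- list()
  descs <- character()
  for (f in fields) {
    nm <- f[[1]]
    members <- f[-(1:2)]
    members <- members[nzchar(members)]
    if (!length(members)) {
      warn(paste0("gene set '", nm, "' has no members; skipped"))
      next
    }
    if (anyDuplicated(members)) {
      warn(paste0("gene set '", nm, "' has duplicate members; de-duplicated"))
      members <- unique(members)
    }
    sets[[nm]] <- members
    descs[nm] <- if (length(f) >= 2) f[[2]] else ""
  }
  attr(sets, "descriptions") <- descs
  sets
}

#' Write a gene-set collection to a GMT file
#'
#' @param sets named list of character vectors.
#' @param path output path.
#' @param descriptions optional named character vector of descriptions.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  if (is.null(names(sets)) || any(!nzchar(names(sets)))) {
    stop_validation("all gene sets must be named")
  }
  descriptions <- descriptions %||% attr(sets, "descriptions") %||%
    stats::setNames(rep("", length(sets)), names(sets))
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, descriptions[[nm]] %||% "", sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Hypergeometric over-representation of a query in gene sets
#'
#' For each set, tests whether the query (e.g. the disease signature) is
#' over-represented using the upper-tail hypergeometric probability
#' P\[X >= k\], where k is the overlap, with the set intersected with the
#' universe first. Benjamini-Hochberg q-values are computed across the
#' collection.
#'
#' @param query character vector of query features; must be a subset of
#'   `universe`.
#' @param collection named list of character vectors.
#' @param universe character vector of all testable features (typically
#'   the features on the expression matrix).
#' @return tibble per set: `set_name`, `universe_size`, `set_size`,
#'   `query_size`, `overlap`, `fraction_of_set`, `p_value`, `q_value`.
#' @export
#' @examples
#' hypergeometric_enrichment(c("a", "b"), list(s = c("a", "b", "c")),
#'                           letters[1:6])
hypergeometric_enrichment <- function(query, collection, universe) {
  universe <- unique(universe)
  if (!length(universe)) stop_validation("empty universe")
  query <- unique(query)
  if (!all(query %in% universe)) {
    stop_validation("query contains features outside the universe")
  }
  N <- length(universe)
  n <- length(query)
  rows <- purrr::imap(collection, function(members, nm) {
    set_u <- intersect(unique(members), universe)
    K <- length(set_u)
    k <- length(intersect(set_u, query))
    p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    tibble(set_name = nm, universe_size = N, set_size = K, query_size = n,
           overlap = k,
           fraction_of_set = if (K > 0) k / K else NA_real_,
           p_value = p)
  })
  res <- dplyr::bind_rows(rows)
  res$q_value <- bh_adjust(res$p_value)
  res
}

#' Filter enrichment records by the published pathway-selection rule
#'
#' Keeps sets with enrichment p strictly below `p_max`, more than
#' `min_query_fraction` of the set's genes in the query, and strictly more
#' than `min_overlap` overlapping genes.
#'
#' @param records output of [hypergeometric_enrichment()].
#' @param p_max enrichment p-value ceiling (exclusive).
#' @param min_query_fraction minimum fraction of the set covered by the
#'   query (exclusive).
#' @param min_overlap minimum overlap count (exclusive).
#' @return filtered tibble.
#' @export
select_enriched <- function(records, p_max = 0.01, min_query_fraction = 0.20,
                            min_overlap = 5) {
  records[records$p_value < p_max &
            !is.na(records$fraction_of_set) &
            records$fraction_of_set > min_query_fraction &
            records$overlap > min_overlap, , drop = FALSE]
}

#' Aggregate percent improvement over gene sets
#'
#' For each set (and each arm/week present in the records), the mean and
#' standard error (sd / sqrt(n)) of the percent improvement over the
#' stable signature genes belonging to the set. A set represented by a
#' single gene reports SE 0 with `single_gene = TRUE`.
#'
#' @param records output of [gene_improvement()].
#' @param sets a named list of character vectors, or a single character
#'   vector of feature ids.
#' @return tibble per (set, arm, week): `set_name`, `arm`, `week`,
#'   `mean_pi`, `se_pi`, `n_genes`, `single_gene`.
#' @export
set_improvement <- function(records, sets) {
  single <- is.character(sets) && is.null(names(sets))
  if (single) sets <- list(set = sets)
  stable <- records[!records$unstable & !is.na(records$pi_percent), , drop = FALSE]
  out <- purrr::imap(sets, function(members, nm) {
    hits <- stable[stable$feature_id %in% members, , drop = FALSE]
    if (!nrow(hits)) return(NULL)
    hits %>%
      dplyr::group_by(.data$arm, .data$week) %>%
      dplyr::summarise(
        mean_pi = mean(.data$pi_percent),
        se_pi = if (dplyr::n() > 1) stats::sd(.data$pi_percent) / sqrt(dplyr::n()) else 0,
        n_genes = dplyr::n(),
        single_gene = dplyr::n() == 1,
        .groups = "drop") %>%
      dplyr::mutate(set_name = nm, .before = 1)
  })
  empty <- vapply(out, is.null, logical(1))
  if (all(empty)) {
    stop_insufficient("no set intersects the stable signature genes")
  }
  if (any(empty)) {
    if (single) stop_insufficient("the set does not intersect the stable signature genes")
    warn(paste0(sum(empty), " set(s) with empty stable-signature intersection dropped"))
  }
  dplyr::bind_rows(out[!empty])
}
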