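#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a PERMANOVA result
#'
#' @param x A [permanova()] result.
#' @param ... Unused.
#' @return One row per term: `term`, `df`, `SumOfSqs`, `R2`, `F`, `p`.
#' @method tidy permanova
#' @export
tidy.permanova <- function(x, ...) x$table

#' @rdname tidy.permanova
#' @method glance permanova
#' @export
glance.permanova <- function(x, ...) {
  tot <- x$table[x$table$term == "Total", ]
  tibble::tibble(
    n_samples = x$n_samples,
    total_ss = tot$SumOfSqs,
    n_permutations = x$n_permutations,
    n_terms = sum(!x$table$term %in% c("Residual", "Total"))
  )
}

#' Tidy per-feature mixed-model results
#'
#' @param x A [fit_feature_lmm()] result.
#' @param ... Unused.
#' @return `tidy()` gives one row per feature (`feature`, `diet_F`,
#'   `diet_df`, `diet_p`, `q`, `note`); `glance()` a one-row summary.
#' @export
tidy.feature_lmm <- function(x, ...) x$stats

#' @rdname tidy.feature_lmm
#' @method glance feature_lmm
#' @export
glance.feature_lmm <- function(x, ...) {
  tibble::tibble(
    n_features = nrow(x$stats),
    n_significant = sum(x$stats$q <= 0.05, na.rm = TRUE),
    n_flagged = sum(!is.na(x$stats$note))
  )
}

#' Tidy a Ward clustering
#'
#' @param x A [ward_cluster()] result.
#' @param ... Unused.
#' @return Tibble of merge steps with heights and member indices (negative
#'   values are leaves, positive earlier merges, `hclust` convention).
#' @method tidy ward_clustering
#' @export
tidy.ward_clustering <- function(x, ...) {
  m <- x$hclust$merge
  tibble::tibble(
    step = seq_len(nrow(m)), left = m[, 1], right = m[, 2],
    height = x$hclust$height
  )
}
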