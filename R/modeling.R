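#' Per-feature linear mixed-effects models
#'
#' Fits, for every feature, `value ~ group * diet + (1 | mouse)` by REML with
#' sum-to-zero contrasts, tests the diet factor with a Type-III F-test using
#' Satterthwaite degrees of freedom, and computes per-diet marginal means
#' (averaged over groups with equal weights) with Wald 95% confidence
#' intervals. Diet p-values are Benjamini-Hochberg adjusted across features.
#'
#' Features with zero variance return a flagged null row. If the design is
#' singular in the sense that some diet is observed in only one group, the
#' interaction cannot be estimated; the model degrades to
#' `value ~ diet + (1 | mouse)` and the row is flagged.
#'
#' @param values Long tibble with `feature`, `sample_id`, `value`.
#' @param metadata Tibble with `sample_id`, `mouse_id`, `group`, `diet`.
#' @return Object of class `feature_lmm`: list with `stats` (tibble:
#'   `feature`, `diet_F`, `diet_df`, `diet_p`, `q`, `note`) and `emmeans`
#'   (tibble: `feature`, `diet`, `emmean`, `lower`, `upper`).
#' @export
fit_feature_lmm <- function(values, metadata) {
  stopifnot(is.data.frame(values),
            all(c("feature", "sample_id", "value") %in% names(values)),
            is.data.frame(metadata),
            all(c("sample_id", "mouse_id", "group", "diet") %in% names(metadata)))
  dat <- dplyr::inner_join(values, metadata, by = "sample_id") |>
    dplyr::mutate(
      group = factor(.data$group), diet = factor(.data$diet),
      mouse_id = factor(.data$mouse_id)
    )
  if (nrow(dat) == 0) rlang::abort("No overlap between `values` and `metadata`.")

  crossed <- with(dplyr::distinct(dat, .data$group, .data$diet),
                  table(diet, group))
  singular_design <- any(crossed == 0) && nlevels(dat$group) > 1

  res <- dat |>
    dplyr::group_by(.data$feature) |>
    dplyr::group_map(~ fit_one_lmm(.x, .y$feature, singular_design))
  stats <- dplyr::bind_rows(purrr::map(res, "stats"))
  emm <- dplyr::bind_rows(purrr::map(res, "emmeans"))
  ok <- !is.na(stats$diet_p)
  stats$q <- NA_real_
  stats$q[ok] <- bh_adjust(stats$diet_p[ok])
  structure(list(stats = stats, emmeans = emm), class = "feature_lmm")
}

fit_one_lmm <- function(df, feature, singular_design) {
  null_row <- function(note) {
    list(
      stats = tibble::tibble(feature = feature, diet_F = NA_real_,
                             diet_df = NA_real_, diet_p = NA_real_,
                             note = note),
      emmeans = df |>
        dplyr::group_by(diet = .data$diet) |>
        dplyr::summarise(emmean = mean(.data$value), .groups = "drop") |>
        dplyr::mutate(feature = feature, lower = .data$emmean,
                      upper = .data$emmean) |>
        dplyr::select("feature", "diet", "emmean", "lower", "upper")
    )
  }
  if (stats::var(df$value) == 0) return(null_row("zero_variance"))

  form <- if (singular_design) {
    value ~ diet + (1 | mouse_id)
  } else {
    value ~ group * diet + (1 | mouse_id)
  }
  fit <- tryCatch(
    suppressMessages(lmerTest::lmer(
      form, data = df, REML = TRUE,
      contrasts = if (singular_design) list(diet = "contr.sum") else
        list(group = "contr.sum", diet = "contr.sum"),
      control = lme4::lmerControl(check.conv.singular = lme4::.makeCC(
        action = "ignore", tol = 1e-4
      ))
    )),
    error = function(e) NULL
  )
  if (is.null(fit)) return(null_row("fit_failed"))

  an <- tryCatch(suppressMessages(stats::anova(fit, type = 3)),
                 error = function(e) NULL)
  if (is.null(an) || !"diet" %in% rownames(an)) return(null_row("anova_failed"))
  drow <- an["diet", ]

  em <- tryCatch(
    suppressMessages(as.data.frame(
      emmeans::emmeans(fit, "diet", weights = "equal",
                       lmer.df = "satterthwaite")
    )),
    error = function(e) NULL
  )
  emm <- if (is.null(em)) {
    null_row("emmeans_failed")$emmeans
  } else {
    tibble::tibble(feature = feature, diet = as.character(em$diet),
                   emmean = em$emmean, lower = em$lower.CL, upper = em$upper.CL)
  }
  list(
    stats = tibble::tibble(
      feature = feature,
      diet_F = drow[["F value"]],
      diet_df = drow[["NumDF"]],
      diet_p = drow[["Pr(>F)"]],
      note = if (singular_design) "singular_design" else NA_character_
    ),
    emmeans = emm
  )
}

#' @export
print.feature_lmm <- function(x, ...) {
  cat(sprintf("<feature_lmm> %d features\n", nrow(x$stats)))
  print(x$stats, ...)
  invisible(x)
}

#' Welch's t-test with log2 fold-change
#'
#' Unequal-variance t-statistic with Welch-Satterthwaite degrees of freedom
#' (delegated to [stats::t.test()]) plus `log2fc = log2(mean_a / mean_b)`
#' with an abundance floor applied to both means to keep the fold-change
#' defined for zero-mean groups.
#'
#' @param group_a,group_b Numeric vectors (>= 2 finite values each).
#' @param floor Abundance floor; default 0 (a zero mean with zero floor gives
#'   `NA` fold-change with a warning).
#' @return Tibble with `t`, `df`, `p`, `log2fc`, `mean_a`, `mean_b`.
#' @export
welch_test <- function(group_a, group_b, floor = 0) {
  group_a <- group_a[is.finite(group_a)]
  group_b <- group_b[is.finite(group_b)]
  if (length(group_a) < 2 || length(group_b) < 2) {
    rlang::abort("Welch's test needs >= 2 finite values per group.")
  }
  ma <- mean(group_a)
  mb <- mean(group_b)
  if (sd(group_a) == 0 && sd(group_b) == 0 && ma == mb) {
    tt <- list(statistic = c(t = 0), parameter = c(df = NA_real_), p.value = 1)
  } else {
    tt <- t.test(group_a, group_b, var.equal = FALSE)
  }
  fa <- max(ma, floor)
  fb <- max(mb, floor)
  log2fc <- if (fa > 0 && fb > 0) log2(fa / fb) else {
    rlang::warn("Zero group mean with zero floor; log2fc undefined.")
    NA_real_
  }
  tibble::tibble(
    t = unname(tt$statistic), df = unname(tt$parameter),
    p = tt$p.value, log2fc = log2fc, mean_a = ma, mean_b = mb
  )
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR adjustment (`q_(i) = min_{j >= i} p_(j) * m / j`), delegated
#' to [stats::p.adjust()].
#'
#' @param pvalues Numeric p-values in `[0, 1]` (NA allowed, propagated).
#' @return q-values in the original order.
#' @examples
#' bh_adjust(c(0.01, 0.02, 0.04))  # 0.03 0.03 0.04
#' @export
bh_adjust <- function(pvalues) {
  finite <- pvalues[!is.na(pvalues)]
  if (any(finite < 0 | finite > 1)) {
    rlang::abort("p-values must lie in [0, 1].")
  }
  p.adjust(pvalues, method = "BH")
}

#' Differential features between two conditions
#'
#' Per-feature Welch's t-tests between two NSAF (or any feature-by-sample)
#' matrices with Benjamini-Hochberg control, signed by log2 fold-change
#' (condition A over condition B). The abundance floor for fold-changes is
#' half the smallest nonzero value across both matrices.
#'
#' @param nsaf_a,nsaf_b Long tibbles (`sample_id`, `feature` or `accession`,
#'   `nsaf_pct`) or feature-by-sample matrices for the two conditions.
#' @param q_threshold Significance threshold on q (default 0.05).
#' @return Tibble with `feature`, `t`, `p`, `q`, `log2fc`, `mean_a`,
#'   `mean_b`, `significant`, `direction` (`"up_a"`/`"up_b"`), all features
#'   reported. Empty (with a warning) if the feature universes do not
#'   intersect.
#' @export
differential_features <- function(nsaf_a, nsaf_b, q_threshold = 0.05) {
  ma <- as_feature_matrix(nsaf_a)
  mb <- as_feature_matrix(nsaf_b)
  shared <- intersect(rownames(ma), rownames(mb))
  if (length(shared) == 0) {
    rlang::warn("No shared features between conditions; empty result.")
    return(tibble::tibble(feature = character(), t = double(), p = double(),
                          q = double(), log2fc = double(), mean_a = double(),
                          mean_b = double(), significant = logical(),
                          direction = character()))
  }
  nz <- c(ma[ma > 0], mb[mb > 0])
  floor <- if (length(nz) > 0) min(nz) / 2 else 0
  rows <- purrr::map(shared, function(f) {
    dplyr::mutate(welch_test(ma[f, ], mb[f, ], floor = floor), feature = f)
  })
  out <- dplyr::bind_rows(rows) |>
    dplyr::relocate("feature") |>
    dplyr::mutate(
      q = bh_adjust(.data$p),
      significant = !is.na(.data$q) & .data$q <= q_threshold,
      direction = dplyr::if_else(.data$log2fc >= 0, "up_a", "up_b")
    ) |>
    dplyr::select("feature", "t", "p", "q", "log2fc", "mean_a", "mean_b",
                  "significant", "direction")
  dplyr::arrange(out, .data$q, .data$p)
}

# Accept a long tidy table or a feature-by-sample matrix.
as_feature_matrix <- function(x) {
  if (is.matrix(x)) {
    storage.mode(x) <- "double"
    return(x)
  }
  stopifnot(is.data.frame(x))
  feat_col <- intersect(c("feature", "accession"), names(x))[1]
  val_col <- intersect(c("nsaf_pct", "value"), names(x))[1]
  if (is.na(feat_col) || is.na(val_col)) {
    rlang::abort("Need `feature`/`accession` and `nsaf_pct`/`value` columns.")
  }
  wide <- x |>
    dplyr::select(feature = dplyr::all_of(feat_col), "sample_id",
                  value = dplyr::all_of(val_col)) |>
    tidyr::pivot_wider(names_from = "sample_id", values_from = "value",
                       values_fill = 0)
  m <- as.matrix(wide[, -1, drop = FALSE])
  rownames(m) <- wide$feature
  m
}
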