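#' Permutational multivariate analysis of variance (PERMANOVA)
#'
#' Sequential (Type-I) partitioning of a distance matrix by an ordered list
#' of factors, with significance from free permutation of sample labels.
#' The squared distance matrix is Gower-centered
#' (`G = (I - 11'/n) (-D^2/2) (I - 11'/n)`); each factor's sum of squares is
#' the increment in `tr(H G)` when its dummy columns join the design, the
#' pseudo-F is `(SS_f / df_f) / (SS_res / df_res)`, and the permutation
#' p-value is `(b + 1) / (m + 1)` where `b` counts permuted pseudo-F values
#' at or above the observed one. `R^2 = SS_f / SS_total`. Sums of squares,
#' `R^2` and F are deterministic; only p-values use the random permutations.
#'
#' @param d A `dist` object or square distance matrix with sample labels.
#' @param metadata Data frame of sample covariates containing `sample_id`.
#' @param factors Character vector of metadata columns, in the order they
#'   should enter the sequential decomposition.
#' @param n_permutations Number of random permutations (>= 1; default 999).
#' @param seed Integer seed for the permutations.
#' @return Object of class `permanova`: list with `table` (tibble: `term`,
#'   `df`, `SumOfSqs`, `R2`, `F`, `p` with Residual and Total rows),
#'   `n_permutations`, `n_samples`.
#' @examples
#' m <- rbind(a1 = c(1, 0), a2 = c(1, 0.1), b1 = c(0, 1), b2 = c(0.1, 1))
#' meta <- tibble::tibble(sample_id = rownames(m),
#'                        grp = c("a", "a", "b", "b"))
#' permanova(dist(m), meta, "grp", n_permutations = 99, seed = 1)
#' @export
permanova <- function(d, metadata, factors, n_permutations = 999, seed = 1L) {
  n_permutations <- check_count(n_permutations, "n_permutations")
  seed <- check_seed(seed)
  dm <- as.matrix(d)
  if (is.null(rownames(dm))) rlang::abort("Distance matrix must carry sample labels.")
  stopifnot(is.data.frame(metadata), "sample_id" %in% names(metadata))
  if (!all(factors %in% names(metadata))) {
    rlang::abort("All `factors` must be metadata columns.")
  }
  meta <- metadata[match(rownames(dm), metadata$sample_id), , drop = FALSE]
  if (anyNA(meta$sample_id)) {
    rlang::abort("Every distance-matrix sample needs a metadata row.")
  }
  n <- nrow(dm)

  G <- gower_center(dm)
  ss_total <- sum(diag(G))

  # Sequential hat matrices: QR of the growing design, intercept first.
  hats <- vector("list", length(factors) + 1)
  X <- matrix(1, n, 1)
  hats[[1]] <- hat_matrix(X)
  ranks <- numeric(length(factors) + 1)
  ranks[1] <- 1
  for (j in seq_along(factors)) {
    f <- factor(meta[[factors[j]]])
    if (nlevels(f) >= 2) {
      X <- cbind(X, stats::model.matrix(~ f)[, -1, drop = FALSE])
    }
    hats[[j + 1]] <- hat_matrix(X)
    ranks[j + 1] <- qr(X)$rank
  }
  df <- diff(ranks)
  df_res <- n - ranks[length(ranks)]
  if (df_res <= 0) rlang::abort("No residual degrees of freedom.")
  if (any(df == 0)) rlang::warn("Collinear factor(s) with 0 df.")

  stat <- function(Gm) {
    tr <- vapply(hats, function(H) sum(H * Gm), numeric(1))
    ss <- diff(tr)
    ss_res <- sum(diag(Gm)) - tr[length(tr)]
    f_val <- ifelse(df > 0, (ss / pmax(df, 1)) / (ss_res / df_res), NA_real_)
    list(ss = ss, ss_res = ss_res, f = f_val)
  }
  obs <- stat(G)

  withr::local_seed(seed)
  exceed <- numeric(length(factors))
  for (b in seq_len(n_permutations)) {
    p <- sample.int(n)
    perm <- stat(G[p, p, drop = FALSE])
    exceed <- exceed + (perm$f >= obs$f - 1e-12)
  }
  pvals <- (exceed + 1) / (n_permutations + 1)
  pvals[df == 0] <- NA_real_

  table <- tibble::tibble(
    term = c(factors, "Residual", "Total"),
    df = c(df, df_res, n - 1),
    SumOfSqs = c(obs$ss, obs$ss_res, ss_total),
    R2 = c(obs$ss, obs$ss_res, ss_total) / ss_total,
    F = c(obs$f, NA, NA),
    p = c(pvals, NA, NA)
  )
  structure(
    list(table = table, n_permutations = n_permutations, n_samples = n),
    class = "permanova"
  )
}

gower_center <- function(dm) {
  n <- nrow(dm)
  A <- -0.5 * dm^2
  C <- diag(n) - matrix(1 / n, n, n)
  C %*% A %*% C
}

hat_matrix <- function(X) {
  q <- qr(X)
  Q <- qr.Q(q)[, seq_len(q$rank), drop = FALSE]
  tcrossprod(Q)
}

#' @export
print.permanova <- function(x, ...) {
  cat(sprintf("PERMANOVA (sequential SS, %d free permutations, %d samples)\n",
              x$n_permutations, x$n_samples))
  print(as.data.frame(x$table), row.names = FALSE, digits = 4)
  invisible(x)
}

#' Pairwise PERMANOVA between groups
#'
#' One two-group PERMANOVA per group pair on the corresponding sub-matrix of
#' the distance matrix, with Benjamini-Hochberg adjustment of the permutation
#' p-values across pairs. Pairs involving a single-sample group are skipped
#' with a warning.
#'
#' @param d Distance matrix or `dist` with sample labels.
#' @param metadata Data frame with `sample_id` and the grouping column.
#' @param group Name of the grouping column (e.g. diet).
#' @param n_permutations Permutations per pair.
#' @param seed Integer seed.
#' @return Tibble with `group_a`, `group_b`, `df`, `R2`, `F`, `p`, `q`.
#' @export
pairwise_permanova <- function(d, metadata, group, n_permutations = 999, seed = 1L) {
  dm <- as.matrix(d)
  stopifnot(is.data.frame(metadata),
            all(c("sample_id", group) %in% names(metadata)))
  meta <- metadata[match(rownames(dm), metadata$sample_id), , drop = FALSE]
  levels <- sort(unique(as.character(meta[[group]])))
  pairs <- utils::combn(levels, 2, simplify = FALSE)
  rows <- purrr::imap(pairs, function(pr, i) {
    keep <- meta[[group]] %in% pr
    if (min(table(meta[[group]][keep])) < 2) {
      rlang::warn(sprintf("Skipping pair %s vs %s: a group has < 2 samples.",
                          pr[1], pr[2]))
      return(NULL)
    }
    sub <- dm[keep, keep, drop = FALSE]
    res <- permanova(sub, meta[keep, , drop = FALSE], group,
                     n_permutations = n_permutations,
                     seed = derive_seed(seed, i))
    row <- res$table[1, ]
    tibble::tibble(group_a = pr[1], group_b = pr[2], df = row$df,
                   R2 = row$R2, F = row$F, p = row$p)
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) > 0) out$q <- bh_adjust(out$p)
  out
}
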