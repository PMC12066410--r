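#' Alpha diversity: Shannon index
#'
#' Shannon entropy in nats, `H = -sum(p_i * ln(p_i))` over the nonzero
#' species proportions within each sample (delegated to [vegan::diversity()]).
#' All-zero samples are reported as `NA`.
#'
#' @param x A `biomass_profile` or a samples-by-species abundance matrix.
#' @return Tibble with `sample_id` and `shannon`.
#' @examples
#' m <- matrix(c(25, 25, 25, 25), 1, dimnames = list("S1", NULL))
#' shannon_index(m)$shannon  # ln(4)
#' @export
shannon_index <- function(x) {
  m <- as_abundance_matrix(x)
  h <- vegan::diversity(m, index = "shannon")
  h[rowSums(m) == 0] <- NA_real_
  tibble::tibble(sample_id = rownames(m), shannon = unname(h))
}

#' Beta diversity: Bray-Curtis dissimilarity
#'
#' `d(A, B) = 1 - 2 * sum(min(A_i, B_i)) / (sum(A_i) + sum(B_i))` for every
#' sample pair (delegated to [vegan::vegdist()]). Pairs of all-zero samples
#' are undefined and flagged with a warning.
#'
#' @param x A `biomass_profile` or a samples-by-species abundance matrix
#'   (>= 2 samples).
#' @return A `dist` object with sample labels.
#' @export
bray_curtis <- function(x) {
  m <- as_abundance_matrix(x)
  if (nrow(m) < 2) rlang::abort("Bray-Curtis needs at least two samples.")
  d <- vegan::vegdist(m, method = "bray")
  if (anyNA(d)) rlang::warn("Undefined Bray-Curtis for all-zero sample pairs (NA).")
  d
}

as_abundance_matrix <- function(x) {
  if (inherits(x, "biomass_profile")) return(biomass_percent_matrix(x))
  m <- as.matrix(x)
  if (is.null(rownames(m))) rownames(m) <- sprintf("S%d", seq_len(nrow(m)))
  storage.mode(m) <- "double"
  if (any(m < 0)) rlang::abort("Abundances must be non-negative.")
  m
}

#' Centered log-ratio PCA
#'
#' Applies the centered log-ratio transform `clr(x) = ln(x + c) - mean(ln(x
#' + c))` per sample and computes principal components of the centered CLR
#' matrix. The pseudocount `c` defaults to half the smallest nonzero
#' abundance in the matrix.
#'
#' @param x A `biomass_profile` or abundance matrix.
#' @param pseudocount Positive pseudocount; default half the minimum nonzero
#'   value.
#' @return Object of class `clr_pca`: list with `scores` (tibble with
#'   `sample_id` and `PC1..`), `loadings`, `sdev` and `pseudocount`.
#' @export
clr_pca <- function(x, pseudocount = NULL) {
  m <- as_abundance_matrix(x)
  if (is.null(pseudocount)) pseudocount <- min(m[m > 0]) / 2
  if (!is.numeric(pseudocount) || pseudocount <= 0) {
    rlang::abort("`pseudocount` must be positive.")
  }
  lm_ <- log(m + pseudocount)
  clr <- lm_ - rowMeans(lm_)
  p <- prcomp(clr, center = TRUE, scale. = FALSE)
  structure(
    list(
      scores = dplyr::bind_cols(tibble::tibble(sample_id = rownames(m)),
                                tibble::as_tibble(p$x)),
      loadings = p$rotation,
      sdev = p$sdev,
      clr = clr,
      pseudocount = pseudocount
    ),
    class = "clr_pca"
  )
}

#' Ward.D2 hierarchical clustering with Newick export
#'
#' Agglomerative clustering of matrix rows with the Ward.D2 criterion on
#' Euclidean distances, optionally on natural-log transformed values. The
#' result carries the `hclust` object and a Newick string whose node heights
#' equal the merge heights.
#'
#' @param m Numeric matrix (>= 2 rows) with row names.
#' @param log_transform Log-transform values before clustering (default TRUE,
#'   matching how abundance heatmaps are usually clustered).
#' @param pseudocount Pseudocount for the log transform; default half the
#'   minimum nonzero value.
#' @return Object of class `ward_clustering`: list with `hclust`, `newick`,
#'   `merge_order` (tibble of merge heights).
#' @export
ward_cluster <- function(m, log_transform = TRUE, pseudocount = NULL) {
  m <- as.matrix(m)
  if (nrow(m) < 2) rlang::abort("Clustering needs at least two rows.")
  if (is.null(rownames(m))) rownames(m) <- sprintf("R%d", seq_len(nrow(m)))
  if (log_transform) {
    if (is.null(pseudocount)) {
      pseudocount <- if (any(m > 0)) min(m[m > 0]) / 2 else 1
    }
    m <- suppressWarnings(log(m + pseudocount))
  }
  if (!all(is.finite(m))) {
    rlang::abort("Non-finite values after transform; cannot cluster.")
  }
  hc <- hclust(dist(m, method = "euclidean"), method = "ward.D2")
  phy <- ape::as.phylo(hc)
  structure(
    list(
      hclust = hc,
      newick = ape::write.tree(phy),
      merge_order = tibble::tibble(step = seq_along(hc$height),
                                   height = hc$height)
    ),
    class = "ward_clustering"
  )
}

#' @export
print.ward_clustering <- function(x, ...) {
  cat(sprintf("<ward_clustering> %d leaves\n", length(x$hclust$labels)))
  cat(x$newick, "\n")
  invisible(x)
}

#' Write a Ward clustering as a Newick file
#'
#' @param clustering A [ward_cluster()] result.
#' @param path Output path.
#' @export
write_newick <- function(clustering, path) {
  stopifnot(inherits(clustering, "ward_clustering"))
  writeLines(clustering$newick, path)
  invisible(path)
}
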