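#' Target-decoy FDR estimation for PSMs
#'
#' Estimates per-PSM q-values by target-decoy competition, independently per
#' sample. At a score threshold s the estimated FDR is
#' `#decoys(score >= s) / max(1, #targets(score >= s))`; the q-value is the
#' monotone non-increasing envelope of that estimate in score, i.e. the
#' smallest estimated FDR attainable at any threshold at or below the PSM's
#' score. With no decoys present all q-values are 0.
#'
#' @param psms PSM tibble with at least `sample_id`, `score`, `is_decoy`.
#' @return The input with a `q` column appended. Row order is preserved and
#'   irrelevant to the result.
#' @examples
#' psms <- tibble::tibble(
#'   sample_id = "S1", spectrum_id = as.character(1:4),
#'   peptide = "PEPTIDEK", score = c(5, 4, 3, 2),
#'   is_decoy = c(FALSE, FALSE, TRUE, FALSE), protein_ids = "p1"
#' )
#' estimate_psm_fdr(psms)$q
#' @export
estimate_psm_fdr <- function(psms) {
  stopifnot(is.data.frame(psms),
            all(c("sample_id", "score", "is_decoy") %in% names(psms)))
  if (nrow(psms) > 0 && all(psms$is_decoy)) {
    rlang::abort("PSM table contains only decoys; q-values are undefined.")
  }
  psms |>
    dplyr::group_by(.data$sample_id) |>
    dplyr::mutate(q = tdc_qvalues(.data$score, .data$is_decoy)) |>
    dplyr::ungroup()
}

# q-values from target-decoy competition on one sample's score vector.
tdc_qvalues <- function(score, is_decoy) {
  if (!any(is_decoy)) return(rep(0, length(score)))
  ord <- order(score, decreasing = TRUE)
  dec <- is_decoy[ord]
  n_dec <- cumsum(dec)
  n_tgt <- cumsum(!dec)
  fdr <- n_dec / pmax(1, n_tgt)
  # Ties share a threshold: each PSM's FDR is the value at the last PSM with
  # its score.
  s_sorted <- score[ord]
  last_of_score <- !duplicated(s_sorted, fromLast = TRUE)
  fdr_at <- fdr
  fdr_at[!last_of_score] <- NA
  fdr_at <- rev(fill_na_locf(rev(fdr_at)))
  # Monotone non-increasing envelope in score: running minimum from the
  # bottom of the score ladder upward.
  q_sorted <- rev(cummin(rev(fdr_at)))
  q <- numeric(length(score))
  q[ord] <- q_sorted
  pmin(q, 1)
}

# Last-observation-carried-forward NA fill (used on a reversed vector to
# propagate each tied score's threshold FDR to all members of the tie).
fill_na_locf <- function(x) {
  for (i in seq_along(x)) {
    if (is.na(x[i])) x[i] <- x[i - 1L]
  }
  x
}

#' Filter PSMs at an FDR threshold
#'
#' Retains target PSMs with q-value at or below the threshold and drops all
#' decoys. q-values are computed with [estimate_psm_fdr()] if absent.
#'
#' @param psms PSM tibble.
#' @param q_threshold FDR threshold; the study default is 0.05.
#' @return Filtered PSM tibble (targets only).
#' @export
filter_psms <- function(psms, q_threshold = 0.05) {
  q_threshold <- check_fraction(q_threshold, "q_threshold")
  if (!"q" %in% names(psms)) psms <- estimate_psm_fdr(psms)
  dplyr::filter(psms, !.data$is_decoy, .data$q <= q_threshold)
}

#' Resolve peptides to proteins and taxa
#'
#' For every distinct peptide in a PSM table, collects the set of database
#' proteins containing it and the set of taxon codes those proteins carry. A
#' peptide is *protein-unique* if it occurs in exactly one protein accession
#' and *taxon-unique* if all its proteins share one taxon code; peptides
#' spanning several species groups route their spectra to the ambiguous
#' partition downstream.
#'
#' @param psms PSM tibble (targets; decoys are ignored).
#' @param database Protein database tibble.
#' @return Tibble with one row per peptide: `peptide`, `proteins` (list
#'   column), `n_proteins`, `protein_unique`, `taxa` (list column),
#'   `n_taxa`, `taxon_unique`.
#' @export
resolve_peptides <- function(psms, database) {
  database <- check_database(database)
  res <- psms |>
    dplyr::filter(!.data$is_decoy) |>
    dplyr::distinct(.data$peptide, .data$protein_ids) |>
    dplyr::mutate(proteins = split_ids(.data$protein_ids)) |>
    dplyr::group_by(.data$peptide) |>
    dplyr::summarise(proteins = list(sort(unique(unlist(.data$proteins)))),
                     .groups = "drop")
  all_acc <- unique(unlist(res$proteins))
  unknown <- setdiff(all_acc, database$accession)
  if (length(unknown) > 0) {
    rlang::abort(sprintf(
      "PSM table references accessions absent from the database: %s",
      paste(utils::head(unknown, 5), collapse = ", ")
    ))
  }
  code_of <- setNames(database$taxon_code, database$accession)
  res |>
    dplyr::mutate(
      n_proteins = lengths(.data$proteins),
      protein_unique = .data$n_proteins == 1L,
      taxa = purrr::map(.data$proteins, ~ sort(unique(unname(code_of[.x])))),
      n_taxa = lengths(.data$taxa),
      taxon_unique = .data$n_taxa == 1L
    )
}

#' Spectral counting per protein
#'
#' Sums FDR-filtered PSMs into per-sample protein spectral counts. Under the
#' default `"unique_only"` policy a PSM contributes only when its peptide is
#' protein-unique, so no spectrum is ever counted twice; `"all"` counts a
#' shared-peptide PSM toward every protein containing the peptide. Following
#' the inclusion rule used throughout the pipeline, a protein is reported
#' only if at least one protein-unique peptide was identified for it anywhere
#' in the study.
#'
#' @param psms FDR-filtered PSM tibble (see [filter_psms()]).
#' @param database Protein database tibble.
#' @param policy `"unique_only"` (default) or `"all"`.
#' @return A protein quantification tibble: `sample_id`, `accession`,
#'   `taxon_code`, `spectral_count`, `n_unique_peptides` (distinct
#'   protein-unique peptides in that sample) and `n_unique_peptides_study`
#'   (across all samples).
#' @export
count_spectra <- function(psms, database, policy = c("unique_only", "all")) {
  policy <- match.arg(policy)
  database <- check_database(database)
  resolved <- resolve_peptides(psms, database)

  long <- psms |>
    dplyr::filter(!.data$is_decoy) |>
    dplyr::select("sample_id", "spectrum_id", "peptide") |>
    dplyr::inner_join(
      resolved |>
        dplyr::select("peptide", "proteins", "protein_unique") |>
        tidyr::unnest_longer("proteins", values_to = "accession"),
      by = "peptide", relationship = "many-to-many"
    )

  counted <- if (policy == "unique_only") {
    dplyr::filter(long, .data$protein_unique)
  } else {
    long
  }

  quant <- counted |>
    dplyr::group_by(.data$sample_id, .data$accession) |>
    dplyr::summarise(spectral_count = dplyr::n(), .groups = "drop")

  uniq <- long |>
    dplyr::filter(.data$protein_unique) |>
    dplyr::group_by(.data$sample_id, .data$accession) |>
    dplyr::summarise(n_unique_peptides = dplyr::n_distinct(.data$peptide),
                     .groups = "drop")
  uniq_study <- long |>
    dplyr::filter(.data$protein_unique) |>
    dplyr::group_by(.data$accession) |>
    dplyr::summarise(n_unique_peptides_study = dplyr::n_distinct(.data$peptide),
                     .groups = "drop")

  quant |>
    dplyr::left_join(uniq, by = c("sample_id", "accession")) |>
    dplyr::mutate(n_unique_peptides = dplyr::coalesce(.data$n_unique_peptides, 0L)) |>
    dplyr::inner_join(uniq_study, by = "accession") |>
    dplyr::left_join(dplyr::select(database, "accession", "taxon_code"),
                     by = "accession") |>
    dplyr::arrange(.data$sample_id, .data$accession)
}
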