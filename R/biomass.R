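#' Species proteinaceous-biomass profiles from protein quantities
#'
#' Sums spectral counts of qualifying proteins into their assigned taxonomy:
#' microbial species groups plus the `AMBIGUOUS`, `LOWQ`, `UNBINNED`, `HOST`
#' and `DIET` partitions. Only proteins with at least `min_unique`
#' protein-unique peptides contribute (default 2, the quantification rule for
#' proteinaceous biomass); proteins whose peptides span several species
#' groups carry the `AMBIGUOUS` code and are never counted toward any single
#' species. Species percentages are expressed relative to the summed
#' species-assigned counts of the sample (the microbial *species* biomass),
#' excluding the ambiguous/low-quality/unbinned partitions.
#'
#' @param quant Protein quantification tibble from [count_spectra()].
#' @param min_unique Minimum protein-unique peptides for a protein to qualify.
#' @param scope `"study"` (default) applies the filter on peptides pooled
#'   over all samples; `"sample"` requires the peptides within each sample.
#' @return A `biomass_profile`: list with `counts` (tibble `sample_id`,
#'   `taxon_code`, `count`), `percent` (tibble `sample_id`, `species`,
#'   `percent`) and the qualifying-protein table `proteins`.
#' @examples
#' quant <- tibble::tibble(
#'   sample_id = "S1", accession = c("p1", "p2"),
#'   spectral_count = c(75L, 25L), n_unique_peptides = c(3L, 2L),
#'   n_unique_peptides_study = c(3L, 2L), taxon_code = c("spA", "spB")
#' )
#' quantify_biomass(quant)$percent
#' @export
quantify_biomass <- function(quant, min_unique = 2, scope = c("study", "sample")) {
  scope <- match.arg(scope)
  need <- c("sample_id", "accession", "spectral_count", "n_unique_peptides",
            "n_unique_peptides_study", "taxon_code")
  stopifnot(is.data.frame(quant), all(need %in% names(quant)))
  if (nrow(quant) == 0) {
    rlang::warn("Empty protein quantification; returning an empty profile.")
    return(structure(list(
      counts = tibble::tibble(sample_id = character(), taxon_code = character(),
                              count = integer()),
      percent = tibble::tibble(sample_id = character(), species = character(),
                               percent = double()),
      proteins = quant
    ), class = "biomass_profile"))
  }

  qualifying <- if (scope == "study") {
    dplyr::filter(quant, .data$n_unique_peptides_study >= min_unique)
  } else {
    dplyr::filter(quant, .data$n_unique_peptides >= min_unique)
  }

  counts <- qualifying |>
    dplyr::group_by(.data$sample_id, .data$taxon_code) |>
    dplyr::summarise(count = sum(.data$spectral_count), .groups = "drop")

  percent <- counts |>
    dplyr::filter(!.data$taxon_code %in% RESERVED_CODES) |>
    dplyr::group_by(.data$sample_id) |>
    dplyr::mutate(percent = 100 * .data$count / sum(.data$count)) |>
    dplyr::ungroup() |>
    dplyr::select("sample_id", species = "taxon_code", "percent")

  structure(
    list(counts = counts, percent = percent, proteins = qualifying),
    class = "biomass_profile"
  )
}

#' @export
print.biomass_profile <- function(x, ...) {
  cat(sprintf(
    "<biomass_profile> %d samples, %d species, %d qualifying proteins\n",
    dplyr::n_distinct(x$counts$sample_id),
    dplyr::n_distinct(x$percent$species),
    dplyr::n_distinct(x$proteins$accession)
  ))
  invisible(x)
}

#' Species percent matrix of a biomass profile
#'
#' @param profile A `biomass_profile`.
#' @return Numeric matrix, samples in rows, species in columns, percent of
#'   the sample's microbial species biomass (rows sum to 100). Species not
#'   detected in a sample are 0.
#' @export
biomass_percent_matrix <- function(profile) {
  stopifnot(inherits(profile, "biomass_profile"))
  wide <- profile$percent |>
    tidyr::pivot_wider(names_from = "species", values_from = "percent",
                       values_fill = 0) |>
    dplyr::arrange(.data$sample_id)
  m <- as.matrix(wide[, -1, drop = FALSE])
  rownames(m) <- wide$sample_id
  m[, order(colnames(m)), drop = FALSE]
}

#' Microbe-to-host biomass ratio
#'
#' Per-sample ratio of microbial to host spectral counts: the summed counts
#' assigned to microbial species, multiple microbial species (ambiguous),
#' low-quality bins and unbinned bacteria, divided by the counts assigned to
#' host proteins. Dietary protein counts enter neither numerator nor
#' denominator. Samples without host counts give `NA` with a warning.
#'
#' @param profile A `biomass_profile`.
#' @return Tibble with `sample_id` and `microbe_host_ratio`.
#' @export
microbe_host_ratio <- function(profile) {
  stopifnot(inherits(profile, "biomass_profile"))
  out <- profile$counts |>
    dplyr::group_by(.data$sample_id) |>
    dplyr::summarise(
      microbial = sum(.data$count[!.data$taxon_code %in% NON_MICROBIAL]),
      host = sum(.data$count[.data$taxon_code == "HOST"]),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      microbe_host_ratio = dplyr::if_else(.data$host > 0,
                                          .data$microbial / .data$host,
                                          NA_real_)
    )
  if (anyNA(out$microbe_host_ratio)) {
    rlang::warn("Some samples have no host spectra; ratio reported as NA.")
  }
  dplyr::select(out, "sample_id", "microbe_host_ratio")
}

#' Abundant-species subset
#'
#' Species carrying at least `threshold_percent` of the microbial species
#' biomass in at least one sample.
#'
#' @param profile A `biomass_profile`.
#' @param threshold_percent Inclusion threshold in percent (default 5).
#' @return Character vector of species ids.
#' @export
abundant_species <- function(profile, threshold_percent = 5) {
  stopifnot(inherits(profile, "biomass_profile"))
  profile$percent |>
    dplyr::group_by(.data$species) |>
    dplyr::summarise(max_pct = max(.data$percent), .groups = "drop") |>
    dplyr::filter(.data$max_pct >= threshold_percent) |>
    dplyr::pull("species") |>
    sort()
}

#' Class-level rollup of species biomass
#'
#' Sums species counts into their taxonomic class per sample. Class sums
#' conserve species totals exactly.
#'
#' @param profile A `biomass_profile`.
#' @param taxonomy Tibble mapping `species` to `class`.
#' @return Tibble with `sample_id`, `class`, `count`.
#' @export
class_rollup <- function(profile, taxonomy) {
  stopifnot(inherits(profile, "biomass_profile"),
            is.data.frame(taxonomy),
            all(c("species", "class") %in% names(taxonomy)))
  species_counts <- dplyr::filter(profile$counts,
                                  !.data$taxon_code %in% RESERVED_CODES)
  missing <- setdiff(unique(species_counts$taxon_code), taxonomy$species)
  if (length(missing) > 0) {
    rlang::abort(sprintf("No class label for species: %s",
                         paste(missing, collapse = ", ")))
  }
  species_counts |>
    dplyr::inner_join(taxonomy, by = c(taxon_code = "species")) |>
    dplyr::group_by(.data$sample_id, .data$class) |>
    dplyr::summarise(count = sum(.data$count), .groups = "drop")
}

#' Per-sample species richness
#'
#' Number of quantifiable species (nonzero qualifying signal) per sample.
#'
#' @param profile A `biomass_profile`.
#' @return Tibble with `sample_id` and `richness`.
#' @export
richness <- function(profile) {
  stopifnot(inherits(profile, "biomass_profile"))
  profile$counts |>
    dplyr::group_by(.data$sample_id) |>
    dplyr::summarise(
      richness = sum(!.data$taxon_code %in% RESERVED_CODES & .data$count > 0),
      .groups = "drop"
    )
}
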