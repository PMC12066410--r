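#' Normalized spectral abundance factor (NSAF%)
#'
#' Length-normalized relative protein abundance: per sample,
#' `SAF_i = count_i / length_i` over microbial proteins and
#' `NSAF%_i = 100 * SAF_i / sum(SAF)`. Host and dietary proteins are excluded
#' from both numerator and denominator; all microbial codes (species groups
#' plus `AMBIGUOUS`, `LOWQ`, `UNBINNED`) are included. Uses every identified
#' protein in `quant` (the >= 1 protein-unique-peptide identification
#' filter), not only the biomass-qualifying subset.
#'
#' @param quant Protein quantification tibble from [count_spectra()].
#' @param database Protein database tibble (provides lengths).
#' @return An NSAF tibble: `sample_id`, `accession`, `taxon_code`,
#'   `nsaf_pct`, with attribute `scope = "all-microbial"`. Columns sum to 100
#'   per sample.
#' @examples
#' quant <- tibble::tibble(
#'   sample_id = "S1", accession = c("a", "b"), spectral_count = c(10L, 10L),
#'   n_unique_peptides = 1L, n_unique_peptides_study = 1L, taxon_code = "sp1"
#' )
#' db <- tibble::tibble(accession = c("a", "b"), sequence = c("X", "Y"),
#'                      taxon_code = "sp1", length = c(100L, 200L))
#' nsaf(quant, db)$nsaf_pct  # 66.67 / 33.33
#' @export
nsaf <- function(quant, database) {
  database <- check_database(database)
  lens <- setNames(database$length, database$accession)
  micro <- quant |>
    dplyr::filter(!.data$taxon_code %in% NON_MICROBIAL)
  if (any(is.na(lens[micro$accession]))) {
    rlang::abort("Some quantified proteins are absent from the database.")
  }
  if (any(lens[micro$accession] <= 0)) {
    rlang::abort("Zero-length protein in database; NSAF undefined.")
  }
  out <- micro |>
    dplyr::mutate(saf = .data$spectral_count / unname(lens[.data$accession])) |>
    dplyr::group_by(.data$sample_id) |>
    dplyr::mutate(nsaf_pct = 100 * .data$saf / sum(.data$saf)) |>
    dplyr::ungroup() |>
    dplyr::select("sample_id", "accession", "taxon_code", "nsaf_pct")
  attr(out, "scope") <- "all-microbial"
  out
}

#' Single-organism NSAF (orgNSAF)
#'
#' NSAF% with numerator and denominator restricted to one species' proteins,
#' so the profile describes the organism's internal proteome allocation and
#' is invariant to every other species' counts.
#'
#' @param quant Protein quantification tibble.
#' @param database Protein database tibble.
#' @param species_code The species-group code to extract.
#' @return NSAF tibble (scope `"single-organism"`), columns summing to 100
#'   per sample over the species' proteins.
#' @export
org_nsaf <- function(quant, database, species_code) {
  sub <- dplyr::filter(quant, .data$taxon_code == species_code)
  if (nrow(sub) == 0) {
    rlang::abort(sprintf("Species `%s` has no quantified proteins.", species_code))
  }
  out <- nsaf(sub, database)
  attr(out, "scope") <- "single-organism"
  attr(out, "species_code") <- species_code
  out
}

#' Consensus annotation with manual curation and extrapolation
#'
#' Combines automated-tool labels with a manually curated subset using the
#' precedence: direct manual label, then extrapolated manual label (the
#' protein shares its full automated label signature with a curated protein),
#' then tool consensus (all tools that labeled the protein agree), then
#' unannotated. If two curated proteins share a signature but disagree, that
#' signature is not extrapolated. Every decision is tagged with its
#' provenance tier.
#'
#' @param tool_labels Tibble with `accession`, `tool`, `label`.
#' @param manual Tibble with `accession`, `label` (curated subset). A single
#'   accession with conflicting manual labels is an error.
#' @return Tibble with `accession`, `label` (NA when unannotated) and
#'   `provenance` (`manual`, `extrapolated`, `consensus`, `unannotated`).
#' @export
consensus_annotate <- function(tool_labels, manual = NULL) {
  stopifnot(is.data.frame(tool_labels),
            all(c("accession", "tool", "label") %in% names(tool_labels)))
  manual <- manual %||% tibble::tibble(accession = character(), label = character())
  conflicts <- manual |>
    dplyr::distinct(.data$accession, .data$label) |>
    dplyr::count(.data$accession) |>
    dplyr::filter(.data$n > 1)
  if (nrow(conflicts) > 0) {
    rlang::abort(sprintf("Conflicting manual labels for: %s",
                         paste(conflicts$accession, collapse = ", ")))
  }
  manual <- dplyr::distinct(manual, .data$accession, .data$label)

  sigs <- tool_labels |>
    dplyr::filter(!is.na(.data$label)) |>
    dplyr::arrange(.data$tool) |>
    dplyr::group_by(.data$accession) |>
    dplyr::summarise(
      signature = paste(.data$tool, .data$label, sep = "=", collapse = "|"),
      consensus = dplyr::n_distinct(.data$label) == 1L,
      consensus_label = dplyr::first(.data$label),
      .groups = "drop"
    )

  # Signatures anchored by exactly one curated label are extrapolated.
  anchors <- sigs |>
    dplyr::inner_join(manual, by = "accession") |>
    dplyr::distinct(.data$signature, .data$label) |>
    dplyr::group_by(.data$signature) |>
    dplyr::filter(dplyr::n() == 1L) |>
    dplyr::ungroup()

  all_acc <- union(sigs$accession, manual$accession)
  out <- tibble::tibble(accession = all_acc) |>
    dplyr::left_join(dplyr::rename(manual, manual_label = "label"),
                     by = "accession") |>
    dplyr::left_join(sigs, by = "accession") |>
    dplyr::left_join(dplyr::rename(anchors, anchor_label = "label"),
                     by = "signature") |>
    dplyr::mutate(
      label = dplyr::case_when(
        !is.na(.data$manual_label) ~ .data$manual_label,
        !is.na(.data$anchor_label) ~ .data$anchor_label,
        .data$consensus %in% TRUE ~ .data$consensus_label,
        TRUE ~ NA_character_
      ),
      provenance = dplyr::case_when(
        !is.na(.data$manual_label) ~ "manual",
        !is.na(.data$anchor_label) ~ "extrapolated",
        .data$consensus %in% TRUE ~ "consensus",
        TRUE ~ "unannotated"
      )
    ) |>
    dplyr::select("accession", "label", "provenance")
  out
}

#' Roll protein NSAF up to a functional level
#'
#' Sums member-protein NSAF% into features at the requested annotation level.
#' Proteins without a label at that level are reported as an explicit
#' `"unannotated"` feature, so columns still sum to 100 within the NSAF
#' scope. PUL membership must partition: a protein mapped to two PULs is an
#' error.
#'
#' @param nsaf_tbl An NSAF tibble from [nsaf()] or [org_nsaf()].
#' @param annotations Tibble with `accession` and the level columns
#'   (`broad_category`, `detailed_category`, `enzyme_name`, `gh_family`,
#'   `pul_id`).
#' @param level One of `"broad"`, `"detailed"`, `"enzyme"`, `"gh_family"`,
#'   `"pul"`.
#' @return Tibble with `sample_id`, `feature`, `nsaf_pct`.
#' @export
rollup <- function(nsaf_tbl, annotations,
                   level = c("broad", "detailed", "enzyme", "gh_family", "pul")) {
  level <- match.arg(level)
  col <- c(broad = "broad_category", detailed = "detailed_category",
           enzyme = "enzyme_name", gh_family = "gh_family", pul = "pul_id")[[level]]
  if (!col %in% names(annotations)) {
    rlang::abort(sprintf("`annotations` lacks the `%s` column.", col))
  }
  ann <- annotations |>
    dplyr::select("accession", feature = dplyr::all_of(col)) |>
    dplyr::distinct()
  dup <- ann |>
    dplyr::filter(!is.na(.data$feature)) |>
    dplyr::count(.data$accession) |>
    dplyr::filter(.data$n > 1)
  if (nrow(dup) > 0) {
    rlang::abort(sprintf("Proteins mapped to multiple %s features: %s",
                         level, paste(dup$accession, collapse = ", ")))
  }
  nsaf_tbl |>
    dplyr::left_join(ann, by = "accession") |>
    dplyr::mutate(feature = dplyr::coalesce(.data$feature, "unannotated")) |>
    dplyr::group_by(.data$sample_id, .data$feature) |>
    dplyr::summarise(nsaf_pct = sum(.data$nsaf_pct), .groups = "drop")
}

#' Amino-acid pathway rollup
#'
#' Sums NSAF% of enzymes by amino acid and reaction direction
#' (degradation, synthesis, interconversion, reversible) using an enzyme
#' pathway map.
#'
#' @param nsaf_tbl NSAF tibble.
#' @param annotations Tibble with `accession`, `enzyme_name`.
#' @param aa_map Tibble with `enzyme_name`, `amino_acid`, `direction`,
#'   `ammonia_product` (see [default_aa_pathway_map()]). An enzyme mapped to
#'   an unknown direction is an error.
#' @return Tibble with `sample_id`, `direction`, `amino_acid`, `nsaf_pct`.
#' @export
amino_acid_class_rollup <- function(nsaf_tbl, annotations, aa_map) {
  stopifnot(all(c("enzyme_name", "amino_acid", "direction") %in% names(aa_map)))
  bad <- setdiff(unique(aa_map$direction),
                 c("degradation", "synthesis", "interconversion", "reversible"))
  if (length(bad) > 0) {
    rlang::abort(sprintf("Unknown reaction direction(s): %s",
                         paste(bad, collapse = ", ")))
  }
  nsaf_tbl |>
    dplyr::inner_join(dplyr::select(annotations, "accession", "enzyme_name"),
                      by = "accession") |>
    dplyr::inner_join(aa_map, by = "enzyme_name",
                      relationship = "many-to-many") |>
    dplyr::group_by(.data$sample_id, .data$direction, .data$amino_acid) |>
    dplyr::summarise(nsaf_pct = sum(.data$nsaf_pct), .groups = "drop")
}

#' Ammonia-producing enzyme panel
#'
#' Summed NSAF% of enzymes classified as degradation or reversible whose
#' potential products include ammonia.
#'
#' @inheritParams amino_acid_class_rollup
#' @return Tibble with `sample_id`, `nsaf_pct`.
#' @export
ammonia_panel <- function(nsaf_tbl, annotations, aa_map) {
  stopifnot("ammonia_product" %in% names(aa_map))
  enzymes <- aa_map |>
    dplyr::filter(.data$direction %in% c("degradation", "reversible"),
                  .data$ammonia_product) |>
    dplyr::pull("enzyme_name")
  enzyme_panel(nsaf_tbl, annotations, enzymes)
}

#' Summed abundance of named enzymes
#'
#' @param nsaf_tbl NSAF tibble.
#' @param annotations Tibble with `accession`, `enzyme_name`.
#' @param enzymes Character vector of enzyme names to sum (e.g. `"urease"`).
#' @return Tibble with `sample_id`, `nsaf_pct` (0 when no member detected).
#' @export
enzyme_panel <- function(nsaf_tbl, annotations, enzymes) {
  member <- annotations |>
    dplyr::filter(.data$enzyme_name %in% enzymes) |>
    dplyr::pull("accession")
  nsaf_tbl |>
    dplyr::group_by(.data$sample_id) |>
    dplyr::summarise(
      nsaf_pct = sum(.data$nsaf_pct[.data$accession %in% member]),
      .groups = "drop"
    )
}
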