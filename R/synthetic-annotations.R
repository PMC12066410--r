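## Synthetic functional annotations: category vocabularies, per-tool labels
## with controlled disagreement, a curated subset, GH families and PUL
## membership, plus an amino-acid pathway map. These exercise the consensus /
## extrapolation mechanics and every rollup level.

BROAD_CATEGORIES <- c(
  "amino acid metabolism", "glycan degradation", "gene expression",
  "monosaccharide metabolism", "fermentation", "stress and cell protection",
  "lipid metabolism", "secondary metabolism"
)

DETAILED_BY_BROAD <- list(
  "amino acid metabolism" = c("amino acid degradation", "amino acid synthesis"),
  "glycan degradation" = c("glycoside hydrolase", "polysaccharide transport"),
  "gene expression" = c("ribosomal proteins", "transcription"),
  "monosaccharide metabolism" = c("glycolysis", "pentose phosphate"),
  "fermentation" = c("short-chain fatty acid production", "hydrogenase"),
  "stress and cell protection" = c("oxidative stress response", "chaperone"),
  "lipid metabolism" = c("fatty acid synthesis", "lipid A synthesis"),
  "secondary metabolism" = c("terpenoid synthesis", "polyketide synthesis")
)

ENZYMES_BY_DETAILED <- list(
  "amino acid degradation" = c("urease", "tryptophanase",
                               "branched-chain amino acid aminotransferase",
                               "glutamate dehydrogenase", "cysteine desulfurase"),
  "amino acid synthesis" = c("glutamine synthetase", "threonine synthase"),
  "glycoside hydrolase" = c("endo-beta-N-acetylglucosaminidase",
                            "alpha-mannosidase", "beta-glucosidase", "fucosidase"),
  "polysaccharide transport" = c("SusC", "SusD", "TonB"),
  "ribosomal proteins" = c("ribosomal protein L2", "ribosomal protein S4"),
  "glycolysis" = c("enolase", "pyruvate kinase")
)

GH_FAMILIES <- c("GH18", "GH92", "GH2", "GH3", "GH20", "GH29", "GH97")

#' Default amino-acid pathway map for synthetic annotations
#'
#' Maps enzyme names to the amino acid they act on, the reaction direction
#' (`degradation`, `synthesis`, `interconversion`, `reversible`) and whether
#' ammonia is among the potential products.
#'
#' @return A tibble with columns `enzyme_name`, `amino_acid`, `direction`,
#'   `ammonia_product`.
#' @export
default_aa_pathway_map <- function() {
  tibble::tribble(
    ~enzyme_name, ~amino_acid, ~direction, ~ammonia_product,
    "urease", "arginine", "degradation", TRUE,
    "tryptophanase", "tryptophan", "degradation", TRUE,
    "branched-chain amino acid aminotransferase", "leucine", "degradation", FALSE,
    "glutamate dehydrogenase", "glutamate", "reversible", TRUE,
    "cysteine desulfurase", "cysteine", "degradation", TRUE,
    "glutamine synthetase", "glutamine", "synthesis", FALSE,
    "threonine synthase", "threonine", "synthesis", FALSE
  )
}

#' Generate synthetic functional annotations for a protein catalog
#'
#' Assigns broad/detailed categories and enzyme names to a fraction of
#' microbial proteins, emits three automated-tool label tables with a
#' controlled disagreement rate, a manually curated subset, GH families for
#' glycoside-hydrolase proteins and PUL membership for a subset of
#' SusC/SusD/TonB-carrying species, mirroring the structure of curated
#' metaproteome annotation tables.
#'
#' @param catalog A [generate_protein_catalog()] result.
#' @param annotated_fraction Fraction of microbial proteins given a category.
#' @param tool_disagreement_rate Probability that a given tool reports a
#'   perturbed label instead of the true one.
#' @param curated_fraction Fraction of annotated proteins manually curated.
#' @param seed Integer seed.
#'
#' @return List with tibbles `annotations` (accession, broad_category,
#'   detailed_category, enzyme_name, gh_family, pul_id), `tool_labels`
#'   (accession, tool, label), `manual` (accession, label), and `aa_map`
#'   (see [default_aa_pathway_map()]).
#' @export
generate_annotations <- function(catalog,
                                 annotated_fraction = 0.8,
                                 tool_disagreement_rate = 0.1,
                                 curated_fraction = 0.3,
                                 seed = 1L) {
  stopifnot(inherits(catalog, "protein_catalog"))
  seed <- check_seed(seed)
  withr::local_seed(seed)

  microbial <- catalog$database |>
    dplyr::filter(!.data$taxon_code %in% NON_MICROBIAL)
  n <- nrow(microbial)
  annotated <- stats::runif(n) < annotated_fraction

  detailed_pool <- unlist(DETAILED_BY_BROAD, use.names = FALSE)
  broad_of <- rep(names(DETAILED_BY_BROAD), lengths(DETAILED_BY_BROAD))
  pick <- sample(seq_along(detailed_pool), n, replace = TRUE)

  enzyme <- vapply(detailed_pool[pick], function(d) {
    pool <- ENZYMES_BY_DETAILED[[d]]
    if (is.null(pool)) NA_character_ else sample(pool, 1L)
  }, character(1), USE.NAMES = FALSE)

  ann <- tibble::tibble(
    accession = microbial$accession,
    taxon_code = microbial$taxon_code,
    broad_category = ifelse(annotated, broad_of[pick], NA_character_),
    detailed_category = ifelse(annotated, detailed_pool[pick], NA_character_),
    enzyme_name = ifelse(annotated, enzyme, NA_character_),
    gh_family = NA_character_,
    pul_id = NA_character_
  )

  gh <- which(ann$detailed_category %in% "glycoside hydrolase")
  ann$gh_family[gh] <- sample(GH_FAMILIES, length(gh), replace = TRUE)

  # PULs: SusC/SusD/TonB plus nearby GHs of one species form numbered loci.
  pul_candidates <- which(ann$enzyme_name %in% c("SusC", "SusD", "TonB") |
                            !is.na(ann$gh_family))
  if (length(pul_candidates) >= 4) {
    by_sp <- split(pul_candidates, ann$taxon_code[pul_candidates])
    pul_n <- 0L
    for (sp in names(by_sp)) {
      rows <- by_sp[[sp]]
      while (length(rows) >= 3) {
        pul_n <- pul_n + 1L
        take <- utils::head(rows, sample(3:6, 1L))
        ann$pul_id[take] <- sprintf("PUL%02d", pul_n)
        rows <- setdiff(rows, take)
      }
    }
  }

  # Automated tools agree with truth except at the disagreement rate.
  true_label <- dplyr::coalesce(ann$enzyme_name, ann$detailed_category)
  tool_labels <- purrr::map(c("eggnog", "mantis", "microbeannotator"), function(tool) {
    flip <- stats::runif(n) < tool_disagreement_rate
    lab <- true_label
    lab[flip & !is.na(lab)] <- paste0(lab[flip & !is.na(lab)], " (putative)")
    tibble::tibble(accession = ann$accession, tool = tool, label = lab)
  }) |>
    dplyr::bind_rows() |>
    dplyr::filter(!is.na(.data$label))

  curated_idx <- which(annotated & stats::runif(n) < curated_fraction)
  manual <- tibble::tibble(
    accession = ann$accession[curated_idx],
    label = true_label[curated_idx]
  )

  list(
    annotations = dplyr::select(ann, -"taxon_code"),
    tool_labels = tool_labels,
    manual = manual,
    aa_map = default_aa_pathway_map()
  )
}
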