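#' Simulate a multi-diet, multi-mouse metaproteomics study
#'
#' Generates one PSM table per mouse x diet sample from a shared base
#' community, imposing species-specific diet, mouse-group and individual-mouse
#' effects on the log biomass fractions. The design mirrors a crossed
#' repeated-measures feeding study: every mouse is sampled under every diet,
#' mice are nested in two groups with different background communities, and
#' three mice share a cage.
#'
#' @param community Base [generate_community()] result.
#' @param catalog [generate_protein_catalog()] result for that community.
#' @param diets Character vector of diet names, in feeding order.
#' @param n_mice Number of mice, split evenly into two groups.
#' @param depth Target PSMs per sample.
#' @param diet_effect_sd,group_effect_sd,mouse_effect_sd Standard deviations
#'   of the species-specific normal shifts applied to log biomass fractions
#'   for each diet, group and mouse. Zero switches an effect off.
#' @param decoy_score_model Passed to [simulate_psm_table()].
#' @param seed Integer seed.
#'
#' @return List with `psms` (all samples row-bound), `metadata` (tibble:
#'   `sample_id`, `mouse_id`, `group`, `diet`, `cage`), `truth` (per-sample
#'   true species fractions), plus the `community` and `catalog` used.
#' @examples
#' comm <- generate_community(4, seed = 5)
#' cat <- generate_protein_catalog(comm, proteins_per_species = 3, seed = 5)
#' st <- simulate_study(comm, cat, diets = c("soy", "yeast"), n_mice = 4,
#'                      depth = 200, seed = 5)
#' st$metadata
#' @export
simulate_study <- function(community, catalog,
                           diets = c("soy20", "casein20", "rice20", "soy40",
                                     "yeast20", "casein40", "pea20", "egg20"),
                           n_mice = 12,
                           depth = 5000,
                           diet_effect_sd = 0.8,
                           group_effect_sd = 0.5,
                           mouse_effect_sd = 0.25,
                           decoy_score_model = list(),
                           seed = 1L) {
  stopifnot(inherits(community, "ground_truth_community"),
            inherits(catalog, "protein_catalog"))
  n_mice <- check_count(n_mice, "n_mice", min = 2L)
  seed <- check_seed(seed)
  withr::local_seed(derive_seed(seed, 777L))

  n_sp <- nrow(community$species)
  base_log <- log(community$species$biomass_fraction)
  diet_shift <- matrix(rnorm(length(diets) * n_sp, 0, diet_effect_sd),
                       nrow = length(diets), dimnames = list(diets, NULL))
  groups <- sort(rep(c("group1", "group2"), length.out = n_mice))
  group_shift <- matrix(rnorm(2 * n_sp, 0, group_effect_sd), nrow = 2,
                        dimnames = list(c("group1", "group2"), NULL))
  mouse_ids <- sprintf("m%02d", seq_len(n_mice))
  mouse_shift <- matrix(rnorm(n_mice * n_sp, 0, mouse_effect_sd), nrow = n_mice,
                        dimnames = list(mouse_ids, NULL))
  cages <- paste0("cage", ceiling(seq_len(n_mice) / 3))

  design <- tidyr::expand_grid(mouse = seq_len(n_mice), diet = diets) |>
    dplyr::mutate(
      mouse_id = mouse_ids[.data$mouse],
      group = groups[.data$mouse],
      cage = cages[.data$mouse],
      sample_id = paste(.data$mouse_id, .data$diet, sep = "_")
    )

  truth <- vector("list", nrow(design))
  psms <- vector("list", nrow(design))
  for (i in seq_len(nrow(design))) {
    lf <- base_log + diet_shift[design$diet[i], ] +
      group_shift[design$group[i], ] + mouse_shift[design$mouse_id[i], ]
    frac <- exp(lf - max(lf))
    frac <- frac / sum(frac)
    comm_i <- set_biomass_fractions(community, frac)
    psms[[i]] <- simulate_psm_table(
      comm_i, catalog, depth = depth, sample_ids = design$sample_id[i],
      decoy_score_model = decoy_score_model, seed = derive_seed(seed, i)
    )
    truth[[i]] <- tibble::tibble(
      sample_id = design$sample_id[i],
      species_id = community$species$species_id,
      true_fraction = frac
    )
  }

  list(
    psms = dplyr::bind_rows(psms),
    metadata = dplyr::select(design, "sample_id", "mouse_id", "group", "diet", "cage"),
    truth = dplyr::bind_rows(truth),
    community = community,
    catalog = catalog
  )
}
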