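#' Default pipeline configuration
#'
#' Assembles the configuration for [run_pipeline()], with every threshold at
#' its study default: 5% PSM FDR, two protein-unique peptides for biomass,
#' 5% abundant-species rule, 0.90/0.95 identity cutoffs, q < 0.05 for
#' differential features, and the sequential PERMANOVA factor order
#' diet, group.
#'
#' @param out_dir Output directory for stage results.
#' @param seed Integer seed registered for every stochastic stage.
#' @param ... Overrides for any default element (nested lists are merged).
#' @return A named list of class `run_config`.
#' @export
run_config <- function(out_dir, seed = 1L, ...) {
  base <- list(
    out_dir = out_dir,
    seed = check_seed(seed),
    simulate = list(
      n_species = 20, dirichlet_alpha = 0.5, proteins_per_species = 8,
      shared_peptide_rate = 0.05,
      diets = c("soy20", "casein20", "yeast20", "egg20"),
      n_mice = 6, depth = 2000
    ),
    thresholds = list(
      fdr = 0.05, biomass_min_unique = 2, abundant_pct = 5,
      identity_merge = 0.90, identity_reference = 0.95, q_threshold = 0.05
    ),
    permanova = list(factors = c("diet", "group"), n_permutations = 199)
  )
  cfg <- utils::modifyList(base, rlang::list2(...))
  validate_run_config(cfg)
}

validate_run_config <- function(cfg) {
  th <- cfg$thresholds
  check_fraction(th$fdr, "thresholds$fdr")
  check_fraction(th$q_threshold, "thresholds$q_threshold")
  check_fraction(th$identity_merge, "thresholds$identity_merge", lo_open = TRUE)
  check_fraction(th$identity_reference, "thresholds$identity_reference", lo_open = TRUE)
  check_count(th$biomass_min_unique, "thresholds$biomass_min_unique")
  check_fraction(th$abundant_pct, "thresholds$abundant_pct", hi = 100)
  if (is.null(cfg$seed)) rlang::abort("A seed is mandatory.")
  structure(cfg, class = "run_config")
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file with the same structure as [run_config()] output.
#' @return A validated `run_config`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) rlang::abort(sprintf("Config file not found: %s", path))
  raw <- yaml::read_yaml(path)
  out_dir <- raw$out_dir %||% rlang::abort("Config must set `out_dir`.")
  seed <- raw$seed %||% rlang::abort("Config must set `seed`.")
  raw$out_dir <- NULL
  raw$seed <- NULL
  rlang::exec(run_config, out_dir = out_dir, seed = seed, !!!raw)
}

#' Run the full analysis pipeline
#'
#' Executes the stages in dependency order - simulate, quantify, biomass,
#' diversity, functions, stats - writing each stage's tables under
#' `config$out_dir` and a manifest (config, seed, md5 checksum per output)
#' as JSON. Re-running with an identical configuration reproduces identical
#' outputs.
#'
#' @param config A `run_config` (or list coercible via
#'   [validate_run_config()]).
#' @return Invisibly, a list with the in-memory stage results and the
#'   manifest path.
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "run_config")) config <- validate_run_config(config)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(f) file.path(config$out_dir, f)
  th <- config$thresholds
  sim_cfg <- config$simulate

  # -- simulate ---------------------------------------------------------
  community <- generate_community(
    sim_cfg$n_species, dirichlet_alpha = sim_cfg$dirichlet_alpha,
    seed = derive_seed(config$seed, 1)
  )
  catalog <- generate_protein_catalog(
    community, proteins_per_species = sim_cfg$proteins_per_species,
    shared_peptide_rate = sim_cfg$shared_peptide_rate,
    seed = derive_seed(config$seed, 2)
  )
  study <- simulate_study(
    community, catalog, diets = sim_cfg$diets, n_mice = sim_cfg$n_mice,
    depth = sim_cfg$depth, seed = derive_seed(config$seed, 3)
  )
  anns <- generate_annotations(catalog, seed = derive_seed(config$seed, 4))
  write_database_fasta(catalog$database, out("database.fasta"))
  write_psm_tsv(study$psms, out("psms.tsv"))
  readr::write_tsv(study$metadata, out("metadata.tsv"), progress = FALSE)
  readr::write_tsv(study$truth, out("truth_biomass.tsv"), progress = FALSE)
  readr::write_tsv(anns$annotations, out("annotations.tsv"), progress = FALSE)

  # -- quantify ---------------------------------------------------------
  filtered <- filter_psms(study$psms, q_threshold = th$fdr)
  quant <- count_spectra(filtered, catalog$database)
  readr::write_tsv(quant, out("protein_quant.tsv"), progress = FALSE)

  # -- biomass ----------------------------------------------------------
  profile <- quantify_biomass(quant, min_unique = th$biomass_min_unique)
  readr::write_tsv(profile$counts, out("biomass_counts.tsv"), progress = FALSE)
  readr::write_tsv(profile$percent, out("biomass_percent.tsv"), progress = FALSE)
  ratio <- microbe_host_ratio(profile)
  readr::write_tsv(ratio, out("microbe_host_ratio.tsv"), progress = FALSE)
  taxonomy <- dplyr::select(community$species, species = "species_id",
                            class = "class_label")
  classes <- class_rollup(profile, taxonomy)
  readr::write_tsv(classes, out("class_rollup.tsv"), progress = FALSE)
  abundant <- abundant_species(profile, th$abundant_pct)

  # -- diversity --------------------------------------------------------
  alpha <- dplyr::left_join(shannon_index(profile), richness(profile),
                            by = "sample_id")
  readr::write_tsv(alpha, out("alpha_diversity.tsv"), progress = FALSE)
  bc <- bray_curtis(profile)
  write_distance_tsv(bc, out("bray_curtis.tsv"))
  perm <- permanova(bc, study$metadata, config$permanova$factors,
                    n_permutations = config$permanova$n_permutations,
                    seed = derive_seed(config$seed, 5))
  readr::write_tsv(perm$table, out("permanova.tsv"), progress = FALSE)
  pm <- biomass_percent_matrix(profile)
  keep <- intersect(colnames(pm), abundant)
  clustering <- NULL
  if (length(keep) >= 2) {
    clustering <- ward_cluster(t(pm[, keep, drop = FALSE]))
    write_newick(clustering, out("abundant_species_dendrogram.nwk"))
  }
  ord <- clr_pca(profile)
  readr::write_tsv(ord$scores, out("clr_pca_scores.tsv"), progress = FALSE)

  # -- functions --------------------------------------------------------
  consensus <- consensus_annotate(anns$tool_labels, anns$manual)
  readr::write_tsv(consensus, out("consensus_annotations.tsv"), progress = FALSE)
  nsaf_tbl <- nsaf(quant, catalog$database)
  readr::write_tsv(nsaf_tbl, out("nsaf_protein.tsv"), progress = FALSE)
  broad <- rollup(nsaf_tbl, anns$annotations, "broad")
  readr::write_tsv(broad, out("nsaf_broad.tsv"), progress = FALSE)
  gh <- rollup(nsaf_tbl, anns$annotations, "gh_family")
  readr::write_tsv(gh, out("nsaf_gh_family.tsv"), progress = FALSE)
  aa <- amino_acid_class_rollup(nsaf_tbl, anns$annotations, anns$aa_map)
  readr::write_tsv(aa, out("nsaf_amino_acid.tsv"), progress = FALSE)

  # -- stats ------------------------------------------------------------
  lmm <- fit_feature_lmm(
    dplyr::rename(broad, feature = "feature", value = "nsaf_pct"),
    study$metadata
  )
  readr::write_tsv(lmm$stats, out("feature_lmm.tsv"), progress = FALSE)
  readr::write_tsv(lmm$emmeans, out("feature_emmeans.tsv"), progress = FALSE)
  diets <- sim_cfg$diets
  contrast <- c(diets[length(diets)], diets[1])
  meta <- study$metadata
  diff <- differential_features(
    dplyr::semi_join(nsaf_tbl, dplyr::filter(meta, .data$diet == contrast[1]),
                     by = "sample_id"),
    dplyr::semi_join(nsaf_tbl, dplyr::filter(meta, .data$diet == contrast[2]),
                     by = "sample_id"),
    q_threshold = th$q_threshold
  )
  readr::write_tsv(diff, out("differential_proteins.tsv"), progress = FALSE)

  # -- manifest ---------------------------------------------------------
  files <- sort(setdiff(list.files(config$out_dir), "manifest.json"))
  manifest <- list(
    package_version = as.character(utils::packageVersion("metaproteo")),
    seed = config$seed,
    thresholds = th,
    checksums = as.list(tools::md5sum(file.path(config$out_dir, files)))
  )
  names(manifest$checksums) <- files
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE)

  invisible(list(
    community = community, catalog = catalog, study = study,
    quant = quant, profile = profile, permanova = perm, nsaf = nsaf_tbl,
    broad = broad, lmm = lmm, differential = diff, clustering = clustering,
    manifest = out("manifest.json")
  ))
}
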