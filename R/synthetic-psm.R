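#' Simulate peptide-spectrum match (PSM) tables
#'
#' Draws target PSMs multinomially over database proteins with weight
#' proportional to `biomass_fraction(taxon) x relative_expression x length`,
#' picks one of the protein's tryptic peptides uniformly per PSM, and records
#' every database protein containing that peptide. A configurable fraction of
#' targets are "false" matches whose scores come from the null distribution
#' (ground truth kept in the `is_false` column), and decoy PSMs with
#' null-distributed scores are appended, so target-decoy FDR estimation can
#' be validated against known false-discovery proportions.
#'
#' @param community A [generate_community()] result; its fractions set the
#'   expected share of host, diet, low-quality and unbinned PSMs.
#' @param catalog A [generate_protein_catalog()] result.
#' @param depth Total number of target PSMs per sample (exact, multinomial).
#' @param sample_ids Character vector of sample identifiers; one table per
#'   sample is generated and row-bound.
#' @param decoy_score_model List with elements `target_mean`, `null_mean`,
#'   `sd` (normal score distributions for correct matches vs false/decoy
#'   matches), `decoy_rate` (expected decoys as a fraction of `depth`) and
#'   `false_target_rate` (fraction of target PSMs drawn from the null). The
#'   default 4-standard-deviation separation means a 5% FDR threshold retains
#'   essentially all true targets.
#' @param seed Integer seed; per-sample seeds are derived deterministically.
#'
#' @return A PSM tibble with columns `sample_id`, `spectrum_id`, `peptide`,
#'   `score`, `is_decoy`, `protein_ids` (semicolon-separated accessions,
#'   empty for decoys) and the ground-truth flag `is_false`.
#' @examples
#' comm <- generate_community(2, seed = 3)
#' cat <- generate_protein_catalog(comm, proteins_per_species = 3, seed = 3)
#' psms <- simulate_psm_table(comm, cat, depth = 100, seed = 3)
#' table(psms$is_decoy)
#' @export
simulate_psm_table <- function(community, catalog,
                               depth = 20000,
                               sample_ids = "S1",
                               decoy_score_model = list(),
                               seed = 1L) {
  stopifnot(inherits(community, "ground_truth_community"),
            inherits(catalog, "protein_catalog"))
  depth <- check_count(depth, "depth")
  if (nrow(catalog$proteins) == 0) rlang::abort("`catalog` is empty.")
  seed <- check_seed(seed)
  model <- utils::modifyList(
    list(target_mean = 4, null_mean = 0, sd = 1,
         decoy_rate = 0.1, false_target_rate = 0.1),
    decoy_score_model
  )

  weights <- psm_protein_weights(community, catalog)
  # peptide -> all database accessions containing it (sorted, deterministic)
  pep_map <- catalog$peptides |>
    dplyr::distinct(.data$peptide, .data$protein_id) |>
    dplyr::group_by(.data$peptide) |>
    dplyr::summarise(ids = paste(sort(.data$protein_id), collapse = ";"),
                     .groups = "drop")
  pep_ids <- setNames(pep_map$ids, pep_map$peptide)
  prot_peps <- catalog$proteins$peptides
  names(prot_peps) <- catalog$proteins$protein_id

  out <- purrr::imap(setNames(sample_ids, sample_ids), function(sid, nm) {
    withr::local_seed(derive_seed(seed, match(sid, sample_ids)))
    counts <- as.vector(rmultinom(1, depth, weights$weight))
    idx <- rep.int(seq_along(counts), counts)
    accession <- weights$protein_id[idx]
    peptide <- unlist(lapply(which(counts > 0), function(j) {
      pp <- prot_peps[[weights$protein_id[j]]]
      if (length(pp) == 1L) rep(pp, counts[j]) else sample(pp, counts[j], replace = TRUE)
    }), use.names = FALSE)
    is_false <- stats::runif(depth) < model$false_target_rate
    score <- rnorm(depth, mean = ifelse(is_false, model$null_mean, model$target_mean),
                   sd = model$sd)
    n_decoy <- rbinom(1, depth, model$decoy_rate)
    decoy_pep <- if (n_decoy > 0) {
      reg <- new.env(hash = TRUE, parent = emptyenv())
      draw_peptides(n_decoy, reg)
    } else character(0)
    target_ids <- unname(pep_ids[peptide])
    tibble::tibble(
      sample_id = sid,
      spectrum_id = sprintf("%s_scan%06d", sid, seq_len(depth + n_decoy)),
      peptide = c(peptide, decoy_pep),
      score = c(score, rnorm(n_decoy, model$null_mean, model$sd)),
      is_decoy = rep(c(FALSE, TRUE), c(depth, n_decoy)),
      protein_ids = c(target_ids, rep("", n_decoy)),
      is_false = c(is_false, rep(TRUE, n_decoy))
    )
  })
  dplyr::bind_rows(out)
}

# Per-protein multinomial sampling weights. Taxon-level mass: host and diet
# fractions first, then the low-quality/unbinned share of the microbial
# remainder, then species by biomass fraction. Within a taxon, weight is
# relative_expression * length (longer proteins yield more peptides/spectra).
psm_protein_weights <- function(community, catalog) {
  micro <- 1 - community$host_fraction - community$diet_fraction
  frac <- c(
    setNames(micro * (1 - community$lowq_fraction - community$unbinned_fraction) *
               community$species$biomass_fraction,
             community$species$species_id),
    LOWQ = micro * community$lowq_fraction,
    UNBINNED = micro * community$unbinned_fraction,
    HOST = community$host_fraction,
    DIET = community$diet_fraction
  )
  w <- catalog$proteins |>
    dplyr::mutate(within = .data$relative_expression * .data$length) |>
    dplyr::group_by(.data$taxon_code) |>
    dplyr::mutate(within = .data$within / sum(.data$within)) |>
    dplyr::ungroup() |>
    dplyr::mutate(taxon_frac = unname(frac[.data$taxon_code])) |>
    dplyr::filter(!is.na(.data$taxon_frac), .data$taxon_frac > 0)
  if (nrow(w) == 0) rlang::abort("No catalog protein has positive sampling weight.")
  w |>
    dplyr::mutate(weight = .data$taxon_frac * .data$within,
                  weight = .data$weight / sum(.data$weight)) |>
    dplyr::select("protein_id", "taxon_code", "weight")
}
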