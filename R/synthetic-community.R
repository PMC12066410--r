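#' Generate a ground-truth microbial community
#'
#' Draws species proteinaceous-biomass fractions from a symmetric Dirichlet
#' distribution and fixes the contamination structure of a simulated faecal
#' metaproteome: the fraction of spectra of host (mouse) origin, of dietary
#' protein origin, and the fractions of the microbial signal carried by
#' proteins from low-quality bins and unbinned contigs. These are the ground
#' truths that the quantification pipeline is expected to recover.
#'
#' @param n_species Number of microbial species groups (>= 1).
#' @param dirichlet_alpha Concentration of the symmetric Dirichlet from which
#'   biomass fractions are drawn. Small values (< 1) give the skewed
#'   rank-abundance profiles typical of gut communities.
#' @param host_fraction,diet_fraction Expected fraction of PSMs drawn from
#'   host and dietary proteins. Their sum must be < 1.
#' @param lowq_fraction,unbinned_fraction Fractions of the *microbial* signal
#'   assigned to the low-quality-bin and unbinned partitions.
#' @param class_labels Optional character vector of taxonomic class labels,
#'   one per species; defaults to a draw from common gut bacterial classes.
#' @param seed Integer seed; identical seeds give identical communities.
#'
#' @return An object of class `ground_truth_community`: a list with a
#'   `species` tibble (`species_id`, `biomass_fraction`, `class_label`),
#'   the four contamination fractions and the seed.
#' @examples
#' comm <- generate_community(5, dirichlet_alpha = 0.5, seed = 42)
#' sum(comm$species$biomass_fraction)
#' @export
generate_community <- function(n_species,
                               dirichlet_alpha = 0.5,
                               host_fraction = 0.30,
                               diet_fraction = 0.02,
                               lowq_fraction = 0.05,
                               unbinned_fraction = 0.05,
                               class_labels = NULL,
                               seed = 1L) {
  n_species <- check_count(n_species, "n_species")
  if (!is.numeric(dirichlet_alpha) || length(dirichlet_alpha) != 1 ||
      is.na(dirichlet_alpha) || dirichlet_alpha <= 0) {
    rlang::abort("`dirichlet_alpha` must be a single positive number.")
  }
  host_fraction <- check_fraction(host_fraction, "host_fraction", hi_open = TRUE)
  diet_fraction <- check_fraction(diet_fraction, "diet_fraction", hi_open = TRUE)
  if (host_fraction + diet_fraction >= 1) {
    rlang::abort("`host_fraction` + `diet_fraction` must be < 1.")
  }
  lowq_fraction <- check_fraction(lowq_fraction, "lowq_fraction", hi_open = TRUE)
  unbinned_fraction <- check_fraction(unbinned_fraction, "unbinned_fraction", hi_open = TRUE)
  if (lowq_fraction + unbinned_fraction >= 1) {
    rlang::abort("`lowq_fraction` + `unbinned_fraction` must be < 1.")
  }
  seed <- check_seed(seed)

  withr::local_seed(seed)
  # Symmetric Dirichlet via normalized gammas; guard against exact zeros at
  # very small alpha so the all-positive invariant holds.
  g <- pmax(rgamma(n_species, shape = dirichlet_alpha, rate = 1), 1e-300)
  fractions <- g / sum(g)

  if (is.null(class_labels)) {
    pool <- c("Bacteroidia", "Clostridia", "Bacilli",
              "Verrucomicrobiae", "Coriobacteriia")
    class_labels <- sample(pool, n_species, replace = TRUE,
                           prob = c(0.35, 0.4, 0.1, 0.05, 0.1))
  } else if (length(class_labels) != n_species) {
    rlang::abort("`class_labels` must have one label per species.")
  }

  structure(
    list(
      species = tibble::tibble(
        species_id = sprintf("sp%03d", seq_len(n_species)),
        biomass_fraction = fractions,
        class_label = class_labels
      ),
      host_fraction = host_fraction,
      diet_fraction = diet_fraction,
      lowq_fraction = lowq_fraction,
      unbinned_fraction = unbinned_fraction,
      seed = seed
    ),
    class = "ground_truth_community"
  )
}

#' @export
print.ground_truth_community <- function(x, ...) {
  cat(sprintf(
    "<ground_truth_community> %d species (host %.2f, diet %.2f, lowq %.2f, unbinned %.2f)\n",
    nrow(x$species), x$host_fraction, x$diet_fraction,
    x$lowq_fraction, x$unbinned_fraction
  ))
  print(x$species, ...)
  invisible(x)
}

#' Replace the biomass fractions of a community
#'
#' Utility used by [simulate_study()] to impose diet/group/mouse effects on a
#' base community while keeping its contamination structure.
#'
#' @param community A `ground_truth_community`.
#' @param fractions New biomass fractions (positive, renormalized to sum 1).
#' @return The modified community.
#' @export
set_biomass_fractions <- function(community, fractions) {
  stopifnot(inherits(community, "ground_truth_community"))
  if (length(fractions) != nrow(community$species) || any(fractions <= 0)) {
    rlang::abort("`fractions` must be positive, one per species.")
  }
  community$species$biomass_fraction <- fractions / sum(fractions)
  community
}
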