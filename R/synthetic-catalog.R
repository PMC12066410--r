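## Synthetic protein catalog: per-taxon protein sequences built by
## concatenating unique tryptic peptides (random amino-acid strings ending in
## K/R, 7-30 residues, no internal K/R so the in-silico digest is exact).

AA_INTERIOR <- strsplit("ACDEFGHILMNPQSTVWY", "")[[1]]

# Draw `n` peptides, globally unique against `registry` (an environment used
# as a hash set). Lengths uniform on 7..30.
draw_peptides <- function(n, registry) {
  out <- character(n)
  i <- 1L
  while (i <= n) {
    len <- sample(7:30, 1L)
    pep <- paste0(
      paste(sample(AA_INTERIOR, len - 1L, replace = TRUE), collapse = ""),
      sample(c("K", "R"), 1L)
    )
    if (is.null(registry[[pep]])) {
      registry[[pep]] <- TRUE
      out[i] <- pep
      i <- i + 1L
    }
  }
  out
}

#' Generate a synthetic protein catalog and taxon-coded database
#'
#' Builds protein sequences for every species in a ground-truth community plus
#' the low-quality, unbinned, host and diet partitions. Each protein is a
#' concatenation of globally unique tryptic peptides; a configurable fraction
#' of microbial peptides is then copied into a second species' proteins,
#' creating the shared-peptide ambiguity that the downstream inference rules
#' (protein-unique peptides, ambiguous taxon routing) must handle. Host and
#' diet proteins never share peptides with microbial proteins.
#'
#' @param community A [generate_community()] result.
#' @param proteins_per_species Proteins per species (>= 2; with fewer, the
#'   two-unique-peptide biomass rule could never be exercised).
#' @param shared_peptide_rate Fraction of microbial peptides duplicated into a
#'   randomly chosen second species; in `[0, 1)`.
#' @param length_meanlog,length_sdlog Log-normal protein length parameters
#'   (amino acids); the default gives a median length of 300 aa.
#' @param n_host_proteins,n_diet_proteins,n_lowq_proteins,n_unbinned_proteins
#'   Number of proteins generated for each non-species partition.
#' @param relative_expression_sdlog Spread (log-normal sdlog) of within-taxon
#'   relative expression weights. Zero gives equal expression, the condition
#'   under which expected PSM shares equal biomass fractions exactly.
#' @param seed Integer seed.
#'
#' @return An object of class `protein_catalog`: list with `proteins`
#'   (tibble: `protein_id`, `taxon_code`, `length`, `relative_expression`,
#'   `sequence`), `peptides` (tibble: `peptide`, `protein_id`, `taxon_code`),
#'   and `database` (a protein database tibble as used throughout the
#'   package).
#' @examples
#' comm <- generate_community(3, seed = 1)
#' cat <- generate_protein_catalog(comm, proteins_per_species = 3, seed = 1)
#' head(cat$database)
#' @export
generate_protein_catalog <- function(community,
                                     proteins_per_species = 20,
                                     shared_peptide_rate = 0,
                                     length_meanlog = log(300),
                                     length_sdlog = 0.4,
                                     n_host_proteins = 30,
                                     n_diet_proteins = 10,
                                     n_lowq_proteins = 10,
                                     n_unbinned_proteins = 10,
                                     relative_expression_sdlog = 0,
                                     seed = 1L) {
  stopifnot(inherits(community, "ground_truth_community"))
  proteins_per_species <- check_count(proteins_per_species, "proteins_per_species", min = 2L)
  shared_peptide_rate <- check_fraction(shared_peptide_rate, "shared_peptide_rate",
                                        hi_open = TRUE)
  seed <- check_seed(seed)
  withr::local_seed(seed)

  taxa <- c(
    setNames(rep(proteins_per_species, nrow(community$species)),
             community$species$species_id),
    LOWQ = n_lowq_proteins, UNBINNED = n_unbinned_proteins,
    HOST = n_host_proteins, DIET = n_diet_proteins
  )
  taxa <- taxa[taxa > 0]

  registry <- new.env(hash = TRUE, parent = emptyenv())
  protein_rows <- vector("list", length(taxa))
  peptide_rows <- vector("list", length(taxa))
  pid <- 0L
  for (t in seq_along(taxa)) {
    taxon <- names(taxa)[t]
    n_prot <- taxa[[t]]
    target_len <- rlnorm(n_prot, meanlog = length_meanlog, sdlog = length_sdlog)
    peps <- vector("list", n_prot)
    ids <- character(n_prot)
    for (j in seq_len(n_prot)) {
      pid <- pid + 1L
      ids[j] <- sprintf("prot%05d", pid)
      # Accumulate peptides until the target protein length is reached; at
      # least two peptides so the protein-unique rules are exercisable.
      pp <- draw_peptides(max(2L, ceiling(target_len[j] / 18)), registry)
      while (sum(nchar(pp)) < target_len[j]) {
        pp <- c(pp, draw_peptides(1L, registry))
      }
      peps[[j]] <- pp
    }
    protein_rows[[t]] <- tibble::tibble(
      protein_id = ids,
      taxon_code = taxon,
      relative_expression = if (relative_expression_sdlog > 0) {
        rlnorm(n_prot, 0, relative_expression_sdlog)
      } else rep(1, n_prot),
      peptides = peps
    )
    peptide_rows[[t]] <- tibble::tibble(
      peptide = unlist(peps),
      protein_id = rep(ids, lengths(peps)),
      taxon_code = taxon
    )
  }
  proteins <- dplyr::bind_rows(protein_rows)
  peptides <- dplyr::bind_rows(peptide_rows)

  # Duplicate a fraction of species peptides into a second, different species.
  species_ids <- community$species$species_id
  if (shared_peptide_rate > 0 && length(species_ids) >= 2) {
    sp_peps <- which(peptides$taxon_code %in% species_ids)
    n_share <- round(shared_peptide_rate * length(sp_peps))
    if (n_share > 0) {
      chosen <- sample(sp_peps, n_share)
      extra <- vector("list", n_share)
      for (k in seq_len(n_share)) {
        row <- peptides[chosen[k], ]
        other <- sample(setdiff(species_ids, row$taxon_code), 1L)
        host_rows <- which(proteins$taxon_code == other)
        target <- sample(host_rows, 1L)
        proteins$peptides[[target]] <- c(proteins$peptides[[target]], row$peptide)
        extra[[k]] <- tibble::tibble(
          peptide = row$peptide,
          protein_id = proteins$protein_id[target],
          taxon_code = other
        )
      }
      peptides <- dplyr::bind_rows(peptides, dplyr::bind_rows(extra))
    }
  }

  proteins <- proteins |>
    dplyr::mutate(
      sequence = vapply(.data$peptides, paste, character(1), collapse = ""),
      length = nchar(.data$sequence)
    )

  database <- proteins |>
    dplyr::select(accession = "protein_id", "sequence", "taxon_code", "length")

  structure(
    list(
      proteins = dplyr::select(proteins, "protein_id", "taxon_code", "length",
                               "relative_expression", "sequence", "peptides"),
      peptides = peptides,
      database = database,
      seed = seed
    ),
    class = "protein_catalog"
  )
}

#' @export
print.protein_catalog <- function(x, ...) {
  cat(sprintf(
    "<protein_catalog> %d proteins, %d peptide-protein links, %d taxa\n",
    nrow(x$proteins), nrow(x$peptides), dplyr::n_distinct(x$proteins$taxon_code)
  ))
  invisible(x)
}
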