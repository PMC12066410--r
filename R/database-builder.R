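#' Quality-screen metagenomic bins
#'
#' Classifies bins into the two acceptance tiers used for database
#' construction: medium-quality bins (completeness > 50%, contamination
#' < 10%) keep their species-group assignment; a second, permissive tier
#' (completeness > 30%, contamination < 5%) is accepted for database
#' comprehensiveness but coded low-quality downstream. Bins failing both
#' tiers are rejected.
#'
#' @param bins Tibble with `bin_id`, `completeness`, `contamination`
#'   (percent, 0-100).
#' @param accept_thresholds List with elements `species = c(min_completeness,
#'   max_contamination)` and `lowq = c(min_completeness, max_contamination)`.
#'   Both bounds are strict.
#' @return Tibble with `bin_id` and `decision` (`ACCEPT_SPECIES`,
#'   `ACCEPT_LOWQ_TIER`, `REJECT`).
#' @examples
#' classify_bins(tibble::tibble(bin_id = c("b1", "b2", "b3"),
#'                              completeness = c(60, 40, 40),
#'                              contamination = c(5, 3, 8)))
#' @export
classify_bins <- function(bins,
                          accept_thresholds = list(species = c(50, 10),
                                                   lowq = c(30, 5))) {
  stopifnot(is.data.frame(bins),
            all(c("bin_id", "completeness", "contamination") %in% names(bins)))
  if (any(bins$completeness < 0 | bins$completeness > 100 |
            bins$contamination < 0 | bins$contamination > 100)) {
    rlang::abort("Completeness and contamination must lie in [0, 100].")
  }
  sp <- accept_thresholds$species
  lq <- accept_thresholds$lowq
  bins |>
    dplyr::mutate(decision = dplyr::case_when(
      .data$completeness > sp[1] & .data$contamination < sp[2] ~ "ACCEPT_SPECIES",
      .data$completeness > lq[1] & .data$contamination < lq[2] ~ "ACCEPT_LOWQ_TIER",
      TRUE ~ "REJECT"
    )) |>
    dplyr::select("bin_id", "decision")
}

#' Merge unbinned gene calls against the binned database
#'
#' An unbinned sequence enters the database (code `UNBINNED`) only if no
#' binned sequence matches it at or above the identity threshold (identity =
#' global-alignment matches / shorter sequence length, the CD-HIT-2D
#' convention); matching sequences are dropped as redundant with the binned
#' catalog.
#'
#' @param binned Tibble with `accession`, `sequence` (binned gene calls).
#' @param unbinned Tibble with `accession`, `sequence`.
#' @param identity_threshold Identity cutoff in `(0, 1]`; default 0.90.
#' @return Tibble of retained unbinned records: `accession`, `sequence`,
#'   `taxon_code = "UNBINNED"`, `length`.
#' @export
merge_binned_unbinned <- function(binned, unbinned, identity_threshold = 0.90) {
  stopifnot(is.data.frame(binned), is.data.frame(unbinned),
            all(c("accession", "sequence") %in% names(binned)),
            all(c("accession", "sequence") %in% names(unbinned)))
  if (!is.numeric(identity_threshold) || identity_threshold <= 0 ||
        identity_threshold > 1) {
    rlang::abort("`identity_threshold` must lie in (0, 1].")
  }
  if (nrow(binned) == 0 || nrow(unbinned) == 0) {
    rlang::abort("Both binned and unbinned sets must be non-empty.")
  }
  keep <- !vapply(unbinned$sequence, matches_any, logical(1),
                  subjects = binned$sequence, threshold = identity_threshold)
  unbinned[keep, c("accession", "sequence")] |>
    dplyr::mutate(taxon_code = "UNBINNED", length = nchar(.data$sequence)) |>
    tibble::as_tibble()
}

#' Assign species codes to binned proteins
#'
#' Codes each binned protein by the species group of its bin. Identical
#' sequences occurring in accepted species-tier bins of different species
#' groups are coded `AMBIGUOUS`; sequences found only in low-quality-tier
#' bins are coded `LOWQ`. A sequence present in both a species-tier and a
#' low-quality-tier bin keeps the species code (precedence species > LOWQ,
#' reported via a message). Duplicate sequences are collapsed to one record
#' (first accession in sort order).
#'
#' @param proteins Tibble with `accession`, `sequence`, `bin_id`.
#' @param bin_map Tibble with `bin_id`, `species_group_id`, `decision` (from
#'   [classify_bins()]; `REJECT` bins are dropped).
#' @return Protein database tibble (`accession`, `sequence`, `taxon_code`,
#'   `length`).
#' @export
assign_species_codes <- function(proteins, bin_map) {
  stopifnot(is.data.frame(proteins),
            all(c("accession", "sequence", "bin_id") %in% names(proteins)),
            is.data.frame(bin_map),
            all(c("bin_id", "species_group_id", "decision") %in% names(bin_map)))
  unknown <- setdiff(unique(proteins$bin_id), bin_map$bin_id)
  if (length(unknown) > 0) {
    rlang::abort(sprintf("Proteins reference unknown bins: %s",
                         paste(unknown, collapse = ", ")))
  }
  joined <- proteins |>
    dplyr::inner_join(bin_map, by = "bin_id") |>
    dplyr::filter(.data$decision != "REJECT")

  coded <- joined |>
    dplyr::group_by(.data$sequence) |>
    dplyr::summarise(
      accession = min(.data$accession),
      n_species_groups = dplyr::n_distinct(
        .data$species_group_id[.data$decision == "ACCEPT_SPECIES"]
      ),
      species_group = if (any(.data$decision == "ACCEPT_SPECIES")) {
        min(.data$species_group_id[.data$decision == "ACCEPT_SPECIES"])
      } else NA_character_,
      any_lowq = any(.data$decision == "ACCEPT_LOWQ_TIER"),
      .groups = "drop"
    ) |>
    dplyr::mutate(taxon_code = dplyr::case_when(
      .data$n_species_groups > 1 ~ "AMBIGUOUS",
      .data$n_species_groups == 1 ~ .data$species_group,
      TRUE ~ "LOWQ"
    ))
  n_precedence <- sum(coded$n_species_groups == 1 & coded$any_lowq)
  if (n_precedence > 0) {
    rlang::inform(sprintf(
      "%d sequence(s) present in both species-tier and low-quality-tier bins; species code kept.",
      n_precedence
    ))
  }
  coded |>
    dplyr::mutate(length = nchar(.data$sequence)) |>
    dplyr::select("accession", "sequence", "taxon_code", "length") |>
    dplyr::arrange(.data$accession)
}

#' Recode database sequences matching a reference proteome
#'
#' Changes the taxon code of every database sequence that aligns to any
#' reference sequence at or above the identity threshold, e.g. to relabel
#' sequences of a reference species of interest.
#'
#' @param database Protein database tibble.
#' @param reference Tibble with `accession`, `sequence` (non-empty).
#' @param new_code Replacement taxon code; must not collide with the
#'   reserved codes.
#' @param identity_threshold Identity cutoff; default 0.95.
#' @return The database with updated `taxon_code`s.
#' @export
relabel_by_reference <- function(database, reference, new_code,
                                 identity_threshold = 0.95) {
  database <- check_database(database)
  stopifnot(is.data.frame(reference),
            all(c("accession", "sequence") %in% names(reference)))
  if (nrow(reference) == 0) rlang::abort("`reference` must be non-empty.")
  if (new_code %in% RESERVED_CODES) {
    rlang::abort(sprintf("`new_code` collides with the reserved code `%s`.",
                         new_code))
  }
  hit <- vapply(database$sequence, matches_any, logical(1),
                subjects = reference$sequence, threshold = identity_threshold)
  database$taxon_code[hit] <- new_code
  database
}

#' Append host and diet reference proteomes
#'
#' Collapses within-proteome redundancy at the identity threshold by greedy
#' clustering (descending length, first-seen tie-break; a sequence matching
#' an already accepted representative is dropped), codes the representatives
#' `HOST` or `DIET`, and appends them to the microbial database. Records
#' already present (same accession, sequence and code) are not duplicated,
#' so the operation is idempotent. Accessions colliding with existing
#' database records are renamed with a source prefix and reported.
#'
#' @param database Protein database tibble (microbial records; untouched).
#' @param host Tibble with `accession`, `sequence`, or NULL.
#' @param diet Tibble with `accession`, `sequence`, or NULL (may be a
#'   row-bound set of several dietary proteomes).
#' @param cluster_identity Within-proteome redundancy threshold; default 0.95.
#' @return The extended protein database tibble.
#' @export
append_host_diet <- function(database, host = NULL, diet = NULL,
                             cluster_identity = 0.95) {
  database <- check_database(database)
  if (is.null(host) && is.null(diet)) {
    rlang::abort("At least one of `host` or `diet` must be given.")
  }
  add_one <- function(db, proteome, code) {
    if (is.null(proteome) || nrow(proteome) == 0) return(db)
    reps <- greedy_cluster(proteome, cluster_identity)
    reps$taxon_code <- code
    reps$length <- nchar(reps$sequence)
    # Idempotence: skip records already present verbatim.
    key <- paste(reps$accession, reps$sequence, reps$taxon_code)
    existing <- paste(db$accession, db$sequence, db$taxon_code)
    reps <- reps[!key %in% existing, , drop = FALSE]
    clash <- reps$accession %in% db$accession
    if (any(clash)) {
      rlang::inform(sprintf("Renaming %d colliding accession(s) with `%s_` prefix.",
                            sum(clash), tolower(code)))
      reps$accession[clash] <- paste0(tolower(code), "_", reps$accession[clash])
    }
    dplyr::bind_rows(db, reps[, c("accession", "sequence", "taxon_code", "length")])
  }
  database |>
    add_one(host, "HOST") |>
    add_one(diet, "DIET")
}

# Greedy identity clustering: longest first, first-seen tie-break; returns
# the representative records.
greedy_cluster <- function(proteome, threshold) {
  ord <- order(-nchar(proteome$sequence), seq_len(nrow(proteome)))
  prot <- proteome[ord, , drop = FALSE]
  reps <- integer(0)
  for (i in seq_len(nrow(prot))) {
    if (length(reps) == 0 ||
          !matches_any(prot$sequence[i], prot$sequence[reps], threshold)) {
      reps <- c(reps, i)
    }
  }
  tibble::as_tibble(prot[reps, c("accession", "sequence"), drop = FALSE])
}

#' Build a taxon-coded protein database from metagenomic inputs
#'
#' Convenience wrapper running the full database-construction logic:
#' quality-screen bins, code binned proteins by species group (with
#' ambiguous/low-quality handling), merge unbinned gene calls at the 90%
#' identity cutoff, optionally relabel sequences matching reference
#' proteomes, and append host/diet references clustered at 95% identity.
#'
#' @param bin_proteins Tibble with `accession`, `sequence`, `bin_id`.
#' @param bin_table Tibble with `bin_id`, `species_group_id`, `completeness`,
#'   `contamination`.
#' @param unbinned Tibble with `accession`, `sequence`, or NULL.
#' @param host,diet Optional reference proteomes (`accession`, `sequence`).
#' @param references Optional named list of reference proteomes for
#'   [relabel_by_reference()]; names become the new taxon codes.
#' @param identity_merge,identity_reference,cluster_identity The three
#'   identity thresholds (defaults 0.90, 0.95, 0.95).
#' @return A protein database tibble.
#' @export
build_database <- function(bin_proteins, bin_table, unbinned = NULL,
                           host = NULL, diet = NULL, references = NULL,
                           identity_merge = 0.90, identity_reference = 0.95,
                           cluster_identity = 0.95) {
  decisions <- classify_bins(bin_table)
  bin_map <- dplyr::inner_join(bin_table, decisions, by = "bin_id")
  db <- assign_species_codes(bin_proteins, bin_map)
  if (!is.null(unbinned) && nrow(unbinned) > 0) {
    db <- dplyr::bind_rows(
      db, merge_binned_unbinned(db, unbinned, identity_merge)
    )
  }
  for (code in names(references %||% list())) {
    db <- relabel_by_reference(db, references[[code]], code, identity_reference)
  }
  if (!is.null(host) || !is.null(diet)) {
    db <- append_host_diet(db, host, diet, cluster_identity)
  }
  db
}
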