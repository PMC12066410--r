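#' Read and write taxon-coded protein databases
#'
#' A protein database is a tibble with one row per protein: `accession`,
#' `sequence`, `taxon_code` and `length` (amino acids). On disk it is a plain
#' FASTA file whose headers are `accession|taxon_code`; the taxon code is
#' either a species-group identifier or one of the reserved codes
#' `AMBIGUOUS`, `LOWQ`, `UNBINNED`, `HOST`, `DIET`.
#'
#' @param database A protein database tibble.
#' @param path Path to a FASTA file.
#' @return `read_database_fasta()` returns a protein database tibble;
#'   `write_database_fasta()` returns `path` invisibly.
#' @examples
#' db <- tibble::tibble(
#'   accession = c("p1", "p2"), sequence = c("MKTAYR", "GLSDK"),
#'   taxon_code = c("sp1", "HOST"), length = c(6L, 5L)
#' )
#' f <- tempfile(fileext = ".fasta")
#' write_database_fasta(db, f)
#' read_database_fasta(f)
#' @export
write_database_fasta <- function(database, path) {
  database <- check_database(database)
  aa <- Biostrings::AAStringSet(database$sequence)
  names(aa) <- paste(database$accession, database$taxon_code, sep = "|")
  Biostrings::writeXStringSet(aa, filepath = path)
  invisible(path)
}

#' @rdname write_database_fasta
#' @export
read_database_fasta <- function(path) {
  aa <- Biostrings::readAAStringSet(path)
  parts <- stringr::str_split_fixed(names(aa), stringr::fixed("|"), 2)
  if (any(parts[, 2] == "")) {
    rlang::abort("FASTA headers must have the form `accession|taxon_code`.")
  }
  tibble::tibble(
    accession = parts[, 1],
    sequence = unname(as.character(aa)),
    taxon_code = parts[, 2],
    length = Biostrings::width(aa)
  )
}

#' Read and write peptide-spectrum match (PSM) tables
#'
#' PSM tables are TSV files with columns `sample_id`, `spectrum_id`,
#' `peptide`, `score`, `is_decoy` and `protein_ids` (semicolon-separated
#' accessions; empty for decoys). Extra columns (e.g. the generator's
#' ground-truth `is_false` flag) survive the round trip.
#'
#' @param psms A PSM tibble.
#' @param path Path to a TSV file.
#' @return A PSM tibble, or `path` invisibly for the writer.
#' @export
write_psm_tsv <- function(psms, path) {
  readr::write_tsv(psms, path, progress = FALSE)
  invisible(path)
}

#' @rdname write_psm_tsv
#' @export
read_psm_tsv <- function(path) {
  readr::read_tsv(
    path,
    col_types = readr::cols(
      sample_id = readr::col_character(),
      spectrum_id = readr::col_character(),
      peptide = readr::col_character(),
      score = readr::col_double(),
      is_decoy = readr::col_logical(),
      protein_ids = readr::col_character(),
      .default = readr::col_guess()
    ),
    progress = FALSE
  ) |>
    dplyr::mutate(protein_ids = dplyr::coalesce(.data$protein_ids, ""))
}

#' Write a distance matrix as TSV
#'
#' @param d A `dist` object or square matrix with dimnames.
#' @param path Output path.
#' @export
write_distance_tsv <- function(d, path) {
  m <- as.matrix(d)
  readr::write_tsv(
    tibble::as_tibble(m, rownames = "sample_id"), path, progress = FALSE
  )
  invisible(path)
}
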