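## Internal helpers shared across modules.

# A seed must stay a 32-bit integer; derive stage seeds by small offsets.
check_seed <- function(seed) {
  if (is.null(seed) || length(seed) != 1 || is.na(seed) || !is.numeric(seed)) {
    rlang::abort("`seed` must be a single integer.")
  }
  as.integer(seed %% .Machine$integer.max)
}

derive_seed <- function(seed, offset) {
  as.integer((as.double(seed) + 1000003 * offset) %% .Machine$integer.max)
}

check_count <- function(x, name, min = 1L) {
  if (length(x) != 1 || is.na(x) || !is.numeric(x) || x < min || x != floor(x)) {
    rlang::abort(sprintf("`%s` must be a single integer >= %d.", name, min))
  }
  as.integer(x)
}

check_fraction <- function(x, name, lo = 0, hi = 1, lo_open = FALSE, hi_open = FALSE) {
  ok <- length(x) == 1 && is.numeric(x) && !is.na(x) &&
    (if (lo_open) x > lo else x >= lo) &&
    (if (hi_open) x < hi else x <= hi)
  if (!ok) {
    rlang::abort(sprintf(
      "`%s` must be a single number in %s%g, %g%s.",
      name, if (lo_open) "(" else "[", lo, hi, if (hi_open) ")" else "]"
    ))
  }
  as.double(x)
}

check_database <- function(database) {
  need <- c("accession", "sequence", "taxon_code", "length")
  if (!is.data.frame(database) || !all(need %in% names(database))) {
    rlang::abort(paste0(
      "`database` must be a data frame with columns ",
      paste(need, collapse = ", "), "."
    ))
  }
  if (anyDuplicated(database$accession)) {
    rlang::abort("`database` accessions must be unique.")
  }
  tibble::as_tibble(database)
}

# Split semicolon-separated protein id strings into a list column.
split_ids <- function(x) strsplit(x, ";", fixed = TRUE)

join_ids <- function(x) vapply(x, paste, character(1), collapse = ";")
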