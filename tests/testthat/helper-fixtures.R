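## Small fixtures built in code.

# A community with no contamination partitions: species PSM shares equal
# biomass fractions exactly in expectation.
clean_community <- function(n_species, alpha = 0.5, seed = 1) {
  generate_community(
    n_species, dirichlet_alpha = alpha,
    host_fraction = 0, diet_fraction = 0,
    lowq_fraction = 0, unbinned_fraction = 0, seed = seed
  )
}

# Hand-built protein quantification rows.
quant_row <- function(sample_id, accession, count, n_unique, taxon,
                      n_unique_study = n_unique) {
  tibble::tibble(
    sample_id = sample_id, accession = accession,
    spectral_count = as.integer(count),
    n_unique_peptides = as.integer(n_unique),
    n_unique_peptides_study = as.integer(n_unique_study),
    taxon_code = taxon
  )
}

toy_database <- function() {
  tibble::tibble(
    accession = c("pA1", "pA2", "pB1", "pH1", "pD1"),
    sequence = c("MKAAAAR", "MKCCCCR", "MKDDDDR", "MKEEEER", "MKFFFFR"),
    taxon_code = c("spA", "spA", "spB", "HOST", "DIET"),
    length = 7L
  )
}

# A PSM row with explicit fields.
psm_row <- function(sample = "S1", spectrum, peptide, score, decoy = FALSE,
                    proteins = "") {
  tibble::tibble(
    sample_id = sample, spectrum_id = as.character(spectrum),
    peptide = peptide, score = score, is_decoy = decoy,
    protein_ids = proteins
  )
}

# Random amino-acid sequence (no K/R interior semantics needed here).
random_seq <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "D", "E", "F", "G", "H", "I", "L", "M",
                 "N", "P", "Q", "S", "T", "V", "W", "Y"), n, replace = TRUE),
        collapse = "")
}

# Mutate `n_sub` positions of a sequence to a different residue.
mutate_seq <- function(s, n_sub) {
  v <- strsplit(s, "")[[1]]
  pos <- sample(seq_along(v), n_sub)
  for (p in pos) {
    v[p] <- sample(setdiff(c("A", "C", "D", "E", "G"), v[p]), 1)
  }
  paste(v, collapse = "")
}
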