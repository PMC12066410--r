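## Percent-identity machinery for database construction. Identity is defined
## as matches in an optimal global alignment divided by the shorter sequence
## length (the CD-HIT `-c` convention), scored match = +1, mismatch = -1,
## gap = -1 per residue: only %identity matters, so no BLOSUM weighting.

identity_submat <- function() {
  letters <- c(AA_INTERIOR, "K", "R", "U", "O", "B", "J", "Z", "X", "*")
  m <- matrix(-1, length(letters), length(letters),
              dimnames = list(letters, letters))
  diag(m) <- 1
  m
}

#' Global-alignment percent identity between two sequences
#'
#' Needleman-Wunsch alignment (via [Biostrings::pairwiseAlignment()]) with
#' unit match/mismatch/gap scores; identity is the number of aligned
#' identical residues divided by the length of the shorter sequence.
#'
#' @param a,b Amino-acid sequence strings.
#' @return Identity in `[0, 1]`.
#' @examples
#' seq_identity("MKTAYR", "MKTAYR")  # 1
#' @export
seq_identity <- function(a, b) {
  if (nchar(a) == 0 || nchar(b) == 0) rlang::abort("Sequences must be non-empty.")
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b),
    type = "global", substitutionMatrix = identity_submat(),
    gapOpening = 0, gapExtension = 1
  )
  Biostrings::nmatch(aln) / min(nchar(a), nchar(b))
}

# Exact-guarantee k-mer prefilter: if identity >= c, the alignment's match
# runs (contiguous in both sequences) include one of length >=
# ceil(ceil(c*L) / (floor((1-c)*L) + 1)) where L is the shorter length, so
# the absence of a shared k-mer of that size proves identity < c.
prefilter_k <- function(len_a, len_b, threshold) {
  L <- min(len_a, len_b)
  m <- ceiling(threshold * L)
  e <- floor((1 - threshold) * L)
  max(1L, as.integer(ceiling(m / (e + 1))))
}

has_shared_kmer <- function(a, b, k) {
  if (nchar(a) < k || nchar(b) < k) return(nchar(a) >= 1 && a == b)
  short <- if (nchar(a) <= nchar(b)) a else b
  long <- if (nchar(a) <= nchar(b)) b else a
  kmers <- unique(substring(short, seq_len(nchar(short) - k + 1),
                            seq_len(nchar(short) - k + 1) + k - 1))
  any(vapply(kmers, function(x) grepl(x, long, fixed = TRUE), logical(1)))
}

# Does `query` match any of `subjects` at >= threshold identity? The k-mer
# screen never discards a pair that could pass.
matches_any <- function(query, subjects, threshold) {
  for (s in subjects) {
    k <- prefilter_k(nchar(query), nchar(s), threshold)
    if (!has_shared_kmer(query, s, k)) next
    if (seq_identity(query, s) >= threshold) return(TRUE)
  }
  FALSE
}
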