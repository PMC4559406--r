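## Shared fixtures, generated in code (no data files).

random_peptides <- function(n, len_range = c(5, 30), seed = 1) {
  aa <- amino_acids()
  set.seed(seed)
  lens <- sample.int(len_range[2] - len_range[1] + 1, n, replace = TRUE) +
    len_range[1] - 1
  vapply(lens, function(L)
    paste(sample(aa, L, replace = TRUE), collapse = ""), character(1))
}

## Small perfectly separable dataset: positives all-Cys, negatives all-Ala
## (plus a sprinkle of other residues so features are not constant).
separable_set <- function(n_per_class = 15, seed = 3) {
  set.seed(seed)
  pos <- vapply(seq_len(n_per_class), function(i)
    paste(sample(c(rep("C", 8), "G", "S"), 10), collapse = ""), character(1))
  neg <- vapply(seq_len(n_per_class), function(i)
    paste(sample(c(rep("A", 8), "L", "V"), 10), collapse = ""), character(1))
  peptide_set(c(sprintf("p%d", seq_len(n_per_class)),
                sprintf("n%d", seq_len(n_per_class))),
              c(pos, neg),
              label = rep(c("positive", "negative"), each = n_per_class))
}

## Brute-force oracle: expand a gapped motif into every concrete string
## (each gap -> nothing or each of the 20 residues) and substring-search.
motif_matches_oracle <- function(motif, sequence) {
  el <- strsplit(motif, "", fixed = TRUE)[[1]]
  expansions <- ""
  for (e in el) {
    expansions <- if (e == "-")
      c(expansions, as.vector(outer(expansions, amino_acids(), paste0)))
    else paste0(expansions, e)
  }
  any(vapply(unique(expansions), function(p)
    grepl(p, sequence, fixed = TRUE), logical(1)))
}

## Small cached synthetic study (shared across test files).
study_small <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- synthetic_study_data(n_clusters = 30, n_curated = 55,
                                     n_independent = 6,
                                     length_range = c(5, 30), seed = 11)
    cache
  }
})
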