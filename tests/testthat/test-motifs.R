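test_that("gap elements match zero or one arbitrary residue", {
  expect_true(motif_matches("CG-G", "CGAG"))   # gap consumes A
  expect_true(motif_matches("CG-G", "CGG"))    # gap consumes nothing
  expect_false(motif_matches("CG-G", "CAG"))
  expect_true(motif_matches("TC", "ATCG"))
  expect_false(motif_matches("TC", "ACTG"))    # contiguity required
  expect_error(motif_matches("-CG", "ACG"), "start or end")
  expect_error(motif_matches("C?G", "ACG"), "invalid motif element")
})

test_that("matcher agrees with the exhaustive-expansion oracle", {
  set.seed(33)
  aa <- amino_acids()
  seqs <- random_peptides(40, c(5, 15), seed = 33)
  for (i in 1:100) {
    len <- sample(2:4, 1)
    el <- sample(aa, len, replace = TRUE)
    ## insert at most one gap at an internal boundary
    if (len >= 2 && runif(1) < 0.5) {
      at <- sample(seq_len(len - 1), 1)
      el <- append(el, "-", after = at)
    }
    motif <- paste(el, collapse = "")
    s <- sample(seqs, 1)
    expect_equal(motif_matches(motif, s), motif_matches_oracle(motif, s),
                 info = sprintf("motif %s vs %s", motif, s))
  }
})

test_that("a forced frequent pattern is discovered with full support", {
  pos <- peptide_set(sprintf("p%d", 1:20), rep("TC", 20), label = "positive")
  neg <- peptide_set(sprintf("n%d", 1:20), rep("GA", 20), label = "negative")
  ms <- enumerate_motifs(pos, neg, min_support = 0.10, max_len = 3)
  tc <- ms[ms$motif == "TC", ]
  expect_equal(nrow(tc), 1)
  expect_equal(tc$support_pos, 20L)
  expect_equal(tc$support_neg, 0L)
  expect_equal(tc$propensity, 1)
})

test_that("enumeration equals a brute-force generator on a small space", {
  set.seed(35)
  pos <- peptide_set(sprintf("p%d", 1:10), random_peptides(10, c(5, 8),
                                                           seed = 36),
                     label = "positive")
  neg <- peptide_set(sprintf("n%d", 1:10), random_peptides(10, c(5, 8),
                                                           seed = 37),
                     label = "negative")
  ms <- enumerate_motifs(pos, neg, min_support = 0.3, max_gaps = 1,
                         max_len = 3)
  ## brute force: every residue/gap string up to 3 elements obeying the
  ## grammar (no leading/trailing gap, no double gap, <= 1 gap)
  aa <- amino_acids()
  cand <- c(aa,
            as.vector(outer(aa, aa, paste0)),
            as.vector(outer(as.vector(outer(aa, aa, paste0)), aa, paste0)),
            as.vector(outer(aa, aa, function(x, y) paste0(x, "-", y))))
  threshold <- ceiling(0.3 * nrow(pos))
  brute <- cand[vapply(cand, function(m)
    sum(vapply(pos$sequence, motif_matches_oracle, logical(1), motif = m)) >=
      threshold, logical(1))]
  expect_setequal(ms$motif, brute)
})

test_that("support is anti-monotone and enumeration is deterministic", {
  sd <- study_small()
  ms1 <- enumerate_motifs(sd$positive, sd$negative, min_support = 0.2,
                          max_len = 5)
  ms2 <- enumerate_motifs(sd$positive, sd$negative, min_support = 0.2,
                          max_len = 5)
  expect_identical(ms1, ms2)
  ## every extension has support <= its parent's
  sup <- stats::setNames(ms1$support_pos, ms1$motif)
  for (m in ms1$motif) {
    parent <- sub("-?[A-Z]$", "", m)
    if (parent %in% names(sup))
      expect_lte(sup[[m]], sup[[parent]])
  }
  ## no duplicates, grammar respected
  expect_false(any(duplicated(ms1$motif)))
  expect_false(any(grepl("--", ms1$motif, fixed = TRUE)))
  expect_false(any(grepl("^-|-$", ms1$motif)))
})

test_that("motif propensity equals the occurrence-fraction ratio", {
  pos <- peptide_set(sprintf("p%d", 1:10),
                     c(rep("ACCA", 5), rep("GGGG", 5)), label = "positive")
  neg <- peptide_set(sprintf("n%d", 1:10),
                     c(rep("ACCA", 5), rep("LLLL", 5)), label = "negative")
  ## equal occurrence fractions -> 0.5
  expect_equal(motif_propensity("CC", pos, neg), 0.5)
  ## present only in positives -> 1
  expect_equal(motif_propensity("GG", pos, neg), 1)
  ## absent everywhere -> NA
  expect_true(is.na(motif_propensity("WW", pos, neg)))
  ## direct recomputation from raw match counts
  sd <- study_small()
  ms <- enumerate_motifs(sd$positive, sd$negative, min_support = 0.2,
                         max_len = 4)
  for (m in utils::head(ms$motif, 10)) {
    fp <- mean(motif_matches(m, sd$positive$sequence))
    fn <- mean(motif_matches(m, sd$negative$sequence))
    expect_equal(ms$propensity[ms$motif == m], fp / (fp + fn))
  }
})

test_that("propensity filtering respects threshold and order", {
  sd <- study_small()
  ms <- enumerate_motifs(sd$positive, sd$negative, min_support = 0.2,
                         max_len = 4)
  f0 <- filter_motifs(ms, 0)
  expect_equal(f0$motif, ms$motif)
  f9 <- filter_motifs(ms, 0.9)
  expect_true(all(f9$propensity >= 0.9))
  expect_equal(f9$motif, ms$motif[!is.na(ms$propensity) &
                                    ms$propensity >= 0.9])
  expect_equal(nrow(filter_motifs(ms, 1 + 1e-9)), 0)
  expect_error(enumerate_motifs(sd$positive, sd$negative, min_support = 0),
               "min_support")
})
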