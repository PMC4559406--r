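test_that("mean composition averages per-peptide compositions", {
  ps <- peptide_set(c("a", "b"), c("AA", "CC"))
  mc <- mean_composition(ps)
  expect_equal(unname(mc[c("A", "C")]), c(50, 50))
  expect_equal(sum(mc), 100, tolerance = 1e-12)
  single <- peptide_set("x", "ACDEFG")
  expect_equal(mean_composition(single), aac("ACDEFG"))
  expect_error(mean_composition(peptide_set(character(0), character(0))),
               "empty")
})

test_that("residue propensity follows the composition ratio", {
  comp <- swissprot_composition()
  ## equal compositions -> 0.5 everywhere
  pt <- residue_propensity(comp, comp)
  expect_equal(pt$propensity, rep(0.5, 20))
  ## boundary: reference zero -> 1
  ref0 <- comp; ref0["C"] <- 0
  expect_equal(residue_propensity(comp, ref0)$propensity[
    match("C", amino_acids())], 1)
  ## direct one-line recomputation on arbitrary compositions
  set.seed(8)
  p <- stats::setNames(runif(20), amino_acids()); p <- 100 * p / sum(p)
  s <- stats::setNames(runif(20), amino_acids()); s <- 100 * s / sum(s)
  pt <- residue_propensity(p, s)
  expect_equal(pt$propensity, unname(p / (p + s)))
  expect_error(residue_propensity(-p, s), "non-negative")
})

test_that("propensity ratio is antisymmetric in its arguments", {
  set.seed(15)
  for (i in 1:20) {
    a <- stats::setNames(runif(20, 0.1, 10), amino_acids())
    b <- stats::setNames(runif(20, 0.1, 10), amino_acids())
    expect_equal(residue_propensity(a, b)$propensity +
                   residue_propensity(b, a)$propensity, rep(1, 20))
  }
})

test_that("synthetic positives rank the signature residues on top", {
  sd <- synthetic_study_data(n_clusters = 120, n_curated = 120,
                             n_independent = 10, seed = 19)
  pt <- residue_propensity(mean_composition(sd$positive),
                           swissprot_composition())
  top5 <- pt$residue[order(-pt$propensity)][1:5]
  ## the class signature puts Cys and Trp among the most preferred residues
  expect_true(all(c("C", "W") %in% top5))
  expect_true(all(top5 %in% c("C", "W", "S", "R", "P", "T", "G")))
})

test_that("positional propensities match a brute-force positional tally", {
  ps <- peptide_set(sprintf("p%d", 1:40),
                    random_peptides(40, c(6, 20), seed = 23))
  ref <- swissprot_composition()
  pp <- positional_propensity(ps, ref, k = 5)
  ## brute-force N3 tally for one residue
  lens <- nchar(ps$sequence)
  third <- substr(ps$sequence[lens >= 3], 3, 3)
  for (r in c("A", "C", "G")) {
    f <- 100 * sum(third == r) / length(third)
    expect_equal(unname(pp$frequency["N3", r]), f)
    expect_equal(unname(pp$propensity["N3", r]), f / (f + ref[[r]]))
  }
  ## C1 indexes the last residue
  last <- substr(ps$sequence, lens, lens)
  fC1 <- 100 * sum(last == "A") / length(last)
  expect_equal(unname(pp$frequency["C1", "A"]), fC1)
  ## flip_c reverses the C labelling
  ppf <- positional_propensity(ps, ref, k = 5, flip_c = TRUE)
  expect_equal(unname(ppf$frequency["C5", ]), unname(pp$frequency["C1", ]))
  expect_error(positional_propensity(ps, ref, k = 11), "at most 10")
})

test_that("degenerate first position gives the boundary propensity", {
  ps <- peptide_set(sprintf("p%d", 1:10),
                    paste0("C", random_peptides(10, c(6, 10), seed = 24)))
  ref <- swissprot_composition()
  pp <- positional_propensity(ps, ref, k = 3)
  expect_equal(unname(pp$frequency["N1", "C"]), 100)
  expect_equal(unname(pp$propensity["N1", "C"]), 100 / (100 + ref[["C"]]))
})

test_that("positional frequencies are null for uniform peptides", {
  set.seed(30)
  seqs <- vapply(1:1000, function(i)
    paste(sample(amino_acids(), 12, replace = TRUE), collapse = ""),
    character(1))
  ps <- peptide_set(sprintf("p%d", 1:1000), seqs)
  uniform_ref <- stats::setNames(rep(5, 20), amino_acids())
  pp <- positional_propensity(ps, uniform_ref, k = 5)
  ## all 200 cells near the null (5 SE of a binomial proportion at p = 1/20:
  ## across 200 cells the chance of any exceedance is ~1e-4)
  se <- sqrt(0.05 * 0.95 / 1000) * 100
  expect_true(all(abs(pp$frequency - 5) < 5 * se))
  ## propagate the frequency band through p = f / (f + 5)
  expect_true(all(abs(pp$propensity - 0.5) < 5 * se * 0.05 + 0.01))
})

test_that("two-sample enrichment flags degenerate separation and identity", {
  same <- peptide_set(sprintf("p%d", 1:20),
                      random_peptides(20, c(8, 12), seed = 26))
  same2 <- peptide_set(paste0("q", 1:20), same$sequence)
  em <- two_sample_enrichment(same, same2, "NT", k = 5)
  expect_true(all(em$difference == 0))
  expect_true(all(em$flag == "ns"))
  ## frequencies sum to 1 per class per position
  for (p in unique(em$position)) {
    expect_equal(sum(em$freq_pos[em$position == p]), 1, tolerance = 1e-9)
    expect_equal(sum(em$freq_neg[em$position == p]), 1, tolerance = 1e-9)
  }

  pos <- peptide_set(sprintf("c%d", 1:30), rep("CCCCC", 30),
                     label = "positive")
  neg <- peptide_set(sprintf("a%d", 1:30), rep("AAAAA", 30),
                     label = "negative")
  em <- two_sample_enrichment(pos, neg, "NT", k = 5)
  cc <- em[em$residue == "C", ]
  expect_true(all(cc$difference == 1))
  expect_true(all(cc$flag == "enriched"))
  aa <- em[em$residue == "A", ]
  expect_true(all(aa$flag == "depleted"))
})

test_that("enrichment p-value matches a hand-coded two-proportion z-test", {
  sd <- study_small()
  em <- two_sample_enrichment(sd$positive, sd$negative, "NT", k = 5)
  cell <- em[which.max(abs(em$difference)), ]
  n1 <- sum(nchar(sd$positive$sequence) >= 5)
  n2 <- sum(nchar(sd$negative$sequence) >= 5)
  x1 <- round(cell$freq_pos * n1)
  x2 <- round(cell$freq_neg * n2)
  ## independent route: pooled two-proportion z statistic
  p_pool <- (x1 + x2) / (n1 + n2)
  z <- (x1 / n1 - x2 / n2) /
    sqrt(p_pool * (1 - p_pool) * (1 / n1 + 1 / n2))
  expect_equal(cell$p_value, 2 * stats::pnorm(-abs(z)), tolerance = 1e-9)
})
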