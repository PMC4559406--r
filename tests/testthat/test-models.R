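test_that("cross-validation folds cover every peptide exactly once", {
  ps <- study_small()$cv
  cv <- cross_validate(ps, "svm", "aac", "WHOLE", k = 5, seed = 2,
                       tune = FALSE)
  expect_length(cv$folds, nrow(ps))
  expect_true(all(cv$folds %in% 1:5))
  ## pooled counts equal the sum of per-fold counts and the dataset size
  total <- with(cv$pooled_counts, tp + tn + fp + fn)
  expect_equal(total, nrow(ps))
  fold_sum <- Reduce(`+`, lapply(cv$fold_metrics, function(m)
    unlist(m$counts)))
  expect_equal(unlist(cv$pooled_counts), fold_sum)
})

test_that("a separable fixture is classified perfectly by every classifier", {
  ps <- separable_set(15)
  for (cl in c("svm", "knn", "tree", "rf", "nb", "logistic", "mlp")) {
    cv <- cross_validate(ps, cl, "aac", "WHOLE", k = 5, seed = 3,
                         tune = FALSE)
    expect_gte(cv$metrics$acc, 95)
  }
  ## and resubstitution is perfect for the svm
  m <- peptide_model(ps, "svm", "aac", "WHOLE", seed = 1, tune = FALSE)
  expect_equal(evaluate(m, ps)$acc, 100)
  expect_equal(cross_validate(ps, "svm", k = 5, seed = 4,
                              tune = FALSE)$metrics$mcc, 1)
})

test_that("label-permuted data scores near-zero MCC", {
  fx <- generate_fixture_data(30, 30, length_range = c(8, 20), seed = 17)
  ps <- bind_peptides(fx$positive, fx$negative)
  mccs <- vapply(1:10, function(s) {
    set.seed(s)
    shuffled <- peptide_set(ps$id, ps$sequence, sample(ps$label))
    cross_validate(shuffled, "svm", "aac", "WHOLE", k = 5, seed = s,
                   tune = FALSE)$metrics$mcc
  }, numeric(1))
  expect_lt(abs(mean(mccs)), 0.15)
})

test_that("training is deterministic and guards feature schemas", {
  ps <- separable_set(10)
  m1 <- peptide_model(ps, "svm", "aac", "WHOLE", seed = 9, tune = FALSE)
  m2 <- peptide_model(ps, "svm", "aac", "WHOLE", seed = 9, tune = FALSE)
  probe <- random_peptides(10, c(8, 15), seed = 10)
  expect_identical(predict(m1, probe), predict(m2, probe))
  ## schema guard: AAC model refuses a DPC matrix
  fm_dpc <- encode_dataset(ps, "WHOLE", "dpc")
  expect_error(predict(m1, fm_dpc), "schema mismatch")
  ## single-class data refuses to train
  expect_error(peptide_model(ps[ps$label == "positive", ], "svm"),
               "both classes")
  expect_error(evaluate(m1, ps[0, ]), "empty|both")
})

test_that("classifier comparison shares one fold assignment", {
  ps <- separable_set(10)
  tab <- compare_classifiers(ps, c("svm", "nb"), k = 5, seed = 6,
                             tune = FALSE)
  expect_equal(nrow(tab), 2)
  folds1 <- attr(tab, "folds")
  tab2 <- compare_classifiers(ps, c("svm", "nb"), k = 5, seed = 6,
                              tune = FALSE)
  expect_identical(folds1, attr(tab2, "folds"))
  ## singleton reduction: identical to a direct cross_validate call
  cv <- cross_validate(ps, "svm", k = 5, seed = 6, tune = FALSE)
  expect_equal(tab$acc[tab$classifier == "svm"], cv$metrics$acc)
})

test_that("stability over re-sampled negative sets is deterministic", {
  sd <- study_small()
  tab1 <- stability_experiment(sd$positive, sd$background, n_repeats = 2,
                               k = 5, seed = 20, tune = FALSE)
  tab2 <- stability_experiment(sd$positive, sd$background, n_repeats = 2,
                               k = 5, seed = 20, tune = FALSE)
  expect_identical(tab1, tab2)
  expect_equal(nrow(tab1), 2)
  ## separable positives stay perfect whatever the negative draw
  sep <- separable_set(12)
  pos <- sep[sep$label == "positive", ]
  tab <- stability_experiment(pos, sd$background, n_repeats = 2, k = 4,
                              seed = 21, tune = FALSE)
  expect_true(all(tab$acc > 90))
})

test_that("cross-validated MCC rises with enrichment strength", {
  strengths <- c(1, 2, 4, 8)
  med_mcc <- vapply(strengths, function(str) {
    mccs <- vapply(1:3, function(s) {
      mult <- stats::setNames(rep(1, 20), amino_acids())
      mult[c("C", "W", "S")] <- str
      fx <- generate_fixture_data(30, 30, length_range = c(8, 20),
                                  enrichment = mult, seed = 100 * s + str)
      ps <- bind_peptides(fx$positive, fx$negative)
      cross_validate(ps, "svm", "aac", "WHOLE", k = 5, seed = s,
                     tune = FALSE)$metrics$mcc
    }, numeric(1))
    stats::median(mccs)
  }, numeric(1))
  rho <- stats::cor(seq_along(strengths), med_mcc, method = "spearman")
  expect_gt(rho, 0.9)
})

test_that("serialized models round-trip to identical predictions", {
  ps <- separable_set(10)
  probe <- random_peptides(15, c(8, 20), seed = 71)
  for (cl in c("svm", "rf", "nb", "mlp")) {
    m <- peptide_model(ps, cl, "aac", "WHOLE", seed = 5, tune = FALSE)
    f <- tempfile(fileext = ".rds")
    saveRDS(m, f)
    m2 <- readRDS(f)
    expect_identical(predict(m2, probe), predict(m, probe), label = cl)
  }
})
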