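#' Reference amino acid composition of a general protein background
#'
#' Average residue composition (percent) of the Swiss-Prot protein knowledge
#' base, the conventional reference when scoring residue preferences of a
#' peptide class against the proteome at large.
#'
#' @return Named numeric vector of length 20 summing to 100.
#' @export
swissprot_composition <- function() {
  comp <- c(A = 8.25, C = 1.37, D = 5.45, E = 6.75, F = 3.86,
            G = 7.07, H = 2.27, I = 5.96, K = 5.84, L = 9.66,
            M = 2.42, N = 4.06, P = 4.70, Q = 3.93, R = 5.53,
            S = 6.56, T = 5.34, V = 6.87, W = 1.08, Y = 2.92)
  100 * comp[AA_ALPHABET] / sum(comp)
}

#' Default positive-class enrichment multipliers
#'
#' Per-residue multipliers applied to the background composition when
#' simulating anti-angiogenic peptides: Cys, Trp, Pro, Ser, Arg, Thr and Gly
#' are boosted while Ala, Asp, Ile, Leu, Val and Phe are depressed, the
#' compositional signature reported for this peptide class. Magnitudes are
#' chosen to give a moderate class contrast (Cys strongly enriched, the rest
#' mild), not a separable toy problem.
#'
#' @return Named numeric vector of 20 positive multipliers.
#' @export
default_enrichment <- function() {
  mult <- stats::setNames(rep(1, 20), AA_ALPHABET)
  mult[c("C", "W", "P", "S", "R", "T", "G")] <-
    c(4, 2, 1.5, 1.4, 1.3, 1.3, 1.2)
  mult[c("A", "D", "I", "L", "V", "F")] <- c(0.65, 0.7, 0.65, 0.6, 0.65, 0.7)
  mult
}

## Multinomial residue probabilities from a composition and multiplier map.
residue_probs <- function(composition = swissprot_composition(),
                          enrichment = NULL) {
  p <- composition[AA_ALPHABET]
  if (!is.null(enrichment)) {
    if (any(enrichment <= 0)) stop("multipliers must be positive",
                                   call. = FALSE)
    mult <- stats::setNames(rep(1, 20), AA_ALPHABET)
    mult[names(enrichment)] <- enrichment
    p <- p * mult
  }
  p <- p / sum(p)
  if (sum(p > 1e-12) < 2)
    stop("degenerate residue distribution: all mass on fewer than 2 residues",
         call. = FALSE)
  p
}

## i.i.d. peptides from a residue distribution (caller seeds the RNG).
draw_peptides <- function(n, lengths, probs) {
  vapply(rep_len(lengths, n), function(L)
    paste(sample(AA_ALPHABET, L, replace = TRUE, prob = probs),
          collapse = ""), character(1))
}

#' Generate synthetic labelled peptide data
#'
#' Emulates the compositional contrast between anti-angiogenic peptides and
#' random background peptides: positives are drawn i.i.d. from the background
#' residue distribution re-weighted by `enrichment`; negatives and a
#' background proteome come from the unweighted distribution. Useful for
#' property tests and demonstrations that need no curated data.
#'
#' @param n_pos,n_neg Numbers of positive / negative peptides.
#' @param length_range Integer pair `(min, max)` of peptide lengths,
#'   `min >= 5`; lengths are sampled uniformly.
#' @param enrichment Named multiplier map (see [default_enrichment()]).
#' @param n_background Number of background proteins (lengths 60-300).
#' @param seed Integer seed; output is reproducible byte-for-byte.
#' @return List with `peptide_set` elements `positive`, `negative`,
#'   `background`.
#' @examples
#' fx <- generate_fixture_data(20, 20, seed = 1)
#' summary(fx$positive)
#' @export
generate_fixture_data <- function(n_pos, n_neg, length_range = c(5, 50),
                                  enrichment = default_enrichment(),
                                  n_background = 100, seed = 42) {
  if (length(length_range) != 2 || length_range[1] < 5 ||
      length_range[2] < length_range[1])
    stop("'length_range' must be (min, max) with min >= 5", call. = FALSE)
  p_pos <- residue_probs(enrichment = enrichment)
  p_bg <- residue_probs()
  with_seed(seed, {
    len_pos <- sample(length_range[1]:length_range[2], n_pos, replace = TRUE)
    len_neg <- sample(length_range[1]:length_range[2], n_neg, replace = TRUE)
    pos <- peptide_set(sprintf("pos_%03d", seq_len(n_pos)),
                       draw_peptides(n_pos, len_pos, p_pos),
                       label = "positive", source = "synthetic",
                       name = "synthetic_positive")
    neg <- peptide_set(sprintf("neg_%03d", seq_len(n_neg)),
                       draw_peptides(n_neg, len_neg, p_bg),
                       label = "negative", source = "synthetic",
                       name = "synthetic_negative")
    bg <- peptide_set(sprintf("bg_%03d", seq_len(n_background)),
                      draw_peptides(n_background,
                                    sample(60:300, n_background,
                                           replace = TRUE), p_bg),
                      label = "unlabeled", source = "synthetic background",
                      name = "synthetic_background")
    list(positive = pos, negative = neg, background = bg)
  })
}

## One synthetic anti-angiogenic-like peptide with positional structure:
## the discriminative enrichment is confined to the first `nt_window`
## residues; beyond that the composition is background, with a mild
## C/G/R preference over the last 5 residues.
draw_structured_positive <- function(L, p_enriched, p_bg, p_ct,
                                     nt_window = 15) {
  res <- character(L)
  for (j in seq_len(L)) {
    p <- if (j <= nt_window) p_enriched
         else if (j > L - 5) p_ct
         else p_bg
    res[j] <- sample(AA_ALPHABET, 1, prob = p)
  }
  paste(res, collapse = "")
}

#' Synthetic stand-in for the curated anti-angiogenic peptide study data
#'
#' Builds, from a seed alone, a complete synthetic analogue of a curated
#' peptide classification study: a redundant "literature" collection of
#' `n_curated` positives organised in `n_clusters` identity clusters (each
#' cluster one founder peptide plus near-duplicate variants differing by a
#' few substitutions, mimicking overlapping literature reports); the
#' `n_clusters` non-redundant positives; a length-matched random negative
#' set sampled from a synthetic background proteome; and a stratified split
#' into a cross-validation set and an independent evaluation set.
#'
#' Positives carry the compositional signature of anti-angiogenic peptides
#' (see [default_enrichment()]) concentrated in the first 15 residues, with
#' a mild Cys/Gly/Arg preference at the C-terminus — emulating the finding
#' that the N-terminal region carries most of the discriminative signal.
#'
#' This generator is a synthetic stand-in: it reproduces the structure and
#' approximate difficulty of the curated datasets, not their sequences.
#'
#' @param n_clusters Number of non-redundant positives (default 135).
#' @param n_curated Size of the redundant curated collection (default 257).
#' @param n_independent Held-out peptides per class (default 28).
#' @param length_range Peptide length range, sampled uniformly.
#' @param enrichment Positive-class multiplier map.
#' @param seed Integer seed.
#' @return List with elements `curated`, `positive`, `negative`,
#'   `background` ([peptide_set]s), `cv` and `independent` (balanced
#'   `peptide_set`s of both classes), and `reference` (the background
#'   composition used).
#' @export
synthetic_study_data <- function(n_clusters = 135, n_curated = 257,
                                 n_independent = 28,
                                 length_range = c(5, 50),
                                 enrichment = default_enrichment(),
                                 seed = 42) {
  stopifnot(n_curated >= n_clusters, n_independent < n_clusters)
  p_enriched <- residue_probs(enrichment = enrichment)
  p_bg <- residue_probs()
  p_ct <- residue_probs(enrichment = c(C = 2, G = 1.3, R = 1.3))

  founders <- with_seed(seed, {
    lens <- sample(length_range[1]:length_range[2], n_clusters,
                   replace = TRUE)
    out <- character(n_clusters)
    for (i in seq_len(n_clusters)) {
      repeat {
        cand <- draw_structured_positive(lens[i], p_enriched, p_bg, p_ct)
        if (i == 1 ||
            all(sequence_identity(out[seq_len(i - 1)], cand) <= 0.6)) break
      }
      out[i] <- cand
    }
    out
  })

  study <- with_seed(seed + 1L, {
    ## Redundant variants: substitutions at a per-founder fixed set of
    ## <= 8% of positions, so every variant stays > 90% identical to its
    ## founder and any two variants of one founder stay > 80% identical to
    ## each other — all well above a 70% clustering threshold.
    n_var <- n_curated - n_clusters
    parents <- sample.int(n_clusters, n_var, replace = TRUE)
    mut_sites <- lapply(founders, function(s) {
      L <- nchar(s)
      sample.int(L, max(1L, ceiling(0.08 * L)))
    })
    variants <- vapply(seq_len(n_var), function(v) {
      p <- parents[v]
      s <- strsplit(founders[p], "")[[1]]
      for (j in mut_sites[[p]]) s[j] <- sample(setdiff(AA_ALPHABET, s[j]), 1)
      paste(s, collapse = "")
    }, character(1))
    curated_seq <- c(founders, variants)
    curated_src <- c(rep("synthetic founder", n_clusters),
                     sprintf("synthetic variant of cluster %d", parents))
    shuffle <- sample.int(n_curated)
    curated <- peptide_set(sprintf("lit_%03d", seq_len(n_curated)),
                           curated_seq[shuffle], label = "positive",
                           source = curated_src[shuffle],
                           name = "synthetic_curated")

    positive <- peptide_set(sprintf("pos_%03d", seq_len(n_clusters)),
                            founders, label = "positive",
                            source = "synthetic founder",
                            name = "synthetic_positive")
    background <- peptide_set(
      sprintf("bg_%03d", 1:300),
      draw_peptides(300, sample(60:300, 300, replace = TRUE), p_bg),
      label = "unlabeled", source = "synthetic background",
      name = "synthetic_background")
    list(curated = curated, positive = positive, background = background)
  })

  negative <- sample_negative_regions(study$background, study$positive,
                                      n = n_clusters, seed = seed + 2L)
  pooled <- bind_peptides(study$positive, negative, name = "synthetic_main")
  split <- split_train_independent(pooled, fraction = n_independent /
                                     n_clusters, seed = seed + 3L)
  list(curated = study$curated, positive = study$positive,
       negative = negative, background = study$background,
       cv = split$train, independent = split$independent,
       reference = swissprot_composition())
}
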