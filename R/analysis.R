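#' Mean amino acid composition of a dataset
#'
#' The arithmetic mean over peptides of each peptide's percentage
#' composition ([aac()]), so every peptide carries equal weight regardless
#' of its length. Sums to 100.
#'
#' @param x A [peptide_set] (non-empty).
#' @return Named numeric vector of length 20.
#' @export
mean_composition <- function(x) {
  stopifnot(inherits(x, "peptide_set"))
  if (nrow(x) == 0) stop("dataset is empty", call. = FALSE)
  colMeans(encode_dataset(x, "WHOLE", "aac"))
}

#' Residue propensity against a reference composition
#'
#' For each residue i, the propensity is
#' `P(i) = AACp(i) / (AACp(i) + AACs(i))`, where `AACp` is the composition
#' in the peptide class of interest and `AACs` the reference composition
#' (both on the same percentage scale). 0.5 means no preference; values
#' above 0.5 mark residues over-represented relative to the reference.
#' Residues absent from both compositions have undefined propensity and are
#' reported as `NA`.
#'
#' @param positive_comp Named 20-vector of percentages (class of interest).
#' @param reference_comp Named 20-vector of percentages (reference), e.g.
#'   [swissprot_composition()].
#' @return A data frame of class `propensity_table` with columns `residue`,
#'   `comp_positive`, `comp_reference`, `propensity`.
#' @export
residue_propensity <- function(positive_comp,
                               reference_comp = swissprot_composition()) {
  p <- positive_comp[AA_ALPHABET]
  s <- reference_comp[AA_ALPHABET]
  if (any(p < 0, na.rm = TRUE) || any(s < 0, na.rm = TRUE))
    stop("compositions must be non-negative", call. = FALSE)
  denom <- p + s
  prop <- ifelse(denom > 0, p / denom, NA_real_)
  out <- data.frame(residue = AA_ALPHABET, comp_positive = as.numeric(p),
                    comp_reference = as.numeric(s),
                    propensity = as.numeric(prop))
  class(out) <- c("propensity_table", "data.frame")
  out
}

#' @export
print.propensity_table <- function(x, digits = 3, ...) {
  cat("Residue propensities (0.5 = no preference)\n")
  df <- as.data.frame(x)
  df$propensity <- round(df$propensity, digits)
  print(df[order(-df$propensity), ], row.names = FALSE)
  invisible(x)
}

## Per-position residue frequency (%) for positions N1..Nk or C1..Ck.
## C1 is the LAST residue, C2 the second-to-last, and so on; `flip_c = TRUE`
## reverses that convention. Peptides shorter than the window contribute
## only their existing positions.
position_frequencies <- function(x, terminus = c("N", "C"), k = 10,
                                 flip_c = FALSE) {
  terminus <- match.arg(terminus)
  freq <- matrix(NA_real_, nrow = k, ncol = 20,
                 dimnames = list(paste0(terminus, seq_len(k)), AA_ALPHABET))
  n_at <- integer(k)
  lens <- nchar(x$sequence)
  for (j in seq_len(k)) {
    has <- lens >= j
    n_at[j] <- sum(has)
    if (n_at[j] == 0) next
    pos <- if (terminus == "N") j else lens[has] - j + 1
    res <- substr(x$sequence[has], pos, pos)
    freq[j, ] <- 100 * as.numeric(table(factor(res, levels = AA_ALPHABET))) /
      n_at[j]
  }
  if (terminus == "C" && flip_c) {
    freq <- freq[rev(seq_len(k)), , drop = FALSE]
    rownames(freq) <- paste0("C", seq_len(k))
    n_at <- rev(n_at)
  }
  list(freq = freq, n = n_at)
}

#' Positional residue propensities at the peptide termini
#'
#' For each of the first k (`N1..Nk`) and last k (`C1..Ck`) positions, the
#' per-residue frequency among peptides long enough to have that position is
#' combined with the reference composition through the same ratio as
#' [residue_propensity()], both operands on the percentage scale. By the
#' package convention `C1` is the last residue and `Ck` the k-th from the
#' end; set `flip_c = TRUE` for the opposite labelling.
#'
#' @param x A [peptide_set].
#' @param reference_comp Named 20-vector of reference percentages.
#' @param k Window length, at most 10.
#' @param flip_c Reverse the C-position labelling (default `FALSE`).
#' @return A list of class `positional_propensity` with matrices
#'   `propensity` (2k x 20), `frequency` (2k x 20, percent) and vector `n`
#'   (peptides contributing per position).
#' @export
positional_propensity <- function(x, reference_comp = swissprot_composition(),
                                  k = 10, flip_c = FALSE) {
  stopifnot(inherits(x, "peptide_set"))
  if (nrow(x) == 0) stop("dataset is empty", call. = FALSE)
  if (k > 10) stop("'k' must be at most 10", call. = FALSE)
  nf <- position_frequencies(x, "N", k)
  cf <- position_frequencies(x, "C", k, flip_c = flip_c)
  freq <- rbind(nf$freq, cf$freq)
  ref <- matrix(reference_comp[AA_ALPHABET], nrow = nrow(freq), ncol = 20,
                byrow = TRUE)
  denom <- freq + ref
  prop <- ifelse(denom > 0, freq / denom, NA_real_)
  dimnames(prop) <- dimnames(freq)
  structure(list(propensity = prop, frequency = freq,
                 n = c(nf$n, cf$n)),
            class = "positional_propensity")
}

#' @export
print.positional_propensity <- function(x, digits = 2, ...) {
  cat("Positional propensities (rows: positions, C1 = last residue)\n")
  print(round(x$propensity, digits))
  invisible(x)
}

#' Per-position residue enrichment between two peptide classes
#'
#' The numeric core of a two-sample logo: for each aligned terminus position
#' and each residue, the residue frequency in the positive and negative
#' class, their difference, a two-proportion z-test p-value, and an
#' enriched/depleted flag (difference sign at p < `alpha`, no
#' multiple-testing correction, mirroring the conventional two-sample-logo
#' default).
#'
#' @param pos,neg Non-empty [peptide_set]s.
#' @param region `"NT"` (positions from the N-terminus) or `"CT"` (positions
#'   counted from the last residue, C1 = last).
#' @param k Window length.
#' @param alpha Significance level for flags (default 0.05).
#' @return A data frame of class `enrichment_matrix` with one row per
#'   (position, residue): columns `position`, `residue`, `freq_pos`,
#'   `freq_neg` (proportions), `difference`, `p_value`, `flag`.
#' @export
two_sample_enrichment <- function(pos, neg, region = c("NT", "CT"), k = 10,
                                  alpha = 0.05) {
  stopifnot(inherits(pos, "peptide_set"), inherits(neg, "peptide_set"))
  if (nrow(pos) == 0 || nrow(neg) == 0)
    stop("both datasets must be non-empty", call. = FALSE)
  region <- match.arg(region)
  term <- if (region == "NT") "N" else "C"
  fp <- position_frequencies(pos, term, k)
  fn <- position_frequencies(neg, term, k)
  rows <- list()
  for (j in seq_len(k)) {
    if (fp$n[j] == 0 || fn$n[j] == 0) next
    for (r in AA_ALPHABET) {
      p1 <- fp$freq[j, r] / 100
      p2 <- fn$freq[j, r] / 100
      x1 <- round(p1 * fp$n[j])
      x2 <- round(p2 * fn$n[j])
      pval <- if (x1 + x2 == 0 || x1 + x2 == fp$n[j] + fn$n[j]) 1 else
        suppressWarnings(stats::prop.test(c(x1, x2), c(fp$n[j], fn$n[j]),
                                          correct = FALSE)$p.value)
      flag <- if (pval < alpha && p1 > p2) "enriched"
              else if (pval < alpha && p1 < p2) "depleted" else "ns"
      rows[[length(rows) + 1]] <- data.frame(
        position = rownames(fp$freq)[j], residue = r, freq_pos = p1,
        freq_neg = p2, difference = p1 - p2, p_value = pval, flag = flag)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("enrichment_matrix", "data.frame")
  out
}

#' @export
print.enrichment_matrix <- function(x, ...) {
  sig <- x[x$flag != "ns", ]
  cat(sprintf("Two-sample enrichment: %d position-residue cells, %d flagged\n",
              nrow(x), nrow(sig)))
  if (nrow(sig) > 0) print(as.data.frame(sig), row.names = FALSE)
  invisible(x)
}
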