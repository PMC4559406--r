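## Gapped sequence motifs are written in the field's text notation:
## residues with '-' for a gap, e.g. "CG-G" or "W-S-C". A gap matches the
## presence OR absence of a single arbitrary residue (zero-or-one). Motifs
## never start or end with a gap and never contain two consecutive gaps.

## Split "CG-G" into elements c("C","G","-","G"), with validation.
motif_elements <- function(motif) {
  el <- strsplit(motif, "", fixed = TRUE)[[1]]
  if (length(el) == 0) stop("empty motif", call. = FALSE)
  if (el[1] == GAP_CHAR || el[length(el)] == GAP_CHAR)
    stop(sprintf("motif '%s' must not start or end with a gap", motif),
         call. = FALSE)
  bad <- !el %in% c(AA_ALPHABET, GAP_CHAR)
  if (any(bad))
    stop(sprintf("invalid motif element '%s' in '%s'", el[bad][1], motif),
         call. = FALSE)
  el
}

## Translate a motif to an (unanchored) regular expression.
motif_regex <- function(motif) {
  el <- motif_elements(motif)
  paste(ifelse(el == GAP_CHAR, ".?", el), collapse = "")
}

#' Match a gapped motif against peptide sequences
#'
#' A motif occurs in a sequence if it matches at some offset, a residue
#' element matching only itself and a gap (`-`) matching zero or one
#' arbitrary residue (both readings tried).
#'
#' @param motif Motif string, e.g. `"CG-G"`.
#' @param sequences Character vector of peptide sequences.
#' @return Logical vector, one element per sequence.
#' @examples
#' motif_matches("CG-G", c("CGAG", "CGG", "CAG"))  # TRUE TRUE FALSE
#' @export
motif_matches <- function(motif, sequences) {
  grepl(motif_regex(motif), sequences, perl = TRUE)
}

## Peptide-level support: number of sequences containing >= 1 match.
motif_support <- function(motif, sequences) sum(motif_matches(motif,
                                                              sequences))

#' Motif propensity against a negative dataset
#'
#' The class preference of a motif, computed with the same ratio as residue
#' propensities but on peptide-level occurrence fractions:
#' `f_pos / (f_pos + f_neg)` where `f_pos` and `f_neg` are the fractions of
#' positive and negative peptides containing the motif. A motif absent from
#' both sets has undefined propensity (`NA`).
#'
#' @param motif Motif string.
#' @param pos,neg Non-empty [peptide_set]s.
#' @return A single numeric value in \[0, 1\] or `NA`.
#' @export
motif_propensity <- function(motif, pos, neg) {
  stopifnot(inherits(pos, "peptide_set"), inherits(neg, "peptide_set"))
  f_pos <- motif_support(motif, pos$sequence) / nrow(pos)
  f_neg <- motif_support(motif, neg$sequence) / nrow(neg)
  if (f_pos + f_neg == 0) return(NA_real_)
  f_pos / (f_pos + f_neg)
}

#' Discriminative gapped motif discovery
#'
#' Level-wise enumeration of gapped motifs frequent in the positive class:
#' single residues seed the search, and every frequent motif is extended on
#' the right by one residue or by a gap followed by a residue (so motifs
#' never end in a gap and never hold two consecutive gaps), within a gap
#' budget and a maximum element length. A motif is retained when it occurs
#' in at least `ceil(min_support * n_pos)` positive peptides; extensions of
#' infrequent motifs are pruned (support is anti-monotone under extension).
#' Negative-set support and propensity are then computed for every frequent
#' motif.
#'
#' @param pos,neg Non-empty [peptide_set]s (positives drive the search;
#'   negatives only score).
#' @param min_support Minimum fraction of positive peptides containing the
#'   motif, in (0, 1\]; default 0.10.
#' @param max_gaps Maximum number of gap elements per motif (default 5).
#' @param max_len Maximum number of motif elements, gaps included
#'   (default 8).
#' @return A data frame of class `motif_set`, sorted by propensity then
#'   positive support (both decreasing), with columns `motif`, `n_gaps`,
#'   `support_pos`, `support_neg`, `propensity`. Discovery parameters are
#'   attached as attribute `"params"`.
#' @examples
#' pos <- peptide_set(paste0("p", 1:4), rep("ATCG", 4), label = "positive")
#' neg <- peptide_set(paste0("n", 1:4), rep("LMKH", 4), label = "negative")
#' enumerate_motifs(pos, neg, min_support = 0.5, max_len = 3)
#' @export
enumerate_motifs <- function(pos, neg, min_support = 0.10, max_gaps = 5,
                             max_len = 8) {
  stopifnot(inherits(pos, "peptide_set"), inherits(neg, "peptide_set"))
  if (nrow(pos) == 0 || nrow(neg) == 0)
    stop("both datasets must be non-empty", call. = FALSE)
  if (!is.numeric(min_support) || min_support <= 0 || min_support > 1)
    stop("'min_support' must be in (0, 1]", call. = FALSE)
  threshold <- ceiling(min_support * nrow(pos))

  seqs <- pos$sequence
  frequent <- character(0)
  support <- integer(0)
  level <- AA_ALPHABET
  parent_support <- stats::setNames(rep.int(nrow(pos), 20), AA_ALPHABET)
  while (length(level) > 0) {
    sup <- vapply(level, motif_support, integer(1), sequences = seqs)
    ## anti-monotonicity guard: no child may exceed its parent's support
    stopifnot(all(sup <= parent_support[level]))
    keep <- sup >= threshold
    frequent <- c(frequent, level[keep])
    support <- c(support, sup[keep])
    nxt <- character(0)
    nxt_parent <- integer(0)
    for (m in level[keep]) {
      n_el <- nchar(m)
      n_gap <- lengths(regmatches(m, gregexpr(GAP_CHAR, m, fixed = TRUE)))
      ext <- character(0)
      if (n_el + 1 <= max_len) ext <- paste0(m, AA_ALPHABET)
      if (n_gap < max_gaps && n_el + 2 <= max_len)
        ext <- c(ext, paste0(m, GAP_CHAR, AA_ALPHABET))
      nxt <- c(nxt, ext)
      nxt_parent <- c(nxt_parent, rep.int(sup[match(m, level)], length(ext)))
    }
    parent_support <- stats::setNames(nxt_parent, nxt)
    level <- nxt
  }

  support_neg <- vapply(frequent, motif_support, integer(1),
                        sequences = neg$sequence)
  f_pos <- support / nrow(pos)
  f_neg <- support_neg / nrow(neg)
  prop <- ifelse(f_pos + f_neg > 0, f_pos / (f_pos + f_neg), NA_real_)
  out <- data.frame(motif = frequent, n_gaps = vapply(
    frequent, function(m) sum(strsplit(m, "")[[1]] == GAP_CHAR), integer(1)),
    support_pos = as.integer(support), support_neg = as.integer(support_neg),
    propensity = prop)
  out <- out[order(-out$propensity, -out$support_pos, out$motif), ]
  rownames(out) <- NULL
  class(out) <- c("motif_set", "data.frame")
  attr(out, "params") <- list(min_support = min_support,
                              max_gaps = max_gaps, max_len = max_len,
                              n_pos = nrow(pos), n_neg = nrow(neg),
                              support_threshold = threshold)
  out
}

#' Filter a motif set by propensity
#'
#' @param motifs A `motif_set` from [enumerate_motifs()].
#' @param min_propensity Retain motifs with propensity at or above this
#'   value (default 0.90).
#' @return The filtered `motif_set`, order preserved.
#' @export
filter_motifs <- function(motifs, min_propensity = 0.90) {
  stopifnot(inherits(motifs, "motif_set"))
  out <- motifs[!is.na(motifs$propensity) &
                  motifs$propensity >= min_propensity, ]
  rownames(out) <- NULL
  class(out) <- c("motif_set", "data.frame")
  attr(out, "params") <- c(attr(motifs, "params"),
                           list(min_propensity = min_propensity))
  out
}

#' @export
print.motif_set <- function(x, n = 20, ...) {
  p <- attr(x, "params")
  cat(sprintf("<motif_set> %d motifs (support >= %d positives)\n", nrow(x),
              p$support_threshold %||% NA))
  print(utils::head(as.data.frame(x), n), row.names = FALSE)
  if (nrow(x) > n) cat(sprintf("... %d more\n", nrow(x) - n))
  invisible(x)
}
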