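#' Stratified train / independent split
#'
#' Holds out `round(fraction * n)` records per class label uniformly at
#' random; the remainder forms the training portion. The two partitions are
#' disjoint and their union is the input.
#'
#' @param x A [peptide_set].
#' @param fraction Held-out fraction per label, in (0, 1).
#' @param seed Integer seed controlling the draw.
#' @return A list with `peptide_set` elements `train` and `independent`.
#' @examples
#' ps <- peptide_set(paste0("p", 1:10), strrep(c("AC", "GH"), 5),
#'                   label = rep(c("positive", "negative"), each = 5))
#' sp <- split_train_independent(ps, 0.2, seed = 1)
#' nrow(sp$independent)  # 2 (1 per class)
#' @export
split_train_independent <- function(x, fraction = 0.2, seed = 42) {
  stopifnot(inherits(x, "peptide_set"))
  if (!is.numeric(fraction) || fraction <= 0 || fraction >= 1)
    stop("'fraction' must be in (0, 1)", call. = FALSE)
  idx_held <- with_seed(seed, {
    unlist(lapply(split(seq_len(nrow(x)), x$label), function(idx) {
      n_out <- round(fraction * length(idx))
      if (n_out == 0 || n_out == length(idx))
        stop(sprintf("fraction %.3g produces an empty partition for a label",
                     fraction), call. = FALSE)
      sample(idx, n_out)
    }), use.names = FALSE)
  })
  list(
    train = subset_peptides(x, setdiff(seq_len(nrow(x)), idx_held),
                            name = paste0(attr(x, "name") %||% "", "_train")),
    independent = subset_peptides(x, sort(idx_held),
                                  name = paste0(attr(x, "name") %||% "",
                                                "_independent"))
  )
}

#' Sample length-matched negative peptide regions from a background proteome
#'
#' Draws `n` contiguous regions from background proteins so that the multiset
#' of sampled lengths equals the multiset of lengths in `length_template`
#' (recycled or truncated to `n`). Each region comes from a uniformly chosen
#' protein among those long enough, at a uniformly chosen start offset. This
#' is the standard construction of a random negative set when experimentally
#' verified negatives do not exist.
#'
#' @param background A [peptide_set] of background protein sequences.
#' @param length_template A [peptide_set] whose sequence lengths define the
#'   target length distribution.
#' @param n Number of negatives to draw (default: size of the template).
#' @param seed Integer seed.
#' @param prefix Id prefix for the sampled records.
#' @return A [peptide_set] of `n` records labelled `"negative"`.
#' @export
sample_negative_regions <- function(background, length_template,
                                    n = nrow(length_template), seed = 42,
                                    prefix = "neg") {
  stopifnot(inherits(background, "peptide_set"),
            inherits(length_template, "peptide_set"))
  lens <- rep_len(nchar(length_template$sequence), n)
  bg_len <- nchar(background$sequence)
  seqs <- with_seed(seed, {
    vapply(lens, function(L) {
      ok <- which(bg_len >= L)
      if (length(ok) == 0)
        stop(sprintf("no background protein of length >= %d", L),
             call. = FALSE)
      p <- ok[sample.int(length(ok), 1)]
      start <- sample.int(bg_len[p] - L + 1, 1)
      substr(background$sequence[p], start, start + L - 1)
    }, character(1))
  })
  peptide_set(sprintf("%s_%03d", prefix, seq_len(n)), seqs,
              label = "negative", source = "sampled background region",
              name = prefix)
}
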