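.pkg_cache <- new.env(parent = emptyenv())

## BLOSUM62 scoring matrix, loaded once per session.
blosum62 <- function() {
  if (is.null(.pkg_cache$BLOSUM62)) {
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    .pkg_cache$BLOSUM62 <- e$BLOSUM62
  }
  .pkg_cache$BLOSUM62
}

#' Pairwise global sequence identity
#'
#' Identity between two peptides is defined as the number of identical
#' aligned residues divided by the alignment length (columns, gaps included)
#' of a Needleman-Wunsch global alignment under BLOSUM62 with gap open 10
#' and gap extension 1.
#'
#' @param a Character vector of peptide sequences.
#' @param b A single peptide sequence to compare against.
#' @return Numeric vector of identities in \[0, 1\], one per element of `a`.
#' @export
sequence_identity <- function(a, b) {
  if (length(a) == 0) return(numeric(0))
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAStringSet(a), Biostrings::AAString(b),
    substitutionMatrix = blosum62(), gapOpening = 10, gapExtension = 1,
    type = "global")
  ## alignment columns (end gaps included): every residue of either peptide
  ## occupies a column, aligned residue pairs share one.
  pairs <- Biostrings::nmatch(aln) + Biostrings::nmismatch(aln)
  width <- nchar(a) + nchar(b) - pairs
  Biostrings::nmatch(aln) / width
}

#' Reduce sequence redundancy by greedy identity clustering
#'
#' Mirrors the CD-HIT strategy: records are sorted longest-first and scanned
#' once; each record joins the first existing cluster whose representative
#' shares more than `identity_threshold` identity with it, otherwise it
#' founds a new cluster. The cluster representatives (the longest member
#' encountered first) are returned, so no two retained sequences exceed the
#' threshold against each other.
#'
#' @param x A [peptide_set].
#' @param identity_threshold Maximum pairwise identity retained, in (0, 1\];
#'   default 0.7.
#' @return A [peptide_set] of cluster representatives, in the sorted scan
#'   order. The integer cluster assignment of every input record is attached
#'   as attribute `"cluster"` (named by id).
#' @examples
#' ps <- peptide_set(c("a", "b"), c("ACDEFGHIK", "ACDEFGHIK"))
#' nrow(reduce_redundancy(ps, 0.7))  # 1
#' @export
reduce_redundancy <- function(x, identity_threshold = 0.7) {
  stopifnot(inherits(x, "peptide_set"))
  if (nrow(x) == 0) stop("dataset is empty", call. = FALSE)
  if (!is.numeric(identity_threshold) || length(identity_threshold) != 1 ||
      identity_threshold <= 0 || identity_threshold > 1)
    stop("'identity_threshold' must be a fraction in (0, 1]", call. = FALSE)

  ord <- order(-nchar(x$sequence))   # stable: ties keep input order
  sorted <- subset_peptides(x, ord)
  rep_idx <- integer(0)              # indices (into sorted) of representatives
  cluster <- integer(nrow(sorted))
  for (i in seq_len(nrow(sorted))) {
    assigned <- 0L
    if (length(rep_idx) > 0) {
      ident <- sequence_identity(sorted$sequence[rep_idx],
                                 sorted$sequence[i])
      hit <- which(ident > identity_threshold)
      if (length(hit) > 0) assigned <- hit[1]
    }
    if (assigned == 0L) {
      rep_idx <- c(rep_idx, i)
      assigned <- length(rep_idx)
    }
    cluster[i] <- assigned
  }
  out <- subset_peptides(sorted, rep_idx,
                         name = paste0(attr(x, "name") %||% "", "_nr"))
  cl <- cluster
  names(cl) <- sorted$id
  attr(out, "cluster") <- cl
  out
}
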