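#' @keywords internal
"_PACKAGE"

## Fixed residue order used by every encoder and table in the package.
AA_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

GAP_CHAR <- "-"

#' Standard one-letter amino acid alphabet
#'
#' Returns the 20 standard residues in the fixed alphabetical order used by
#' all feature encoders and propensity tables in this package.
#'
#' @return Character vector of length 20.
#' @export
amino_acids <- function() AA_ALPHABET

## Evaluate `expr` with the RNG seeded at `seed`, restoring the caller's
## RNG state afterwards so library functions never perturb user randomness.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}

## Validate peptide sequences; returns positions of offending characters.
check_sequence <- function(sequence, id = "<peptide>") {
  chars <- strsplit(sequence, "", fixed = TRUE)[[1]]
  bad <- which(!chars %in% AA_ALPHABET)
  if (length(bad) > 0) {
    stop(sprintf("invalid residue '%s' at position %d in sequence '%s'",
                 chars[bad[1]], bad[1], id), call. = FALSE)
  }
  invisible(TRUE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
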