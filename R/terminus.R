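TERMINUS_REGIONS <- c("WHOLE", "NT", "CT", "NTCT")

#' Terminus extraction schemes
#'
#' Peptide classifiers in this package can be trained on the whole peptide or
#' on terminus views: the first k residues (`NTk`), the last k residues
#' (`CTk`), or their concatenation (`NTCTk`), for k in {5, 10, 15}. Schemes
#' are named `"WHOLE"`, `"NT5"`, ..., `"NTCT15"`.
#'
#' @return Character vector of the ten scheme names.
#' @export
terminus_schemes <- function() {
  c("WHOLE", paste0(rep(c("NT", "CT", "NTCT"), 3),
                    rep(c(5, 10, 15), each = 3)))
}

## Parse "NT15" -> list(region = "NT", k = 15)
parse_scheme <- function(scheme) {
  scheme <- toupper(scheme)
  if (scheme == "WHOLE") return(list(region = "WHOLE", k = NA_integer_))
  m <- regmatches(scheme, regexec("^(NTCT|NT|CT)([0-9]+)$", scheme))[[1]]
  if (length(m) != 3)
    stop(sprintf("unknown terminus scheme '%s'", scheme), call. = FALSE)
  k <- as.integer(m[3])
  if (!k %in% c(5L, 10L, 15L))
    stop(sprintf("terminus window must be 5, 10 or 15 (got %d)", k),
         call. = FALSE)
  list(region = m[2], k = k)
}

#' Extract a terminus region from a peptide
#'
#' `NTk` returns the first k residues, `CTk` the last k, `NTCTk` their
#' concatenation (residues may appear in both halves when the peptide is
#' shorter than 2k), and `WHOLE` the input unchanged. Peptides shorter than
#' k fall back to the whole sequence, so composition features stay
#' well-defined for short peptides.
#'
#' @param sequence Peptide string (or character vector; vectorized).
#' @param scheme A scheme name, e.g. `"NT15"`; see [terminus_schemes()].
#' @return Character vector of extracted regions.
#' @examples
#' extract_terminus("ACDEFGHIK", "NT5")   # "ACDEF"
#' extract_terminus("ACDEFGHIK", "NTCT5") # "ACDEFFGHIK"
#' @export
extract_terminus <- function(sequence, scheme) {
  sc <- parse_scheme(scheme)
  if (sc$region == "WHOLE") return(sequence)
  n <- nchar(sequence)
  k <- sc$k
  nt <- substr(sequence, 1, pmin(k, n))
  ct <- substr(sequence, pmax(1, n - k + 1), n)
  switch(sc$region, NT = nt, CT = ct, NTCT = paste0(nt, ct))
}
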