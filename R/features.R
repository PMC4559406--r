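#' Amino acid composition (AAC)
#'
#' The 20-dimensional percentage composition of a peptide:
#' `AAC(i) = 100 * count(i) / length`, in the fixed residue order
#' `ACDEFGHIKLMNPQRSTVWY`. Values sum to 100.
#'
#' @param sequence A peptide string.
#' @return Named numeric vector of length 20.
#' @examples
#' aac("ACDE")  # A = C = D = E = 25
#' @export
aac <- function(sequence) {
  check_sequence(sequence)
  chars <- strsplit(sequence, "", fixed = TRUE)[[1]]
  counts <- table(factor(chars, levels = AA_ALPHABET))
  stats::setNames(100 * as.numeric(counts) / length(chars), AA_ALPHABET)
}

#' Dipeptide composition (DPC)
#'
#' The 400-dimensional percentage composition of overlapping residue pairs:
#' `DPC(d) = 100 * count(d) / (length - 1)`, features in fixed lexicographic
#' order (AA, AC, ..., YY). Values sum to 100. Requires length >= 2.
#'
#' @param sequence A peptide string of length at least 2.
#' @return Named numeric vector of length 400.
#' @examples
#' dpc("ACAC")["AC"]  # 66.67
#' @export
dpc <- function(sequence) {
  check_sequence(sequence)
  n <- nchar(sequence)
  if (n < 2)
    stop("dipeptide composition requires length >= 2", call. = FALSE)
  chars <- strsplit(sequence, "", fixed = TRUE)[[1]]
  pairs <- paste0(chars[-n], chars[-1])
  lv <- as.vector(t(outer(AA_ALPHABET, AA_ALPHABET, paste0)))
  counts <- table(factor(pairs, levels = lv))
  stats::setNames(100 * as.numeric(counts) / (n - 1), lv)
}

#' Binary (one-hot) profile
#'
#' Position-wise one-hot encoding: each residue becomes a 20-element
#' indicator block in the fixed residue order, giving a vector of length
#' `20 * width`. The peptide length must equal `width` exactly (no padding),
#' so binary profiles are only defined on fixed-width terminus views.
#'
#' @param sequence A peptide string of length exactly `width`.
#' @param width Required peptide length.
#' @return Named numeric 0/1 vector of length `20 * width`.
#' @examples
#' length(binary_profile("ACDEF", 5))  # 100
#' @export
binary_profile <- function(sequence, width = nchar(sequence)) {
  check_sequence(sequence)
  n <- nchar(sequence)
  if (n != width)
    stop(sprintf("binary profile requires length exactly %d (got %d)",
                 width, n), call. = FALSE)
  chars <- strsplit(sequence, "", fixed = TRUE)[[1]]
  out <- numeric(20 * width)
  idx <- match(chars, AA_ALPHABET)
  out[(seq_len(width) - 1) * 20 + idx] <- 1
  names(out) <- paste0("p", rep(seq_len(width), each = 20), "_",
                       rep(AA_ALPHABET, width))
  out
}

FEATURE_KINDS <- c("aac", "dpc", "binary")

#' Encode a peptide dataset as a feature matrix
#'
#' Applies a terminus scheme (see [extract_terminus()]) then one of the
#' three encoders to every record, producing a numeric matrix with one row
#' per peptide. For `kind = "binary"` all extracted regions must share one
#' length (fixed-width requirement); records failing encoding are reported
#' together by id.
#'
#' @param x A [peptide_set].
#' @param scheme Terminus scheme name (default `"WHOLE"`).
#' @param kind One of `"aac"`, `"dpc"`, `"binary"`.
#' @return A numeric matrix of class `feature_matrix` with row names set to
#'   peptide ids and attributes `schema` (list of `kind`, `scheme`, `width`)
#'   and `labels`.
#' @examples
#' ps <- peptide_set(c("a", "b"), c("ACDEFGHIK", "GHIKLMNPQ"))
#' dim(encode_dataset(ps, "NT5", "aac"))  # 2 x 20
#' @export
encode_dataset <- function(x, scheme = "WHOLE", kind = c("aac", "dpc",
                                                         "binary")) {
  stopifnot(inherits(x, "peptide_set"))
  kind <- match.arg(kind)
  regions <- extract_terminus(x$sequence, scheme)
  width <- NA_integer_
  if (kind == "binary") {
    sc <- parse_scheme(scheme)
    if (is.na(sc$k))
      stop("binary encoding requires a fixed-width terminus scheme",
           call. = FALSE)
    width <- if (sc$region == "NTCT") 2L * sc$k else sc$k
  }
  encode1 <- function(region) switch(kind, aac = aac(region),
                                     dpc = dpc(region),
                                     binary = binary_profile(region, width))
  rows <- vector("list", nrow(x))
  errs <- character(0)
  for (i in seq_len(nrow(x))) {
    rows[[i]] <- tryCatch(encode1(regions[i]), error = function(e) {
      errs <<- c(errs, x$id[i])
      NULL
    })
  }
  if (length(errs) > 0)
    stop(sprintf("encoding failed for %d record(s): %s", length(errs),
                 paste(errs, collapse = ", ")), call. = FALSE)
  ncol_fixed <- switch(kind, aac = 20L, dpc = 400L, binary = 20L * width)
  m <- matrix(0, nrow = nrow(x), ncol = ncol_fixed)
  if (nrow(x) > 0) {
    m <- do.call(rbind, rows)
  } else {
    colnames(m) <- names(encode1(strrep("A", max(2, width, na.rm = TRUE))))
  }
  rownames(m) <- x$id
  structure(m, class = c("feature_matrix", class(m)),
            schema = list(kind = kind, scheme = toupper(scheme),
                          width = width),
            labels = stats::setNames(x$label, x$id))
}

#' @export
print.feature_matrix <- function(x, ...) {
  sc <- attr(x, "schema")
  cat(sprintf("<feature_matrix> %d x %d (%s, scheme %s)\n", nrow(x), ncol(x),
              sc$kind, sc$scheme))
  invisible(x)
}
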