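#' Construct a labelled peptide dataset
#'
#' A `peptide_set` is the basic data container of the package: a data frame
#' with one row per peptide carrying a unique `id`, an upper-case `sequence`
#' over the 20 standard residues, a `label` (`"positive"`, `"negative"` or
#' `"unlabeled"`) and a free-text `source`.
#'
#' @param id Character vector of unique identifiers.
#' @param sequence Character vector of peptide sequences (coerced to upper
#'   case; only the 20 standard one-letter codes are accepted).
#' @param label Class labels, recycled if length 1. One of `"positive"`,
#'   `"negative"`, `"unlabeled"`.
#' @param source Free-text provenance, recycled if length 1.
#' @param name Optional dataset name stored as an attribute.
#'
#' @return A data frame of class `peptide_set`.
#' @examples
#' ps <- peptide_set(c("p1", "p2"), c("ACDEF", "GHIKL"), label = "positive")
#' summary(ps)
#' @export
peptide_set <- function(id, sequence, label = "unlabeled", source = "",
                        name = NULL) {
  id <- as.character(id)
  sequence <- toupper(as.character(sequence))
  if (length(id) != length(sequence))
    stop("'id' and 'sequence' must have equal length", call. = FALSE)
  if (anyDuplicated(id))
    stop(sprintf("duplicate peptide ids: %s",
                 paste(unique(id[duplicated(id)]), collapse = ", ")),
         call. = FALSE)
  label <- rep_len(as.character(label), length(id))
  bad_lab <- setdiff(unique(label), c("positive", "negative", "unlabeled"))
  if (length(bad_lab) > 0)
    stop(sprintf("unknown label(s): %s", paste(bad_lab, collapse = ", ")),
         call. = FALSE)
  if (length(id) > 0 && any(nchar(sequence) < 1))
    stop(sprintf("empty sequence for id(s): %s",
                 paste(id[nchar(sequence) < 1], collapse = ", ")),
         call. = FALSE)
  for (i in seq_along(sequence)) check_sequence(sequence[i], id[i])
  out <- data.frame(id = id, sequence = sequence, label = label,
                    source = rep_len(as.character(source), length(id)),
                    stringsAsFactors = FALSE)
  class(out) <- c("peptide_set", "data.frame")
  attr(out, "name") <- name %||% "peptide_set"
  out
}

#' @export
print.peptide_set <- function(x, ...) {
  cat(sprintf("<peptide_set '%s'> %d peptides\n", attr(x, "name") %||% "",
              nrow(x)))
  tab <- table(x$label)
  cat("  labels:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "),
      "\n")
  if (nrow(x) > 0)
    cat(sprintf("  lengths: %d-%d (median %g)\n", min(nchar(x$sequence)),
                max(nchar(x$sequence)), stats::median(nchar(x$sequence))))
  invisible(x)
}

#' @method summary peptide_set
#' @export
summary.peptide_set <- function(object, ...) {
  out <- list(name = attr(object, "name"), n = nrow(object),
              labels = table(object$label),
              length_summary = summary(nchar(object$sequence)))
  class(out) <- "summary.peptide_set"
  out
}

#' @export
print.summary.peptide_set <- function(x, ...) {
  cat(sprintf("Peptide dataset '%s': %d sequences\n", x$name, x$n))
  print(x$labels)
  print(x$length_summary)
  invisible(x)
}

#' Read peptides from a FASTA file
#'
#' Headers are parsed as `id|label` where the optional token after the
#' configurable separator gives the class (`pos`/`positive`,
#' `neg`/`negative`); anything else is kept as provenance and the record is
#' `unlabeled`.
#'
#' @param path Path to a FASTA file.
#' @param label_sep Header token separator (default `"|"`).
#' @param name Dataset name; defaults to the file name.
#' @param map_nonstandard If `TRUE`, selenocysteine (U) is mapped to C,
#'   pyrrolysine (O) to K, and records containing ambiguity codes
#'   (B, Z, J, X) are dropped with a message. By default non-standard
#'   residues are an error.
#'
#' @return A [peptide_set].
#' @examples
#' f <- tempfile(fileext = ".fasta")
#' writeLines(c(">p1|pos", "ACDEF", ">p2|neg", "GHIKL"), f)
#' read_fasta(f)
#' @export
read_fasta <- function(path, label_sep = "|", name = basename(path),
                       map_nonstandard = FALSE) {
  if (!file.exists(path))
    stop(sprintf("FASTA file not found: %s", path), call. = FALSE)
  seqs <- tryCatch(
    Biostrings::readBStringSet(path),
    error = function(e) stop(sprintf("malformed FASTA '%s': %s", path,
                                     conditionMessage(e)), call. = FALSE))
  headers <- names(seqs)
  parts <- strsplit(headers, label_sep, fixed = TRUE)
  ids <- vapply(parts, function(p) trimws(p[1]), character(1))
  ## First whitespace-free token is the id if no separator present
  ids <- vapply(strsplit(ids, "\\s+"), `[`, character(1), 1)
  labels <- vapply(parts, function(p) {
    tok <- if (length(p) >= 2) tolower(trimws(p[2])) else ""
    if (tok %in% c("pos", "positive")) "positive"
    else if (tok %in% c("neg", "negative")) "negative"
    else "unlabeled"
  }, character(1))
  sequences <- toupper(as.character(seqs))
  if (map_nonstandard) {
    sequences <- chartr("UO", "CK", sequences)
    drop <- grepl("[BZJX]", sequences)
    if (any(drop)) {
      message(sprintf("dropping %d record(s) with ambiguity codes: %s",
                      sum(drop), paste(ids[drop], collapse = ", ")))
      sequences <- sequences[!drop]
      ids <- ids[!drop]
      labels <- labels[!drop]
      headers <- headers[!drop]
    }
  }
  peptide_set(ids, sequences, label = labels, source = headers, name = name)
}

#' Write a dataset manifest as TSV
#'
#' One row per peptide with columns `id`, `label`, `length`, `source`.
#'
#' @param x A [peptide_set].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(x, path) {
  stopifnot(inherits(x, "peptide_set"))
  utils::write.table(
    data.frame(id = x$id, label = x$label, length = nchar(x$sequence),
               source = x$source),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a peptide dataset to FASTA
#'
#' Headers are written as `id|pos` / `id|neg` (unlabeled records get a bare
#' id); sequences are wrapped at 60 columns.
#'
#' @param x A [peptide_set].
#' @param path Output file path.
#' @param width Line-wrap width (default 60).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(x, path, width = 60) {
  stopifnot(inherits(x, "peptide_set"))
  tag <- c(positive = "|pos", negative = "|neg", unlabeled = "")[x$label]
  seqs <- Biostrings::BStringSet(x$sequence)
  names(seqs) <- paste0(x$id, tag)
  Biostrings::writeXStringSet(seqs, path, width = width)
  invisible(path)
}

## Subset a peptide_set preserving class and name.
subset_peptides <- function(x, idx, name = attr(x, "name")) {
  out <- as.data.frame(x)[idx, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("peptide_set", "data.frame")
  attr(out, "name") <- name
  out
}

#' Combine peptide datasets
#'
#' @param ... `peptide_set` objects with disjoint ids.
#' @param name Name of the combined set.
#' @return A [peptide_set].
#' @export
bind_peptides <- function(..., name = "combined") {
  parts <- list(...)
  df <- do.call(rbind, lapply(parts, as.data.frame))
  peptide_set(df$id, df$sequence, df$label, df$source, name = name)
}
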