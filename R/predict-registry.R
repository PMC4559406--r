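#' Build a length-routing model registry
#'
#' The deployed predictor uses two models: an N-terminus model (AAC on the
#' first 15 residues), the best-performing configuration, for peptides of at
#' least `min_length` residues, and a whole-peptide AAC model for shorter
#' ones. Both are typically trained on all available sequences.
#'
#' @param whole_model A [peptide_model()] with scheme `"WHOLE"`.
#' @param nt15_model A [peptide_model()] with scheme `"NT15"`.
#' @param min_length Peptides at least this long route to the NT15 model
#'   (default 15).
#' @return An object of class `model_registry`.
#' @export
model_registry <- function(whole_model, nt15_model, min_length = 15) {
  stopifnot(inherits(whole_model, "peptide_model"),
            inherits(nt15_model, "peptide_model"))
  if (whole_model$schema$scheme != "WHOLE")
    stop("'whole_model' must use the WHOLE scheme", call. = FALSE)
  if (nt15_model$schema$scheme != "NT15")
    stop("'nt15_model' must use the NT15 scheme", call. = FALSE)
  structure(list(whole = whole_model, nt15 = nt15_model,
                 min_length = min_length),
            class = "model_registry")
}

#' @export
print.model_registry <- function(x, ...) {
  cat(sprintf("<model_registry> length >= %d -> NT15 model, else whole\n",
              x$min_length))
  invisible(x)
}

#' Route a peptide to a model by length
#'
#' @param sequence Peptide string(s).
#' @param registry A [model_registry()].
#' @return `"nt15"` or `"whole"` per sequence.
#' @export
route_model <- function(sequence, registry) {
  stopifnot(inherits(registry, "model_registry"))
  ifelse(nchar(sequence) >= registry$min_length, "nt15", "whole")
}

#' Predict a batch of peptides with length routing
#'
#' One prediction per input, in input order; each peptide is routed to the
#' registry model matching its length. Records whose sequence cannot be
#' encoded yield an error entry rather than aborting the batch.
#'
#' @param peptides A [peptide_set] or character vector of sequences.
#' @param registry A [model_registry()].
#' @return Data frame with columns `id`, `sequence`, `model`, `score`,
#'   `class`, `error` (`NA` unless the record failed).
#' @export
predict_batch <- function(peptides, registry) {
  stopifnot(inherits(registry, "model_registry"))
  if (is.character(peptides))
    peptides <- peptide_set(sprintf("q%d", seq_along(peptides)), peptides)
  n <- nrow(peptides)
  out <- data.frame(id = peptides$id, sequence = peptides$sequence,
                    model = rep(NA_character_, n),
                    score = rep(NA_real_, n),
                    class = rep(NA_character_, n),
                    error = rep(NA_character_, n))
  if (n == 0) return(out)
  out$model <- route_model(peptides$sequence, registry)
  for (i in seq_len(n)) {
    res <- tryCatch({
      m <- registry[[out$model[i]]]
      p <- predict(m, peptides$sequence[i], type = "both")
      list(score = p$score, class = p$class)
    }, error = function(e) list(error = conditionMessage(e)))
    if (is.null(res$error)) {
      out$score[i] <- res$score
      out$class[i] <- if (res$class == "positive") "anti-angiogenic"
                      else "non-anti-angiogenic"
    } else {
      out$error[i] <- res$error
    }
  }
  out
}

#' Single-mutant analog scan
#'
#' Enumerates all `19 * L` single-residue substitutions of a parent peptide,
#' predicts each analog with the same length-routing rule as the parent, and
#' flags the substitutions that flip the predicted class — the candidate
#' minimum mutations toward (or away from) anti-angiogenic activity.
#'
#' @param sequence Parent peptide string.
#' @param registry A [model_registry()].
#' @return An object of class `mutant_scan`: list with `parent` (one-row
#'   prediction data frame) and `analogs` (data frame with 1-based
#'   `position`, `from`, `to`, `sequence`, `score`, `class`, `flips_class`),
#'   sorted by position then substituted residue.
#' @export
mutant_scan <- function(sequence, registry) {
  stopifnot(is.character(sequence), length(sequence) == 1,
            nchar(sequence) >= 1)
  check_sequence(sequence)
  parent <- predict_batch(sequence, registry)
  chars <- strsplit(sequence, "", fixed = TRUE)[[1]]
  L <- length(chars)
  position <- rep(seq_len(L), each = 19)
  from <- chars[position]
  to <- unlist(lapply(chars, function(r) setdiff(AA_ALPHABET, r)))
  analog_seq <- vapply(seq_along(position), function(i) {
    s <- chars
    s[position[i]] <- to[i]
    paste(s, collapse = "")
  }, character(1))
  pred <- predict_batch(peptide_set(sprintf("mut_%d_%s", position, to),
                                    analog_seq), registry)
  analogs <- data.frame(position = position, from = from, to = to,
                        sequence = analog_seq, model = pred$model,
                        score = pred$score, class = pred$class,
                        flips_class = pred$class != parent$class)
  structure(list(parent = parent, analogs = analogs), class = "mutant_scan")
}

#' @export
print.mutant_scan <- function(x, ...) {
  cat(sprintf("Mutant scan of %s (%s, score %.3f)\n", x$parent$sequence,
              x$parent$class, x$parent$score))
  flips <- x$analogs[x$analogs$flips_class, ]
  cat(sprintf("%d analogs, %d flip the predicted class\n", nrow(x$analogs),
              nrow(flips)))
  if (nrow(flips) > 0)
    print(utils::head(flips[, c("position", "from", "to", "score", "class")],
                      20), row.names = FALSE)
  invisible(x)
}
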