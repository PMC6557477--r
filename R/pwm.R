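# Base order is fixed package-wide: columns of every weight matrix are A,C,G,T.
DNA_BASES <- c("A", "C", "G", "T")

#' Construct a position weight matrix object
#'
#' A PWM holds per-position, per-base log-odds weights describing a
#' transcription factor's binding preference, together with an optional
#' table of score thresholds keyed by p-value level (as distributed with
#' HOCOMOCO models).
#'
#' @param name Motif identifier, e.g. \code{"FOXA1_MOUSE.H11MO.0.A"}.
#' @param weights Numeric matrix with L rows (motif positions) and 4 columns
#'   in A, C, G, T order; all entries must be finite.
#' @param thresholds Named numeric vector mapping p-value levels (names,
#'   e.g. \code{"0.0001"}) to minimum scores. May be empty. Must be
#'   monotone: a smaller p-value level implies a larger score threshold.
#'
#' @return An object of class \code{"pwm"} with elements \code{name},
#'   \code{length}, \code{weights} and \code{thresholds}.
#' @export
#' @examples
#' w <- matrix(c(1, 0, 0, 0, 0, 0, 0, 2), nrow = 2, byrow = TRUE)
#' pwm <- new_pwm("TOY", w)
#' pwm$length
new_pwm <- function(name, weights, thresholds = numeric()) {
  weights <- as.matrix(weights)
  if (nrow(weights) < 1L) {
    stop("a PWM needs at least one position")
  }
  if (ncol(weights) != 4L) {
    stop("PWM weights must have exactly 4 columns (A, C, G, T); got ",
         ncol(weights))
  }
  if (!is.numeric(weights) || any(!is.finite(weights))) {
    stop("PWM weights must all be finite numbers")
  }
  colnames(weights) <- DNA_BASES
  rownames(weights) <- NULL
  thresholds <- validate_thresholds(thresholds)
  structure(
    list(name = as.character(name), length = nrow(weights),
         weights = weights, thresholds = thresholds),
    class = "pwm"
  )
}

validate_thresholds <- function(thresholds) {
  if (length(thresholds) == 0L) return(stats::setNames(numeric(0), character(0)))
  if (is.null(names(thresholds)) || any(!nzchar(names(thresholds)))) {
    stop("thresholds must be named by p-value level")
  }
  p <- as.numeric(names(thresholds))
  if (any(is.na(p)) || any(p <= 0) || any(p >= 1)) {
    stop("threshold names must be p-value levels in (0, 1)")
  }
  ord <- order(p)
  thresholds <- thresholds[ord]
  p <- p[ord]
  # smaller p-value level => more stringent => larger score threshold
  if (is.unsorted(rev(thresholds), strictly = FALSE)) {
    stop("thresholds must be monotone: smaller p-value, larger score")
  }
  thresholds
}

#' @export
print.pwm <- function(x, ...) {
  cat(sprintf("PWM %s: %d positions\n", x$name, x$length))
  if (length(x$thresholds)) {
    cat("thresholds:",
        paste(sprintf("p<%s: %.3g", names(x$thresholds), x$thresholds),
              collapse = ", "), "\n")
  }
  invisible(x)
}

#' Read a PWM from a HOCOMOCO-style plain-text file
#'
#' The expected layout is a header line \code{">NAME"} followed by one row
#' per motif position containing four whitespace-separated numbers in
#' A, C, G, T order. A companion two-column TSV of thresholds
#' (\code{p_level} then \code{score}) may be supplied; by convention it
#' sits next to the matrix as \code{<file>.thr} and is picked up
#' automatically when present.
#'
#' @param path Path to the matrix file.
#' @param thresholds_path Optional path to a threshold table; default looks
#'   for \code{paste0(path, ".thr")}.
#' @return A \code{\link{new_pwm}} object.
#' @export
read_pwm <- function(path, thresholds_path = NULL) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 2L || !startsWith(lines[[1L]], ">")) {
    stop("malformed PWM file (expected '>NAME' header then weight rows): ",
         path)
  }
  name <- trimws(sub("^>", "", lines[[1L]]))
  rows <- lapply(seq_along(lines[-1L]), function(i) {
    fields <- strsplit(trimws(lines[[i + 1L]]), "[ \t]+")[[1L]]
    if (length(fields) != 4L) {
      stop(sprintf("PWM parse error at line %d of %s: expected 4 columns, got %d",
                   i + 1L, path, length(fields)))
    }
    vals <- suppressWarnings(as.numeric(fields))
    if (any(is.na(vals))) {
      stop(sprintf("PWM parse error at line %d of %s: non-numeric weight",
                   i + 1L, path))
    }
    vals
  })
  weights <- do.call(rbind, rows)
  if (is.null(thresholds_path)) {
    cand <- paste0(path, ".thr")
    if (file.exists(cand)) thresholds_path <- cand
  }
  thresholds <- if (!is.null(thresholds_path)) {
    read_pwm_thresholds(thresholds_path)
  } else {
    numeric()
  }
  new_pwm(name, weights, thresholds)
}

#' Read a PWM score-to-p-value threshold table
#'
#' @param path Two-column TSV: p-value level, minimum score. A header line
#'   is detected and skipped.
#' @return Named numeric vector (names are p-value levels).
#' @export
read_pwm_thresholds <- function(path) {
  tab <- utils::read.table(path, header = FALSE, sep = "\t",
                           colClasses = "character")
  if (ncol(tab) != 2L) stop("threshold table must have two columns: ", path)
  if (is.na(suppressWarnings(as.numeric(tab[1L, 1L])))) {
    tab <- tab[-1L, , drop = FALSE]
  }
  p <- as.numeric(tab[[1L]])
  s <- as.numeric(tab[[2L]])
  if (any(is.na(p)) || any(is.na(s))) {
    stop("non-numeric entry in threshold table: ", path)
  }
  validate_thresholds(stats::setNames(s, format(p, scientific = FALSE, trim = TRUE)))
}

#' Write a PWM in HOCOMOCO-style plain text
#'
#' Inverse of \code{\link{read_pwm}}; thresholds, when present, are written
#' alongside as \code{<path>.thr}.
#'
#' @param pwm A \code{pwm} object.
#' @param path Output file path.
#' @return \code{path}, invisibly.
#' @export
write_pwm <- function(pwm, path) {
  stopifnot(inherits(pwm, "pwm"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0(">", pwm$name), con)
  utils::write.table(format(pwm$weights, trim = TRUE, digits = 15),
                     con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  if (length(pwm$thresholds)) {
    utils::write.table(
      data.frame(p = names(pwm$thresholds), score = unname(pwm$thresholds)),
      paste0(path, ".thr"),
      sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}

#' Look up the score threshold at a p-value level
#'
#' @param pwm A \code{pwm} object.
#' @param p_level P-value level, e.g. \code{1e-4}.
#' @return The minimum score at that level.
#' @export
pwm_threshold <- function(pwm, p_level = 1e-4) {
  stopifnot(inherits(pwm, "pwm"))
  if (!length(pwm$thresholds)) {
    stop("PWM ", pwm$name, " has no threshold table")
  }
  p <- as.numeric(names(pwm$thresholds))
  hit <- which(abs(p - p_level) <= 1e-12 * max(p_level, p))
  if (!length(hit)) {
    stop(sprintf("no threshold at p-value level %g for PWM %s", p_level,
                 pwm$name))
  }
  unname(pwm$thresholds[[hit[[1L]]]])
}

#' Reverse-complement a DNA sequence
#'
#' Alphabet is A, C, G, T plus the ambiguity code N (which maps to N).
#'
#' @param seq Character scalar DNA sequence.
#' @return The reverse complement.
#' @export
#' @examples
#' reverse_complement("ACGT")
reverse_complement <- function(seq) {
  if (!is.character(seq) || length(seq) != 1L) {
    stop("seq must be a single character string")
  }
  if (!nzchar(seq)) stop("cannot reverse-complement an empty sequence")
  if (grepl("[^ACGTN]", seq)) {
    stop("illegal character in DNA sequence (alphabet is A,C,G,T,N)")
  }
  chartr("ACGTN", "TGCAN",
         paste(rev(strsplit(seq, "", fixed = TRUE)[[1L]]), collapse = ""))
}

# Map a sequence to column indices 1..5; index 5 (N) selects the row
# minimum, the pessimistic score for an unknown base.
seq_to_idx <- function(seq) {
  bases <- strsplit(seq, "", fixed = TRUE)[[1L]]
  idx <- match(bases, c(DNA_BASES, "N"))
  if (anyNA(idx)) {
    stop("illegal character in DNA sequence (alphabet is A,C,G,T,N)")
  }
  idx
}

weights_with_n <- function(pwm) {
  cbind(pwm$weights, apply(pwm$weights, 1L, min))
}

#' Score a single window against a PWM
#'
#' Sums the weight of the observed base at every motif position. A position
#' holding N contributes that position's minimum weight.
#'
#' @param pwm A \code{pwm} object.
#' @param seq DNA string of length exactly \code{pwm$length}.
#' @return The (unclamped) log-odds score.
#' @export
score_window <- function(pwm, seq) {
  stopifnot(inherits(pwm, "pwm"))
  if (!is.character(seq) || length(seq) != 1L || !nzchar(seq)) {
    stop("seq must be a non-empty character string")
  }
  if (nchar(seq) != pwm$length) {
    stop(sprintf("sequence length %d does not match motif length %d",
                 nchar(seq), pwm$length))
  }
  idx <- seq_to_idx(seq)
  w <- weights_with_n(pwm)
  sum(w[cbind(seq_len(pwm$length), idx)])
}

# Scores of every L-window start along seq (one strand), vectorised over
# starts. Returns numeric(0) when seq is shorter than the motif.
score_positions <- function(pwm, seq) {
  n <- nchar(seq)
  L <- pwm$length
  if (n < L) return(numeric(0))
  idx <- seq_to_idx(seq)
  w <- weights_with_n(pwm)
  n_win <- n - L + 1L
  out <- numeric(n_win)
  starts <- seq_len(n_win)
  for (j in seq_len(L)) {
    out <- out + unname(w[j, idx[starts + j - 1L]])
  }
  out
}

#' Best-window scores on both strands
#'
#' Scans every motif-length window of \code{seq} on the given strand and of
#' its reverse complement, reporting the best score per strand. Negative
#' best scores are clamped to 0 in the reported \code{score} (a no-match is
#' printed as 0.00 in the standard report); the unclamped optimum is kept
#' as \code{raw} for diagnostics. Ties are broken towards the smallest
#' start offset.
#'
#' @param pwm A \code{pwm} object.
#' @param seq DNA string at least as long as the motif.
#' @return List with elements \code{plus} and \code{minus}, each a list
#'   \code{(score, raw, start_offset, strand)}; \code{start_offset} is the
#'   1-based offset of the best window within the scanned sequence (the
#'   reverse complement for \code{minus}).
#' @export
best_strand_scores <- function(pwm, seq) {
  stopifnot(inherits(pwm, "pwm"))
  if (nchar(seq) < pwm$length) {
    stop(sprintf("sequence length %d shorter than motif length %d",
                 nchar(seq), pwm$length))
  }
  one <- function(s, strand) {
    sc <- score_positions(pwm, s)
    best <- which.max(sc)  # which.max takes the first maximum: smallest offset
    list(score = max(0, sc[[best]]), raw = sc[[best]],
         start_offset = best, strand = strand)
  }
  list(plus = one(seq, "+"),
       minus = one(reverse_complement(seq), "-"))
}
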