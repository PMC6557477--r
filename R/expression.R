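#' Default condition labels for the Z statistic
#'
#' The four F1 condition labels entering Z, in the order: alternative-strain
#' treated, alternative-strain control, reference-strain treated,
#' reference-strain control.
#'
#' @return Character vector of length 4.
#' @export
z_conditions <- function() {
  c("FVB.D300.F1", "FVB.CTL.F1", "C57.D300.F1", "C57.CTL.F1")
}

#' Strain-specific treatment-response statistic Z
#'
#' Z contrasts the treated-vs-control log2 fold change between the two
#' strains:
#' \deqn{Z = \log_2\frac{FPKM_{FVB.D300.F1}+c}{FPKM_{FVB.CTL.F1}+c} -
#'           \log_2\frac{FPKM_{C57.D300.F1}+c}{FPKM_{C57.CTL.F1}+c}}
#' with pseudocount \eqn{c} (default 0.1) added to every FPKM before
#' division. Large positive Z marks genes whose treatment response is
#' specific to the alternative (FVB) strain or whose silencing is specific
#' to the reference (C57) strain.
#'
#' @param fpkm Data.frame of condition-level FPKM with one row per gene
#'   and the four condition columns, plus a \code{gene} column (or row
#'   names) identifying genes.
#' @param conditions Character vector of the four condition labels in the
#'   order of \code{\link{z_conditions}}.
#' @param pseudocount Pseudocount added to every FPKM (default 0.1).
#' @return Named numeric vector of Z values (NA, with a warning, when a
#'   condition column is missing).
#' @export
#' @examples
#' tbl <- data.frame(gene = "g1", FVB.D300.F1 = 102.3, FVB.CTL.F1 = 0,
#'                   C57.D300.F1 = 5, C57.CTL.F1 = 5)
#' compute_z(tbl)  # log2(1024) = 10
compute_z <- function(fpkm, conditions = z_conditions(), pseudocount = 0.1) {
  stopifnot(length(conditions) == 4L)
  genes <- if ("gene" %in% names(fpkm)) fpkm$gene else rownames(fpkm)
  missing_cond <- setdiff(conditions, names(fpkm))
  if (length(missing_cond)) {
    warning("missing condition column(s): ",
            paste(missing_cond, collapse = ", "), "; Z undefined")
    return(stats::setNames(rep(NA_real_, nrow(fpkm)), genes))
  }
  v <- lapply(conditions, function(cl) {
    x <- fpkm[[cl]]
    if (any(x < 0, na.rm = TRUE)) stop("FPKM values must be non-negative")
    x + pseudocount
  })
  z <- log2(v[[1L]] / v[[2L]]) - log2(v[[3L]] / v[[4L]])
  stats::setNames(z, genes)
}

#' Pairwise Wilcoxon rank-sum tests with Benjamini-Hochberg correction
#'
#' Two-sided rank-sum tests for every pair of conditions, with the
#' p-values adjusted by Benjamini-Hochberg across the family of pairs.
#' The exact null distribution is used at small sample sizes without ties;
#' otherwise the normal approximation with continuity correction (ties
#' handled by mid-ranks), as in \code{stats::wilcox.test}. Pairs involving
#' a condition with fewer than two values are reported as NA.
#'
#' @param replicates Named list mapping condition label to a numeric vector
#'   of per-replicate values.
#' @return Data.frame with columns \code{cond1}, \code{cond2}, \code{p}
#'   and \code{p_adj}.
#' @export
pairwise_wilcoxon_bh <- function(replicates) {
  stopifnot(is.list(replicates), !is.null(names(replicates)))
  conds <- names(replicates)
  if (length(conds) < 2L) stop("need at least two conditions")
  pairs <- utils::combn(conds, 2L)
  p <- apply(pairs, 2L, function(pr) {
    x <- replicates[[pr[[1L]]]]
    y <- replicates[[pr[[2L]]]]
    if (length(x) < 2L || length(y) < 2L) return(NA_real_)
    suppressWarnings(stats::wilcox.test(x, y, alternative = "two.sided")$p.value)
  })
  data.frame(
    cond1 = pairs[1L, ], cond2 = pairs[2L, ],
    p = p, p_adj = stats::p.adjust(p, method = "BH"),
    stringsAsFactors = FALSE
  )
}
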