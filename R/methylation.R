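#' Derive promoter regions from gene models
#'
#' Two distinct promoter flavors are in use and deliberately kept apart:
#' \describe{
#'   \item{\code{"methylation"}}{2000 bp upstream of the gene's 5' end to
#'     200 bp downstream (2200 bp, the span of the probed methylation
#'     region; the 5'-most base counts as the first downstream base).}
#'   \item{\code{"motif_scan"}}{-2000 to 0 bp relative to the 5' end
#'     (2000 bp, excluding the 5' base itself), the span scanned for
#'     binding sites.}
#' }
#' "Upstream" is resolved by strand: reverse-strand genes mirror around
#' their 5' end (the \code{end} coordinate). Regions running off the start
#' of a contig are truncated at base 1 (and at the contig end when
#' \code{contig_lengths} is given), with a message.
#'
#' @param genes Data.frame with columns \code{chrom}, \code{start},
#'   \code{end}, \code{strand} (\code{"+"}/\code{"-"}), \code{symbol}.
#' @param flavor \code{"methylation"} or \code{"motif_scan"}.
#' @param contig_lengths Optional named vector of contig lengths for
#'   right-truncation.
#' @return Data.frame \code{symbol}, \code{chrom}, \code{start},
#'   \code{end}, \code{strand} (1-based inclusive coordinates).
#' @export
promoter_region <- function(genes, flavor = c("methylation", "motif_scan"),
                            contig_lengths = NULL) {
  flavor <- match.arg(flavor)
  up <- 2000L
  down <- if (flavor == "methylation") 200L else 0L
  plus <- genes$strand == "+"
  tss <- ifelse(plus, genes$start, genes$end)
  start <- ifelse(plus, tss - up, tss - down + 1L)
  end <- ifelse(plus, tss + down - 1L, tss + up)
  if (flavor == "motif_scan") {
    # -2000..0 excludes the 5' base: shift the inner edge off the TSS
    start <- ifelse(plus, start, tss + 1L)
    end <- ifelse(plus, tss - 1L, end)
  }
  trunc_left <- start < 1L
  start <- pmax(start, 1L)
  trunc_right <- rep(FALSE, length(end))
  if (!is.null(contig_lengths)) {
    lim <- unname(contig_lengths[genes$chrom])
    trunc_right <- !is.na(lim) & end > lim
    end <- ifelse(trunc_right, lim, end)
  }
  if (any(trunc_left | trunc_right)) {
    message(sprintf("promoter_region: %d region(s) truncated at contig edge",
                    sum(trunc_left | trunc_right)))
  }
  data.frame(symbol = genes$symbol, chrom = genes$chrom,
             start = as.integer(start), end = as.integer(end),
             strand = genes$strand, stringsAsFactors = FALSE)
}

#' Promoter methylation level: reads per CpG
#'
#' The methylation level of a probed promoter region is its capture-read
#' count divided by the number of CpG sites in the region. Undefined
#' (NA, with a warning) when the region contains no CpG.
#'
#' @param read_count Non-negative integer vector.
#' @param cpg_count Non-negative integer vector.
#' @return Numeric vector of levels.
#' @export
#' @examples
#' methylation_level(44, 22)  # 2
methylation_level <- function(read_count, cpg_count) {
  if (any(read_count < 0, na.rm = TRUE) || any(cpg_count < 0, na.rm = TRUE)) {
    stop("counts must be non-negative")
  }
  zero <- !is.na(cpg_count) & cpg_count == 0
  if (any(zero)) {
    warning(sprintf("%d region(s) with zero CpG sites: level undefined",
                    sum(zero)))
  }
  out <- read_count / cpg_count
  out[zero] <- NA_real_
  out
}

#' Rank correlations between promoter methylation and expression
#'
#' Kendall's tau and Spearman's rho over the genes common to both inputs,
#' with two-sided p-values (mid-ranks for ties). A negative correlation is
#' the signature of promoter-methylation silencing.
#'
#' @param levels Named numeric vector of methylation levels by gene.
#' @param fpkm Named numeric vector of expression (FPKM) by gene.
#' @return List \code{(kendall_tau, tau_p, spearman_rho, rho_p, n)}; all
#'   NA with a warning when fewer than 3 genes overlap.
#' @export
correlate_meth_expr <- function(levels, fpkm) {
  common <- intersect(names(levels), names(fpkm))
  x <- levels[common]; y <- fpkm[common]
  keep <- !is.na(x) & !is.na(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3L) {
    warning("fewer than 3 genes in common: correlations undefined")
    return(list(kendall_tau = NA_real_, tau_p = NA_real_,
                spearman_rho = NA_real_, rho_p = NA_real_,
                n = length(x)))
  }
  kt <- suppressWarnings(
    stats::cor.test(x, y, method = "kendall", alternative = "two.sided"))
  sp <- suppressWarnings(
    stats::cor.test(x, y, method = "spearman", alternative = "two.sided"))
  list(kendall_tau = unname(kt$estimate), tau_p = kt$p.value,
       spearman_rho = unname(sp$estimate), rho_p = sp$p.value,
       n = length(x))
}

#' Count motif binding sites in promoter sequences
#'
#' Scans each promoter on both strands and counts the window start
#' positions whose score reaches the motif's threshold at \code{p_level}.
#' Each start position counts once per strand, so overlapping matches at
#' different offsets each contribute.
#'
#' @param pwms List of \code{pwm} objects (all with threshold tables).
#' @param promoters Named character vector (or list) of promoter sequences
#'   keyed by gene symbol (motif-scan flavor).
#' @param p_level Significance level for the threshold (default
#'   \code{1e-4}).
#' @return Integer matrix, genes x motifs, of site counts.
#' @export
count_promoter_sites <- function(pwms, promoters, p_level = 1e-4) {
  promoters <- unlist(promoters)
  if (is.null(names(promoters))) stop("promoters must be named by gene")
  thr <- vapply(pwms, pwm_threshold, numeric(1L), p_level = p_level)
  out <- matrix(0L, nrow = length(promoters), ncol = length(pwms),
                dimnames = list(names(promoters),
                                vapply(pwms, `[[`, character(1L), "name")))
  for (j in seq_along(pwms)) {
    for (i in seq_along(promoters)) {
      seq <- promoters[[i]]
      if (nchar(seq) < pwms[[j]]$length) next
      fwd <- score_positions(pwms[[j]], seq)
      rev <- score_positions(pwms[[j]], reverse_complement(seq))
      out[i, j] <- sum(fwd >= thr[[j]]) + sum(rev >= thr[[j]])
    }
  }
  out
}
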