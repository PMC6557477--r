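#' Score both alleles of a SNP against a PWM (the delta statistic)
#'
#' Computes the four clamped best-window scores (reference and alternative
#' allele, forward and reverse strand) over the windows that overlap the
#' SNP -- the statistic measures SNP-dependent binding, so windows not
#' covering the SNP are ineligible -- and derives
#' \code{delta = ref - alt} and \code{delta_rev = ref_rev - alt_rev}.
#' A SNP x motif pair is \code{significant} when any of the four scores
#' reaches the motif's threshold at \code{p_level}. Negative delta marks a
#' binding site specific to the alternative strain (site created by the
#' alternative allele); positive delta marks a reference-strain-specific
#' site.
#'
#' @param windows Data.frame from \code{\link{build_allele_windows}} (one
#'   or more rows).
#' @param pwm A \code{pwm} object with a threshold table.
#' @param p_level Significance level for the threshold lookup (default
#'   \code{1e-4}).
#' @return Data.frame with one row per SNP: \code{snp_id}, \code{pwm_name},
#'   \code{chrom}, \code{pos}, \code{ref_seq}, \code{alt_seq}, \code{ref},
#'   \code{ref_rev}, \code{alt}, \code{alt_rev} (clamped scores),
#'   \code{delta}, \code{delta_rev}, \code{significant}.
#' @export
score_snp_motif <- function(windows, pwm, p_level = 1e-4) {
  stopifnot(inherits(pwm, "pwm"))
  L <- pwm$length
  thr <- pwm_threshold(pwm, p_level)
  if (nrow(windows) == 0L) {
    out <- data.frame(snp_id = character(), pwm_name = character(),
                      chrom = character(), pos = integer(),
                      ref_seq = character(), alt_seq = character(),
                      ref = numeric(), ref_rev = numeric(), alt = numeric(),
                      alt_rev = numeric(), delta = numeric(),
                      delta_rev = numeric(), significant = logical(),
                      stringsAsFactors = FALSE)
    return(out)
  }
  one <- function(i) {
    off <- windows$snp_offset[[i]]
    w_ref <- windows$ref_seq[[i]]
    w_alt <- windows$alt_seq[[i]]
    # restrict the scan to the sub-window whose L-windows all overlap the SNP
    lo <- max(1L, off - L + 1L)
    hi <- min(nchar(w_ref), off + L - 1L)
    if (hi - lo + 1L < L) {
      stop("window too short to hold one motif-length window over the SNP: ",
           windows$id[[i]])
    }
    r <- best_strand_scores(pwm, substr(w_ref, lo, hi))
    a <- best_strand_scores(pwm, substr(w_alt, lo, hi))
    c(ref = r$plus$score, ref_rev = r$minus$score,
      alt = a$plus$score, alt_rev = a$minus$score)
  }
  sc <- t(vapply(seq_len(nrow(windows)), one, numeric(4L)))
  out <- data.frame(
    snp_id = windows$id, pwm_name = pwm$name,
    chrom = windows$chrom, pos = windows$pos,
    ref_seq = windows$ref_seq, alt_seq = windows$alt_seq,
    ref = sc[, "ref"], ref_rev = sc[, "ref_rev"],
    alt = sc[, "alt"], alt_rev = sc[, "alt_rev"],
    stringsAsFactors = FALSE
  )
  out$delta <- out$ref - out$alt
  out$delta_rev <- out$ref_rev - out$alt_rev
  out$significant <- pmax(out$ref, out$ref_rev, out$alt, out$alt_rev) >= thr
  rownames(out) <- NULL
  out
}

#' Annotate SNPs with the nearest gene
#'
#' Distance is 0 when the SNP lies inside a gene body, otherwise the
#' number of base pairs to the nearer gene boundary (a SNP one base past a
#' gene end is at distance 1). Ties are resolved towards the smaller
#' distance, then the lexicographically smaller gene symbol. SNPs on a
#' chromosome with no genes get symbol \code{NA} and distance \code{NA}.
#'
#' @param snps Data.frame with columns \code{chrom} and \code{pos} (and
#'   optionally \code{id}).
#' @param genes Data.frame with columns \code{chrom}, \code{start},
#'   \code{end} (1-based, inclusive), \code{strand}, \code{symbol}.
#' @return \code{snps} with added columns \code{gene} and \code{distance}.
#' @export
annotate_nearest_gene <- function(snps, genes) {
  need <- c("chrom", "start", "end", "strand", "symbol")
  if (!all(need %in% names(genes))) {
    stop("gene table needs columns: ", paste(need, collapse = ", "))
  }
  lvl <- unique(c(snps$chrom, genes$chrom))
  snp_gr <- GenomicRanges::GRanges(
    factor(snps$chrom, levels = lvl),
    IRanges::IRanges(snps$pos, snps$pos))
  gene_gr <- GenomicRanges::GRanges(
    factor(genes$chrom, levels = lvl),
    IRanges::IRanges(genes$start, genes$end))
  hits <- GenomicRanges::distanceToNearest(snp_gr, gene_gr, select = "all")
  qh <- S4Vectors::queryHits(hits)
  sh <- S4Vectors::subjectHits(hits)
  inside <- GenomicRanges::start(snp_gr)[qh] >= genes$start[sh] &
    GenomicRanges::start(snp_gr)[qh] <= genes$end[sh]
  # IRanges counts gap bases (adjacent = 0); the reporting convention here
  # counts boundary-to-SNP bp (adjacent = 1)
  dist <- ifelse(inside, 0L, S4Vectors::mcols(hits)$distance + 1L)
  sym <- genes$symbol[sh]
  gene_out <- rep(NA_character_, nrow(snps))
  dist_out <- rep(NA_integer_, nrow(snps))
  for (q in unique(qh)) {
    sel <- which(qh == q)
    sel <- sel[order(dist[sel], sym[sel])]
    gene_out[[q]] <- sym[[sel[[1L]]]]
    dist_out[[q]] <- dist[[sel[[1L]]]]
  }
  snps$gene <- gene_out
  snps$distance <- dist_out
  snps
}

#' Integrate motif disruption with expression response
#'
#' Joins per-SNP motif score results with nearest-gene annotation and the
#' genes' Z statistic, then retains the hits that (a) reach motif
#' significance, (b) show a strain-specific score difference
#' \code{|delta| > delta_cut} on either strand, and (c) lie nearest to a
#' gene with \code{|Z| > z_cut}. Hits whose nearest gene has no Z value
#' are dropped with a message. The report is sorted by motif, then
#' chromosome and position.
#'
#' @param results Data.frame of motif score results, typically rbind-ed
#'   outputs of \code{\link{score_snp_motif}} over several motifs.
#' @param zmap Named numeric vector of Z values keyed by gene symbol.
#' @param genes Gene-model data.frame (see
#'   \code{\link{annotate_nearest_gene}}).
#' @param delta_cut Threshold on \code{|delta|} per strand (default 1).
#' @param z_cut Threshold on \code{|Z|} (default 7).
#' @return Data.frame of integrated hits with added columns \code{gene},
#'   \code{distance}, \code{z}, \code{passes_delta}, \code{passes_z}.
#' @export
integrate_hits <- function(results, zmap, genes, delta_cut = 1.0,
                           z_cut = 7.0) {
  stopifnot(delta_cut > 0, z_cut > 0)
  empty <- results[0, , drop = FALSE]
  empty$gene <- character(); empty$distance <- integer()
  empty$z <- numeric(); empty$passes_delta <- logical()
  empty$passes_z <- logical()
  if (nrow(results) == 0L) return(empty)
  ann <- annotate_nearest_gene(results, genes)
  no_z <- !is.na(ann$gene) & !(ann$gene %in% names(zmap))
  if (any(no_z)) {
    message(sprintf("integrate_hits: %d hit(s) dropped (nearest gene missing from Z map)",
                    sum(no_z)))
  }
  ann <- ann[!no_z & !is.na(ann$gene), , drop = FALSE]
  if (nrow(ann) == 0L) return(empty)
  ann$z <- unname(zmap[ann$gene])
  ann$passes_delta <- abs(ann$delta) > delta_cut |
    abs(ann$delta_rev) > delta_cut
  ann$passes_z <- !is.na(ann$z) & abs(ann$z) > z_cut
  hits <- ann[ann$significant & ann$passes_delta & ann$passes_z, ,
              drop = FALSE]
  hits <- hits[order(hits$pwm_name, hits$chrom, hits$pos), , drop = FALSE]
  rownames(hits) <- NULL
  hits
}
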