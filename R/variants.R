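#' Load strain-difference SNPs from a VCF
#'
#' Reads a VCF (v4.x) of variants between an alternative strain and the
#' reference genome and keeps only biallelic single-nucleotide
#' substitutions, optionally restricted to \code{FILTER == PASS}
#' ("high-quality" variants). Indels, MNPs and multi-allelic sites are
#' dropped and the dropped counts reported via \code{message()}.
#'
#' @param vcf_path Path to a VCF file.
#' @param quality_filter Keep only records with \code{FILTER == PASS}
#'   (default \code{TRUE}).
#' @return A data.frame with columns \code{id}, \code{chrom}, \code{pos}
#'   (1-based), \code{ref_allele}, \code{alt_allele}, \code{pass_quality}.
#'   The counts of records dropped at each step are attached as attribute
#'   \code{"dropped"}.
#' @export
read_strain_snps <- function(vcf_path, quality_filter = TRUE) {
  vcf <- VariantAnnotation::readVcf(vcf_path)
  rr <- SummarizedExperiment::rowRanges(vcf)
  n_in <- length(rr)
  chrom <- as.character(GenomicRanges::seqnames(rr))
  pos <- GenomicRanges::start(rr)
  unsorted <- n_in > 1L &&
    any(unlist(tapply(pos, chrom, is.unsorted), use.names = FALSE))
  if (isTRUE(unsorted)) {
    warning("VCF records are not position-sorted; passing them through as-is")
  }
  is_snv <- VariantAnnotation::isSNV(vcf, singleAltOnly = TRUE)
  filt <- VariantAnnotation::fixed(vcf)$FILTER
  pass <- filt == "PASS"
  keep <- is_snv & (if (quality_filter) pass else TRUE)
  n_nonsnv <- sum(!is_snv)
  n_lowq <- sum(is_snv & !pass & quality_filter)
  message(sprintf(
    "read_strain_snps: %d records; kept %d biallelic SNVs (%d non-SNV/multi-allelic dropped, %d failing FILTER dropped)",
    n_in, sum(keep), n_nonsnv, n_lowq))
  ref <- as.character(VariantAnnotation::ref(vcf))[keep]
  alt <- as.character(unlist(VariantAnnotation::alt(vcf)[keep]))
  ids <- names(rr)[keep]
  if (is.null(ids)) ids <- paste0("snv", seq_len(sum(keep)))
  out <- data.frame(
    id = ids,
    chrom = chrom[keep],
    pos = pos[keep],
    ref_allele = ref,
    alt_allele = alt,
    pass_quality = pass[keep],
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  attr(out, "dropped") <- c(non_snv = n_nonsnv, low_quality = n_lowq)
  out
}

#' Reconstruct paired allele windows around SNPs
#'
#' For each SNP, extracts a genomic window of length 2L (motif length L)
#' with the SNP at window index L (1-based), so that every L-window
#' overlapping the SNP is contained in it, and builds the two
#' strain-specific alleles: the reference sequence read from the genome
#' and the alternative sequence with the alternative base substituted at
#' the SNP. Windows are truncated at chromosome ends (with the SNP index
#' adjusted accordingly). SNPs whose genome base disagrees with the VCF
#' reference allele are flagged and skipped with a message.
#'
#' @param snps Data.frame from \code{\link{read_strain_snps}}.
#' @param genome A \code{Biostrings::DNAStringSet} (or path to a FASTA
#'   file) whose names match \code{snps$chrom}.
#' @param L Motif length in bp.
#' @return Data.frame with one row per usable SNP: \code{id}, \code{chrom},
#'   \code{pos}, \code{window_start}, \code{window_end} (1-based,
#'   inclusive), \code{snp_offset} (1-based index of the SNP within the
#'   window), \code{ref_seq}, \code{alt_seq}. The number of
#'   reference-mismatch records skipped is attached as attribute
#'   \code{"n_ref_mismatch"}.
#' @export
build_allele_windows <- function(snps, genome, L) {
  if (is.character(genome)) {
    genome <- Biostrings::readDNAStringSet(genome)
    names(genome) <- sub("\\s.*$", "", names(genome))
  }
  stopifnot(methods::is(genome, "DNAStringSet"))
  L <- as.integer(L)
  stopifnot(L >= 1L)
  missing_chr <- setdiff(unique(snps$chrom), names(genome))
  if (length(missing_chr)) {
    stop("chromosome(s) absent from genome FASTA: ",
         paste(missing_chr, collapse = ", "))
  }
  chr_len <- stats::setNames(Biostrings::width(genome), names(genome))
  n <- nrow(snps)
  if (n == 0L) {
    out <- data.frame(id = character(), chrom = character(), pos = integer(),
                      window_start = integer(), window_end = integer(),
                      snp_offset = integer(), ref_seq = character(),
                      alt_seq = character(), stringsAsFactors = FALSE)
    attr(out, "n_ref_mismatch") <- 0L
    return(out)
  }
  len <- chr_len[snps$chrom]
  if (any(snps$pos < 1L | snps$pos > len)) {
    stop("SNP position outside chromosome bounds")
  }
  ws <- pmax(1L, snps$pos - (L - 1L))
  we <- pmin(unname(len), snps$pos + L)
  off <- snps$pos - ws + 1L
  seqs <- as.character(Biostrings::subseq(genome[snps$chrom], start = ws,
                                          end = we))
  genome_base <- substr(seqs, off, off)
  ok <- genome_base == snps$ref_allele
  if (any(!ok)) {
    message(sprintf(
      "build_allele_windows: %d SNP(s) skipped (genome base does not match VCF reference allele)",
      sum(!ok)))
  }
  alt_seqs <- seqs
  substr(alt_seqs, off, off) <- snps$alt_allele
  out <- data.frame(
    id = snps$id, chrom = snps$chrom, pos = snps$pos,
    window_start = ws, window_end = we, snp_offset = off,
    ref_seq = seqs, alt_seq = alt_seqs,
    stringsAsFactors = FALSE
  )[ok, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_ref_mismatch") <- sum(!ok)
  out
}
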