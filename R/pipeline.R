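#' Assemble and validate a pipeline configuration
#'
#' Collects the file paths and thresholds used by \code{\link{run_scan}}
#' and friends. Referenced input paths must exist at run time.
#'
#' @param genome Path to the genome FASTA.
#' @param vcf Path to the strain-difference SNP VCF.
#' @param pwm_dir Directory of HOCOMOCO-style \code{*.pwm} files (with
#'   companion \code{*.pwm.thr} threshold tables).
#' @param gene_table Path to a gene-model TSV with columns \code{chrom},
#'   \code{start}, \code{end}, \code{strand}, \code{symbol}.
#' @param fpkm Path to a condition-level FPKM TSV (column \code{gene} plus
#'   one column per condition).
#' @param methylation Optional path to a methylation TSV with columns
#'   \code{gene}, \code{condition}, \code{cpg_count}, \code{read_count}.
#' @param out_dir Output directory for reports.
#' @param delta_cut,z_cut,p_level,pseudocount Analysis thresholds
#'   (defaults 1, 7, 1e-4, 0.1).
#' @param report_decimals Decimals for rounded score columns in the
#'   human-readable report (default 2; the machine-readable report keeps
#'   full precision).
#' @param conditions The four condition labels entering Z, in
#'   \code{\link{z_conditions}} order.
#' @return A list of class \code{"pipeline_config"}.
#' @export
pipeline_config <- function(genome, vcf, pwm_dir, gene_table, fpkm,
                            methylation = NULL, out_dir = ".",
                            delta_cut = 1.0, z_cut = 7.0, p_level = 1e-4,
                            pseudocount = 0.1, report_decimals = 2L,
                            conditions = z_conditions()) {
  stopifnot(delta_cut > 0, z_cut > 0, p_level > 0, p_level < 1,
            pseudocount >= 0, length(conditions) == 4L)
  cfg <- list(genome = genome, vcf = vcf, pwm_dir = pwm_dir,
              gene_table = gene_table, fpkm = fpkm,
              methylation = methylation, out_dir = out_dir,
              delta_cut = delta_cut, z_cut = z_cut, p_level = p_level,
              pseudocount = pseudocount,
              report_decimals = as.integer(report_decimals),
              conditions = conditions)
  required <- c("genome", "vcf", "pwm_dir", "gene_table", "fpkm")
  for (nm in required) {
    if (!file.exists(cfg[[nm]])) {
      stop(sprintf("pipeline input '%s' does not exist: %s", nm, cfg[[nm]]))
    }
  }
  if (!is.null(cfg$methylation) && !file.exists(cfg$methylation)) {
    stop("pipeline input 'methylation' does not exist: ", cfg$methylation)
  }
  structure(cfg, class = "pipeline_config")
}

load_pwm_dir <- function(pwm_dir) {
  files <- sort(list.files(pwm_dir, pattern = "\\.pwm$", full.names = TRUE))
  if (!length(files)) stop("no *.pwm files found in ", pwm_dir)
  pwms <- lapply(files, read_pwm)
  names(pwms) <- vapply(pwms, `[[`, character(1L), "name")
  pwms
}

read_gene_table <- function(path) {
  genes <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("chrom", "start", "end", "strand", "symbol")
  if (!all(need %in% names(genes))) {
    stop("gene table needs columns: ", paste(need, collapse = ", "))
  }
  genes
}

#' Run the allele-motif interaction scan
#'
#' End-to-end scan: loads the genome, SNPs, motif models, gene models and
#' FPKM table, reconstructs allele windows per motif, scores both alleles
#' on both strands, computes Z, integrates and filters, and writes two
#' reports into \code{out_dir}: \code{snp_motif_report.tsv} (scores and
#' deltas rounded to \code{report_decimals}) and
#' \code{snp_motif_report_full.tsv} (full precision).
#'
#' @param config A \code{\link{pipeline_config}}.
#' @return The integrated hit data.frame, invisibly.
#' @export
run_scan <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  genome <- Biostrings::readDNAStringSet(config$genome)
  names(genome) <- sub("\\s.*$", "", names(genome))
  snps <- read_strain_snps(config$vcf)
  pwms <- load_pwm_dir(config$pwm_dir)
  genes <- read_gene_table(config$gene_table)
  fpkm <- utils::read.delim(config$fpkm, stringsAsFactors = FALSE)
  z <- compute_z(fpkm, conditions = config$conditions,
                 pseudocount = config$pseudocount)
  scores <- do.call(rbind, lapply(pwms, function(pw) {
    windows <- build_allele_windows(snps, genome, pw$length)
    score_snp_motif(windows, pw, p_level = config$p_level)
  }))
  rownames(scores) <- NULL
  hits <- integrate_hits(scores, z, genes, delta_cut = config$delta_cut,
                         z_cut = config$z_cut)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  full_path <- file.path(config$out_dir, "snp_motif_report_full.tsv")
  utils::write.table(hits, full_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  rounded <- hits
  for (cl in c("ref", "ref_rev", "alt", "alt_rev", "delta", "delta_rev",
               "z")) {
    rounded[[cl]] <- round(rounded[[cl]], config$report_decimals)
  }
  report <- rounded[, c("snp_id", "pwm_name", "ref_seq", "alt_seq", "delta",
                        "delta_rev", "ref", "ref_rev", "alt", "alt_rev",
                        "gene", "distance", "z")]
  utils::write.table(report,
                     file.path(config$out_dir, "snp_motif_report.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(hits)
}

#' Summarise the target catalog to a TSV report
#'
#' @param catalog_path Path to a catalog TSV; defaults to the shipped
#'   fixture.
#' @param out_dir Output directory.
#' @return The summary list, invisibly.
#' @export
run_catalog <- function(catalog_path = NULL, out_dir = ".") {
  cat <- if (is.null(catalog_path)) read_target_catalog() else
    read_target_catalog(catalog_path)
  s <- catalog_summaries(cat)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- data.frame(
    quantity = c("n_total", "n_hormonal", "n_androgen",
                 paste0("class_", names(s$class_counts)),
                 "percent_increasing", "n_yes", "n_no", "n_na"),
    value = c(s$n_total, s$n_hormonal, s$n_androgen,
              as.integer(s$class_counts), s$percent_increasing,
              s$n_yes, s$n_no, s$n_na)
  )
  utils::write.table(out, file.path(out_dir, "catalog_summary.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(s)
}

#' Run the promoter methylation-expression integration
#'
#' Computes per-promoter methylation levels (reads per CpG) and their
#' Kendall/Spearman rank correlations with expression, per condition, and
#' writes \code{methylation_correlations.tsv}.
#'
#' @param methylation_path TSV with columns \code{gene}, \code{condition},
#'   \code{cpg_count}, \code{read_count}.
#' @param fpkm_path Condition-level FPKM TSV.
#' @param out_dir Output directory.
#' @return Data.frame of per-condition correlations, invisibly.
#' @export
run_methylation <- function(methylation_path, fpkm_path, out_dir = ".") {
  meth <- utils::read.delim(methylation_path, stringsAsFactors = FALSE)
  fpkm <- utils::read.delim(fpkm_path, stringsAsFactors = FALSE)
  conds <- intersect(unique(meth$condition), names(fpkm))
  if (!length(conds)) stop("no common condition between the two tables")
  rows <- lapply(conds, function(cl) {
    m <- meth[meth$condition == cl, , drop = FALSE]
    lvl <- stats::setNames(methylation_level(m$read_count, m$cpg_count),
                           m$gene)
    expr <- stats::setNames(fpkm[[cl]], fpkm$gene)
    r <- correlate_meth_expr(lvl, expr)
    data.frame(condition = cl, kendall_tau = r$kendall_tau,
               tau_p = r$tau_p, spearman_rho = r$spearman_rho,
               rho_p = r$rho_p, n = r$n)
  })
  out <- do.call(rbind, rows)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.table(out,
                     file.path(out_dir, "methylation_correlations.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(out)
}

#' Simulate a dataset to disk
#'
#' @param seed Integer seed.
#' @param out_dir Output directory for the bundle files.
#' @param ... Further arguments to \code{\link{simulation_config}}.
#' @return The bundle, invisibly.
#' @export
run_simulate <- function(seed = 7L, out_dir = "sim_bundle", ...) {
  cfg <- simulation_config(seed = seed, ...)
  invisible(simulate_dataset(cfg, dir = out_dir))
}
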