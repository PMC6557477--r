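#' Build a sharply informative synthetic PWM
#'
#' Synthetic motifs carry weight \code{match} at the consensus base and
#' \code{mismatch} elsewhere, so the score of a window is determined by
#' its Hamming distance to the consensus and score thresholds are
#' unambiguous at toy scale. The default threshold table is calibrated
#' exactly against the i.i.d. uniform-ACGT background of the simulated
#' genome: a window's score is determined by its match count m to the
#' 10-bp consensus (score = 4m - 20, m ~ Binomial(10, 1/4)), and each
#' level maps to the smallest score whose tail probability is below it
#' (P(m>=7) = 3.5e-3 < 0.01, P(m>=8) = 4.2e-4 < 0.001,
#' P(m>=9) = 3.0e-5 < 1e-4).
#'
#' @param name Motif name.
#' @param consensus Consensus DNA string.
#' @param match,mismatch Weights for consensus/non-consensus bases.
#' @param thresholds Named numeric threshold vector (p-value level ->
#'   score).
#' @return A \code{pwm} object.
#' @export
synthetic_pwm <- function(name, consensus, match = 2, mismatch = -2,
                          thresholds = c("0.01" = 8, "0.001" = 12,
                                         "0.0001" = 16)) {
  bases <- strsplit(consensus, "", fixed = TRUE)[[1L]]
  stopifnot(all(bases %in% DNA_BASES))
  w <- matrix(mismatch, nrow = length(bases), ncol = 4L,
              dimnames = list(NULL, DNA_BASES))
  w[cbind(seq_along(bases), match(bases, DNA_BASES))] <- match
  new_pwm(name, w, thresholds)
}

# The five synthetic motifs emulate the hormone-receptor motif families
# scanned in the real analysis (AR, ESR1, FOXA1-3); consensi are fixed
# arbitrary 10-mers chosen to be mutually dissimilar and non-palindromic.
synthetic_pwm_set <- function() {
  cons <- c(SYN_AR = "AGAACAGGGA", SYN_ESR1 = "CTGGGTCACA",
            SYN_FOXA1 = "TGTTTACACA", SYN_FOXA2 = "GGATCCTTGA",
            SYN_FOXA3 = "CCAGTAATCC")
  lapply(names(cons), function(nm) synthetic_pwm(nm, cons[[nm]]))
}

#' Default planted genome-by-exposure interactions
#'
#' Five planted SNP-motif-expression interactions: two resistance-like
#' (the alternative allele creates a binding site, expected delta < 0,
#' treatment induction planted in the alternative strain) and three
#' susceptibility-like (the alternative allele destroys a reference-strain
#' site, expected delta > 0, treatment silencing planted in the reference
#' strain). Planted effect sizes (|delta| = 4 score units, |Z| = 10)
#' clear the reporting thresholds (1 and 7) with margin.
#'
#' @return Data.frame with columns \code{pwm_name}, \code{effect},
#'   \code{target_gene} (index into the simulated gene table) and
#'   \code{z_effect}.
#' @export
default_planted_interactions <- function() {
  data.frame(
    pwm_name = c("SYN_FOXA1", "SYN_FOXA2", "SYN_AR", "SYN_AR", "SYN_ESR1"),
    effect = c("create_site", "create_site", "destroy_site", "destroy_site",
               "destroy_site"),
    target_gene = c(3L, 8L, 14L, 25L, 33L),
    z_effect = c(10, 10, 10, 10, 10),
    stringsAsFactors = FALSE
  )
}

#' Simulation configuration
#'
#' Assembles and validates the parameters of the synthetic dataset: a
#' small uniform-composition genome carrying genes on a regular grid,
#' null SNPs scattered at random, and planted SNPs that create or destroy
#' consensus motif instances next to target genes whose FPKM tables carry
#' a planted strain-by-treatment response against log-normal background
#' expression with log2-normal condition noise.
#'
#' @param seed Integer seed; the single source of randomness.
#' @param n_chromosomes Number of chromosomes.
#' @param genes_per_chromosome Genes per chromosome, placed every
#'   \code{gene_spacing} bp.
#' @param gene_length,gene_spacing Gene body length and grid spacing (bp).
#' @param n_null_snps Background SNPs with no planted effect.
#' @param planted_interactions Data.frame as
#'   \code{\link{default_planted_interactions}}; may have zero rows.
#' @param snp_gene_distance Distance (bp) from a planted SNP to its target
#'   gene's start.
#' @param fpkm_noise_sd SD of per-condition log2 FPKM noise.
#' @param baseline_fpkm_meanlog,baseline_fpkm_sdlog Log-normal parameters
#'   of baseline gene expression.
#' @param meth_baseline Baseline promoter methylation level (reads per
#'   CpG).
#' @param meth_expr_slope Strength of the negative coupling between log2
#'   expression and methylation level (silencing signature).
#' @param meth_noise_sd SD of methylation level noise.
#' @param silencing_shift Extra methylation level added in the treated
#'   reference-strain condition at silenced target promoters.
#' @return A validated list of class \code{"sim_config"}.
#' @export
simulation_config <- function(seed = 7L,
                              n_chromosomes = 2L,
                              genes_per_chromosome = 20L,
                              gene_length = 1000L,
                              gene_spacing = 2500L,
                              n_null_snps = 500L,
                              planted_interactions = default_planted_interactions(),
                              snp_gene_distance = 300L,
                              fpkm_noise_sd = 0.25,
                              baseline_fpkm_meanlog = log(300),
                              baseline_fpkm_sdlog = 0.4,
                              meth_baseline = 3,
                              meth_expr_slope = 0.4,
                              meth_noise_sd = 0.15,
                              silencing_shift = 1.5) {
  cfg <- list(seed = as.integer(seed), n_chromosomes = as.integer(n_chromosomes),
              genes_per_chromosome = as.integer(genes_per_chromosome),
              gene_length = as.integer(gene_length),
              gene_spacing = as.integer(gene_spacing),
              n_null_snps = as.integer(n_null_snps),
              planted_interactions = planted_interactions,
              snp_gene_distance = as.integer(snp_gene_distance),
              fpkm_noise_sd = fpkm_noise_sd,
              baseline_fpkm_meanlog = baseline_fpkm_meanlog,
              baseline_fpkm_sdlog = baseline_fpkm_sdlog,
              meth_baseline = meth_baseline,
              meth_expr_slope = meth_expr_slope,
              meth_noise_sd = meth_noise_sd,
              silencing_shift = silencing_shift)
  counts <- c(cfg$n_chromosomes, cfg$genes_per_chromosome, cfg$gene_length,
              cfg$gene_spacing, cfg$n_null_snps, cfg$snp_gene_distance)
  stopifnot(all(counts >= 0L), cfg$n_chromosomes >= 1L,
            cfg$fpkm_noise_sd >= 0, cfg$meth_noise_sd >= 0)
  pl <- cfg$planted_interactions
  if (nrow(pl)) {
    stopifnot(all(pl$effect %in% c("create_site", "destroy_site")),
              all(pl$z_effect != 0))
    n_genes <- cfg$n_chromosomes * cfg$genes_per_chromosome
    if (any(pl$target_gene < 1L | pl$target_gene > n_genes)) {
      stop("planted target_gene index outside the simulated gene table")
    }
    if (cfg$snp_gene_distance >= cfg$gene_spacing - cfg$gene_length) {
      stop("snp_gene_distance too large: planted SNP would be nearer to the upstream gene")
    }
    if (anyDuplicated(pl$target_gene)) {
      stop("each planted interaction needs its own target gene")
    }
  }
  structure(cfg, class = "sim_config")
}

# deterministic "different base": next base in A->C->G->T->A order
other_base <- function(base) {
  DNA_BASES[(match(base, DNA_BASES)) %% 4L + 1L]
}

#' Simulate a full in-silico dataset with planted interactions
#'
#' Generates a genome, gene models, a strain-difference SNP set (null +
#' planted), the synthetic PWM set, condition-level FPKM tables for the
#' four F1 conditions and a promoter methylation table, together with a
#' truth manifest of the planted interactions. Planted SNPs either insert
#' a consensus motif in the alternative allele (resistance-like, delta
#' strongly negative) or break a site present in the reference allele
#' (susceptibility-like, delta strongly positive); target genes sit
#' \code{snp_gene_distance} bp downstream of their SNP so they are the
#' nearest gene. Fully reproducible from \code{cfg$seed}.
#'
#' @param cfg A \code{\link{simulation_config}}.
#' @param dir Optional directory; when given, all components are written
#'   as plain-text files (FASTA, VCF, TSV, PWM text) and the paths are
#'   returned in the bundle.
#' @return A list bundle: \code{genome} (DNAStringSet), \code{snps},
#'   \code{genes}, \code{pwms}, \code{fpkm}, \code{methylation},
#'   \code{truth}, \code{bundle_id}, and \code{paths} when written.
#' @export
simulate_dataset <- function(cfg, dir = NULL) {
  stopifnot(inherits(cfg, "sim_config"))
  withr::with_seed(cfg$seed, simulate_dataset_impl(cfg, dir))
}

simulate_dataset_impl <- function(cfg, dir) {
  pwms <- synthetic_pwm_set()
  names(pwms) <- vapply(pwms, `[[`, character(1L), "name")
  L <- unique(vapply(pwms, `[[`, integer(1L), "length"))
  stopifnot(length(L) == 1L)
  chrom_len <- cfg$genes_per_chromosome * cfg$gene_spacing + 2000L
  chroms <- paste0("chr", seq_len(cfg$n_chromosomes))

  # genome: i.i.d. uniform ACGT
  genome <- Biostrings::DNAStringSet(vapply(chroms, function(ch) {
    paste(sample(DNA_BASES, chrom_len, replace = TRUE), collapse = "")
  }, character(1L)))
  names(genome) <- chroms

  # gene grid; alternating strand
  n_genes <- cfg$n_chromosomes * cfg$genes_per_chromosome
  gi <- seq_len(n_genes)
  chrom_of <- chroms[ceiling(gi / cfg$genes_per_chromosome)]
  slot <- (gi - 1L) %% cfg$genes_per_chromosome
  start <- slot * cfg$gene_spacing + 1500L
  genes <- data.frame(
    chrom = chrom_of, start = start, end = start + cfg$gene_length - 1L,
    strand = rep_len(c("+", "-"), n_genes),
    symbol = sprintf("gene%03d", gi),
    stringsAsFactors = FALSE
  )

  # planted SNPs: embed motif instance with the SNP at motif position 6
  pl <- cfg$planted_interactions
  planted <- NULL
  if (nrow(pl)) {
    snp_pos <- genes$start[pl$target_gene] - cfg$snp_gene_distance
    snp_chrom <- genes$chrom[pl$target_gene]
    motif_off <- 6L
    ref_bases <- alt_bases <- character(nrow(pl))
    for (i in seq_len(nrow(pl))) {
      pw <- pwms[[pl$pwm_name[[i]]]]
      consensus <- DNA_BASES[apply(pw$weights, 1L, which.max)]
      site <- consensus
      if (pl$effect[[i]] == "create_site") {
        # reference carries a one-mismatch site; the alternative allele
        # restores the consensus
        site[motif_off] <- other_base(consensus[motif_off])
        ref_bases[i] <- site[motif_off]
        alt_bases[i] <- consensus[motif_off]
      } else {
        ref_bases[i] <- consensus[motif_off]
        alt_bases[i] <- other_base(consensus[motif_off])
      }
      m_start <- snp_pos[i] - motif_off + 1L
      stopifnot(m_start >= 1L)
      genome[[snp_chrom[i]]] <- Biostrings::replaceAt(
        genome[[snp_chrom[i]]],
        IRanges::IRanges(m_start, m_start + pw$length - 1L),
        paste(site, collapse = ""))
    }
    planted <- data.frame(
      id = sprintf("sim_rs_p%02d", seq_len(nrow(pl))),
      chrom = snp_chrom, pos = snp_pos,
      ref_allele = ref_bases, alt_allele = alt_bases,
      stringsAsFactors = FALSE
    )
    # Scrub the flanks of each planted locus: redraw the bases around the
    # embedded motif until no OTHER motif is score-significant at the SNP,
    # so each planted SNP disrupts exactly the motif it was planted for
    # and the truth manifest stays unambiguous.
    for (i in seq_len(nrow(pl))) {
      m_start <- snp_pos[i] - motif_off + 1L
      m_end <- m_start + pwms[[pl$pwm_name[[i]]]]$length - 1L
      flank <- setdiff(seq(max(1L, snp_pos[i] - (L - 1L)),
                           min(chrom_len, snp_pos[i] + (L - 1L))),
                       seq(m_start, m_end))
      clean <- FALSE
      for (attempt in 1:100) {
        clean <- TRUE
        for (nm in names(pwms)) {
          if (nm == pl$pwm_name[[i]]) next
          w <- build_allele_windows(planted[i, , drop = FALSE], genome,
                                    pwms[[nm]]$length)
          if (score_snp_motif(w, pwms[[nm]])$significant) {
            clean <- FALSE
            break
          }
        }
        if (clean) break
        genome[[snp_chrom[i]]] <- Biostrings::replaceAt(
          genome[[snp_chrom[i]]], IRanges::IRanges(flank, flank),
          sample(DNA_BASES, length(flank), replace = TRUE))
      }
      if (!clean) {
        stop("could not construct an unambiguous flank for planted SNP ",
             planted$id[i])
      }
    }
  }

  # Null SNPs keep clear of the planted loci: both the planted motif
  # footprint and the whole neighborhood of each target gene are excluded,
  # so that no null SNP has a planted-response gene as its nearest gene
  # and the truth manifest stays unambiguous.
  excluded <- if (!is.null(planted)) {
    c(GenomicRanges::GRanges(planted$chrom,
                             IRanges::IRanges(planted$pos - L,
                                              planted$pos + L)),
      GenomicRanges::GRanges(
        genes$chrom[pl$target_gene],
        IRanges::IRanges(pmax(1L, genes$start[pl$target_gene] - cfg$gene_spacing),
                         genes$end[pl$target_gene] + cfg$gene_spacing)))
  } else {
    GenomicRanges::GRanges()
  }
  null_snps <- NULL
  if (cfg$n_null_snps > 0L) {
    n_draw <- cfg$n_null_snps * 2L
    cand_chrom <- sample(chroms, n_draw, replace = TRUE)
    cand_pos <- sample.int(chrom_len - 2L * L, n_draw, replace = TRUE) + L
    cand <- GenomicRanges::GRanges(cand_chrom,
                                   IRanges::IRanges(cand_pos, cand_pos))
    ok <- !IRanges::overlapsAny(cand, excluded) &
      !duplicated(paste(cand_chrom, cand_pos))
    take <- which(ok)[seq_len(cfg$n_null_snps)]
    if (anyNA(take)) stop("could not place the requested number of null SNPs")
    refb <- vapply(take, function(k) {
      as.character(Biostrings::subseq(genome[[cand_chrom[k]]],
                                      cand_pos[k], cand_pos[k]))
    }, character(1L))
    altb <- vapply(refb, other_base, character(1L))
    null_snps <- data.frame(
      id = sprintf("sim_rs_n%04d", seq_len(cfg$n_null_snps)),
      chrom = cand_chrom[take], pos = cand_pos[take],
      ref_allele = refb, alt_allele = unname(altb),
      stringsAsFactors = FALSE
    )
  }
  snps <- rbind(planted, null_snps)
  if (is.null(snps)) {
    snps <- data.frame(id = character(), chrom = character(), pos = integer(),
                       ref_allele = character(), alt_allele = character(),
                       stringsAsFactors = FALSE)
  }
  snps <- snps[order(snps$chrom, snps$pos), , drop = FALSE]
  snps$pass_quality <- TRUE
  rownames(snps) <- NULL

  # FPKM: log-normal baseline, log2-normal condition noise, planted
  # response on the treated column of the affected strain
  conds <- z_conditions()
  baseline <- stats::rlnorm(n_genes, cfg$baseline_fpkm_meanlog,
                            cfg$baseline_fpkm_sdlog)
  fpkm <- data.frame(gene = genes$symbol, stringsAsFactors = FALSE)
  for (cl in conds) {
    fpkm[[cl]] <- baseline * 2^stats::rnorm(n_genes, 0, cfg$fpkm_noise_sd)
  }
  if (nrow(pl)) {
    for (i in seq_len(nrow(pl))) {
      g <- pl$target_gene[[i]]
      if (pl$effect[[i]] == "create_site") {
        fpkm$FVB.D300.F1[g] <- fpkm$FVB.D300.F1[g] * 2^pl$z_effect[[i]]
      } else {
        fpkm$C57.D300.F1[g] <- fpkm$C57.D300.F1[g] * 2^(-pl$z_effect[[i]])
      }
    }
  }

  # promoter methylation: reads-per-CpG level negatively coupled to log2
  # expression, plus a silencing shift at destroyed-site targets in the
  # treated reference-strain condition
  cpg <- stats::rpois(n_genes, 20) + 5L
  silenced <- if (nrow(pl)) pl$target_gene[pl$effect == "destroy_site"] else integer()
  meth <- do.call(rbind, lapply(conds, function(cl) {
    lvl <- cfg$meth_baseline -
      cfg$meth_expr_slope * log2(fpkm[[cl]] + 0.1) +
      stats::rnorm(n_genes, 0, cfg$meth_noise_sd)
    if (cl == "C57.D300.F1" && length(silenced)) {
      lvl[silenced] <- lvl[silenced] + cfg$silencing_shift
    }
    lvl <- pmax(lvl, 0)
    data.frame(gene = genes$symbol, condition = cl, cpg_count = cpg,
               read_count = as.integer(round(lvl * cpg)),
               stringsAsFactors = FALSE)
  }))
  rownames(meth) <- NULL

  truth <- if (nrow(pl)) {
    data.frame(
      snp_id = planted$id, chrom = planted$chrom, pos = planted$pos,
      pwm_name = pl$pwm_name, effect = pl$effect,
      expected_delta_sign = ifelse(pl$effect == "create_site", -1L, 1L),
      gene = genes$symbol[pl$target_gene],
      z_effect = pl$z_effect,
      stringsAsFactors = FALSE
    )
  } else {
    data.frame(snp_id = character(), chrom = character(), pos = integer(),
               pwm_name = character(), effect = character(),
               expected_delta_sign = integer(), gene = character(),
               z_effect = numeric(), stringsAsFactors = FALSE)
  }

  bundle_id <- sprintf("sim-%d-%d-%d", cfg$seed, cfg$n_null_snps, nrow(pl))
  attr(truth, "bundle_id") <- bundle_id
  bundle <- list(genome = genome, snps = snps, genes = genes, pwms = pwms,
                 fpkm = fpkm, methylation = meth, truth = truth,
                 bundle_id = bundle_id, config = cfg)
  if (!is.null(dir)) {
    bundle$paths <- write_bundle(bundle, dir)
  }
  bundle
}

write_bundle <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p <- list(
    genome = file.path(dir, "genome.fa"),
    vcf = file.path(dir, "snps.vcf"),
    genes = file.path(dir, "genes.tsv"),
    pwm_dir = file.path(dir, "pwms"),
    fpkm = file.path(dir, "fpkm.tsv"),
    methylation = file.path(dir, "methylation.tsv"),
    truth = file.path(dir, "truth_manifest.tsv")
  )
  Biostrings::writeXStringSet(bundle$genome, p$genome)
  write_snp_vcf(bundle$snps, bundle$genome, p$vcf)
  utils::write.table(bundle$genes, p$genes, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  dir.create(p$pwm_dir, showWarnings = FALSE)
  for (pw in bundle$pwms) {
    write_pwm(pw, file.path(p$pwm_dir, paste0(pw$name, ".pwm")))
  }
  utils::write.table(bundle$fpkm, p$fpkm, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(bundle$methylation, p$methylation, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(bundle$truth, p$truth, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  p
}

# minimal sorted VCF v4.2 writer for the simulated SNP set
write_snp_vcf <- function(snps, genome, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##fileformat=VCFv4.2", con)
  for (ch in names(genome)) {
    writeLines(sprintf("##contig=<ID=%s,length=%d>", ch,
                       Biostrings::width(genome)[names(genome) == ch]), con)
  }
  writeLines("#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO", con)
  if (nrow(snps)) {
    ord <- order(snps$chrom, snps$pos)
    writeLines(sprintf("%s\t%d\t%s\t%s\t%s\t.\t%s\t.",
                       snps$chrom[ord], snps$pos[ord], snps$id[ord],
                       snps$ref_allele[ord], snps$alt_allele[ord],
                       ifelse(snps$pass_quality[ord], "PASS", "LowQual")),
               con)
  }
  invisible(path)
}

#' Run the full allele-motif scan on a simulated bundle
#'
#' Convenience wrapper chaining window reconstruction, per-motif allele
#' scoring, Z computation and integration at the reporting thresholds.
#'
#' @param bundle Output of \code{\link{simulate_dataset}}.
#' @param delta_cut,z_cut,p_level Reporting thresholds (defaults 1, 7,
#'   1e-4).
#' @return Integrated hit data.frame (see \code{\link{integrate_hits}})
#'   with the bundle id attached as attribute \code{"bundle_id"}.
#' @export
scan_bundle <- function(bundle, delta_cut = 1.0, z_cut = 7.0,
                        p_level = 1e-4) {
  scores <- do.call(rbind, lapply(bundle$pwms, function(pw) {
    windows <- build_allele_windows(bundle$snps, bundle$genome, pw$length)
    score_snp_motif(windows, pw, p_level = p_level)
  }))
  z <- compute_z(bundle$fpkm)
  hits <- integrate_hits(scores, z, bundle$genes, delta_cut = delta_cut,
                         z_cut = z_cut)
  attr(hits, "bundle_id") <- bundle$bundle_id
  hits
}

#' Compare recovered hits against the planted truth
#'
#' @param hits Integrated hits from \code{\link{scan_bundle}} (or
#'   \code{\link{integrate_hits}}).
#' @param truth Truth manifest from the same bundle.
#' @return List \code{(sensitivity, false_positives, sign_concordance,
#'   n_planted, n_recovered)}; sensitivity and sign concordance are NA
#'   for a null bundle with nothing planted.
#' @export
evaluate_recovery <- function(hits, truth) {
  hid <- attr(hits, "bundle_id")
  tid <- attr(truth, "bundle_id")
  if (!is.null(hid) && !is.null(tid) && !identical(hid, tid)) {
    stop("hits and truth manifest come from different bundles")
  }
  key <- function(id, pwm) paste(id, pwm, sep = "\r")
  truth_keys <- key(truth$snp_id, truth$pwm_name)
  hit_keys <- key(hits$snp_id, hits$pwm_name)
  recovered <- truth_keys %in% hit_keys
  fp <- sum(!(hit_keys %in% truth_keys))
  sens <- if (nrow(truth)) mean(recovered) else NA_real_
  sign_ok <- NA_real_
  if (any(recovered)) {
    m <- match(truth_keys[recovered], hit_keys)
    sign_ok <- mean(sign(hits$delta[m]) == truth$expected_delta_sign[recovered])
  }
  list(sensitivity = sens, false_positives = fp,
       sign_concordance = sign_ok,
       n_planted = nrow(truth), n_recovered = sum(recovered))
}
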