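# a window pair laid out by hand: L = 4 consensus-style matrix
toy_pwm4 <- function(thr = c("0.0001" = 6)) {
  # consensus ACGT, match 2, mismatch -2
  w <- matrix(-2, 4, 4, dimnames = list(NULL, BASES))
  w[cbind(1:4, match(c("A", "C", "G", "T"), BASES))] <- 2
  new_pwm("TOY4", w, thresholds = thr)
}

window_row <- function(ref_seq, alt_seq, off, id = "s1") {
  data.frame(id = id, chrom = "chr1", pos = 100L,
             window_start = 100L - off + 1L,
             window_end = 100L - off + nchar(ref_seq),
             snp_offset = off, ref_seq = ref_seq, alt_seq = alt_seq,
             stringsAsFactors = FALSE)
}

test_that("allele scoring reports clamped scores, deltas and the ANY-score significance rule", {
  pwm <- toy_pwm4()
  # ref carries the consensus around the SNP, alt breaks it: T -> G at offset 4
  row <- window_row("ACGTACGA", "ACGGACGA", 4L)
  res <- score_snp_motif(row, pwm)
  expect_equal(res$ref, 8)          # perfect consensus window
  expect_equal(res$alt, 4)          # one mismatch
  expect_equal(res$delta, 4)
  expect_equal(res$delta_rev, res$ref_rev - res$alt_rev)
  expect_true(res$significant)      # ref reaches 6

  # only the alternative allele reaches the threshold: still significant
  row2 <- window_row("ACGGACGA", "ACGTACGA", 4L)
  res2 <- score_snp_motif(row2, pwm)
  expect_true(res2$significant)
  expect_equal(res2$delta, -4)

  # nothing near the threshold: not significant
  row3 <- window_row("AAAAAAAA", "AACAAAAA", 3L)
  res3 <- score_snp_motif(row3, pwm)
  expect_false(res3$significant)
})

test_that("windows not overlapping the SNP are ineligible", {
  pwm <- toy_pwm4()
  # perfect consensus sits at positions 5-8, shared by both alleles;
  # the SNP at offset 4 only touches windows starting at 1-4, and the
  # eligible scan region 1..7 never sees the full flank site
  ref <- paste0("TTTA", "ACGT")
  alt <- paste0("TTTC", "ACGT")
  res <- score_snp_motif(window_row(ref, alt, 4L), pwm)
  expect_lt(res$ref, 8)
  expect_lt(res$alt, 8)
  # whereas an unrestricted scan of the full window would find the site
  expect_equal(best_strand_scores(pwm, ref)$plus$score, 8)
})

test_that("zero-information positions give delta 0 for both strands", {
  flat <- new_pwm("FLAT", matrix(1, 4, 4), thresholds = c("0.0001" = 10))
  res <- score_snp_motif(window_row("ACGTACGA", "ACGGACGA", 4L), flat)
  expect_equal(res$delta, 0)
  expect_equal(res$delta_rev, 0)
})

test_that("delta negates when the strain roles are swapped", {
  b <- simulate_dataset(simulation_config(seed = 13, n_null_snps = 40))
  pwm <- b$pwms[[1]]
  w <- build_allele_windows(b$snps, b$genome, pwm$length)
  fwd <- score_snp_motif(w, pwm)
  swapped <- w
  swapped$ref_seq <- w$alt_seq
  swapped$alt_seq <- w$ref_seq
  rev <- score_snp_motif(swapped, pwm)
  expect_equal(rev$delta, -fwd$delta, tolerance = 1e-12)
  expect_equal(rev$delta_rev, -fwd$delta_rev, tolerance = 1e-12)
})

test_that("nearest-gene annotation handles inside, boundary, tie and missing cases", {
  genes <- data.frame(
    chrom = c("chr1", "chr1", "chr1"),
    start = c(100L, 500L, 900L),
    end = c(200L, 600L, 1000L),
    strand = "+",
    symbol = c("Svs4", "Aaa1", "Zzz1"))
  snps <- data.frame(
    id = c("inside", "past_end", "tie", "far"),
    chrom = "chr1",
    pos = c(150L, 201L, 350L, 700L))
  ann <- annotate_nearest_gene(snps, genes)
  expect_equal(ann$gene, c("Svs4", "Svs4", "Aaa1", "Aaa1"))
  expect_equal(ann$distance, c(0L, 1L, 150L, 100L))
  # tie at equal distance resolves lexicographically
  tie <- annotate_nearest_gene(
    data.frame(id = "t", chrom = "chr1", pos = 350L),
    data.frame(chrom = "chr1", start = c(100L, 500L), end = c(200L, 600L),
               strand = "+", symbol = c("Bbb", "Aaa")))
  expect_equal(tie$gene, "Aaa")
  # no gene on that chromosome
  none <- annotate_nearest_gene(
    data.frame(id = "n", chrom = "chr2", pos = 10L), genes)
  expect_true(is.na(none$gene))
  expect_true(is.na(none$distance))
})

test_that("integration filters on significance, delta and Z, and stays monotone in the cuts", {
  empty <- score_snp_motif(
    build_allele_windows(data.frame(id = character(), chrom = character(),
                                    pos = integer(), ref_allele = character(),
                                    alt_allele = character(),
                                    pass_quality = logical()),
                         toy_genome(chr1 = strrep("A", 50)), 4L),
    toy_pwm4())
  expect_equal(nrow(integrate_hits(empty, c(g = 1),
                                   data.frame(chrom = "chr1", start = 1L,
                                              end = 10L, strand = "+",
                                              symbol = "g"))), 0L)

  b <- simulate_dataset(simulation_config(seed = 21, n_null_snps = 120))
  hits <- suppressMessages(scan_bundle(b))
  expect_equal(sort(hits$snp_id), sort(b$truth$snp_id))
  # stored scores re-verify the flags
  expect_equal(hits$delta, hits$ref - hits$alt, tolerance = 1e-12)
  expect_true(all(abs(hits$delta) > 1 | abs(hits$delta_rev) > 1))
  expect_true(all(abs(hits$z) > 7))
  expect_true(all(hits$significant))
  # raising the cuts never adds hits
  stricter <- suppressMessages(scan_bundle(b, delta_cut = 3, z_cut = 9))
  expect_true(all(stricter$snp_id %in% hits$snp_id))
  expect_lte(nrow(stricter), nrow(hits))
  # hits whose nearest gene lacks a Z value are dropped with a message
  z <- compute_z(b$fpkm)
  scores <- do.call(rbind, lapply(b$pwms, function(pw) {
    score_snp_motif(build_allele_windows(b$snps, b$genome, pw$length), pw)
  }))
  z_partial <- z[setdiff(names(z), b$truth$gene[1])]
  expect_message(
    partial <- integrate_hits(scores, z_partial, b$genes),
    "dropped")
  expect_false(b$truth$snp_id[1] %in% partial$snp_id)
})
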