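test_that("promoter regions follow the two flavors, strand-aware", {
  genes <- data.frame(chrom = "chr1",
                      start = c(10000L, 8000L),
                      end = c(12000L, 10000L),
                      strand = c("+", "-"),
                      symbol = c("plusg", "minusg"))
  meth <- promoter_region(genes, "methylation")
  expect_equal(meth$end - meth$start + 1L, c(2200L, 2200L))
  # + strand: 2000 bp upstream of the 5' end through 200 bp downstream
  expect_equal(meth$start[1], 8000L)
  expect_equal(meth$end[1], 10199L)
  # - strand mirrors around the 5' end (the gene end coordinate)
  expect_equal(meth$start[2], 9801L)
  expect_equal(meth$end[2], 12000L)

  scan <- promoter_region(genes, "motif_scan")
  expect_equal(scan$end - scan$start + 1L, c(2000L, 2000L))
  expect_equal(scan$end[1], 9999L)   # excludes the 5' base itself
  expect_equal(scan$start[2], 10001L)

  # truncation at contig edges is applied and reported
  near_edge <- data.frame(chrom = "chr1", start = 500L, end = 700L,
                          strand = "+", symbol = "edge")
  expect_message(tr <- promoter_region(near_edge, "methylation"),
                 "truncated")
  expect_equal(tr$start, 1L)
  expect_message(
    tr2 <- promoter_region(
      data.frame(chrom = "chr1", start = 900L, end = 950L, strand = "-",
                 symbol = "e2"),
      "methylation", contig_lengths = c(chr1 = 1000L)),
    "truncated")
  expect_equal(tr2$end, 1000L)
})

test_that("methylation level is reads per CpG with zero-CpG guarding", {
  expect_equal(methylation_level(44, 22), 2)
  expect_equal(methylation_level(0, 15), 0)
  withr::with_seed(55, {
    reads <- sample(0:500, 10)
    cpg <- sample(1:40, 10)
  })
  expect_equal(methylation_level(reads, cpg), reads / cpg)
  expect_warning(lvl <- methylation_level(c(10, 10), c(5, 0)), "zero CpG")
  expect_true(is.na(lvl[2]))
  expect_error(methylation_level(-1, 5), "non-negative")
})

test_that("rank correlations match a naive pair-count oracle and flag silencing", {
  x <- c(a = 1, b = 2, c = 3, d = 4, e = 5)
  y <- c(a = 10, b = 8, c = 6, d = 4, e = 2)
  r <- correlate_meth_expr(x, y)
  expect_equal(r$kendall_tau, -1)
  expect_equal(r$spearman_rho, -1)

  withr::with_seed(66, {
    lv <- stats::setNames(runif(5), letters[1:5])
    fp <- stats::setNames(runif(5), letters[1:5])
  })
  r2 <- correlate_meth_expr(lv, fp)
  expect_equal(r2$kendall_tau, naive_kendall(lv, fp), tolerance = 1e-12)
  expect_true(abs(r2$kendall_tau) <= 1 && abs(r2$spearman_rho) <= 1)
  if (r2$kendall_tau != 0) {
    expect_equal(sign(r2$kendall_tau), sign(r2$spearman_rho))
  }

  expect_warning(r3 <- correlate_meth_expr(c(a = 1, b = 2), c(a = 3, b = 1)),
                 "fewer than 3")
  expect_true(is.na(r3$kendall_tau))

  # synthetic silencing: planted methylation-up / expression-down coupling
  b <- simulate_dataset(simulation_config(seed = 3, n_null_snps = 0))
  m <- b$methylation[b$methylation$condition == "C57.D300.F1", ]
  lvl <- stats::setNames(methylation_level(m$read_count, m$cpg_count), m$gene)
  expr <- stats::setNames(b$fpkm$C57.D300.F1, b$fpkm$gene)
  rs <- correlate_meth_expr(lvl, expr)
  expect_lt(rs$kendall_tau, 0)
  expect_lt(rs$spearman_rho, 0)
})

test_that("promoter site counting finds planted consensus sites on both strands", {
  # consensus ACGTACGT, counted only at the perfect-match threshold
  w <- matrix(-2, 8, 4, dimnames = list(NULL, BASES))
  cons <- c("A", "C", "G", "T", "A", "C", "G", "T")
  w[cbind(1:8, match(cons, BASES))] <- 2
  pwm <- new_pwm("CONS8", w, thresholds = c("0.01" = 8, "0.0001" = 16))

  background <- strrep("TTGG", 30)  # never a perfect match
  promoters <- c(
    none = background,
    three = paste0(background, "ACGTACGT", background, "ACGTACGT",
                   background, "ACGTACGT", background))
  counts <- count_promoter_sites(list(pwm), promoters, p_level = 1e-4)
  expect_equal(unname(counts["none", "CONS8"]), 0L)
  # ACGTACGT is its own reverse complement: 3 plus-strand starts + 3
  # minus-strand starts, each start counted once per strand
  expect_equal(unname(counts["three", "CONS8"]), 6L)

  # a strictly minus-strand site is still found
  w2 <- matrix(-2, 6, 4, dimnames = list(NULL, BASES))
  cons2 <- c("A", "A", "C", "C", "G", "A")
  w2[cbind(1:6, match(cons2, BASES))] <- 2
  pwm2 <- new_pwm("CONS6", w2, thresholds = c("0.0001" = 12))
  prom2 <- c(g = paste0(strrep("T", 30), reverse_complement("AACCGA"),
                        strrep("T", 30)))
  expect_equal(unname(count_promoter_sites(list(pwm2), prom2)["g", "CONS6"]),
               1L)

  # counts are monotone non-increasing with threshold stringency
  withr::with_seed(88, {
    prom3 <- c(g = random_seq(800))
  })
  loose <- count_promoter_sites(list(pwm), prom3, p_level = 0.01)
  strict <- count_promoter_sites(list(pwm), prom3, p_level = 1e-4)
  expect_gte(loose["g", "CONS8"], strict["g", "CONS8"])

  expect_error(count_promoter_sites(list(pwm), promoters, p_level = 0.5),
               "no threshold")
})
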