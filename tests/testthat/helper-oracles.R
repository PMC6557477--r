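# Independent oracles, deliberately written without reusing any package
# scoring code: plain loops over explicit base lookups.

BASES <- c("A", "C", "G", "T")

# complement by explicit table lookup (not chartr)
naive_revcomp <- function(seq) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  paste(rev(unname(comp[strsplit(seq, "")[[1]]])), collapse = "")
}

# per-window score: position loop, N takes the row minimum
naive_score_window <- function(weights, seq) {
  bases <- strsplit(seq, "")[[1]]
  total <- 0
  for (i in seq_along(bases)) {
    total <- total + if (bases[i] == "N") {
      min(weights[i, ])
    } else {
      weights[i, match(bases[i], BASES)]
    }
  }
  total
}

# exhaustive both-strand best-window scan with clamping
naive_best_scores <- function(weights, seq) {
  L <- nrow(weights)
  scan <- function(s) {
    best <- -Inf
    for (start in 1:(nchar(s) - L + 1)) {
      sc <- naive_score_window(weights, substr(s, start, start + L - 1))
      if (sc > best) best <- sc
    }
    best
  }
  c(plus = max(0, scan(seq)), minus = max(0, scan(naive_revcomp(seq))))
}

random_weights <- function(L) {
  matrix(stats::rnorm(4 * L, sd = 2), nrow = L,
         dimnames = list(NULL, BASES))
}

random_seq <- function(n) {
  paste(sample(BASES, n, replace = TRUE), collapse = "")
}

# exact two-sided rank-sum p-value by enumerating all group assignments
exact_ranksum_p <- function(x, y) {
  pooled <- c(x, y)
  n <- length(pooled)
  k <- length(x)
  r <- rank(pooled)
  w_obs <- sum(r[seq_len(k)]) - k * (k + 1) / 2
  idx <- utils::combn(n, k)
  w_all <- apply(idx, 2, function(sel) sum(r[sel]) - k * (k + 1) / 2)
  mu <- k * (n - k) / 2
  mean(abs(w_all - mu) >= abs(w_obs - mu) - 1e-9)
}

# Kendall tau by explicit O(n^2) concordant/discordant pair counting
naive_kendall <- function(x, y) {
  n <- length(x)
  num <- 0
  den <- 0
  for (i in 1:(n - 1)) {
    for (j in (i + 1):n) {
      num <- num + sign(x[i] - x[j]) * sign(y[i] - y[j])
      den <- den + 1
    }
  }
  unname(num / den)
}

# small toy VCF writer for variant tests
write_toy_vcf <- function(path, rows,
                          contigs = c(chr1 = 10000L, chr14 = 10000L)) {
  lines <- c("##fileformat=VCFv4.2",
             sprintf("##contig=<ID=%s,length=%d>", names(contigs), contigs),
             "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
             rows)
  writeLines(lines, path)
  path
}

toy_genome <- function(...) {
  g <- Biostrings::DNAStringSet(c(...))
  g
}
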