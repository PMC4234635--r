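# fixture builders shared across test files

write_lines_tmp <- function(lines, ext = ".tsv") {
  tf <- tempfile(fileext = ext)
  con <- file(tf, open = "wb")
  writeLines(lines, con, sep = "\n", useBytes = TRUE)
  close(con)
  tf
}

count_fixture <- function() {
  write_lines_tmp(c("gene_id\tlength_bp\tcount_a\tcount_b",
                    "g1\t1000\t10\t20",
                    "g2\t500\t0\t3",
                    "g3\t2000\t7\t0"))
}

term_fixture <- function() {
  write_lines_tmp(c("gene_id\tterm_id\tnamespace\tterm_name",
                    "g1\tGO:1\tGO\tcell wall",
                    "g2\tko1\tKEGG\tflavonoid biosynthesis"))
}

# independent brute-force two-sided Audic-Claverie p-value: naive term-by-
# term summation of the conditional law in plain arithmetic (no log space)
brute_ac_pvalue <- function(x, y, total_a, total_b) {
  r <- total_b / total_a
  pmf <- function(k) r^k * choose(x + k, k) / (1 + r)^(x + k + 1)
  kmax <- ceiling(10 * (x + 1) * max(r, 1)) + 200
  probs <- pmf(0:kmax)
  lower <- sum(probs[1:(y + 1)])
  upper <- sum(probs[(y + 1):(kmax + 1)])
  min(1, 2 * min(lower, upper))
}

# independent hand implementation of Benjamini-Hochberg step-up
brute_bh <- function(p) {
  n <- length(p)
  o <- order(p, decreasing = TRUE)
  ro <- order(o)
  pmin(1, cummin(n / (n:1) * p[o]))[ro]
}

# Table 5 printed cells: RPKM in each library and the one-decimal ratio
table5 <- data.frame(
  rpkm_a = c(40.4792, 36.5823, 1.8516, 2.1838, 80.13, 2.78, 16.85, 3.59,
             3.32, 1.1851, 5.06, 4.86, 22.708, 0.86, 6.59),
  rpkm_b = c(19.2683, 3.0274, 5.7002, 9.8675, 230.84, 1.20, 45.17, 0.50,
             14.7, 5.9315, 14.98, 61.24, 90.2862, 9.38, 21.61),
  ratio = c(-1.1, -3.6, 1.6, 2.2, 1.5, -1.2, 1.4, -2.8, 2.1, 2.3, 1.5,
            3.7, 1.9, 3.4, 1.7))
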