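test_that("ac_probability matches closed forms and normalises to one", {
  expect_equal(ac_probability(0, 0, 1e6, 1e6), 0.5)
  expect_equal(ac_probability(5, 1, 1e6, 1e6), 6 / 128)
  for (x in c(0, 3, 50)) {
    for (r in c(0.1, 1, 10)) {
      total <- sum(ac_probability(x, 0:5000, 1e6, 1e6 * r))
      expect_equal(total, 1, tolerance = 1e-12)
    }
  }
  expect_error(ac_probability(-1, 0, 1e6, 1e6), ">= 0")
  expect_error(ac_probability(1.5, 0, 1e6, 1e6), "integers")
})

test_that("two-sided p-value agrees with brute-force summation for x+y <= 30", {
  for (r in c(0.5, 1, 2)) {
    n1 <- 1e6; n2 <- r * 1e6
    for (x in c(0, 1, 3, 8, 15)) {
      for (y in c(0, 1, 5, 12, 30 - x)) {
        if (x + y > 30) next
        expect_equal(ac_pvalue(x, y, n1, n2), brute_ac_pvalue(x, y, n1, n2),
                     tolerance = 1e-10)
      }
    }
  }
})

test_that("p-value closed forms, symmetry and tail monotonicity hold", {
  expect_equal(ac_pvalue(0, 10, 1e6, 1e6), 2^-9, tolerance = 1e-12)
  expect_equal(ac_pvalue(7, 7, 1e6, 1e6), 1)
  # the conditional pmf is exchangeable at equal totals ...
  set.seed(21)
  for (i in 1:25) {
    x <- rpois(1, 40); y <- rpois(1, 40)
    expect_equal(ac_probability(x, y, 2e6, 2e6), ac_probability(y, x, 2e6, 2e6))
  }
  # ... while the tail-based two-sided p carries a small, vanishing
  # orientation dependence (one conditioning count enters the tail index)
  expect_equal(ac_pvalue(120, 80, 1e6, 1e6), ac_pvalue(80, 120, 1e6, 1e6),
               tolerance = 0.05)
  # beyond the conditional mode the two-sided p shrinks as y grows
  p <- ac_pvalue(5, 6:60, 1e6, 1e6)
  expect_true(all(diff(p) <= 1e-12))
  # extreme counts stay finite and tiny without overflow
  expect_lt(ac_pvalue(0, 2000, 1e6, 1e6), 1e-300)
})

test_that("bh_fdr reproduces hand step-up adjustment", {
  expect_equal(bh_fdr(0.03), 0.03)
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(rep(1, 5)), rep(1, 5))
  set.seed(22)
  for (i in 1:10) {
    p <- runif(sample(3:50, 1))^2
    expect_equal(bh_fdr(p), brute_bh(p))
  }
  expect_error(bh_fdr(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("call_degs applies the FDR and ratio gates and skips untestable genes", {
  # identical libraries: every two-sided p is 1, nothing is called
  g <- data.frame(gene_id = paste0("g", 1:50), length_bp = 1000,
                  count_a = rep(c(10, 100, 1000), length.out = 50))
  g$count_b <- g$count_a
  deg <- call_degs(library_pair(g))
  expect_true(all(deg$status == "ns"))
  expect_true(all(deg$p_value > 1 - 1e-9))

  # one planted extreme gene among nulls, plus an all-zero gene
  set.seed(23)
  g2 <- data.frame(gene_id = paste0("g", 1:200), length_bp = 1000,
                   count_a = rpois(200, 100), count_b = rpois(200, 100))
  g2$count_a[1] <- 0; g2$count_b[1] <- 1000
  g2$count_a[2] <- 0; g2$count_b[2] <- 0
  deg2 <- call_degs(library_pair(g2))
  expect_equal(deg2$status[1], "up")
  expect_equal(deg2$log2_ratio[1], Inf)
  expect_equal(deg2$status[2], "ns")
  expect_equal(deg2$p_value[2], 1)
  expect_equal(deg2$fdr[2], 1)
  expect_equal(attr(deg2, "n_tested"), 199L)

  # significant p but sub-threshold ratio is gated to ns; the tested gene
  # is a small share of deep libraries so totals stay balanced
  g3 <- data.frame(gene_id = c("big", paste0("n", 1:20)), length_bp = 1000,
                   count_a = c(10000, rpois(20, 50000)),
                   count_b = c(14000, rpois(20, 50000)))
  deg3 <- call_degs(library_pair(g3))
  expect_lt(deg3$fdr[1], 1e-6)
  expect_lt(abs(deg3$log2_ratio[1]), 1)
  expect_equal(deg3$status[1], "ns")
})

test_that("swapping libraries negates ratios and flips confident calls", {
  sim <- simulate_pair(sim_config(n_genes = 400, total_a = 2e5, total_b = 2e5,
                                  de_fraction = 0.1, de_min_mean = 20, seed = 9))
  g <- sim$pair$genes
  fwd <- call_degs(library_pair(g))
  swapped <- g[, c("gene_id", "length_bp", "count_b", "count_a")]
  names(swapped)[3:4] <- c("count_a", "count_b")
  rev <- call_degs(library_pair(swapped))
  both <- is.finite(fwd$log2_ratio)
  expect_equal(rev$log2_ratio[both], -fwd$log2_ratio[both])
  # calls well clear of both gates are orientation-stable
  strong_up <- fwd$fdr < 1e-6 & fwd$log2_ratio >= 1.2
  expect_true(any(strong_up))
  expect_true(all(rev$status[strong_up] == "down"))
  strong_down <- fwd$fdr < 1e-6 & fwd$log2_ratio <= -1.2
  expect_true(all(rev$status[strong_down] == "up"))
})
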