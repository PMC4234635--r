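#' Audic-Claverie conditional probability
#'
#' Probability of observing \code{y} tags for a gene in library B given
#' \code{x} tags in library A, under the model that each library's count
#' is Poisson and the gene is expressed at the same per-tag rate in both:
#' \deqn{p(y \mid x) = \left(\frac{N_2}{N_1}\right)^{y}
#'   \frac{(x+y)!}{x!\,y!\,(1 + N_2/N_1)^{x+y+1}}}
#' with \eqn{N_1, N_2} the library totals. Evaluated in log space via
#' \code{lgamma}, so it is stable for counts in the tens of thousands.
#' For fixed \code{x}, \eqn{\sum_y p(y|x) = 1}.
#'
#' @param x,y Non-negative integer counts (vectorised elementwise).
#' @param total_a,total_b Library totals, both \eqn{\ge 1}.
#' @return Probability in \[0, 1\].
#' @references Audic S, Claverie JM (1997) The significance of digital
#'   gene expression profiles. Genome Research 7:986-995.
#' @export
#' @examples
#' ac_probability(0, 0, 1e6, 1e6)  # 0.5
#' ac_probability(5, 1, 1e6, 1e6)  # 6/128
ac_probability <- function(x, y, total_a, total_b) {
  check_ac_args(x, y, total_a, total_b)
  exp(ac_log_prob(x, y, total_b / total_a))
}

# log p(y | x) at ratio r = N2/N1; vectorised over y (x scalar or vector)
ac_log_prob <- function(x, y, r) {
  y * log(r) + lgamma(x + y + 1) - lgamma(x + 1) - lgamma(y + 1) -
    (x + y + 1) * log1p(r)
}

#' Two-sided exact p-value for differential tag counts
#'
#' Tests whether a gene is expressed equally in two libraries. The
#' conditional law of \code{y} given \code{x} ([ac_probability()]) gives
#' one-sided tail probabilities; the two-sided p-value is the doubled
#' smaller tail, capped at 1, with the observed \code{y} included in both
#' tails:
#' \deqn{p = \min\{1,\; 2 \min(P(Y \le y \mid x),\; P(Y \ge y \mid x))\}}
#' The smaller tail is accumulated directly from log-space terms (the
#' larger one by complement), so tiny p-values keep full relative
#' precision down to the double-precision underflow limit.
#'
#' @inheritParams ac_probability
#' @return p-value in \[0, 1\]; vectorised elementwise over \code{x},
#'   \code{y}.
#' @export
#' @examples
#' ac_pvalue(0, 10, 1e6, 1e6)  # 2^-9
#' ac_pvalue(7, 7, 1e6, 1e6)   # 1
ac_pvalue <- function(x, y, total_a, total_b) {
  check_ac_args(x, y, total_a, total_b)
  n <- max(length(x), length(y))
  x <- rep_len(x, n); y <- rep_len(y, n)
  r <- total_b / total_a
  vapply(seq_len(n), function(i) ac_pvalue_1(x[i], y[i], r), numeric(1))
}

ac_pvalue_1 <- function(x, y, r) {
  mean_y <- (x + 1) * r  # mean of the conditional law
  if (y <= mean_y) {
    lower <- sum(exp(ac_log_prob(x, 0:y, r)))
    upper <- 1 - lower + exp(ac_log_prob(x, y, r))
  } else {
    upper <- ac_upper_tail(x, y, r)
    lower <- 1 - upper + exp(ac_log_prob(x, y, r))
  }
  min(1, 2 * min(lower, upper))
}

# P(Y >= y | x) summed upward from y in chunks until the remainder is
# negligible; only called beyond the mode, where terms decay geometrically
ac_upper_tail <- function(x, y, r, chunk = 512L) {
  total <- 0
  k0 <- y
  repeat {
    ks <- k0:(k0 + chunk - 1L)
    terms <- exp(ac_log_prob(x, ks, r))
    total <- total + sum(terms)
    last <- terms[chunk]
    if (last == 0 || last < total * 1e-17) break
    k0 <- k0 + chunk
  }
  min(total, 1)
}

check_ac_args <- function(x, y, total_a, total_b) {
  if (any(x < 0) || any(y < 0)) stop("counts must be >= 0")
  if (any(x != round(x)) || any(y != round(y))) stop("counts must be integers")
  if (length(total_a) != 1L || length(total_b) != 1L || total_a < 1 || total_b < 1)
    stop("library totals must be single values >= 1")
  invisible(TRUE)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment, returned in input order. Thin wrapper around
#' [stats::p.adjust()] with input validation, kept as the single named
#' place where the multiple-testing procedure is chosen.
#'
#' @param p_values Numeric vector of p-values in \[0, 1\].
#' @return Adjusted values in \[0, 1\], same order as the input.
#' @export
bh_fdr <- function(p_values) {
  if (any(is.na(p_values)) || any(p_values < 0) || any(p_values > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(p_values, method = "BH")
}

#' Call differentially expressed genes between two libraries
#'
#' For every gene: RPKM in each library, the log2 ratio of library B over
#' library A, the two-sided Audic-Claverie p-value, the BH-adjusted FDR
#' over all tested genes, and a status call. A gene is \code{up} when
#' \code{fdr <= fdr_max} and \code{log2_ratio >= min_abs_log2},
#' \code{down} when \code{fdr <= fdr_max} and
#' \code{log2_ratio <= -min_abs_log2}, otherwise \code{ns}.
#'
#' Genes with zero counts in both libraries are untestable; they are
#' excluded from the multiple-testing family and reported with
#' \code{p_value = fdr = 1} and status \code{ns}.
#'
#' @param pair A \code{library_pair} from [read_count_table()] or
#'   [simulate_pair()].
#' @param fdr_max FDR significance gate, default \code{0.001}.
#' @param min_abs_log2 Minimum absolute log2 ratio, default \code{1}.
#' @param pseudo Pseudocount passed to [log2_ratio()], default 0 (zero
#'   RPKMs then yield infinite ratios, which satisfy any threshold).
#' @return data.frame with columns \code{gene_id}, \code{rpkm_a},
#'   \code{rpkm_b}, \code{log2_ratio}, \code{p_value}, \code{fdr},
#'   \code{status}, one row per input gene in input order. The number of
#'   tested genes is attached as attribute \code{n_tested}.
#' @export
call_degs <- function(pair, fdr_max = 0.001, min_abs_log2 = 1, pseudo = 0) {
  stopifnot(inherits(pair, "library_pair"))
  if (fdr_max <= 0 || min_abs_log2 <= 0)
    stop("fdr_max and min_abs_log2 must be > 0")
  g <- pair$genes
  rpkm_a <- rpkm(g$count_a, g$length_bp, pair$total_a)
  rpkm_b <- rpkm(g$count_b, g$length_bp, pair$total_b)
  ratio <- log2_ratio(rpkm_a, rpkm_b, pseudo)
  tested <- g$count_a > 0 | g$count_b > 0
  p <- rep(1, nrow(g))
  fdr <- rep(1, nrow(g))
  if (any(tested)) {
    p[tested] <- ac_pvalue(g$count_a[tested], g$count_b[tested],
                           pair$total_a, pair$total_b)
    fdr[tested] <- bh_fdr(p[tested])
  }
  status <- rep("ns", nrow(g))
  sig <- tested & fdr <= fdr_max
  status[sig & !is.na(ratio) & ratio >= min_abs_log2] <- "up"
  status[sig & !is.na(ratio) & ratio <= -min_abs_log2] <- "down"
  out <- data.frame(gene_id = g$gene_id, rpkm_a = rpkm_a, rpkm_b = rpkm_b,
                    log2_ratio = ratio, p_value = p, fdr = fdr,
                    status = status, stringsAsFactors = FALSE)
  attr(out, "n_tested") <- sum(tested)
  out
}
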