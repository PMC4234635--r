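#' Configuration for a synthetic two-library experiment
#'
#' Bundles all generator settings with defaults that emulate a deeply
#' sequenced two-library tag-count comparison at reduced scale: a few
#' thousand genes, one million tags per library, a small planted fraction
#' of genes changed by a known log2 fold change, and Poisson count noise.
#'
#' @param n_genes Number of genes, default 5000.
#' @param total_a,total_b Expected library depths (tags), default 1e6
#'   each.
#' @param de_fraction Fraction of genes planted as differentially
#'   expressed, default 0.05.
#' @param log2_fc_magnitude Planted |log2 fold change|, default 2.
#' @param de_min_mean Minimum expected baseline count (in the shallower
#'   library) for a gene to be eligible for DE planting, default 50;
#'   keeps planted effects detectable rather than drowned in shot noise.
#' @param length_range_bp Gene length range in bp, default c(200, 3000).
#' @param expression_shape Gamma shape for baseline relative abundances,
#'   default 0.6 (right-skewed, like real transcript abundances);
#'   \code{Inf} gives every gene the same expected expression.
#' @param length_weighted If TRUE, expected counts are proportional to
#'   gene length as well as abundance (read-count model); default FALSE
#'   (tag-count model: one tag site per transcript).
#' @param overdispersion Negative-binomial overdispersion (1/size); 0
#'   (default) gives pure Poisson noise, matching the model the exact
#'   test assumes.
#' @param n_terms Number of annotation terms, default 50, split
#'   alternately between the GO and KEGG namespaces.
#' @param planted_terms Number of terms planted as DE-enriched, default 2.
#' @param term_size_range Genes per term, default c(10, 100).
#' @param planted_odds Sampling odds of a DE gene vs a non-DE gene when
#'   filling a planted term, default 10.
#' @param seed Integer seed governing all randomness, default 1.
#' @return A \code{sim_config} list.
#' @export
sim_config <- function(n_genes = 5000, total_a = 1e6, total_b = 1e6,
                       de_fraction = 0.05, log2_fc_magnitude = 2,
                       de_min_mean = 50, length_range_bp = c(200, 3000),
                       expression_shape = 0.6, length_weighted = FALSE,
                       overdispersion = 0, n_terms = 50, planted_terms = 2,
                       term_size_range = c(10, 100), planted_odds = 10,
                       seed = 1) {
  cfg <- list(n_genes = n_genes, total_a = total_a, total_b = total_b,
              de_fraction = de_fraction, log2_fc_magnitude = log2_fc_magnitude,
              de_min_mean = de_min_mean, length_range_bp = length_range_bp,
              expression_shape = expression_shape,
              length_weighted = length_weighted,
              overdispersion = overdispersion, n_terms = n_terms,
              planted_terms = planted_terms,
              term_size_range = term_size_range, planted_odds = planted_odds,
              seed = seed)
  if (n_genes < 2 || total_a < 1 || total_b < 1) stop("degenerate sizes")
  if (de_fraction < 0 || de_fraction >= 1) stop("de_fraction must be in [0, 1)")
  if (de_fraction > 0 && de_fraction * n_genes < 1)
    stop("de_fraction * n_genes must be >= 1 when de_fraction > 0")
  if (log2_fc_magnitude <= 0) stop("log2_fc_magnitude must be > 0")
  if (length(length_range_bp) != 2 || diff(length_range_bp) <= 0 ||
      length_range_bp[1] < 1) stop("length_range_bp must be a widening interval >= 1")
  if (length(term_size_range) != 2 || diff(term_size_range) < 0)
    stop("term_size_range must be non-degenerate")
  if (planted_terms > n_terms) stop("more planted terms than terms")
  if (overdispersion < 0 || planted_odds <= 0) stop("invalid noise/odds settings")
  if (seed != round(seed)) stop("seed must be an integer")
  class(cfg) <- "sim_config"
  cfg
}

# run expr with a private RNG stream; global .Random.seed is untouched
with_sim_rng <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Simulate a two-library count experiment with planted fold changes
#'
#' Baseline relative abundances are drawn from a gamma distribution with
#' the configured shape and normalised to sum to one. A random
#' \code{de_fraction} subset of sufficiently expressed genes receives a
#' fold change of \code{±log2_fc_magnitude} (sign chosen at random,
#' applied in library B). Counts are then drawn independently per gene
#' and library, Poisson by default, with mean = abundance × depth (times
#' a length weight under the read-count model).
#'
#' @param config A [sim_config()].
#' @return list with \code{pair} (a \code{library_pair}) and \code{truth}
#'   (data.frame with \code{gene_id}, \code{true_log2_fc}, \code{is_de}).
#'   Identical for identical configs.
#' @export
simulate_pair <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_sim_rng(config$seed, {
    n <- config$n_genes
    gene_id <- sprintf("g%05d", seq_len(n))
    len <- sample(config$length_range_bp[1]:config$length_range_bp[2], n,
                  replace = TRUE)
    ab <- if (is.finite(config$expression_shape))
      stats::rgamma(n, shape = config$expression_shape) else rep(1, n)
    if (config$length_weighted) ab <- ab * len
    ab <- ab / sum(ab)

    fc <- rep(0, n)
    if (config$de_fraction > 0) {
      n_de <- round(config$de_fraction * n)
      eligible <- which(ab * min(config$total_a, config$total_b) >=
                          config$de_min_mean)
      if (length(eligible) < n_de)
        stop("only ", length(eligible), " genes reach de_min_mean but ",
             n_de, " DE genes requested; lower de_min_mean or raise depth")
      de_idx <- sample(eligible, n_de)
      fc[de_idx] <- sample(c(-1, 1), n_de, replace = TRUE) *
        config$log2_fc_magnitude
    }
    mu_a <- ab * config$total_a
    mu_b <- ab * 2^fc * config$total_b
    draw <- function(mu) {
      if (config$overdispersion > 0)
        stats::rnbinom(n, mu = mu, size = 1 / config$overdispersion)
      else stats::rpois(n, mu)
    }
    genes <- data.frame(gene_id = gene_id, length_bp = len,
                        count_a = draw(mu_a), count_b = draw(mu_b),
                        stringsAsFactors = FALSE)
    truth <- data.frame(gene_id = gene_id, true_log2_fc = fc,
                        is_de = abs(fc) >= config$log2_fc_magnitude,
                        stringsAsFactors = FALSE)
    list(pair = library_pair(genes), truth = truth)
  })
}

#' Simulate gene-to-term assignments with planted enriched terms
#'
#' Background terms draw their member genes uniformly at random. Each
#' planted term draws members preferentially from DE genes with the
#' configured odds (default 10:1), so a planted term is over-represented
#' among DEGs in expectation. Terms alternate between the GO and KEGG
#' namespaces; planted terms take the lowest term ids, so they land in
#' both namespaces when more than one is planted.
#'
#' @param truth Truth table from [simulate_pair()].
#' @param config The same [sim_config()].
#' @return data.frame of assignments (\code{gene_id}, \code{term_id},
#'   \code{namespace}, \code{term_name}) with attribute
#'   \code{planted_terms}: the ids of the planted terms.
#' @export
simulate_terms <- function(truth, config) {
  stopifnot(inherits(config, "sim_config"), nrow(truth) > 0)
  with_sim_rng(config$seed + 1L, {
    nt <- config$n_terms
    term_id <- sprintf("T%03d", seq_len(nt))
    namespace <- rep(c("GO", "KEGG"), length.out = nt)
    sizes <- sample(config$term_size_range[1]:config$term_size_range[2], nt,
                    replace = TRUE)
    sizes <- pmin(sizes, nrow(truth))
    w_planted <- ifelse(truth$is_de, config$planted_odds, 1)
    rows <- vector("list", nt)
    for (t in seq_len(nt)) {
      planted <- t <= config$planted_terms
      members <- if (planted)
        sample(truth$gene_id, sizes[t], prob = w_planted)
      else sample(truth$gene_id, sizes[t])
      rows[[t]] <- data.frame(
        gene_id = members, term_id = term_id[t], namespace = namespace[t],
        term_name = paste0(ifelse(planted, "planted ", "background "),
                           "term ", term_id[t]),
        stringsAsFactors = FALSE)
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    attr(out, "planted_terms") <- term_id[seq_len(config$planted_terms)]
    out
  })
}
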