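#' Hypergeometric upper-tail probability
#'
#' Probability that a term contains at least \code{m} differentially
#' expressed genes by chance, given that the term covers \code{M} of the
#' \code{N} annotated genes and \code{n} of the \code{N} are DEGs:
#' \deqn{P(X \ge m) = \sum_{i=m}^{\min(n, M)}
#'   \frac{\binom{M}{i}\binom{N-M}{n-i}}{\binom{N}{n}}}
#' Terms are evaluated as log binomial coefficients and combined by
#' log-sum-exp, so the tail is accurate even when it is astronomically
#' small. The observed count is included in the tail: \eqn{P(X \ge 0) = 1}.
#'
#' @param m DEGs annotated to the term.
#' @param n DEGs with any annotation in the namespace.
#' @param M Annotated genes in the term.
#' @param N Genes with any annotation in the namespace.
#' @return Upper-tail probability in \[0, 1\].
#' @export
#' @examples
#' hypergeom_upper_tail(16, 3213, 41, 20242)  # 2.99e-4
hypergeom_upper_tail <- function(m, n, M, N) {
  vals <- c(m = m, n = n, M = M, N = N)
  if (any(vals != round(vals)) || any(vals < 0))
    stop("m, n, M, N must be non-negative integers")
  if (M > N || n > N) stop("inconsistent contingency: need M <= N and n <= N")
  if (m > min(n, M)) stop("inconsistent contingency: need m <= min(n, M)")
  if (m == 0) return(1)
  i <- m:min(n, M)
  lo <- lchoose(M, i) + lchoose(N - M, n - i) - lchoose(N, n)
  top <- max(lo)
  min(1, exp(top + log(sum(exp(lo - top)))))
}

#' Term enrichment among differentially expressed genes
#'
#' Hypergeometric enrichment of GO terms or KEGG pathways in a DEG set
#' against the annotated-gene background. The universe \eqn{N} is the set
#' of genes carrying at least one assignment in the chosen namespace
#' (computed independently for GO and KEGG), \eqn{n} the DEGs among them,
#' and per term \eqn{M} / \eqn{m} the annotated genes / DEGs it contains.
#' Q-values are BH-adjusted over all terms of the namespace.
#'
#' The significance gate mirrors common practice for the two namespaces:
#' GO terms are flagged on the raw p-value (\code{p <= p_max}), KEGG
#' pathways on the q-value (\code{q <= q_max}).
#'
#' @param deg_ids Character vector of DEG gene ids.
#' @param assignments Assignment table from [read_term_table()] or
#'   [simulate_terms()].
#' @param namespace \code{"GO"} or \code{"KEGG"}.
#' @param p_max Raw p-value gate (GO), default 0.05.
#' @param q_max Q-value gate (KEGG), default 0.05.
#' @return data.frame with columns \code{term_id}, \code{namespace},
#'   \code{term_name}, \code{m}, \code{n}, \code{M}, \code{N},
#'   \code{p_value}, \code{q_value}, \code{enriched}, ordered by
#'   ascending p-value with ties broken by term id. Terms with \code{m = 0}
#'   are reported with \code{p = 1}, never dropped.
#' @export
enrich_terms <- function(deg_ids, assignments, namespace = c("GO", "KEGG"),
                         p_max = 0.05, q_max = 0.05) {
  namespace <- match.arg(namespace)
  asg <- assignments[assignments$namespace == namespace, , drop = FALSE]
  if (nrow(asg) == 0L)
    stop("no assignments in namespace ", namespace)
  universe <- unique(asg$gene_id)
  N <- length(universe)
  deg_in <- unique(deg_ids[deg_ids %in% universe])
  n <- length(deg_in)
  if (n == 0L)
    warning("no DEG carries a ", namespace, " annotation; all m = 0")
  term_ids <- unique(asg$term_id)
  M <- as.integer(table(asg$term_id)[term_ids])
  is_deg <- asg$gene_id %in% deg_in
  m_tab <- table(asg$term_id[is_deg])
  m <- as.integer(ifelse(term_ids %in% names(m_tab), m_tab[term_ids], 0L))
  name_of <- asg$term_name[!duplicated(asg$term_id)]
  names(name_of) <- asg$term_id[!duplicated(asg$term_id)]
  p <- vapply(seq_along(term_ids),
              function(i) hypergeom_upper_tail(m[i], n, M[i], N), numeric(1))
  q <- bh_fdr(p)
  enriched <- if (namespace == "GO") p <= p_max else q <= q_max
  out <- data.frame(term_id = term_ids, namespace = namespace,
                    term_name = unname(name_of[term_ids]),
                    m = m, n = n, M = M, N = N,
                    p_value = p, q_value = q, enriched = enriched,
                    stringsAsFactors = FALSE)
  out <- out[order(out$p_value, out$term_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}
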