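#' Run the whole two-library analysis from one config
#'
#' Orchestrates simulate (or load) -> differential expression -> GO and
#' KEGG enrichment, writing every output table plus a run manifest that
#' echoes every threshold and set size used, so each reported number can
#' be recomputed from the referenced inputs.
#'
#' The config is either a named list or the path of a plain-text
#' \code{key = value} file (\code{#} comments and blank lines ignored).
#' Keys:
#' \describe{
#'   \item{mode}{\code{"simulate"} (default) or \code{"counts"}.}
#'   \item{out_dir}{Output directory, created if needed (required).}
#'   \item{counts, terms}{Input TSV paths (mode \code{"counts"};
#'     \code{terms} optional).}
#'   \item{fdr_max, min_abs_log2, pseudo}{DEG thresholds, defaults 0.001,
#'     1, 0.}
#'   \item{p_max, q_max}{Enrichment gates, defaults 0.05.}
#'   \item{any [sim_config()] argument}{Simulation settings (mode
#'     \code{"simulate"}), e.g. \code{n_genes}, \code{total_a},
#'     \code{seed}.}
#' }
#'
#' @param config Named list or path to a config file.
#' @return Invisibly, the manifest as a named list. Side effects: writes
#'   \code{deg.tsv}, \code{enrichment.tsv}, \code{manifest.txt} (and, in
#'   simulate mode, \code{counts.tsv}, \code{terms.tsv},
#'   \code{truth.tsv}) under \code{out_dir}. Reruns with an identical
#'   config produce byte-identical files.
#' @export
run_all <- function(config) {
  cfg <- if (is.character(config)) read_run_config(config) else config
  if (is.null(cfg$out_dir)) stop("config must set out_dir")
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  mode <- if (is.null(cfg$mode)) "simulate" else cfg$mode
  fdr_max <- cfg$fdr_max %||% 0.001
  min_abs_log2 <- cfg$min_abs_log2 %||% 1
  pseudo <- cfg$pseudo %||% 0
  p_max <- cfg$p_max %||% 0.05
  q_max <- cfg$q_max %||% 0.05

  truth <- NULL
  if (mode == "simulate") {
    sim_args <- cfg[intersect(names(cfg), names(formals(sim_config)))]
    sc <- do.call(sim_config, sim_args)
    sim <- simulate_pair(sc)
    pair <- sim$pair
    truth <- sim$truth
    assignments <- simulate_terms(truth, sc)
    write_count_table(pair, file.path(cfg$out_dir, "counts.tsv"))
    write_results(assignments, file.path(cfg$out_dir, "terms.tsv"))
    write_results(truth, file.path(cfg$out_dir, "truth.tsv"))
  } else if (mode == "counts") {
    if (is.null(cfg$counts)) stop("mode = counts needs a 'counts' path")
    pair <- read_count_table(cfg$counts)
    assignments <- if (!is.null(cfg$terms))
      read_term_table(cfg$terms, count_genes = pair$genes$gene_id) else NULL
  } else stop("unknown mode '", mode, "'")

  deg <- call_degs(pair, fdr_max = fdr_max, min_abs_log2 = min_abs_log2,
                   pseudo = pseudo)
  write_results(deg, file.path(cfg$out_dir, "deg.tsv"))
  deg_ids <- deg$gene_id[deg$status != "ns"]

  enr <- NULL
  universes <- list()
  if (!is.null(assignments) && nrow(assignments) > 0) {
    parts <- list()
    for (ns in intersect(c("GO", "KEGG"), unique(assignments$namespace))) {
      e <- enrich_terms(deg_ids, assignments, ns, p_max = p_max, q_max = q_max)
      universes[[ns]] <- c(N = e$N[1], n = e$n[1])
      parts[[ns]] <- e
    }
    enr <- do.call(rbind, parts)
    rownames(enr) <- NULL
    write_results(enr, file.path(cfg$out_dir, "enrichment.tsv"))
  }

  manifest <- c(
    list(tool = "tagdge", version = as.character(utils::packageVersion("tagdge")),
         mode = mode),
    if (mode == "counts") list(counts = cfg$counts, terms = cfg$terms %||% "none"),
    if (mode == "simulate") list(seed = cfg$seed %||% formals(sim_config)$seed),
    list(fdr_max = fdr_max, min_abs_log2 = min_abs_log2, pseudo = pseudo,
         p_max = p_max, q_max = q_max,
         genes_total = nrow(pair$genes),
         genes_tested = attr(deg, "n_tested"),
         deg_up = sum(deg$status == "up"),
         deg_down = sum(deg$status == "down"),
         deg_ns = sum(deg$status == "ns")))
  for (ns in names(universes)) {
    manifest[[paste0(tolower(ns), "_universe_N")]] <- universes[[ns]][["N"]]
    manifest[[paste0(tolower(ns), "_universe_n")]] <- universes[[ns]][["n"]]
    manifest[[paste0(tolower(ns), "_enriched_terms")]] <-
      sum(enr$enriched[enr$namespace == ns])
  }
  writeLines(paste(names(manifest), unlist(lapply(manifest, as.character)),
                   sep = " = "),
             file.path(cfg$out_dir, "manifest.txt"))
  invisible(manifest)
}

#' Read a plain-text key = value run config
#'
#' @param path Config file path.
#' @return Named list; values that parse as numbers become numeric.
#' @export
read_run_config <- function(path) {
  lines <- read_tsv_lines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  kv <- regmatches(lines, regexec("^([A-Za-z0-9_]+)\\s*=\\s*(.*)$", lines))
  bad <- vapply(kv, length, integer(1)) != 3L
  if (any(bad))
    stop("config line not of the form 'key = value': '", lines[bad][1], "'")
  keys <- vapply(kv, `[`, character(1), 2)
  vals <- vapply(kv, `[`, character(1), 3)
  out <- lapply(vals, function(v) {
    num <- suppressWarnings(as.numeric(v))
    if (!is.na(num)) num else v
  })
  names(out) <- keys
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Scatter plot of gene expression coloured by DEG status
#'
#' Log10 RPKM in library A against library B, with up-regulated genes in
#' red, down-regulated in green and non-significant in blue.
#'
#' @param deg Output of [call_degs()].
#' @param ... Passed to [plot()].
#' @return Invisibly, \code{NULL}.
#' @export
plot_deg <- function(deg, ...) {
  eps <- 0.5 * min(c(deg$rpkm_a[deg$rpkm_a > 0], deg$rpkm_b[deg$rpkm_b > 0]))
  col <- c(up = "red", down = "green3", ns = "blue")[deg$status]
  graphics::plot(log10(deg$rpkm_a + eps), log10(deg$rpkm_b + eps),
                 col = col, pch = 20, cex = 0.4,
                 xlab = "log10 RPKM (library A)",
                 ylab = "log10 RPKM (library B)", ...)
  graphics::abline(0, 1, lty = 2)
  invisible(NULL)
}
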