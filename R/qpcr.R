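#' Relative expression by the 2^-ddCt (Livak) method
#'
#' Normalises a target gene's qRT-PCR cycle threshold to an internal
#' control gene within each sample, then to a calibrator sample:
#' \deqn{\Delta Ct = \overline{Ct}_{target} - \overline{Ct}_{control};\quad
#'   \Delta\Delta Ct = \Delta Ct_{sample} - \Delta Ct_{calibrator};\quad
#'   fold = 2^{-\Delta\Delta Ct}}
#' Replicates are averaged by arithmetic mean of Ct before differencing.
#' The calibrator normalises itself to fold exactly 1, and adding any
#' constant to every Ct leaves the fold unchanged.
#'
#' @param target Ct replicates of the target gene in the sample.
#' @param reference Ct replicates of the internal control gene in the
#'   sample.
#' @param target_calibrator,reference_calibrator The same two
#'   measurements in the calibrator sample.
#' @return A list with \code{delta_ct}, \code{delta_delta_ct} and
#'   \code{fold}.
#' @export
#' @examples
#' relative_expression(25, 20, 28, 21)$fold  # 4
relative_expression <- function(target, reference,
                                target_calibrator, reference_calibrator) {
  for (v in list(target, reference, target_calibrator, reference_calibrator)) {
    if (length(v) == 0L) stop("every measurement needs at least one Ct replicate")
    if (any(!is.finite(v)) || any(v <= 0) || any(v >= 60))
      stop("Ct values must lie in (0, 60)")
  }
  delta_ct <- mean(target) - mean(reference)
  delta_ct_cal <- mean(target_calibrator) - mean(reference_calibrator)
  ddct <- delta_ct - delta_ct_cal
  list(delta_ct = delta_ct, delta_delta_ct = ddct, fold = 2^(-ddct))
}

#' Read a qRT-PCR Ct table
#'
#' TSV with header \code{sample_id gene ct}, one row per technical
#' replicate.
#'
#' @param path Path to the TSV file.
#' @return data.frame with columns \code{sample_id}, \code{gene},
#'   \code{ct} (numeric).
#' @export
read_ct_table <- function(path) {
  lines <- read_tsv_lines(path)
  expect_header(lines[1], c("sample_id", "gene", "ct"), path)
  body <- lines[-1]
  body <- body[nzchar(body)]
  if (length(body) == 0L) stop("Ct table '", path, "' has no rows")
  fields <- strsplit(body, "\t", fixed = TRUE)
  if (any(lengths(fields) != 3L)) {
    bad <- which(lengths(fields) != 3L)[1]
    stop("line ", bad + 1L, " of '", path, "': expected 3 fields")
  }
  mat <- matrix(unlist(fields), ncol = 3L, byrow = TRUE)
  ct <- suppressWarnings(as.numeric(mat[, 3]))
  if (any(is.na(ct))) {
    bad <- which(is.na(ct))[1]
    stop("line ", bad + 1L, " of '", path, "': non-numeric ct '", mat[bad, 3], "'")
  }
  if (any(ct <= 0 | ct >= 60)) {
    bad <- which(ct <= 0 | ct >= 60)[1]
    stop("line ", bad + 1L, " of '", path, "': ct must lie in (0, 60)")
  }
  data.frame(sample_id = mat[, 1], gene = mat[, 2], ct = ct,
             stringsAsFactors = FALSE)
}

#' Tabulate relative expression for a whole Ct table
#'
#' Applies [relative_expression()] to every (sample, target gene)
#' combination in a Ct table, normalising to one reference gene and one
#' calibrator sample.
#'
#' @param ct_table data.frame from [read_ct_table()].
#' @param reference_gene Internal control gene id (e.g. \code{"Gh18S"}).
#' @param calibrator Sample id used as the calibrator.
#' @return data.frame with columns \code{sample_id}, \code{gene},
#'   \code{delta_ct}, \code{delta_delta_ct}, \code{fold}, \code{ct_sd}
#'   (standard deviation of the target Ct replicates; NA for a single
#'   replicate).
#' @export
qpcr_relative <- function(ct_table, reference_gene, calibrator) {
  stopifnot(is.data.frame(ct_table),
            all(c("sample_id", "gene", "ct") %in% names(ct_table)))
  if (!reference_gene %in% ct_table$gene)
    stop("reference gene '", reference_gene, "' not in Ct table")
  if (!calibrator %in% ct_table$sample_id)
    stop("calibrator sample '", calibrator, "' not in Ct table")
  pick <- function(sample, gene) {
    v <- ct_table$ct[ct_table$sample_id == sample & ct_table$gene == gene]
    if (length(v) == 0L)
      stop("no Ct replicates for gene '", gene, "' in sample '", sample, "'")
    v
  }
  targets <- setdiff(unique(ct_table$gene), reference_gene)
  samples <- unique(ct_table$sample_id)
  rows <- list()
  for (g in targets) {
    cal_t <- pick(calibrator, g)
    cal_r <- pick(calibrator, reference_gene)
    for (s in samples) {
      ct_t <- pick(s, g)
      rel <- relative_expression(ct_t, pick(s, reference_gene), cal_t, cal_r)
      rows[[length(rows) + 1L]] <- data.frame(
        sample_id = s, gene = g,
        delta_ct = rel$delta_ct, delta_delta_ct = rel$delta_delta_ct,
        fold = rel$fold,
        ct_sd = if (length(ct_t) > 1L) stats::sd(ct_t) else NA_real_,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
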