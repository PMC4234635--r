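#' Read a two-library gene count table
#'
#' Parses a tab-separated count table with the fixed header
#' \code{gene_id length_bp count_a count_b} into a validated
#' \code{library_pair}. Library totals are always recomputed from the
#' count columns, never taken on trust from the file.
#'
#' The dialect is deliberately strict: UTF-8, Unix newlines, tabs as the
#' only separator, no quoting, and exactly the four expected columns in
#' that order. Violations are reported with their 1-based line number so
#' a malformed file can be fixed by inspection.
#'
#' @param path Path to a TSV file.
#' @param label_a,label_b Library display labels (defaults \code{"A"},
#'   \code{"B"}).
#' @return A \code{library_pair} object: a list with elements
#'   \code{label_a}, \code{label_b}, \code{genes} (a data.frame with
#'   columns \code{gene_id}, \code{length_bp}, \code{count_a},
#'   \code{count_b}, in file order), \code{total_a} and \code{total_b}.
#' @seealso [library_pair()], [write_results()]
#' @export
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' writeLines(c("gene_id\tlength_bp\tcount_a\tcount_b",
#'              "g1\t1000\t10\t20", "g2\t500\t0\t3"), tf)
#' pair <- read_count_table(tf)
#' pair$total_a  # 10
read_count_table <- function(path, label_a = "A", label_b = "B") {
  lines <- read_tsv_lines(path)
  expect_header(lines[1], c("gene_id", "length_bp", "count_a", "count_b"), path)
  body <- lines[-1]
  body <- body[nzchar(body)]
  n <- length(body)
  if (n == 0L) stop("count table '", path, "' has a header but no rows")
  fields <- strsplit(body, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != 4L)) {
    bad <- which(nf != 4L)[1]
    stop("line ", bad + 1L, " of '", path, "': expected 4 tab-separated fields, found ", nf[bad])
  }
  mat <- matrix(unlist(fields), ncol = 4L, byrow = TRUE)
  gene_id <- mat[, 1]
  if (any(!nzchar(gene_id))) {
    bad <- which(!nzchar(gene_id))[1]
    stop("line ", bad + 1L, " of '", path, "': empty gene_id")
  }
  if (anyDuplicated(gene_id)) {
    dup <- gene_id[duplicated(gene_id)][1]
    stop("duplicate gene_id '", dup, "' in '", path, "'")
  }
  length_bp <- parse_int_column(mat[, 2], "length_bp", path)
  count_a <- parse_int_column(mat[, 3], "count_a", path)
  count_b <- parse_int_column(mat[, 4], "count_b", path)
  if (any(length_bp < 1L)) {
    bad <- which(length_bp < 1L)[1]
    stop("line ", bad + 1L, " of '", path, "': length_bp must be >= 1, got ", length_bp[bad])
  }
  for (col in list(list(v = count_a, nm = "count_a"), list(v = count_b, nm = "count_b"))) {
    if (any(col$v < 0L)) {
      bad <- which(col$v < 0L)[1]
      stop("line ", bad + 1L, " of '", path, "': ", col$nm, " must be >= 0, got ", col$v[bad])
    }
  }
  genes <- data.frame(gene_id = gene_id, length_bp = length_bp,
                      count_a = count_a, count_b = count_b,
                      stringsAsFactors = FALSE)
  library_pair(genes, label_a = label_a, label_b = label_b)
}

#' Construct a validated library pair from a gene count data.frame
#'
#' @param genes data.frame with columns \code{gene_id}, \code{length_bp},
#'   \code{count_a}, \code{count_b}. Row order is preserved everywhere
#'   downstream.
#' @param label_a,label_b Library labels.
#' @return A \code{library_pair} (see [read_count_table()]).
#' @export
library_pair <- function(genes, label_a = "A", label_b = "B") {
  required <- c("gene_id", "length_bp", "count_a", "count_b")
  missing_cols <- setdiff(required, names(genes))
  if (length(missing_cols))
    stop("genes table lacks column(s): ", paste(missing_cols, collapse = ", "))
  if (nrow(genes) == 0L) stop("genes table is empty")
  if (anyDuplicated(genes$gene_id))
    stop("duplicate gene_id '", genes$gene_id[duplicated(genes$gene_id)][1], "'")
  if (any(genes$length_bp < 1)) stop("length_bp must be >= 1")
  if (any(genes$count_a < 0) || any(genes$count_b < 0)) stop("counts must be >= 0")
  if (any(genes$count_a != round(genes$count_a)) || any(genes$count_b != round(genes$count_b)))
    stop("counts must be integers")
  total_a <- sum(as.numeric(genes$count_a))
  total_b <- sum(as.numeric(genes$count_b))
  if (total_a < 1 || total_b < 1) stop("each library must contain at least one tag")
  structure(list(label_a = label_a, label_b = label_b,
                 genes = genes[, required], total_a = total_a, total_b = total_b),
            class = "library_pair")
}

#' @export
print.library_pair <- function(x, ...) {
  cat("library_pair:", nrow(x$genes), "genes;",
      x$label_a, "=", format(x$total_a, big.mark = ","), "tags,",
      x$label_b, "=", format(x$total_b, big.mark = ","), "tags\n")
  invisible(x)
}

#' Read a gene-to-term assignment table
#'
#' Parses a TSV with header \code{gene_id term_id namespace term_name}.
#' The namespace column must be \code{GO} or \code{KEGG}. Exact duplicate
#' (gene, term) rows are collapsed to one with a warning.
#'
#' @param path Path to a TSV file.
#' @param count_genes Optional character vector of gene ids from the count
#'   table. When supplied, assignments for genes absent from it are
#'   dropped (with a message giving the count) unless
#'   \code{keep_unmatched = TRUE}.
#' @param keep_unmatched Keep assignments whose gene is not in
#'   \code{count_genes} (they then still contribute to the enrichment
#'   universe). Default \code{FALSE}.
#' @return data.frame with columns \code{gene_id}, \code{term_id},
#'   \code{namespace}, \code{term_name}, in file order after
#'   deduplication.
#' @export
read_term_table <- function(path, count_genes = NULL, keep_unmatched = FALSE) {
  lines <- read_tsv_lines(path)
  expect_header(lines[1], c("gene_id", "term_id", "namespace", "term_name"), path)
  body <- lines[-1]
  body <- body[nzchar(body)]
  if (length(body) == 0L)
    return(data.frame(gene_id = character(), term_id = character(),
                      namespace = character(), term_name = character(),
                      stringsAsFactors = FALSE))
  fields <- strsplit(body, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != 4L)) {
    bad <- which(nf != 4L)[1]
    stop("line ", bad + 1L, " of '", path, "': expected 4 tab-separated fields, found ", nf[bad])
  }
  mat <- matrix(unlist(fields), ncol = 4L, byrow = TRUE)
  asg <- data.frame(gene_id = mat[, 1], term_id = mat[, 2],
                    namespace = mat[, 3], term_name = mat[, 4],
                    stringsAsFactors = FALSE)
  if (any(!nzchar(asg$term_id))) {
    bad <- which(!nzchar(asg$term_id))[1]
    stop("line ", bad + 1L, " of '", path, "': empty term_id")
  }
  unknown <- !(asg$namespace %in% c("GO", "KEGG"))
  if (any(unknown)) {
    bad <- which(unknown)[1]
    stop("line ", bad + 1L, " of '", path, "': unknown namespace '",
         asg$namespace[bad], "' (expected GO or KEGG)")
  }
  key <- paste(asg$gene_id, asg$term_id, sep = "\r")
  if (anyDuplicated(key)) {
    ndup <- sum(duplicated(key))
    warning("collapsed ", ndup, " duplicate (gene, term) row(s) in '", path, "'")
    asg <- asg[!duplicated(key), , drop = FALSE]
  }
  if (!is.null(count_genes) && !keep_unmatched) {
    drop <- !(asg$gene_id %in% count_genes)
    if (any(drop)) {
      message("dropped ", sum(drop),
              " assignment(s) for genes absent from the count table")
      asg <- asg[!drop, , drop = FALSE]
    }
  }
  rownames(asg) <- NULL
  asg
}

#' Write a result table as strict TSV
#'
#' Writes any homogeneous record collection (a data.frame such as the
#' outputs of [call_degs()], [enrich_terms()] or [qpcr_relative()]) as a
#' tab-separated file with a header row. Floating-point columns are
#' rendered with 6 significant digits; such a file round-trips through
#' [read_results()] up to that precision.
#'
#' @param records A data.frame.
#' @param path Output path; its directory must exist.
#' @return Invisibly, \code{path}.
#' @export
write_results <- function(records, path) {
  if (!is.data.frame(records)) stop("records must be a data.frame")
  dir <- dirname(path)
  if (!dir.exists(dir)) stop("directory '", dir, "' does not exist")
  cols <- lapply(records, function(v) {
    if (is.double(v)) {
      out <- vapply(v, function(x) {
        if (is.na(x)) "NA"
        else if (is.infinite(x)) ifelse(x > 0, "Inf", "-Inf")
        else format(signif(x, 6), scientific = FALSE, trim = TRUE)
      }, character(1))
      out
    } else as.character(v)
  })
  if (nrow(records) > 0 && any(vapply(cols, function(v) any(grepl("\t", v, fixed = TRUE)), logical(1))))
    stop("tab characters are not allowed inside fields")
  header <- paste(names(records), collapse = "\t")
  body <- if (nrow(records) == 0L) character(0) else do.call(paste, c(cols, sep = "\t"))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(c(header, body), con, sep = "\n", useBytes = TRUE)
  invisible(path)
}

#' Read back a result table written by [write_results()]
#'
#' @param path Path to a TSV result file.
#' @param numeric_cols Character vector of column names to convert to
#'   numeric; all others stay character.
#' @return A data.frame.
#' @export
read_results <- function(path, numeric_cols = NULL) {
  lines <- read_tsv_lines(path)
  header <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  body <- lines[-1]
  body <- body[nzchar(body)]
  if (length(body) == 0L) {
    df <- as.data.frame(setNames(rep(list(character(0)), length(header)), header),
                        stringsAsFactors = FALSE)
  } else {
    fields <- strsplit(body, "\t", fixed = TRUE)
    if (any(lengths(fields) != length(header)))
      stop("ragged rows in '", path, "'")
    mat <- matrix(unlist(fields), ncol = length(header), byrow = TRUE)
    df <- as.data.frame(mat, stringsAsFactors = FALSE)
    names(df) <- header
  }
  for (nm in intersect(numeric_cols, names(df)))
    df[[nm]] <- as.numeric(df[[nm]])
  df
}

#' Write a library pair back to count-table TSV
#'
#' Inverse of [read_count_table()]: for any valid table,
#' \code{write_count_table(read_count_table(f), g)} makes \code{g}
#' byte-identical to \code{f} (modulo a trailing newline).
#'
#' @param pair A \code{library_pair}.
#' @param path Output path; its directory must exist.
#' @return Invisibly, \code{path}.
#' @export
write_count_table <- function(pair, path) {
  stopifnot(inherits(pair, "library_pair"))
  write_results(pair$genes, path)
}

# -- internal helpers ---------------------------------------------------

read_tsv_lines <- function(path) {
  if (!file.exists(path)) stop("file '", path, "' does not exist")
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  if (length(lines) == 0L) stop("file '", path, "' is empty")
  lines
}

expect_header <- function(line, expected, path) {
  got <- strsplit(line, "\t", fixed = TRUE)[[1]]
  if (length(got) != length(expected) || any(got != expected))
    stop("malformed header in '", path, "': expected '",
         paste(expected, collapse = "\\t"), "', got '",
         paste(got, collapse = "\\t"), "'")
  invisible(TRUE)
}

parse_int_column <- function(chr, name, path) {
  ok <- grepl("^[+-]?[0-9]+$", chr)
  if (!all(ok)) {
    bad <- which(!ok)[1]
    stop("line ", bad + 1L, " of '", path, "': ", name,
         " is not an integer: '", chr[bad], "'")
  }
  as.integer(chr)
}
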