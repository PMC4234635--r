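#' RPKM expression value
#'
#' Reads per kilobase of transcript model per million mapped reads:
#' \deqn{RPKM = 10^9 \cdot C / (N \cdot L)}
#' where \eqn{C} is the tag count for the gene, \eqn{N} the total mapped
#' tags in the library and \eqn{L} the gene length in base pairs.
#'
#' @param count Non-negative integer tag count (vectorised).
#' @param length_bp Gene length in bp, \eqn{\ge 1}.
#' @param library_total Total tags in the library, \eqn{\ge 1}.
#' @return Non-negative numeric; zero exactly when \code{count} is zero.
#' @export
#' @examples
#' rpkm(100, 1000, 1e6)  # 100
rpkm <- function(count, length_bp, library_total) {
  if (any(length_bp < 1)) stop("length_bp must be >= 1")
  if (any(library_total < 1)) stop("library_total must be >= 1")
  if (any(count < 0)) stop("count must be >= 0")
  1e9 * count / (as.numeric(library_total) * length_bp)
}

#' Log2 expression ratio of library B over library A
#'
#' \code{log2((rpkm_b + pseudo) / (rpkm_a + pseudo))}. With the default
#' \code{pseudo = 0} a zero on one side produces a signed infinity
#' sentinel (\code{+Inf} when only \code{rpkm_a} is zero, \code{-Inf}
#' when only \code{rpkm_b} is); both zero gives \code{NA}. A positive
#' pseudocount makes every ratio finite.
#'
#' @param rpkm_a,rpkm_b Non-negative expression values (vectorised).
#' @param pseudo Non-negative pseudocount added to both sides, default 0.
#' @return Numeric; antisymmetric under swapping the two libraries.
#' @export
#' @examples
#' log2_ratio(36.5823, 3.0274)          # about -3.595
#' round_half_out(log2_ratio(4.86, 61.24), 1)  # 3.7
log2_ratio <- function(rpkm_a, rpkm_b, pseudo = 0) {
  if (any(rpkm_a < 0) || any(rpkm_b < 0)) stop("rpkm values must be >= 0")
  if (length(pseudo) != 1L || pseudo < 0) stop("pseudo must be a single value >= 0")
  a <- rpkm_a + pseudo
  b <- rpkm_b + pseudo
  out <- log2(b / a)
  out[a == 0 & b == 0] <- NA_real_
  out
}

#' Round half away from zero
#'
#' Report-column rounding: ties go away from zero (1.25 -> 1.3,
#' -1.25 -> -1.3), matching how one-decimal ratio columns are printed in
#' the field's tables, unlike base [round()] which rounds half to even.
#'
#' @param x Numeric vector.
#' @param digits Decimal places.
#' @return Rounded numeric vector; infinities and NA pass through.
#' @export
round_half_out <- function(x, digits = 1) {
  s <- 10^digits
  out <- sign(x) * floor(abs(x) * s + 0.5) / s
  out[!is.finite(x)] <- x[!is.finite(x)]
  out
}
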