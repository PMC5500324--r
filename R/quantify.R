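#' Reads per kilobase of exon per million mapped reads
#'
#' Converts a raw gene-level count matrix to RPKM:
#' \deqn{RPKM_{g,s} = 10^9 \, c_{g,s} / (L_g N_s)}
#' where \eqn{c_{g,s}} is the read count, \eqn{L_g} the exon-union length of
#' gene \eqn{g} in base pairs, and \eqn{N_s} the per-sample mapped-read
#' depth. By default \eqn{N_s} is the column sum of the count matrix; when
#' the true number of mapped reads (which may include reads outside gene
#' models) is known, pass it through `depths`.
#'
#' @param counts An expression-matrix tibble with unit `"counts"`.
#' @param lengths A tibble with columns `gene_id` and `length` (bp), one row
#'   per gene; every gene in `counts` must be present with `length >= 1`.
#' @param depths Optional named numeric vector of per-sample mapped-read
#'   totals overriding the column sums.
#' @param unit Output unit label; `"FPKM"` uses the same arithmetic with
#'   fragment counts.
#' @return An expression-matrix tibble with unit `"RPKM"` (or `"FPKM"`).
#' @examples
#' counts <- expr_matrix(tibble::tibble(gene_id = "g1", s1 = 100), "counts")
#' compute_rpkm(counts, tibble::tibble(gene_id = "g1", length = 1000),
#'              depths = c(s1 = 1e6))
#' @export
compute_rpkm <- function(counts, lengths, depths = NULL, unit = c("RPKM", "FPKM")) {
  unit <- match.arg(unit)
  m <- expr_values(counts)
  lengths <- tibble::as_tibble(lengths)
  len <- lengths$length[match(rownames(m), lengths$gene_id)]
  if (anyNA(len)) {
    missing <- rownames(m)[is.na(len)]
    stop("no length for gene(s): ", paste(utils::head(missing, 5L), collapse = ", "), call. = FALSE)
  }
  if (any(len < 1)) {
    stop("gene lengths must be >= 1 bp", call. = FALSE)
  }
  n <- resolve_depths(m, depths)
  out <- 1e9 * (m / len) / rep(n, each = nrow(m))
  expr_from_values(out, unit)
}

#' Reads per million mapped reads
#'
#' Depth-normalized expression without length correction:
#' \eqn{RPM_{g,s} = 10^6 c_{g,s} / N_s}. Columns of the result sum to
#' \eqn{10^6}.
#'
#' @inheritParams compute_rpkm
#' @return An expression-matrix tibble with unit `"RPM"`.
#' @export
compute_rpm <- function(counts, depths = NULL) {
  m <- expr_values(counts)
  n <- resolve_depths(m, depths)
  expr_from_values(1e6 * m / rep(n, each = nrow(m)), "RPM")
}

resolve_depths <- function(m, depths) {
  if (is.null(depths)) {
    n <- colSums(m)
  } else {
    n <- depths[colnames(m)]
    if (anyNA(n)) {
      stop("`depths` is missing sample(s): ",
           paste(colnames(m)[is.na(n)], collapse = ", "), call. = FALSE)
    }
  }
  if (any(n <= 0)) {
    stop("zero-depth sample(s): ", paste(colnames(m)[n <= 0], collapse = ", "), call. = FALSE)
  }
  n
}

#' Quantile normalization
#'
#' Forces every sample to share one reference distribution: the reference is
#' the mean across samples of the sorted columns, and each value is replaced
#' by the reference value at its within-column rank. Ties within a column
#' receive the mean of the reference values over their rank span, so the
#' operation is deterministic and idempotent.
#'
#' @param x An expression-matrix tibble (any unit).
#' @return An expression-matrix tibble of the same unit with normalized
#'   values.
#' @examples
#' m <- expr_matrix(tibble::tibble(gene_id = c("g1", "g2"),
#'                                 a = c(1, 5), b = c(3, 7)), "RPKM")
#' quantile_normalize(m)  # both columns become (2, 6)
#' @export
quantile_normalize <- function(x) {
  m <- expr_values(x)
  ref <- rowMeans(apply(m, 2L, sort))
  cum <- cumsum(ref)
  out <- apply(m, 2L, function(v) {
    lo <- rank(v, ties.method = "min")
    hi <- rank(v, ties.method = "max")
    (cum[hi] - c(0, cum)[lo]) / (hi - lo + 1)
  })
  dimnames(out) <- dimnames(m)
  expr_from_values(out, expr_unit(x))
}

#' Shifted log2 transform
#'
#' Maps every value to `log2(x + 1)`, the transform applied ahead of
#' heatmap and PCA inspection so that zeros stay at zero.
#'
#' @param x An expression-matrix tibble.
#' @return An expression-matrix tibble with unit `"normlog2"`.
#' @export
log2p1 <- function(x) {
  expr_from_values(log2(expr_values(x) + 1), "normlog2")
}
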