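#' Tidy a screen result
#'
#' Returns the per-gene provenance trace: one row per gene per stage it
#' entered, with whether it passed, and the sample/value that triggered the
#' decision where applicable.
#'
#' @param x A `screen_result` from [run_screen()].
#' @param ... Unused.
#' @return A tibble with columns `gene_id`, `stage`, `pass`, `sample`,
#'   `value`.
#' @export
tidy.screen_result <- function(x, ...) {
  x$trace
}

#' Glance at a screen result
#'
#' @param x A `screen_result` from [run_screen()].
#' @param ... Unused.
#' @return A one-row tibble with the size of each cascade stage.
#' @export
glance.screen_result <- function(x, ...) {
  out <- tibble::as_tibble(as.list(stats::setNames(x$stage_counts$n,
                                                   x$stage_counts$stage)))
  if ("secondary_detected" %in% names(x$psg)) {
    out$secondary_detected <- sum(x$psg$secondary_detected)
  }
  out
}

#' Tidy a PCA quality-control fit
#'
#' @param x A `pca_qc` object.
#' @param matrix `"variance"` for per-component variance fractions,
#'   `"scores"` for per-sample component scores.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.pca_qc <- function(x, matrix = c("variance", "scores"), ...) {
  matrix <- match.arg(matrix)
  if (matrix == "variance") {
    tibble::tibble(component = seq_along(x$variance_fraction),
                   variance_fraction = x$variance_fraction)
  } else {
    x$scores
  }
}
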