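#' Expression matrix tibbles
#'
#' An expression matrix is stored as a tibble whose first column is
#' `gene_id` (character, unique) and whose remaining columns are one numeric
#' column per sample, all values >= 0. The measurement unit travels with the
#' tibble as the `"unit"` attribute and is one of `"counts"`, `"RPKM"`,
#' `"FPKM"`, `"RPM"` or `"normlog2"`.
#'
#' @param data A data frame with a `gene_id` column followed by numeric
#'   sample columns.
#' @param unit Measurement unit of the values.
#' @return A validated expression-matrix tibble with class `expr_matrix`.
#' @examples
#' expr_matrix(tibble::tibble(gene_id = c("g1", "g2"), s1 = c(0, 5)), "counts")
#' @export
expr_matrix <- function(data,
                        unit = c("counts", "RPKM", "FPKM", "RPM", "normlog2")) {
  unit <- match.arg(unit)
  data <- tibble::as_tibble(data)
  if (ncol(data) < 2L) {
    stop("an expression matrix needs a `gene_id` column and at least one sample column", call. = FALSE)
  }
  if (names(data)[1L] != "gene_id") {
    stop("the first column must be named `gene_id`", call. = FALSE)
  }
  if (nrow(data) == 0L) {
    stop("expression matrix has no genes", call. = FALSE)
  }
  data$gene_id <- as.character(data$gene_id)
  dup_g <- unique(data$gene_id[duplicated(data$gene_id)])
  if (length(dup_g) > 0L) {
    stop("duplicate gene ids: ", paste(utils::head(dup_g, 5L), collapse = ", "), call. = FALSE)
  }
  samples <- names(data)[-1L]
  if (anyDuplicated(samples)) {
    stop("duplicate sample ids", call. = FALSE)
  }
  for (s in samples) {
    if (!is.numeric(data[[s]])) {
      stop("non-numeric values in sample `", s, "`", call. = FALSE)
    }
    if (anyNA(data[[s]])) {
      stop("missing values in sample `", s, "`", call. = FALSE)
    }
    if (any(data[[s]] < 0)) {
      stop("negative values in sample `", s, "`", call. = FALSE)
    }
  }
  attr(data, "unit") <- unit
  class(data) <- unique(c("expr_matrix", class(data)))
  data
}

#' Unit of an expression matrix
#' @param x An expression-matrix tibble.
#' @return The unit string.
#' @export
expr_unit <- function(x) {
  attr(x, "unit") %||% "counts"
}

#' Sample ids of an expression matrix
#' @param x An expression-matrix tibble.
#' @return Character vector of sample ids.
#' @export
expr_samples <- function(x) {
  setdiff(names(x), "gene_id")
}

## internal: dense numeric matrix with gene_id rownames
expr_values <- function(x) {
  m <- as.matrix(x[, setdiff(names(x), "gene_id"), drop = FALSE])
  rownames(m) <- x$gene_id
  m
}

## internal: rebuild an expr_matrix tibble from a values matrix
expr_from_values <- function(values, unit) {
  out <- tibble::as_tibble(as.data.frame(values, check.names = FALSE))
  out <- tibble::add_column(out, gene_id = rownames(values), .before = 1L)
  expr_matrix(out, unit)
}

#' Read an expression matrix from TSV
#'
#' The dialect is fixed: tab separated, a header row of sample ids, first
#' column `gene_id`. Duplicate ids, non-numeric cells and empty files are
#' errors.
#'
#' @param path Path to a TSV file.
#' @param unit Measurement unit to attach to the values.
#' @return An expression-matrix tibble.
#' @export
read_matrix <- function(path, unit = "counts") {
  tbl <- readr::read_tsv(path, col_types = readr::cols(
    gene_id = readr::col_character(),
    .default = readr::col_double()
  ), progress = FALSE)
  probs <- readr::problems(tbl)
  if (nrow(probs) > 0L) {
    stop("malformed matrix TSV `", path, "` (first problem at row ", probs$row[1L], ")", call. = FALSE)
  }
  if (nrow(tbl) == 0L) {
    stop("empty expression matrix: ", path, call. = FALSE)
  }
  expr_matrix(tbl, unit)
}

#' Write an expression matrix to TSV
#'
#' Round-trips through [read_matrix()] with values preserved to full double
#' precision.
#'
#' @param x An expression-matrix tibble.
#' @param path Output path.
#' @return `x`, invisibly.
#' @export
write_matrix <- function(x, path) {
  readr::write_tsv(tibble::as_tibble(x), path)
  invisible(x)
}

#' Strip trailing version suffixes from gene ids
#'
#' Tomato ITAG ids circulate both with and without a trailing `.N` version
#' (`Solyc01g007270.2` vs `Solyc01g007270`); cross-dataset joins strip the
#' version so that both forms match.
#'
#' @param ids Character vector of gene ids.
#' @return Ids with any trailing `.<digits>` removed.
#' @examples
#' strip_gene_version(c("Solyc01g007270.2.1", "Solyc01g008540"))
#' @export
strip_gene_version <- function(ids) {
  sub("(\\.\\d+)+$", "", as.character(ids))
}

#' Sample annotation table
#'
#' Validates a per-sample annotation tibble with columns `sample_id`,
#' `tissue`, `stage` and `group`. `group` is one of `pistil`, `other_floral`,
#' `vegetative`, `fruit`, or a cell-type label of the form `celltype:<name>`.
#'
#' @param data A data frame of sample annotations.
#' @return A validated tibble.
#' @export
sample_annotation <- function(data) {
  data <- tibble::as_tibble(data)
  needed <- c("sample_id", "tissue", "stage", "group")
  missing <- setdiff(needed, names(data))
  if (length(missing) > 0L) {
    stop("annotation is missing column(s): ", paste(missing, collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(data$sample_id)) {
    stop("duplicate sample ids in annotation", call. = FALSE)
  }
  ok <- data$group %in% c("pistil", "other_floral", "vegetative", "fruit") |
    startsWith(data$group, "celltype:")
  if (!all(ok)) {
    stop("unknown group label(s): ", paste(unique(data$group[!ok]), collapse = ", "), call. = FALSE)
  }
  data
}

## internal: sample ids of a group present in an expression matrix
samples_in_group <- function(x, annotations, group) {
  ann <- sample_annotation(annotations)
  intersect(expr_samples(x), ann$sample_id[ann$group %in% group])
}
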