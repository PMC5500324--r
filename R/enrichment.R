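#' Hypergeometric over-representation p-value
#'
#' Exact upper-tail probability \eqn{P(X \ge k)} for
#' \eqn{X \sim Hypergeometric(N, K, n)}: the chance of drawing at least `k`
#' annotated genes in a study set of size `n` sampled without replacement
#' from a population of `N` genes of which `K` carry the annotation.
#' Vectorized over its arguments.
#'
#' @param k Study hits (genes in the study set carrying the term).
#' @param n Study set size.
#' @param K Population hits (genes in the population carrying the term).
#' @param N Population size.
#' @return Tail probability in `[0, 1]`.
#' @examples
#' hypergeom_test(5, 5, 5, 20)  # 1 / choose(20, 5)
#' @export
hypergeom_test <- function(k, n, K, N) {
  bad <- k < 0 | k > n | n > N | K > N | k > K
  if (any(bad)) {
    stop("need 0 <= k <= min(n, K) and n, K <= N", call. = FALSE)
  }
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false discovery rate adjustment
#' \eqn{q_{(i)} = \min_{j \ge i} p_{(j)} m / j}, capped at 1, returned in
#' the input order.
#'
#' @param p Numeric vector of p-values.
#' @return Adjusted values of the same length and order.
#' @examples
#' bh_fdr(c(0.01, 0.02, 0.04))  # 0.03 0.03 0.04
#' @export
bh_fdr <- function(p) {
  stats::p.adjust(p, method = "BH")
}

#' Read gene-to-term annotations
#'
#' Supports a two-column TSV (`gene_id`, `term_id`, optional `term_name`
#' third column, with or without a header) and GAF 2.x (gene from column 2,
#' term from column 5; `!` comment lines skipped).
#'
#' @param path Path to the annotation file.
#' @param format `"tsv"` or `"gaf"`.
#' @return A tibble with columns `gene_id`, `term_id` and (TSV only, when
#'   present) `term_name`.
#' @export
read_go_annotations <- function(path, format = c("tsv", "gaf")) {
  format <- match.arg(format)
  if (format == "gaf") {
    raw <- readr::read_tsv(path, comment = "!", col_names = FALSE,
                           col_types = readr::cols(.default = readr::col_character()),
                           progress = FALSE)
    if (ncol(raw) < 5L) stop("GAF file has fewer than 5 columns", call. = FALSE)
    return(dplyr::distinct(tibble::tibble(gene_id = raw[[2L]], term_id = raw[[5L]])))
  }
  first <- readr::read_lines(path, n_max = 1L)
  has_header <- grepl("gene_id", first, fixed = TRUE)
  raw <- readr::read_tsv(path, col_names = has_header,
                         col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  if (!has_header) {
    names(raw)[1:2] <- c("gene_id", "term_id")
    if (ncol(raw) >= 3L) names(raw)[3L] <- "term_name"
  }
  dplyr::distinct(tibble::as_tibble(raw[, intersect(c("gene_id", "term_id", "term_name"), names(raw))]))
}

#' GO-term over-representation test
#'
#' One-sided hypergeometric enrichment of a study gene set against an
#' annotation table, with Benjamini-Hochberg FDR control across all tested
#' terms. A term is tested when it has at least one study hit; the BH family
#' size is the number of tested terms. The test uses direct annotations as
#' given -- no ontology-graph propagation -- so pre-propagate upstream if
#' ancestor terms should inherit hits.
#'
#' @param study Character vector (or tibble with `gene_id`) of study genes.
#' @param annotations Tibble with columns `gene_id`, `term_id` and optional
#'   `term_name` (see [read_go_annotations()]).
#' @param fdr_max Terms at or below this FDR are flagged significant
#'   (default 0.05).
#' @param population Optional explicit gene universe; defaults to all genes
#'   in `annotations`. Study genes outside the population are dropped with
#'   a warning.
#' @return A tibble of class `enrich_result`, one row per tested term:
#'   `term_id`, `term_name` (if available), study hits `k`, study size `n`,
#'   population hits `K`, population size `N`, `p_value`, `fdr`,
#'   `significant`; sorted by p-value then term id. The number of dropped
#'   study genes is in `attr(, "n_dropped")`.
#' @export
enrich <- function(study, annotations, fdr_max = 0.05, population = NULL) {
  study <- unique(as_gene_ids(study))
  annotations <- dplyr::distinct(tibble::as_tibble(annotations))
  if (is.null(population)) {
    population <- unique(annotations$gene_id)
  } else {
    population <- unique(as.character(population))
    annotations <- annotations[annotations$gene_id %in% population, , drop = FALSE]
  }
  if (length(population) == 0L) stop("empty population", call. = FALSE)
  in_pop <- study %in% population
  n_dropped <- sum(!in_pop)
  if (n_dropped > 0L) {
    warning(n_dropped, " study gene(s) outside the population were dropped",
            call. = FALSE)
  }
  study <- study[in_pop]
  n <- length(study)
  N <- length(population)

  hits <- annotations[annotations$gene_id %in% study, , drop = FALSE]
  if (nrow(hits) == 0L) {
    out <- tibble::tibble(term_id = character(), k = integer(), n = integer(),
                          K = integer(), N = integer(), p_value = double(),
                          fdr = double(), significant = logical())
    return(structure(out, n_dropped = n_dropped, class = c("enrich_result", class(out))))
  }
  k_tbl <- dplyr::count(hits, .data$term_id, name = "k")
  K_tbl <- dplyr::count(annotations, .data$term_id, name = "K")
  out <- dplyr::inner_join(k_tbl, K_tbl, by = "term_id")
  out$n <- n
  out$N <- N
  out$p_value <- hypergeom_test(out$k, out$n, out$K, out$N)
  out$fdr <- bh_fdr(out$p_value)
  out$significant <- out$fdr <= fdr_max
  if ("term_name" %in% names(annotations)) {
    names_tbl <- dplyr::distinct(annotations[, c("term_id", "term_name")])
    names_tbl <- names_tbl[!duplicated(names_tbl$term_id), ]
    out <- dplyr::left_join(out, names_tbl, by = "term_id")
  }
  out <- out[order(out$p_value, out$term_id),
             intersect(c("term_id", "term_name", "k", "n", "K", "N",
                         "p_value", "fdr", "significant"), names(out))]
  structure(tibble::as_tibble(out), n_dropped = n_dropped,
            class = c("enrich_result", class(tibble::tibble())))
}

#' @export
print.enrich_result <- function(x, ...) {
  cat("GO over-representation:", nrow(x), "term(s) tested,",
      sum(x$significant), "significant\n")
  NextMethod()
}
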