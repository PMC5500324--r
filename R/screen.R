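#' Screening thresholds
#'
#' Bundles the expression cutoffs of the specificity cascade. All
#' comparisons in the cascade are strict inequalities, so a gene sitting
#' exactly on a cutoff fails the "keep" side of that filter.
#'
#' @param candidate_on RPKM a gene must exceed in at least one pistil sample
#'   to become a candidate (default 0.5).
#' @param candidate_off RPKM that every non-pistil sample must stay below
#'   (default 0.5).
#' @param public_detect Expression floor for "detected" in the public
#'   compendium; the default 0 counts any positive value as detection.
#' @param veg_exclude RPKM above which expression in any vegetative sample
#'   disqualifies a gene (default 1).
#' @param celltype_min RPM a gene must exceed in at least one pistil
#'   cell-type sample (default 2).
#' @param secondary_detect FPKM above which a gene counts as detected in the
#'   secondary two-tissue comparison (default 0.5).
#' @return A list of class `screen_thresholds`.
#' @export
screen_thresholds <- function(candidate_on = 0.5, candidate_off = 0.5,
                              public_detect = 0, veg_exclude = 1,
                              celltype_min = 2, secondary_detect = 0.5) {
  th <- list(candidate_on = candidate_on, candidate_off = candidate_off,
             public_detect = public_detect, veg_exclude = veg_exclude,
             celltype_min = celltype_min, secondary_detect = secondary_detect)
  if (any(unlist(th) < 0)) stop("thresholds must be >= 0", call. = FALSE)
  structure(th, class = "screen_thresholds")
}

as_gene_ids <- function(genes) {
  if (is.data.frame(genes)) as.character(genes$gene_id) else as.character(genes)
}

## row-wise max over a possibly 0-column matrix
row_max <- function(m) {
  if (ncol(m) == 0L) rep(-Inf, nrow(m)) else apply(m, 1L, max)
}

#' Select tissue-specific candidate genes
#'
#' A gene becomes a candidate when its expression is above `candidate_on`
#' in at least one pistil-group sample and below `candidate_off` in every
#' other sample (strict on both sides).
#'
#' @param rpkm An expression-matrix tibble (RPKM) covering pistil and
#'   non-pistil samples.
#' @param annotations Sample annotation tibble (see [sample_annotation()]).
#' @param thresholds A [screen_thresholds()] list.
#' @return A tibble of selected genes with the pistil sample and value that
#'   triggered selection and the maximum off-target value.
#' @export
select_candidates <- function(rpkm, annotations, thresholds = screen_thresholds()) {
  ann <- sample_annotation(annotations)
  m <- expr_values(rpkm)
  pistil <- samples_in_group(rpkm, ann, "pistil")
  if (length(pistil) == 0L) {
    stop("no pistil-group samples annotated in the matrix", call. = FALSE)
  }
  other <- setdiff(colnames(m), pistil)
  if (length(other) == 0L) {
    stop("no non-pistil samples in the matrix", call. = FALSE)
  }
  mp <- m[, pistil, drop = FALSE]
  best <- max.col(mp, ties.method = "first")
  pistil_max <- mp[cbind(seq_len(nrow(mp)), best)]
  other_max <- row_max(m[, other, drop = FALSE])
  keep <- pistil_max > thresholds$candidate_on & other_max < thresholds$candidate_off
  tibble::tibble(
    gene_id = rownames(m)[keep],
    pistil_sample = pistil[best][keep],
    pistil_max = unname(pistil_max[keep]),
    other_max = unname(other_max[keep])
  )
}

#' Keep genes detected in an external compendium
#'
#' A gene survives when its value exceeds `floor` in at least one sample of
#' `public`. Genes whose id is absent from the external matrix are treated
#' as not detected (cross-dataset id drop-out) and removed.
#'
#' @param genes Candidate genes: a character vector or a tibble with a
#'   `gene_id` column.
#' @param public External expression-matrix tibble.
#' @param floor Detection floor (default 0: any positive value).
#' @param strip_versions Strip trailing `.N` version suffixes before
#'   matching ids across datasets (default `TRUE`).
#' @return A tibble of retained genes with the detecting sample and value.
#' @export
filter_detected <- function(genes, public, floor = 0, strip_versions = TRUE) {
  ids <- as_gene_ids(genes)
  m <- expr_values(public)
  key <- if (strip_versions) strip_gene_version(rownames(m)) else rownames(m)
  idx <- match(if (strip_versions) strip_gene_version(ids) else ids, key)
  present <- !is.na(idx)
  keep <- logical(length(ids))
  sample <- rep(NA_character_, length(ids))
  value <- rep(NA_real_, length(ids))
  if (any(present)) {
    mm <- m[idx[present], , drop = FALSE]
    best <- max.col(mm, ties.method = "first")
    vmax <- mm[cbind(seq_len(nrow(mm)), best)]
    keep[present] <- vmax > floor
    sample[present] <- colnames(m)[best]
    value[present] <- vmax
  }
  tibble::tibble(gene_id = ids, sample = sample, value = value,
                 absent = !present)[keep, c("gene_id", "sample", "value")]
}

#' Exclude genes expressed in vegetative tissues
#'
#' Drops a gene when its value exceeds `veg_exclude` in any vegetative-group
#' sample of the external matrix (strict: a value exactly at the cutoff is
#' retained). Genes absent from the matrix pass unchanged, having already
#' cleared detection upstream.
#'
#' @inheritParams filter_detected
#' @param annotations Annotation tibble covering the vegetative samples of
#'   `public`.
#' @param thresholds A [screen_thresholds()] list.
#' @return A tibble of retained genes with their maximum vegetative value.
#' @export
filter_vegetative <- function(genes, public, annotations,
                              thresholds = screen_thresholds(),
                              strip_versions = TRUE) {
  ids <- as_gene_ids(genes)
  m <- expr_values(public)
  veg <- samples_in_group(public, annotations, "vegetative")
  if (length(veg) == 0L) {
    warning("no vegetative samples found in the external matrix; nothing excluded",
            call. = FALSE)
    return(tibble::tibble(gene_id = ids, veg_max = NA_real_))
  }
  key <- if (strip_versions) strip_gene_version(rownames(m)) else rownames(m)
  idx <- match(if (strip_versions) strip_gene_version(ids) else ids, key)
  veg_max <- rep(NA_real_, length(ids))
  present <- !is.na(idx)
  veg_max[present] <- row_max(m[idx[present], veg, drop = FALSE])
  keep <- is.na(veg_max) | veg_max <= thresholds$veg_exclude
  tibble::tibble(gene_id = ids, veg_max = veg_max)[keep, ]
}

#' Keep genes expressed in pistil cell types
#'
#' A gene survives when its RPM exceeds `celltype_min` in at least one
#' pistil cell-type sample. Genes absent from the cell-type matrix are
#' dropped.
#'
#' @inheritParams filter_detected
#' @param celltype_rpm Cell-type expression-matrix tibble (RPM).
#' @param thresholds A [screen_thresholds()] list.
#' @return A tibble of retained genes with the triggering sample and value.
#' @export
filter_celltype <- function(genes, celltype_rpm,
                            thresholds = screen_thresholds(),
                            strip_versions = TRUE) {
  filter_detected(genes, celltype_rpm, floor = thresholds$celltype_min,
                  strip_versions = strip_versions)
}

#' Run the full pistil-specificity screen
#'
#' Composes the cascade: RPKM quantification of the in-house counts,
#' candidate selection (on in pistil, off elsewhere), detection in the
#' public compendium, exclusion of vegetative expression (giving the
#' floral-organ-specific set) and, in parallel from the candidates,
#' the cell-type expression filter (giving the pistil-expressed set).
#' The screen's result set is the intersection of the two branches. An
#' optional secondary two-tissue matrix annotates -- never filters -- each
#' final gene with whether it was detected there above
#' `thresholds$secondary_detect`.
#'
#' @param counts In-house expression-matrix tibble with unit `"counts"`.
#' @param lengths Gene-length tibble (`gene_id`, `length`).
#' @param annotations Annotation tibble covering the in-house samples and
#'   the vegetative samples of `public`.
#' @param public External expression matrix (RPKM) including vegetative
#'   samples.
#' @param celltype Cell-type expression matrix (RPM).
#' @param secondary Optional two-tissue expression matrix (FPKM) used for
#'   annotation only.
#' @param thresholds A [screen_thresholds()] list.
#' @param depths Optional per-sample depth override for RPKM.
#' @param strip_versions Strip `.N` id suffixes when joining datasets.
#' @return A `screen_result` object: stage gene sets, stage counts, a
#'   per-gene provenance trace, and the final gene table. Use [tidy()] for
#'   the trace and [glance()] for one-row stage counts.
#' @export
run_screen <- function(counts, lengths, annotations, public, celltype,
                       secondary = NULL, thresholds = screen_thresholds(),
                       depths = NULL, strip_versions = TRUE) {
  ann <- sample_annotation(annotations)
  rpkm <- compute_rpkm(counts, lengths, depths = depths)

  candidates <- select_candidates(rpkm, ann, thresholds)
  detected <- filter_detected(candidates, public,
                              floor = thresholds$public_detect,
                              strip_versions = strip_versions)
  floral <- filter_vegetative(detected, public, ann, thresholds,
                              strip_versions = strip_versions)
  pistil_expr <- filter_celltype(candidates, celltype, thresholds,
                                 strip_versions = strip_versions)
  psg_ids <- intersect(floral$gene_id, pistil_expr$gene_id)

  psg <- tibble::tibble(gene_id = psg_ids)
  if (!is.null(secondary)) {
    det2 <- filter_detected(psg_ids, secondary,
                            floor = thresholds$secondary_detect,
                            strip_versions = strip_versions)
    psg$secondary_detected <- psg$gene_id %in% det2$gene_id
  }

  sets <- list(candidates = candidates$gene_id,
               detected_public = detected$gene_id,
               floral_specific = floral$gene_id,
               pistil_expressed = pistil_expr$gene_id,
               psg = psg_ids)
  trace <- screen_trace(rpkm, candidates, detected, floral, pistil_expr, psg_ids)

  structure(list(
    stage_sets = sets,
    stage_counts = tibble::tibble(stage = names(sets),
                                  n = lengths_int(sets)),
    trace = trace,
    psg = psg,
    thresholds = thresholds
  ), class = "screen_result")
}

lengths_int <- function(x) vapply(x, length, integer(1))

screen_trace <- function(rpkm, candidates, detected, floral, pistil_expr, psg_ids) {
  all_genes <- rpkm$gene_id
  stage <- function(name, entered, kept, sample = NULL, value = NULL) {
    tibble::tibble(
      gene_id = entered,
      stage = name,
      pass = entered %in% kept,
      sample = if (is.null(sample)) NA_character_ else sample[match(entered, kept)],
      value = if (is.null(value)) NA_real_ else value[match(entered, kept)]
    )
  }
  dplyr::bind_rows(
    stage("candidate", all_genes, candidates$gene_id,
          candidates$pistil_sample, candidates$pistil_max),
    stage("detected_public", candidates$gene_id, detected$gene_id,
          detected$sample, detected$value),
    stage("floral_specific", detected$gene_id, floral$gene_id,
          value = floral$veg_max),
    stage("pistil_expressed", candidates$gene_id, pistil_expr$gene_id,
          pistil_expr$sample, pistil_expr$value),
    stage("psg", union(floral$gene_id, pistil_expr$gene_id), psg_ids)
  )
}

#' @export
print.screen_result <- function(x, ...) {
  cat("Pistil-specificity screen\n")
  counts <- x$stage_counts
  labels <- c(candidates = "candidates (pistil on / other off)",
              detected_public = "detected in public compendium",
              floral_specific = "floral organ-specific",
              pistil_expressed = "pistil expressed (cell types)",
              psg = "pistil-specific genes")
  for (i in seq_len(nrow(counts))) {
    cat(sprintf("  %-34s %d\n", labels[[counts$stage[i]]], counts$n[i]))
  }
  if ("secondary_detected" %in% names(x$psg)) {
    cat(sprintf("  detected in secondary dataset      %d of %d\n",
                sum(x$psg$secondary_detected), nrow(x$psg)))
  }
  invisible(x)
}

#' Assign each gene a preferred pistil cell type
#'
#' Formalizes "preferential expression" as the cell-type group with the
#' largest mean RPM. Genes with an all-zero profile are labelled
#' `"unclassified"`; ties go to the earlier group in `group_order` (by
#' default the order in which groups first appear in the matrix columns).
#'
#' @param genes Character vector or tibble with `gene_id`.
#' @param celltype_rpm Cell-type expression-matrix tibble (RPM).
#' @param groups Optional named character vector mapping sample id to
#'   cell-type group; by default every sample is its own group.
#' @param group_order Optional explicit tie-break order of group labels.
#' @param strip_versions Strip `.N` id suffixes when matching.
#' @return A tibble with columns `gene_id`, `celltype` and `mean_rpm`.
#' @export
classify_celltype_preference <- function(genes, celltype_rpm, groups = NULL,
                                         group_order = NULL,
                                         strip_versions = TRUE) {
  ids <- as_gene_ids(genes)
  m <- expr_values(celltype_rpm)
  if (is.null(groups)) {
    groups <- stats::setNames(colnames(m), colnames(m))
  }
  groups <- groups[colnames(m)]
  if (is.null(group_order)) group_order <- unique(unname(groups))
  ## group means, columns ordered by group_order
  gm <- sapply(group_order, function(g) {
    rowMeans(m[, names(groups)[groups == g], drop = FALSE])
  })
  if (is.null(dim(gm))) gm <- matrix(gm, nrow = nrow(m), dimnames = list(rownames(m), group_order))
  key <- if (strip_versions) strip_gene_version(rownames(m)) else rownames(m)
  idx <- match(if (strip_versions) strip_gene_version(ids) else ids, key)
  label <- rep("unclassified", length(ids))
  best_val <- rep(NA_real_, length(ids))
  present <- !is.na(idx)
  if (any(present)) {
    sub <- gm[idx[present], , drop = FALSE]
    best <- max.col(sub, ties.method = "first")
    val <- sub[cbind(seq_len(nrow(sub)), best)]
    lab <- group_order[best]
    lab[val <= 0] <- "unclassified"
    label[present] <- lab
    best_val[present] <- val
  }
  tibble::tibble(gene_id = ids, celltype = label, mean_rpm = best_val)
}

#' Top-ranked genes in a sample or group
#'
#' Orders genes by expression in one named sample (or by the mean over a
#' sample group) and returns the top `k`, ties broken lexicographically by
#' gene id.
#'
#' @param x An expression-matrix tibble.
#' @param sample A single sample id, or a character vector of sample ids
#'   whose mean is ranked.
#' @param k Number of genes to return; if `k` exceeds the gene count all
#'   genes are returned.
#' @param genes Optional restriction to a gene subset (character vector or
#'   tibble with `gene_id`).
#' @return A tibble with `gene_id` and `value`, ordered descending.
#' @export
rank_top_genes <- function(x, sample, k = 10, genes = NULL) {
  m <- expr_values(x)
  missing <- setdiff(sample, colnames(m))
  if (length(missing) > 0L) {
    stop("sample(s) not in matrix: ", paste(missing, collapse = ", "), call. = FALSE)
  }
  v <- rowMeans(m[, sample, drop = FALSE])
  tbl <- tibble::tibble(gene_id = rownames(m), value = unname(v))
  if (!is.null(genes)) {
    tbl <- tbl[tbl$gene_id %in% as_gene_ids(genes), ]
  }
  tbl <- tbl[order(-tbl$value, tbl$gene_id), ]
  utils::head(tbl, k)
}

#' PCA quality control of an expression matrix
#'
#' Principal component analysis of the samples after centering every gene's
#' row, computed by singular value decomposition. Used as a sanity check
#' that samples separate along tissue identity; the per-component variance
#' fractions sum to 1.
#'
#' @param x An expression-matrix tibble, typically `normlog2` values.
#' @return An object of class `pca_qc` with `variance_fraction` (numeric)
#'   and `scores` (tibble of per-sample component scores).
#' @export
pca_qc <- function(x) {
  m <- expr_values(x)
  if (ncol(m) < 2L) stop("PCA needs at least two samples", call. = FALSE)
  fit <- stats::prcomp(t(m), center = TRUE, scale. = FALSE)
  frac <- fit$sdev^2 / sum(fit$sdev^2)
  scores <- tibble::as_tibble(fit$x)
  scores <- tibble::add_column(scores, sample_id = colnames(m), .before = 1L)
  structure(list(variance_fraction = frac, scores = scores), class = "pca_qc")
}

#' @export
print.pca_qc <- function(x, ...) {
  cat("PCA over", nrow(x$scores), "samples\n")
  shown <- utils::head(x$variance_fraction, 5L)
  cat("  variance fractions:",
      paste(sprintf("PC%d %.1f%%", seq_along(shown), 100 * shown), collapse = ", "),
      "\n")
  invisible(x)
}

#' Intersect a gene set with an external DEG list
#'
#' Order-stable set intersection (in the order of `genes`), with optional
#' id-version stripping, for comparing screen hits with externally derived
#' differentially-expressed-gene lists.
#'
#' @param genes Character vector or tibble with `gene_id`.
#' @param deg_ids Character vector of external gene ids.
#' @param strip_versions Strip `.N` id suffixes before matching.
#' @return Character vector of shared gene ids, in `genes` order.
#' @export
intersect_with_deg_list <- function(genes, deg_ids, strip_versions = TRUE) {
  ids <- as_gene_ids(genes)
  a <- if (strip_versions) strip_gene_version(ids) else ids
  b <- if (strip_versions) strip_gene_version(deg_ids) else deg_ids
  unique(ids[a %in% b])
}
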