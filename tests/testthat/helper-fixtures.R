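# Small constructors and independent reference implementations used as
# oracles. The oracles are deliberately naive (double loops, exhaustive
# enumeration) and share no code with the package internals.

make_expr <- function(..., unit = "counts", gene_id = NULL) {
  cols <- list(...)
  n <- length(cols[[1L]])
  if (is.null(gene_id)) gene_id <- sprintf("g%02d", seq_len(n))
  expr_matrix(tibble::tibble(gene_id = gene_id, !!!cols), unit)
}

random_expr <- function(n_genes, samples, max = 10, unit = "RPKM") {
  vals <- matrix(round(stats::runif(n_genes * length(samples), 0, max), 2),
                 n_genes, length(samples), dimnames = list(NULL, samples))
  tbl <- tibble::as_tibble(as.data.frame(vals))
  tbl <- tibble::add_column(tbl, gene_id = sprintf("g%03d", seq_len(n_genes)),
                            .before = 1L)
  expr_matrix(tbl, unit)
}

expr_as_matrix <- function(x) {
  m <- as.matrix(tibble::as_tibble(x)[, -1L])
  rownames(m) <- x$gene_id
  m
}

## per-cell loop RPKM reference
oracle_rpkm <- function(counts, lengths) {
  m <- expr_as_matrix(counts)
  out <- m
  for (s in seq_len(ncol(m))) {
    N <- sum(m[, s])
    for (g in seq_len(nrow(m))) {
      L <- lengths$length[lengths$gene_id == rownames(m)[g]]
      out[g, s] <- 1e9 * m[g, s] / (L * N)
    }
  }
  out
}

## double-loop reference implementations of the cascade stages
oracle_candidates <- function(rpkm, ann, on = 0.5, off = 0.5) {
  m <- expr_as_matrix(rpkm)
  pistil <- ann$sample_id[ann$group == "pistil"]
  pistil <- intersect(colnames(m), pistil)
  other <- setdiff(colnames(m), pistil)
  keep <- character(0)
  for (g in rownames(m)) {
    if (max(m[g, pistil]) > on && all(m[g, other] < off)) keep <- c(keep, g)
  }
  keep
}

oracle_detected <- function(genes, public, floor = 0) {
  m <- expr_as_matrix(public)
  keep <- character(0)
  for (g in genes) {
    if (g %in% rownames(m) && any(m[g, ] > floor)) keep <- c(keep, g)
  }
  keep
}

oracle_vegetative <- function(genes, public, ann, cutoff = 1) {
  m <- expr_as_matrix(public)
  veg <- intersect(colnames(m), ann$sample_id[ann$group == "vegetative"])
  keep <- character(0)
  for (g in genes) {
    drop <- g %in% rownames(m) && any(m[g, veg] > cutoff)
    if (!drop) keep <- c(keep, g)
  }
  keep
}

oracle_celltype <- function(genes, rpm, cutoff = 2) {
  oracle_detected(genes, rpm, floor = cutoff)
}

## exhaustive log-space tail sum for the hypergeometric test
oracle_hyper <- function(k, n, K, N) {
  i <- k:min(n, K)
  if (length(i) == 0L) return(0)
  sum(exp(lchoose(K, i) + lchoose(N - K, n - i) - lchoose(N, n)))
}

## hand step-up BH
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- p[o] * m / seq_len(m)
  q_sorted <- rev(cummin(rev(q_sorted)))
  q <- numeric(m)
  q[o] <- pmin(q_sorted, 1)
  q
}

## naive character scan for C-terminal cysteines
oracle_cys <- function(seq, frac, mature_start = 1) {
  mature <- substring(seq, mature_start)
  L <- nchar(mature)
  from <- ceiling((1 - frac) * L) + 1
  if (from > L) return(0L)
  sum(unlist(strsplit(substring(mature, from, L), "")) == "C")
}

## random small screen instance for property fuzzing
random_screen_instance <- function(n_genes = 30) {
  ids <- sprintf("g%03d", seq_len(n_genes))
  ann <- tibble::tibble(
    sample_id = c("p1", "p2", "fl1", "fl2", "v1", "pubf1", "pubp1", "pubv1", "pubv2"),
    tissue = "t", stage = "s",
    group = c("pistil", "pistil", "other_floral", "vegetative", "vegetative",
              "other_floral", "pistil", "vegetative", "vegetative")
  )
  ## sparse counts with occasional strong expression so every cascade
  ## stage sees both passing and failing genes
  counts_m <- matrix(rpois(n_genes * 5, 0.5) *
                       sample(c(1, 60), n_genes * 5, replace = TRUE),
                     n_genes, 5,
                     dimnames = list(NULL, c("p1", "p2", "fl1", "fl2", "v1")))
  counts <- expr_matrix(tibble::add_column(
    tibble::as_tibble(as.data.frame(counts_m)), gene_id = ids, .before = 1L
  ), "counts")
  lengths <- tibble::tibble(gene_id = ids, length = sample(500:3000, n_genes, TRUE))
  pub_ids <- sample(ids, round(0.8 * n_genes))  # id drop-out across datasets
  public <- expr_matrix(tibble::tibble(
    gene_id = pub_ids,
    pubf1 = round(runif(length(pub_ids), 0, 4), 2),
    pubp1 = round(runif(length(pub_ids), 0, 4), 2),
    pubv1 = round(runif(length(pub_ids), 0, 2), 2),
    pubv2 = round(runif(length(pub_ids), 0, 2), 2)
  ), "RPKM")
  ct_ids <- sample(ids, round(0.9 * n_genes))
  celltype <- expr_matrix(tibble::tibble(
    gene_id = ct_ids,
    ovule = round(runif(length(ct_ids), 0, 6), 2),
    embryo = round(runif(length(ct_ids), 0, 6), 2)
  ), "RPM")
  list(counts = counts, lengths = lengths, ann = ann, public = public,
       celltype = celltype)
}
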