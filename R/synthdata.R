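GENE_CLASSES <- c("pistil_specific", "floral_nonpistil", "vegetative",
                  "ubiquitous", "silent")
PROTEIN_CLASSES <- c("crp", "too_long", "no_signal", "bad_cys")
CELLTYPES <- c("ovule", "embryo", "endosperm", "seed_coat", "pericarp",
               "placenta", "septum")
SYNTH_DATASETS <- c("inhouse17", "public26", "celltype", "twotissue")

#' Synthetic-data configuration
#'
#' Parameters for the generator that emulates the multi-dataset expression
#' study the screen consumes: an in-house 17-sample matrix spanning pistil,
#' anther, other floral, vegetative and fruit samples; a 26-sample public
#' compendium with 9 vegetative samples; a 7-sample pistil cell-type
#' matrix; and a two-tissue ovule/ovary-wall matrix. Genes fall into five
#' planted classes -- `pistil_specific` (on only in pistil and cell-type
#' samples), `floral_nonpistil` (anther/petal/sepal), `vegetative`,
#' `ubiquitous` and `silent` -- allocated by largest remainder so class
#' counts are deterministic.
#'
#' Counts are drawn as Poisson with rate proportional to
#' `depth * length * concentration`, normalized per sample so expected
#' depth is respected; "on" concentrations are log-normal, "off" states
#' leak at `expr_off_level * leak` (0 by default). Dropout zeroes each
#' count independently with probability `dropout` after the draw.
#'
#' @param n_genes Number of genes (default 2000).
#' @param class_fractions Named fractions over the five gene classes,
#'   summing to 1.
#' @param expr_high_mu,expr_high_sigma Log-normal meanlog/sdlog of "on"
#'   concentrations (defaults `log(50)`, 1).
#' @param expr_off_level Mean leak concentration of "off" states
#'   (default 0).
#' @param depth_per_sample Total mapped reads per sample (default 1e7,
#'   matching typical bulk RNA-seq library sizes).
#' @param dropout Probability a drawn count is zeroed (default 0).
#' @param leak Multiplier on `expr_off_level` (default 1).
#' @param n_proteins Proteome size (default 500).
#' @param protein_class_fractions Named fractions over protein classes
#'   `crp` (true positive by construction), `too_long`, `no_signal` and
#'   `bad_cys` (decoys each violating exactly one CRP property).
#' @param seed Integer RNG seed; identical configurations yield identical
#'   outputs.
#' @return A list of class `synth_config`.
#' @export
synth_config <- function(n_genes = 2000,
                         class_fractions = c(pistil_specific = 0.05,
                                             floral_nonpistil = 0.15,
                                             vegetative = 0.20,
                                             ubiquitous = 0.50,
                                             silent = 0.10),
                         expr_high_mu = log(50), expr_high_sigma = 1,
                         expr_off_level = 0,
                         depth_per_sample = 1e7,
                         dropout = 0, leak = 1,
                         n_proteins = 500,
                         protein_class_fractions = c(crp = 0.25,
                                                     too_long = 0.25,
                                                     no_signal = 0.25,
                                                     bad_cys = 0.25),
                         seed = 1L) {
  cfg <- list(n_genes = as.integer(n_genes),
              class_fractions = class_fractions,
              expr_high_mu = expr_high_mu, expr_high_sigma = expr_high_sigma,
              expr_off_level = expr_off_level,
              depth_per_sample = depth_per_sample,
              dropout = dropout, leak = leak,
              n_proteins = as.integer(n_proteins),
              protein_class_fractions = protein_class_fractions,
              seed = as.integer(seed))
  validate_synth_config(cfg)
  structure(cfg, class = "synth_config")
}

validate_synth_config <- function(cfg) {
  if (cfg$n_genes < 1L) stop("n_genes must be >= 1", call. = FALSE)
  if (cfg$depth_per_sample < 1) stop("depth_per_sample must be >= 1", call. = FALSE)
  if (!setequal(names(cfg$class_fractions), GENE_CLASSES)) {
    stop("class_fractions must name exactly: ",
         paste(GENE_CLASSES, collapse = ", "), call. = FALSE)
  }
  if (abs(sum(cfg$class_fractions) - 1) > 1e-9) {
    stop("class_fractions must sum to 1", call. = FALSE)
  }
  if (abs(sum(cfg$protein_class_fractions) - 1) > 1e-9) {
    stop("protein_class_fractions must sum to 1", call. = FALSE)
  }
  if (cfg$dropout < 0 || cfg$dropout > 1) stop("dropout must be in [0, 1]", call. = FALSE)
  invisible(cfg)
}

#' Read / write a synthetic-data configuration as YAML
#'
#' @param path YAML file path.
#' @return For `synth_config_from_yaml`, a validated [synth_config()].
#' @export
synth_config_from_yaml <- function(path) {
  raw <- yaml::read_yaml(path)
  for (f in c("class_fractions", "protein_class_fractions")) {
    if (!is.null(raw[[f]])) raw[[f]] <- unlist(raw[[f]])
  }
  do.call(synth_config, raw)
}

#' @rdname synth_config_from_yaml
#' @param config A [synth_config()] object.
#' @export
write_synth_config <- function(config, path) {
  yaml::write_yaml(lapply(unclass(config), function(v) as.list(v)), path)
  invisible(config)
}

#' Largest-remainder integer allocation
#'
#' Splits `n` items over fractions deterministically: each class gets
#' `floor(n * f)` and the leftover units go to the largest fractional
#' remainders, ties broken by position.
#'
#' @param n Total count.
#' @param fractions Named fractions summing to 1.
#' @return Named integer vector summing to `n`.
#' @export
largest_remainder <- function(n, fractions) {
  exact <- n * fractions
  base <- floor(exact)
  left <- n - sum(base)
  if (left > 0) {
    rem <- exact - base
    take <- order(-rem, seq_along(rem))[seq_len(left)]
    base[take] <- base[take] + 1
  }
  stats::setNames(as.integer(base), names(fractions))
}

## deterministic per-gene truth shared by all datasets of one config
synth_gene_truth <- function(config) {
  withr::local_seed(config$seed)
  n <- config$n_genes
  counts <- largest_remainder(n, config$class_fractions[GENE_CLASSES])
  class <- rep(names(counts), counts)
  gene_id <- sprintf("gene%05d", seq_len(n))
  length <- pmax(200, round(stats::rlnorm(n, log(1500), 0.4)))
  conc <- stats::rlnorm(n, config$expr_high_mu, config$expr_high_sigma)
  preferred <- rep(NA_character_, n)
  is_ps <- class == "pistil_specific"
  preferred[is_ps] <- sample(CELLTYPES, sum(is_ps), replace = TRUE)
  tibble::tibble(gene_id = gene_id, class = class, length = length,
                 conc = conc, preferred_celltype = preferred)
}

#' Sample design of an emulated dataset
#'
#' @param dataset One of `"inhouse17"`, `"public26"`, `"celltype"`,
#'   `"twotissue"`.
#' @return An annotation tibble (`sample_id`, `tissue`, `stage`, `group`).
#' @export
synth_design <- function(dataset = SYNTH_DATASETS) {
  dataset <- match.arg(dataset)
  switch(dataset,
    inhouse17 = tibble::tibble(
      sample_id = c("pistil_bud2mm", "pistil_bud4mm", "pistil_1dbf",
                    "pistil_0daf", "pistil_5daf", "ovary_7daf",
                    "anther_bud4mm", "anther_1dbf", "anther_0daf",
                    "sepal_0daf", "petal_0daf",
                    "young_leaf", "mature_leaf", "stem", "root",
                    "fruit_mg", "fruit_red"),
      tissue = c(rep("pistil", 5), "ovary", rep("anther", 3), "sepal",
                 "petal", "leaf", "leaf", "stem", "root", "fruit", "fruit"),
      stage = c("bud2mm", "bud4mm", "1dbf", "0daf", "5daf", "7daf",
                "bud4mm", "1dbf", "0daf", "0daf", "0daf",
                "3wk", "mature", "mature", "mature", "33daf", "44daf"),
      group = c(rep("pistil", 6), rep("other_floral", 5),
                rep("vegetative", 4), rep("fruit", 2))
    ),
    public26 = tibble::tibble(
      sample_id = c(paste0("pub_veg", 1:9), paste0("pub_floral", 1:10),
                    paste0("pub_pistil", 1:4), paste0("pub_fruit", 1:3)),
      tissue = c("leaf", "leaf", "root", "root", "stem", "stem",
                 "seedling", "cotyledon", "hypocotyl",
                 rep("flower_bud", 5), rep("flower", 5),
                 rep("ovary", 4), rep("fruit", 3)),
      stage = "mixed",
      group = c(rep("vegetative", 9), rep("other_floral", 10),
                rep("pistil", 4), rep("fruit", 3))
    ),
    celltype = tibble::tibble(
      sample_id = CELLTYPES,
      tissue = CELLTYPES,
      stage = c("0daf", "4daf", "4daf", "4daf", "0daf", "4daf", "4daf"),
      group = paste0("celltype:", CELLTYPES)
    ),
    twotissue = tibble::tibble(
      sample_id = c("mm_ovule", "mm_ovary_wall"),
      tissue = c("ovule", "ovary_wall"),
      stage = "anthesis",
      group = c("celltype:ovule", "celltype:ovary_wall")
    )
  )
}

## on/off concentration of a gene class in a sample group
class_concentration <- function(truth, design, config) {
  off <- config$expr_off_level * config$leak
  conc <- matrix(off, nrow(truth), nrow(design),
                 dimnames = list(truth$gene_id, design$sample_id))
  is_cell <- startsWith(design$group, "celltype:")
  cell_name <- sub("^celltype:", "", design$group)
  for (j in seq_len(nrow(design))) {
    grp <- design$group[j]
    on <- switch_class_on(truth$class, grp, is_cell[j])
    val <- truth$conc
    if (is_cell[j]) {
      ## pistil-specific genes peak in their preferred cell type
      scale <- ifelse(truth$class == "pistil_specific" &
                        !is.na(truth$preferred_celltype) &
                        truth$preferred_celltype != cell_name[j], 0.1, 1)
      val <- val * scale
    }
    conc[on, j] <- val[on]
  }
  conc
}

switch_class_on <- function(class, group, is_celltype) {
  if (is_celltype) {
    class %in% c("pistil_specific", "ubiquitous")
  } else {
    switch(group,
      pistil = class %in% c("pistil_specific", "ubiquitous"),
      other_floral = class %in% c("floral_nonpistil", "ubiquitous"),
      vegetative = class %in% c("vegetative", "ubiquitous"),
      fruit = class == "ubiquitous",
      class == "ubiquitous"
    )
  }
}

#' Generate a synthetic count matrix with ground truth
#'
#' Draws a gene-by-sample count matrix for one emulated dataset. The gene
#' universe (classes, lengths, base concentrations) is derived
#' deterministically from the configuration seed and shared across
#' datasets; the count draw uses a dataset-specific stream, so the same
#' `(config, dataset)` pair is bit-identical across calls.
#'
#' @param config A [synth_config()].
#' @param dataset One of `"inhouse17"`, `"public26"`, `"celltype"`,
#'   `"twotissue"`.
#' @return A list with `counts` (expression-matrix tibble, unit counts),
#'   `lengths` (gene-length tibble), `annotations` (sample design) and
#'   `truth` (per-gene class labels).
#' @export
generate_count_matrix <- function(config, dataset) {
  validate_synth_config(config)
  if (!dataset %in% SYNTH_DATASETS) {
    stop("unknown dataset id `", dataset, "`; use one of: ",
         paste(SYNTH_DATASETS, collapse = ", "), call. = FALSE)
  }
  truth <- synth_gene_truth(config)
  design <- synth_design(dataset)
  offset <- c(inhouse17 = 101L, public26 = 211L, celltype = 307L,
              twotissue = 401L)[[dataset]]
  withr::local_seed(config$seed + offset)

  conc <- class_concentration(truth, design, config)
  weights <- conc * truth$length
  totals <- colSums(weights)
  rate <- sweep(weights, 2L, ifelse(totals > 0, totals, 1), "/") *
    config$depth_per_sample
  rate[, totals <= 0] <- 0
  counts <- matrix(stats::rpois(length(rate), rate), nrow(rate),
                   dimnames = dimnames(rate))
  if (config$dropout > 0) {
    drop <- matrix(stats::runif(length(counts)) < config$dropout, nrow(counts))
    counts[drop] <- 0L
  }
  list(counts = expr_from_values(counts, "counts"),
       lengths = truth[, c("gene_id", "length")],
       annotations = design,
       truth = truth[, c("gene_id", "class", "preferred_celltype")])
}

#' Generate all screen inputs from one configuration
#'
#' Convenience wrapper producing everything [run_screen()] consumes: the
#' in-house count matrix and gene lengths, a combined sample annotation,
#' the public compendium converted to RPKM, the cell-type matrix in RPM,
#' the two-tissue secondary matrix in FPKM, and the planted gene-class
#' truth.
#'
#' @param config A [synth_config()].
#' @return A named list: `counts`, `lengths`, `annotations`, `public_rpkm`,
#'   `celltype_rpm`, `secondary_fpkm`, `truth`.
#' @export
simulate_screen_inputs <- function(config) {
  inhouse <- generate_count_matrix(config, "inhouse17")
  public <- generate_count_matrix(config, "public26")
  celltype <- generate_count_matrix(config, "celltype")
  twotissue <- generate_count_matrix(config, "twotissue")
  list(
    counts = inhouse$counts,
    lengths = inhouse$lengths,
    annotations = dplyr::bind_rows(inhouse$annotations, public$annotations),
    public_rpkm = compute_rpkm(public$counts, public$lengths),
    celltype_rpm = compute_rpm(celltype$counts),
    secondary_fpkm = compute_rpkm(twotissue$counts, twotissue$lengths,
                                  unit = "FPKM"),
    truth = inhouse$truth
  )
}

## ---- synthetic proteome ----------------------------------------------------

AA20 <- names(KD_SCALE)[names(KD_SCALE) != "X"]
BODY_AA <- setdiff(AA20, "C")                 # cysteine-free body alphabet
POLAR_AA <- c("D", "E", "N", "Q", "S", "T", "G", "P")  # no K/R, hydrophilic
HYDRO_AA <- c("L", "I", "V", "F")             # KD >= 2.8

synth_signal <- function() {
  ## charged n-region then 9-residue hydrophobic run: satisfies the
  ## predictor's two clauses by construction (14 residues total)
  paste0("M", sample(c("K", "R"), 1L),
         paste(sample(POLAR_AA, 3L, replace = TRUE), collapse = ""),
         paste(sample(HYDRO_AA, 9L, replace = TRUE), collapse = ""))
}

synth_no_signal <- function() {
  ## first 30 residues hydrophilic and K/R-free: both predictor clauses fail
  paste(sample(POLAR_AA, 30L, replace = TRUE), collapse = "")
}

synth_tail <- function(n_cys, tail_len) {
  tail <- sample(BODY_AA, tail_len, replace = TRUE)
  tail[sort(sample(tail_len, n_cys))] <- "C"
  paste(tail, collapse = "")
}

synth_protein <- function(class) {
  total <- if (class == "too_long") sample(220:500, 1L) else sample(90:180, 1L)
  n_cys <- if (class == "bad_cys") sample(c(2L, 3L, 5L, 7L), 1L) else sample(c(4L, 6L, 8L), 1L)
  head_seq <- if (class == "no_signal") synth_no_signal() else synth_signal()
  tail_len <- max(3L * n_cys, ceiling(0.15 * total))
  body_len <- total - nchar(head_seq) - tail_len
  seq <- paste0(head_seq,
                paste(sample(BODY_AA, body_len, replace = TRUE), collapse = ""),
                synth_tail(n_cys, tail_len))
  list(sequence = seq, length = total, n_cys = n_cys,
       has_signal = class != "no_signal")
}

#' Generate a synthetic proteome with planted CRPs and decoys
#'
#' Builds `config$n_proteins` protein sequences in four planted classes:
#' `crp` (small, signal-bearing, 4/6/8 C-terminal cysteines -- classified
#' as a CRP by construction) and three decoy classes each violating exactly
#' one CRP property: `too_long` (>= 200 aa), `no_signal` (hydrophilic,
#' K/R-free N terminus) and `bad_cys` (2, 3, 5 or 7 cysteines). All
#' cysteines are confined to the C-terminal tail and the rest of each
#' sequence is cysteine-free, so the planted count is exactly what the
#' classifier sees.
#'
#' @param config A [synth_config()].
#' @return A list with `proteins` (tibble `id`, `sequence`, `length`) and
#'   `truth` (tibble `id`, `class`, `length`, `is_small`, `has_signal`,
#'   `n_cterm_cys`, `is_crp`).
#' @export
generate_proteome <- function(config) {
  validate_synth_config(config)
  withr::local_seed(config$seed + 977L)
  counts <- largest_remainder(config$n_proteins,
                              config$protein_class_fractions[PROTEIN_CLASSES])
  class <- rep(names(counts), counts)
  built <- lapply(class, synth_protein)
  id <- sprintf("prot%04d", seq_along(class))
  proteins <- tibble::tibble(
    id = id,
    sequence = vapply(built, `[[`, character(1), "sequence"),
    length = vapply(built, `[[`, integer(1), "length")
  )
  truth <- tibble::tibble(
    id = id,
    class = class,
    length = proteins$length,
    is_small = proteins$length < 200L,
    has_signal = vapply(built, `[[`, logical(1), "has_signal"),
    n_cterm_cys = vapply(built, `[[`, integer(1), "n_cys"),
    is_crp = class == "crp"
  )
  list(proteins = proteins, truth = truth)
}
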