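simple_ann <- tibble::tibble(
  sample_id = c("pistil1", "pistil2", "leaf", "anther"),
  tissue = c("pistil", "pistil", "leaf", "anther"),
  stage = "s",
  group = c("pistil", "pistil", "vegetative", "other_floral")
)

test_that("candidate selection applies strict on/off cutoffs", {
  rpkm <- make_expr(pistil1 = c(0.6, 0.6, 0.5, 0.4),
                    pistil2 = c(0.0, 0.1, 0.0, 0.0),
                    leaf    = c(0.0, 0.6, 0.0, 0.0),
                    anther  = c(0.0, 0.0, 0.0, 0.0),
                    gene_id = c("on_clean", "on_leaky", "boundary", "weak"),
                    unit = "RPKM")
  got <- select_candidates(rpkm, simple_ann)
  # 0.6 in one pistil sample, 0 elsewhere -> selected
  # 0.6 in pistil AND 0.6 in leaf -> rejected
  # exactly 0.5 in best pistil sample -> rejected (strict >)
  expect_identical(got$gene_id, "on_clean")
  expect_identical(got$pistil_sample, "pistil1")
  expect_equal(got$pistil_max, 0.6)
})

test_that("candidate selection requires annotated pistil samples", {
  rpkm <- make_expr(leaf = c(1, 2), anther = c(0, 1), unit = "RPKM")
  expect_error(select_candidates(rpkm, simple_ann), "pistil")
})

test_that("public detection keeps any positive value and drops absent ids", {
  public <- make_expr(s1 = c(0.2, 0), s2 = c(0, 0),
                      gene_id = c("hit", "zero"), unit = "RPKM")
  got <- filter_detected(c("hit", "zero", "missing"), public)
  expect_identical(got$gene_id, "hit")
  expect_identical(got$sample, "s1")
})

test_that("vegetative exclusion is strict and spares absent genes", {
  ann <- tibble::tibble(sample_id = c("root", "leaf", "flower"),
                        tissue = "t", stage = "s",
                        group = c("vegetative", "vegetative", "other_floral"))
  public <- make_expr(root = c(1.2, 0.9, 1.0), leaf = c(0, 0.9, 0.5),
                      flower = c(9, 9, 9),
                      gene_id = c("in_root", "low_veg", "boundary"),
                      unit = "RPKM")
  got <- filter_vegetative(c("in_root", "low_veg", "boundary", "absent"),
                           public, ann)
  # 1.2 in root -> dropped; 0.9 everywhere -> kept; exactly 1.0 -> kept
  expect_setequal(got$gene_id, c("low_veg", "boundary", "absent"))
})

test_that("cell-type filter keeps RPM strictly above the cutoff", {
  rpm <- make_expr(ovule = c(2.5, 1.9, 2.0), embryo = c(0, 0, 0),
                   gene_id = c("hi", "lo", "edge"), unit = "RPM")
  got <- filter_celltype(c("hi", "lo", "edge"), rpm)
  expect_identical(got$gene_id, "hi")
})

test_that("gene id version suffixes are stripped when joining datasets", {
  public <- make_expr(s1 = c(5, 5), gene_id = c("gA.2", "gB.1"), unit = "RPKM")
  got <- filter_detected(c("gA", "gC"), public)
  expect_identical(got$gene_id, "gA")
  strict <- filter_detected(c("gA", "gC"), public, strip_versions = FALSE)
  expect_identical(nrow(strict), 0L)
  expect_identical(strip_gene_version("Solyc01g007270.2.1"), "Solyc01g007270")
})

test_that("every cascade stage equals its double-loop reference on random instances", {
  withr::local_seed(301)
  inst <- random_screen_instance(200)
  th <- screen_thresholds()
  rpkm <- compute_rpkm(inst$counts, inst$lengths)
  cand <- select_candidates(rpkm, inst$ann, th)
  expect_setequal(cand$gene_id, oracle_candidates(rpkm, inst$ann))
  det <- filter_detected(cand, inst$public, floor = th$public_detect)
  expect_setequal(det$gene_id, oracle_detected(cand$gene_id, inst$public))
  flo <- filter_vegetative(det, inst$public, inst$ann, th)
  expect_setequal(flo$gene_id,
                  oracle_vegetative(det$gene_id, inst$public, inst$ann))
  pe <- filter_celltype(cand, inst$celltype, th)
  expect_setequal(pe$gene_id, oracle_celltype(cand$gene_id, inst$celltype))
})

test_that("noiseless synthetic data is recovered exactly by the full screen", {
  cfg <- synth_config(n_genes = 400, seed = 5)
  sim <- simulate_screen_inputs(cfg)
  res <- run_screen(sim$counts, sim$lengths, sim$annotations, sim$public_rpkm,
                    sim$celltype_rpm, sim$secondary_fpkm)
  planted <- sim$truth$gene_id[sim$truth$class == "pistil_specific"]
  expect_setequal(res$stage_sets$psg, planted)
  expect_true(all(res$psg$secondary_detected))
  # nested stage structure
  s <- res$stage_sets
  expect_true(all(s$psg %in% s$floral_specific))
  expect_true(all(s$floral_specific %in% s$detected_public))
  expect_true(all(s$detected_public %in% s$candidates))
  expect_true(all(s$pistil_expressed %in% s$candidates))
  # counts equal set sizes and are monotone along the main branch
  expect_equal(res$stage_counts$n, lengths(s), ignore_attr = TRUE)
  main <- res$stage_counts$n[1:3]
  expect_true(all(diff(main) <= 0))
})

test_that("public-matrix dropout can only lose true positives, never add false ones", {
  cfg_clean <- synth_config(n_genes = 400, seed = 9)
  cfg_drop <- synth_config(n_genes = 400, seed = 9, dropout = 0.3)
  sim <- simulate_screen_inputs(cfg_clean)
  noisy_public <- simulate_screen_inputs(cfg_drop)$public_rpkm
  res <- run_screen(sim$counts, sim$lengths, sim$annotations, noisy_public,
                    sim$celltype_rpm, thresholds = screen_thresholds())
  planted <- sim$truth$gene_id[sim$truth$class == "pistil_specific"]
  psg <- res$stage_sets$psg
  expect_true(all(psg %in% planted))            # precision 1
  expect_lte(length(psg), length(planted))      # recall <= 1
})

test_that("nestedness and threshold monotonicity hold on fuzzed instances", {
  withr::local_seed(302)
  for (rep in 1:25) {
    inst <- random_screen_instance(30)
    res <- run_screen(inst$counts, inst$lengths, inst$ann, inst$public,
                      inst$celltype)
    s <- res$stage_sets
    expect_true(all(s$psg %in% s$floral_specific))
    expect_true(all(s$floral_specific %in% s$detected_public))
    expect_true(all(s$detected_public %in% s$candidates))
    expect_true(all(s$pistil_expressed %in% s$candidates))
    expect_setequal(s$psg, intersect(s$floral_specific, s$pistil_expressed))

    rpkm <- compute_rpkm(inst$counts, inst$lengths)
    loose <- select_candidates(rpkm, inst$ann,
                               screen_thresholds(candidate_off = 2))$gene_id
    tight <- select_candidates(rpkm, inst$ann,
                               screen_thresholds(candidate_off = 0.5))$gene_id
    expect_true(all(tight %in% loose))

    det <- filter_detected(s$candidates, inst$public)
    v_loose <- filter_vegetative(det, inst$public, inst$ann,
                                 screen_thresholds(veg_exclude = 2))$gene_id
    v_tight <- filter_vegetative(det, inst$public, inst$ann,
                                 screen_thresholds(veg_exclude = 0.5))$gene_id
    expect_true(all(v_tight %in% v_loose))

    c_loose <- filter_celltype(s$candidates, inst$celltype,
                               screen_thresholds(celltype_min = 1))$gene_id
    c_tight <- filter_celltype(s$candidates, inst$celltype,
                               screen_thresholds(celltype_min = 4))$gene_id
    expect_true(all(c_tight %in% c_loose))
  }
})

test_that("cell-type preference is the argmax group with documented tie and zero rules", {
  rpm <- make_expr(ovule = c(50, 0, 3), embryo = c(1, 0, 3),
                   gene_id = c("ov", "zero", "tie"), unit = "RPM")
  got <- classify_celltype_preference(c("ov", "zero", "tie", "absent"), rpm)
  expect_identical(got$celltype,
                   c("ovule", "unclassified", "ovule", "unclassified"))

  # planted preference recovered from synthetic cell-type data
  cfg <- synth_config(n_genes = 300, seed = 21)
  ct <- generate_count_matrix(cfg, "celltype")
  rpm_ct <- compute_rpm(ct$counts)
  planted <- ct$truth[ct$truth$class == "pistil_specific", ]
  pref <- classify_celltype_preference(planted$gene_id, rpm_ct)
  expect_identical(pref$celltype, planted$preferred_celltype)
})

test_that("top-gene ranking is descending with lexicographic ties", {
  m <- make_expr(s1 = c(5, 9, 5, 1), gene_id = c("gB", "gC", "gA", "gD"),
                 unit = "RPM")
  got <- rank_top_genes(m, "s1", k = 3)
  expect_identical(got$gene_id, c("gC", "gA", "gB"))
  expect_identical(nrow(rank_top_genes(m, "s1", k = 99)), 4L)
  expect_error(rank_top_genes(m, "nope"), "nope")
})

test_that("PCA variance fractions behave as the covariance eigenstructure dictates", {
  # rank-1 matrix: all variation on PC1
  rank1 <- make_expr(a = c(1, 2), b = c(2, 4), c = c(3, 6), unit = "normlog2")
  p1 <- pca_qc(rank1)
  expect_equal(p1$variance_fraction[1], 1)
  expect_equal(sum(p1$variance_fraction), 1)

  # two uncorrelated genes with variances 4/3 and 16/3 -> fractions 0.8 / 0.2
  # (rows are centered internally, so the +2/+3 shifts keeping values
  # non-negative do not change the covariance)
  blocks <- make_expr(s1 = c(3, 5), s2 = c(1, 5), s3 = c(3, 1), s4 = c(1, 1),
                      unit = "normlog2")
  p2 <- pca_qc(blocks)
  expect_equal(p2$variance_fraction[1:2], c(0.8, 0.2))
  expect_error(pca_qc(make_expr(a = c(1, 2), unit = "normlog2")), "two samples")
})

test_that("DEG-list intersection matches a membership loop and keeps order", {
  expect_identical(intersect_with_deg_list(c("a", "b"), c("c", "d")), character(0))
  expect_identical(intersect_with_deg_list(c("b", "a"), c("a", "b", "z")),
                   c("b", "a"))
  withr::local_seed(303)
  for (rep in 1:10) {
    x <- sample(sprintf("g%02d", 1:30), 10)
    y <- sample(sprintf("g%02d", 1:30), 12)
    loop <- x[vapply(x, function(g) any(g == y), logical(1))]
    expect_identical(intersect_with_deg_list(x, y, strip_versions = FALSE), loop)
  }
  expect_identical(intersect_with_deg_list("gA.2", "gA"), "gA.2")
})

test_that("tidy and glance expose trace and stage counts", {
  cfg <- synth_config(n_genes = 200, seed = 31)
  sim <- simulate_screen_inputs(cfg)
  res <- run_screen(sim$counts, sim$lengths, sim$annotations, sim$public_rpkm,
                    sim$celltype_rpm)
  tr <- tidy(res)
  expect_true(all(c("gene_id", "stage", "pass", "sample", "value") %in% names(tr)))
  expect_identical(sum(tr$stage == "candidate"), nrow(sim$counts))
  gl <- glance(res)
  expect_identical(nrow(gl), 1L)
  expect_identical(gl$psg, length(res$stage_sets$psg))
  expect_s3_class(ggplot2::autoplot(res), "ggplot")
})
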