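test_that("generation is deterministic and independent of call order", {
  cfg <- synth_config(n_tissues = 2, samples_per_tissue = 30, n_genes = 120,
                      seed = 7)
  a <- generate_tissue_study(cfg, 1)
  b <- generate_cancer_dataset(cfg, 1, 2)   # interleave another stream
  a2 <- generate_tissue_study(cfg, 1)
  b2 <- generate_cancer_dataset(cfg, 1, 2)
  expect_identical(a$exprs, a2$exprs)
  expect_identical(a$samples, a2$samples)
  expect_identical(b$exprs, b2$exprs)
  expect_identical(generate_annotations(cfg), generate_annotations(cfg))
  expect_identical(generate_lifespan_assay(cfg), generate_lifespan_assay(cfg))
  # different tissue index gives different data
  expect_false(identical(a$exprs, generate_tissue_study(cfg, 2)$exprs))
})

test_that("planted age-gene truth has the configured count, signs and slopes", {
  cfg <- synth_config(frac_age_associated = 0.2, n_genes = 500,
                      frac_age_down = 0.6, age_effect_size = 0.35, seed = 3)
  st <- generate_tissue_study(cfg, 1)
  truth <- st$truth$age_genes
  expect_equal(nrow(truth), 100)  # round(0.2 * 500)
  expect_equal(sum(truth$direction == "down"), 60)
  expect_true(all(abs(truth$slope_per_year) == 0.35 / 10))
  expect_true(all(truth$gene_id %in% rownames(st$exprs)))

  # degenerate fraction: no gene has a nonzero planted slope
  cfg0 <- synth_config(frac_age_associated = 0, n_genes = 200, seed = 3)
  expect_equal(nrow(generate_tissue_study(cfg0, 1)$truth$age_genes), 0)
})

test_that("cancer datasets share the planted DE set within a cancer", {
  cfg <- synth_config(n_genes = 1000, frac_de_genes = 0.1, seed = 11)
  d1 <- generate_cancer_dataset(cfg, 1, 1)
  d2 <- generate_cancer_dataset(cfg, 1, 2)
  d3 <- generate_cancer_dataset(cfg, 1, 3)
  expect_equal(nrow(d1$truth$de_genes), 100)
  expect_identical(d1$truth$de_genes, d2$truth$de_genes)
  expect_identical(d2$truth$de_genes, d3$truth$de_genes)
  # a different cancer plants a different set
  expect_false(identical(d1$truth$de_genes,
                         generate_cancer_dataset(cfg, 2, 1)$truth$de_genes))
})

test_that("null configuration leaves the two arms exchangeable", {
  cfg <- synth_config(frac_de_genes = 0, de_logfc_mean = 0,
                      frac_pathways_planted_up = 0,
                      frac_pathways_planted_down = 0,
                      n_genes = 300, seed = 5)
  d <- generate_cancer_dataset(cfg, 1, 1)
  expect_equal(nrow(d$truth$de_genes), 0)
  case_mean <- rowMeans(d$exprs[, d$samples$condition == "case"])
  ctrl_mean <- rowMeans(d$exprs[, d$samples$condition == "control"])
  # no planted shift: mean difference is pure noise
  expect_lt(abs(mean(case_mean - ctrl_mean)), 0.05)
})

test_that("pathway collection satisfies its structural invariants", {
  cfg <- synth_config(n_pathways = 40, n_processes = 27,
                      genes_per_pathway = 15, n_genes = 300, seed = 2)
  pc <- generate_pathway_collection(cfg)
  expect_length(pc$sets, 40)
  expect_equal(length(unique(unname(pc$process))), 27)
  expect_true(all(lengths(pc$sets) == 15))
  expect_true(all(unlist(pc$sets) %in% sprintf("G%05d", 1:300)))
  expect_true(all(vapply(pc$sets, anyDuplicated, integer(1)) == 0))
  expect_error(synth_config(genes_per_pathway = 500, n_genes = 300),
               "genes_per_pathway")
  expect_error(synth_config(n_processes = 50, n_pathways = 40),
               "n_processes")
})

test_that("annotations carry valid rank lists, hallmark map and ledger", {
  cfg <- synth_config(n_genes = 400, n_cancers = 3, seed = 13)
  ann <- generate_annotations(cfg)
  expect_length(ann$hallmark_keywords, 12)
  by_list <- split(ann$rank_lists, ann$rank_lists[c("setting", "cancer")])
  for (d in by_list) {
    expect_equal(sort(d$rank), 1:100)
    expect_equal(anyDuplicated(d$gene_id), 0)
  }
  expect_true(all(ann$ledger$lifespan_effect %in%
                    c("extends", "shortens", "no_effect", "none")))
  expect_true(all(ann$ledger$evidence_models[
    ann$ledger$lifespan_effect == "none"] == ""))
  expect_true(all(ann$tsg %in% sprintf("G%05d", 1:400)))
})

test_that("lifespan assay matches the configured design and planted shift", {
  cfg <- synth_config(worms_per_group = 90, n_repeats = 3,
                      lifespan_control_median = 19,
                      lifespan_shift_percent = 15.8, seed = 21)
  assay <- generate_lifespan_assay(cfg)
  expect_equal(sum(assay$arm == "control"), 270)
  expect_equal(sum(assay$arm == "treatment"), 270)
  expect_true(all(assay$day > 0))

  # zero shift: both arms from the identical law
  cfg0 <- synth_config(lifespan_shift_percent = 0, worms_per_group = 2000,
                       n_repeats = 1, seed = 9)
  a0 <- generate_lifespan_assay(cfg0)
  m <- tapply(a0$day, a0$arm, median)
  expect_equal(unname(m["control"]), unname(m["treatment"]), tolerance = 0.06)

  # large-n Monte Carlo: empirical median ratio within 2% of 1.158
  cfgL <- synth_config(worms_per_group = 10000, n_repeats = 1,
                       lifespan_control_median = 19,
                       lifespan_shift_percent = 15.8, seed = 33)
  aL <- generate_lifespan_assay(cfgL)
  mL <- tapply(aL$day, aL$arm, median)
  expect_equal(unname(mL["treatment"] / mL["control"]), 1.158,
               tolerance = 0.02)
  expect_error(synth_config(lifespan_shift_percent = -120), "-100")
})

test_that("gompertz sampler matches flexsurv's parameterization", {
  skip_if_not_installed("flexsurv")
  shape <- 0.45
  rate <- dualtarget:::gompertz_rate_for_median(18.5, shape)
  set.seed(1)
  mine <- dualtarget:::rgompertz_inv(50000, shape, rate)
  set.seed(1)
  ref <- flexsurv::rgompertz(50000, shape = shape, rate = rate)
  expect_equal(quantile(mine, c(.1, .25, .5, .75, .9)),
               quantile(ref, c(.1, .25, .5, .75, .9)), tolerance = 0.01)
  expect_equal(median(mine), 18.5, tolerance = 0.01)
})

test_that("expression studies round-trip through TSV and GMT files", {
  cfg <- synth_config(n_tissues = 1, samples_per_tissue = 12, n_genes = 40,
                      seed = 4)
  st <- generate_tissue_study(cfg, 1)
  mp <- tempfile(fileext = ".tsv"); sp <- tempfile(fileext = ".tsv")
  write_expression_tsv(st, mp, sp)
  back <- read_expression_tsv(mp, sp)
  expect_equal(unname(back$exprs), unname(st$exprs), tolerance = 1e-9)
  expect_equal(back$samples$age, st$samples$age)

  pc <- generate_pathway_collection(cfg)
  gp <- tempfile(fileext = ".gmt")
  write_gmt(pc$sets, gp)
  expect_equal(read_gmt(gp)[names(pc$sets)], pc$sets,
               ignore_attr = TRUE)
})
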