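test_that("pathway score is the scaled significance-gated weighted mean", {
  de <- data.frame(gene_id = c("g1", "g2", "g3"),
                   logfc = c(1.0, -0.5, 0.2),
                   p_value = c(0.01, 0.01, 0.01))
  res <- pathway_activation_score(de, c("g1", "g2", "g3"))
  expect_equal(res$score, 0.1 * (0.7 / 3), tolerance = 1e-12)
  expect_equal(res$status, "activated")

  # zero fold changes: zero score, status none
  de0 <- transform(de, logfc = 0)
  expect_equal(pathway_activation_score(de0, c("g1", "g2"))$score, 0)
  expect_equal(pathway_activation_score(de0, c("g1", "g2"))$status, "none")

  # all positive and significant: positive score
  dep <- data.frame(gene_id = c("g1", "g2"), logfc = c(2, 1),
                    p_value = c(0.001, 0.001))
  expect_gt(pathway_activation_score(dep, c("g1", "g2"))$score, 0)

  # non-significant genes are down-weighted by s_relax
  demix <- data.frame(gene_id = c("g1", "g2"), logfc = c(1, 1),
                      p_value = c(0.01, 0.5))
  expect_equal(pathway_activation_score(demix, c("g1", "g2"))$score,
               0.1 * (1 + 0.1) / 2, tolerance = 1e-12)

  # missing genes ignored; no measured gene -> undefined
  expect_equal(pathway_activation_score(de, c("g1", "zzz"))$n_genes_scored, 1)
  expect_equal(pathway_activation_score(de, c("x", "y"))$status, "undefined")

  # coexpression-module members collapse to their module mean first
  dem <- data.frame(gene_id = c("g1", "g2", "g3"),
                    logfc = c(1, 1, -2), p_value = rep(0.01, 3))
  res_m <- pathway_activation_score(
    dem, list(genes = c("g1", "g2", "g3"),
              modules = c(g1 = "m1", g2 = "m1", g3 = "m2")))
  expect_equal(res_m$score, 0.1 * (1 + (-2)) / 2, tolerance = 1e-12)
})

test_that("consensus applies the unidirectional >= 50% and mean-score rules", {
  up <- consensus_direction(c(0.02, 0.03, -0.005))
  expect_equal(up$final_status, "activated")
  expect_equal(up$mean_score, 0.025)
  expect_equal(c(up$n_up, up$n_down), c(2, 0))

  # single dataset below the threshold
  expect_equal(consensus_direction(0.005)$final_status, "none")

  # exact 50/50 split is unidirectional for neither direction
  tie <- consensus_direction(c(0.02, -0.02))
  expect_equal(tie$final_status, "none")
  expect_true(is.na(tie$mean_score))

  # the mean is taken over the majority-direction extracted scores only,
  # so a large opposite-direction score cannot drag the call down
  maj <- consensus_direction(c(0.02, 0.04, -0.9))
  expect_equal(maj$final_status, "activated")
  expect_equal(maj$mean_score, 0.03)

  # permutation invariance over dataset order
  set.seed(8)
  sc <- rnorm(9, 0, 0.03)
  ref <- consensus_direction(sc)
  for (i in 1:5) {
    perm <- consensus_direction(sample(sc))
    expect_equal(perm$final_status, ref$final_status)
    expect_equal(perm$mean_score, ref$mean_score)
  }
})

test_that("process summary reports percentages over total pathway counts", {
  cfg <- synth_config(n_pathways = 30, n_processes = 3, genes_per_pathway = 5,
                      n_genes = 200, seed = 6)
  pc <- generate_pathway_collection(cfg)
  proc1 <- names(pc$process)[pc$process == "process_01"]
  calls <- data.frame(pathway_id = proc1,
                      final_status = rep(c("activated", "none"),
                                         length.out = length(proc1)))
  ps <- process_summary(calls, pc)
  row1 <- ps[ps$process_name == "process_01", ]
  expect_equal(row1$percent_up,
               100 * ceiling(length(proc1) / 2) / length(proc1))
  expect_equal(row1$percent_down, 0)
  expect_true(all(ps$percent_up + ps$percent_down <= 100))
  # processes without any call report zero
  expect_equal(ps$percent_up[ps$process_name == "process_02"], 0)
  expect_error(process_summary(data.frame(pathway_id = "bogus",
                                          final_status = "activated"), pc),
               "unknown pathway")
})

test_that("cross-classification assigns the four aging x cancer categories", {
  cfg <- synth_config(n_pathways = 10, n_processes = 2, genes_per_pathway = 5,
                      n_genes = 100, seed = 9)
  pc <- generate_pathway_collection(cfg)
  ids <- names(pc$sets)
  aging <- data.frame(pathway_id = ids,
                      final_status = c("inhibited", "activated", "none",
                                       "inhibited", "activated", "inhibited",
                                       "none", "activated", "inhibited",
                                       "activated"))
  cancer <- data.frame(pathway_id = ids,
                       final_status = c("activated", "activated", "activated",
                                        "inhibited", "inhibited", "none",
                                        "none", "activated", "activated",
                                        "inhibited"))
  x <- cross_classify(aging, cancer, pc)
  get <- function(pid, cat) {
    pr <- unname(pc$process[pid])
    x$n_pathways[x$process_name == pr & x$category == cat]
  }
  # pathway 1: up in cancer, down in aging -> category 3
  expect_equal(sum(x$n_pathways[x$category == "up_cancer_down_aging"]), 2)
  expect_equal(sum(x$n_pathways[x$category == "up_both"]), 2)
  expect_equal(sum(x$n_pathways[x$category == "down_both"]), 1)
  expect_equal(sum(x$n_pathways[x$category == "down_cancer_up_aging"]), 2)
  # pathways with "none" in either comparison are not overlapped
  expect_equal(sum(x$n_pathways), 7)

  # empty overlap: all percentages zero
  none <- data.frame(pathway_id = ids, final_status = "none")
  x0 <- cross_classify(none, cancer, pc)
  expect_true(all(x0$n_pathways == 0))
  expect_true(all(x0$percent_of_process == 0))
  expect_true(all(x0$percent_of_overlap == 0))
})

test_that("planted pathway directions are recovered through the full chain", {
  cfg <- synth_config(n_genes = 1500, n_pathways = 60, genes_per_pathway = 15,
                      n_processes = 10, n_cancers = 1, datasets_per_cancer = 4,
                      frac_de_genes = 0.05, seed = 23)
  datasets <- lapply(1:4, function(d) generate_cancer_dataset(cfg, 1, d))
  truth <- datasets[[1]]$truth$pathway_directions
  collection <- generate_pathway_collection(cfg)
  scores <- do.call(rbind, lapply(seq_along(datasets), function(d) {
    de <- de_case_control(datasets[[d]])
    sc <- score_pathways(de, collection)
    sc$dataset_id <- d
    sc[, c("pathway_id", "dataset_id", "score")]
  }))
  cons <- consensus_calls(scores, group = "cancer01")
  called <- setNames(cons$final_status, cons$pathway_id)
  expected <- ifelse(truth$direction == "up", "activated", "inhibited")
  agree <- called[truth$pathway_id] == expected
  expect_gte(mean(agree), 0.95)
})
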