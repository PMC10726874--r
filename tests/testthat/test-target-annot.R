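hm12 <- aging_hallmark_keywords()

test_that("hallmark mapping is case-insensitive substring on term names", {
  go <- data.frame(
    gene_id = c("a", "a", "b", "c"),
    term_name = c("positive regulation of DNA repair",
                  "telomere maintenance",
                  "generic process", "Cellular SENESCENCE program"))
  hm <- map_hallmarks(go, hm12)
  a <- hm[hm$gene_id == "a", ]
  expect_true(all(c("genomic_instability", "telomere_attrition") %in%
                    a$hallmarks[[1]]))
  expect_equal(hm$n_hallmarks[hm$gene_id == "b"], 0L)
  expect_equal(hm$hallmarks[hm$gene_id == "c"][[1]], "cellular_senescence")

  # a gene whose terms hit keywords of all 12 hallmarks reaches the maximum
  allkw <- vapply(hm12, `[`, character(1), 1)
  go_all <- data.frame(gene_id = "mega", term_name = paste("role in", allkw))
  expect_equal(map_hallmarks(go_all, hm12)$n_hallmarks, 12L)

  # unannotated genes get zero hallmarks with a warning
  expect_warning(out <- map_hallmarks(go, hm12, genes = c("a", "zzz")),
                 "no GO annotation")
  expect_equal(out$n_hallmarks[out$gene_id == "zzz"], 0L)
  expect_error(map_hallmarks(go, hm12[1:5]), "12")
})

test_that("age-association filter applies the strict >10% and hallmark rules", {
  calls <- do.call(rbind, lapply(1:47, function(t) data.frame(
    gene_id = c("five", "four", "six_nohm"),
    tissue = sprintf("t%02d", t),
    is_age_associated = c(t <= 5, t <= 4, t <= 6),
    direction = "down")))
  hm <- data.frame(gene_id = c("five", "four", "six_nohm"),
                   n_hallmarks = c(2L, 2L, 0L))
  targets <- data.frame(gene_id = c("five", "four", "six_nohm"))
  out <- filter_age_associated_targets(targets, calls, hm, tissue_count = 47)
  expect_equal(out$gene_id, "five")             # 5 > 4.7 kept
  expect_equal(out$n_tissues_age_associated, 5L)
  expect_false("four" %in% out$gene_id)         # 4 <= 4.7 dropped
  expect_false("six_nohm" %in% out$gene_id)     # no hallmark dropped
  # threshold is the smallest integer strictly above min_frac * tissue_count:
  # with 40 tissues the bound is >4, so a 4-tissue gene still fails ...
  out40 <- filter_age_associated_targets(targets, calls, hm, tissue_count = 40)
  expect_equal(out40$gene_id, "five")
  # ... while with 30 tissues (>3) it passes
  out30 <- filter_age_associated_targets(targets, calls, hm, tissue_count = 30)
  expect_equal(sort(out30$gene_id), c("five", "four"))
})

test_that("therapeutic direction follows the significant expression majority", {
  meta <- data.frame(gene_id = "g", cancer = sprintf("c%02d", 1:11),
                     combined_logfc = c(rep(1, 8), rep(-1, 3)),
                     fdr = c(rep(0.01, 8), rep(0.01, 3)))
  expect_equal(propose_direction(meta)$cancer_direction, "antagonism")

  meta_dn <- transform(meta, combined_logfc = -combined_logfc)
  expect_equal(propose_direction(meta_dn)$cancer_direction, "agonism")

  # override wins regardless of expression (the VDR-style case)
  ov <- data.frame(gene_id = "g", direction = "agonism")
  res_ov <- propose_direction(meta, overrides = ov)
  expect_equal(res_ov$cancer_direction, "agonism")
  expect_equal(res_ov$basis, "override")

  # exact tie without override: unknown and flagged
  tie <- data.frame(gene_id = "g", combined_logfc = c(1, -1),
                    fdr = c(0.01, 0.01))
  res_tie <- propose_direction(tie)
  expect_true(is.na(res_tie$cancer_direction))
  expect_true(res_tie$flagged)

  # non-significant cancers do not count
  ns <- data.frame(gene_id = "g", combined_logfc = c(1, 1, -2),
                   fdr = c(0.2, 0.2, 0.01))
  expect_equal(propose_direction(ns)$cancer_direction, "agonism")
})

test_that("group classification implements the four evidence rules", {
  ledger <- data.frame(
    gene_id = c("ext_same", "ext_opp", "short", "none", "noeff"),
    lifespan_effect = c("extends", "extends", "shortens", "none", "no_effect"),
    aging_direction = c("antagonism", "antagonism", "unknown", "unknown",
                        "unknown"))
  dirs <- data.frame(gene_id = ledger$gene_id,
                     cancer_direction = c("antagonism", "agonism",
                                          "antagonism", "antagonism",
                                          "antagonism"))
  targets <- data.frame(gene_id = ledger$gene_id)
  asg <- classify_groups(targets, ledger, dirs, tsg_ids = "ext_same")
  expect_equal(setNames(asg$group, asg$gene_id),
               c(ext_same = 1L, ext_opp = 2L, short = 3L, none = 4L,
                 noeff = 4L))
  # groups partition the targets
  expect_equal(sum(table(asg$group)), nrow(targets))
  # dual-purpose requires group 1 AND not TSG
  expect_false(asg$is_dual_purpose[asg$gene_id == "ext_same"])

  # contradictory multi-row evidence resolves to extension with a warning
  ledger2 <- rbind(ledger,
                   data.frame(gene_id = "ext_same",
                              lifespan_effect = "shortens",
                              aging_direction = "unknown"))
  expect_warning(asg2 <- classify_groups(targets, ledger2, dirs),
                 "extension retained")
  expect_equal(asg2$group[asg2$gene_id == "ext_same"], 1L)

  # classification is a pure function of its inputs
  expect_identical(classify_groups(targets, ledger, dirs),
                   classify_groups(targets, ledger, dirs))
  expect_error(classify_groups(data.frame(gene_id = "missing"), ledger, dirs),
               "missing from the evidence ledger")
})

test_that("dual-purpose proposal excludes TSGs and orders by tissue count", {
  g1 <- data.frame(gene_id = c("b_tsg", "a", "c", "d"),
                   n_tissues_dysregulated = c(30, 10, 20, 10))
  out <- propose_dual_purpose(g1, tsg_ids = "b_tsg")
  expect_equal(out$gene_id, c("c", "a", "d"))  # ties broken alphabetically

  # empty TSG list is the identity (up to ordering)
  expect_equal(sort(propose_dual_purpose(g1)$gene_id), sort(g1$gene_id))

  # all group-1 genes TSGs: empty with a warning
  expect_warning(none <- propose_dual_purpose(g1, tsg_ids = g1$gene_id),
                 "every Group-1")
  expect_equal(nrow(none), 0)
})
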