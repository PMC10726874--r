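test_that("partial correlation matches its algebra on designed cases", {
  # expression identical to age: partial correlation collapses to 1
  r1 <- partial_pearson(age = c(1, 2, 3, 4), expr = c(1, 2, 3, 4),
                        sex = c(0, 1, 0, 1))
  expect_equal(r1$r_partial, 1)
  expect_equal(r1$p_value, 0)

  # expression orthogonal to both age and sex on a balanced design
  r0 <- partial_pearson(age = c(1, 2, 3, 4), expr = c(1, -1, -1, 1),
                        sex = c(0, 0, 1, 1))
  expect_equal(r0$r_partial, 0)
  expect_equal(r0$p_value, 1)

  # constant sex leaves the plain Pearson correlation
  set.seed(1)
  a <- rnorm(20); e <- rnorm(20)
  rc <- partial_pearson(a, e, rep(0, 20))
  expect_equal(rc$r_partial, cor(a, e))

  expect_error(partial_pearson(c(1, 1, 1, 1), rnorm(4), c(0, 1, 0, 1)),
               "constant")
  expect_error(partial_pearson(rnorm(4), rep(2, 4), c(0, 1, 0, 1)),
               "constant")
  expect_error(partial_pearson(c(1, 2, 3, 4), rnorm(4), c(1, 2, 3, 4)),
               "degenerate")
})

test_that("partial correlation equals the residual-regression oracle", {
  set.seed(11)
  for (i in 1:200) {
    n <- 20
    age <- rnorm(n); expr <- rnorm(n); sex <- rbinom(n, 1, 0.5)
    if (sd(sex) == 0) next
    expect_equal(partial_pearson(age, expr, sex)$r_partial,
                 oracle_partial_residual(age, expr, sex),
                 tolerance = 1e-10)
  }
  # and the vectorized path agrees with the scalar one
  Y <- matrix(rnorm(30 * 25), nrow = 30,
              dimnames = list(sprintf("g%02d", 1:30), NULL))
  age <- runif(25, 20, 79); sex <- rbinom(25, 1, 0.5)
  vec <- dualtarget:::partial_pearson_matrix(Y, age, sex)
  for (g in c(1, 15, 30)) {
    sc <- partial_pearson(age, Y[g, ], sex)
    expect_equal(vec$r_partial[g], sc$r_partial, tolerance = 1e-12)
    expect_equal(vec$p_value[g], sc$p_value, tolerance = 1e-12)
  }
})

test_that("old/young fit reproduces the OLS coefficients and handles edges", {
  # 6-sample worked design: young (1,2,3), old (3,4,5), sex balanced
  m <- matrix(c(1, 2, 3, 3, 4, 5), nrow = 1)
  st <- make_study(rbind(m, m + 1), age = c(30, 35, 40, 65, 70, 75),
                   sex = c(0, 1, 0, 1, 0, 1))
  de <- de_old_young(st)
  old <- c(0, 0, 0, 1, 1, 1); sx <- st$samples$sex
  ols <- lm(m[1, ] ~ old + sx)
  expect_equal(de$logfc[1], unname(coef(ols)["old"]), tolerance = 1e-10)

  # gene constant in all samples: zero effect, p = 1
  cst <- make_study(rbind(g1 = rep(4, 6), g2 = c(1, 2, 3, 3, 4, 5)),
                    age = c(30, 35, 40, 65, 70, 75),
                    sex = c(0, 1, 0, 1, 0, 1))
  dc <- de_old_young(cst)
  expect_equal(dc$logfc[dc$gene_id == "g1"], 0)
  expect_equal(dc$p_value[dc$gene_id == "g1"], 1)

  # mid-aged samples are excluded from the contrast
  st_mid <- make_study(matrix(rnorm(2 * 8), nrow = 2),
                       age = c(30, 35, 52, 55, 58, 65, 70, 75),
                       sex = c(0, 1, 0, 1, 0, 1, 0, 1))
  d_mid <- de_old_young(st_mid)
  expect_equal(attr(d_mid, "n_old") + attr(d_mid, "n_young"), 5)

  expect_error(de_old_young(make_study(matrix(rnorm(8), 2),
                                       age = c(20, 25, 30, 40),
                                       sex = c(0, 1, 0, 1))),
               "stratum")
})

test_that("moderated t reduces to ordinary OLS t at zero prior df", {
  set.seed(5)
  n <- 40
  age <- c(runif(20, 20, 49), runif(20, 60, 79))
  sex <- rbinom(n, 1, 0.5)
  Y <- matrix(rnorm(150 * n), nrow = 150,
              dimnames = list(sprintf("g%03d", 1:150), NULL))
  st <- make_study(Y, age = age, sex = sex)
  de0 <- de_old_young(st, prior_df = 0)
  old <- as.numeric(age >= 60)
  for (g in seq(1, 150, by = 10)) {
    fit <- summary(lm(Y[g, ] ~ old + sex))
    expect_equal(de0$moderated_t[g], fit$coefficients["old", "t value"],
                 tolerance = 1e-8)
    expect_equal(de0$p_value[g], fit$coefficients["old", "Pr(>|t|)"],
                 tolerance = 1e-8)
  }
  # moderation increases the effective degrees of freedom
  de_eb <- de_old_young(st)
  expect_true(all(de_eb$moderated_df >= n - 3))
})

test_that("dual-criterion calls require both p-values below alpha", {
  pc <- data.frame(gene_id = c("a", "b", "c"),
                   r_partial = c(.5, .4, -.6),
                   p_value = c(0.04, 0.01, 0.01))
  de <- data.frame(gene_id = c("a", "b", "c"),
                   logfc = c(1, 2, -1),
                   p_value = c(0.06, 0.01, 0.01))
  calls <- call_age_associated(pc, de)
  expect_equal(calls$is_age_associated, c(FALSE, TRUE, TRUE))
  expect_equal(calls$direction[calls$gene_id == "c"], "down")
  expect_equal(calls$direction[calls$gene_id == "b"], "up")
  expect_error(call_age_associated(pc[1:2, ], de), "gene sets differ")
})

test_that("each criterion alone rejects at the nominal rate under the null", {
  cfg <- synth_config(n_tissues = 1, samples_per_tissue = 150, n_genes = 2000,
                      frac_age_associated = 0, frac_pathways_planted_up = 0,
                      frac_pathways_planted_down = 0, seed = 17)
  st <- generate_tissue_study(cfg, 1)
  pc <- dualtarget:::partial_pearson_matrix(st$exprs, st$samples$age,
                                            st$samples$sex)
  de <- de_old_young(st)
  se3 <- 3 * sqrt(0.05 * 0.95 / 2000)
  expect_lt(abs(mean(pc$p_value < 0.05) - 0.05), se3)
  expect_lt(abs(mean(de$p_value < 0.05) - 0.05), se3)
})

test_that("TSG chi-square matches the closed-form statistic", {
  # identical proportions: statistic 0, p = 1
  calls <- data.frame(
    gene_id = sprintf("g%03d", 1:200),
    is_age_associated = rep(c(TRUE, FALSE), c(40, 160)))
  tsg <- c(sprintf("g%03d", 1:8), sprintf("g%03d", 41:72))  # 8/40, 32/160
  res <- tsg_enrichment_test(calls, tsg)
  expect_equal(res$chi2, 0, tolerance = 1e-12)
  expect_equal(res$p_value, 1)

  # skewed table: agreement with the cross-product formula, row-swap symmetry
  calls2 <- data.frame(
    gene_id = sprintf("g%03d", 1:200),
    is_age_associated = c(rep(TRUE, 30), rep(FALSE, 70),
                          rep(TRUE, 10), rep(FALSE, 90)))
  tsg2 <- sprintf("g%03d", 1:100)
  res2 <- tsg_enrichment_test(calls2, tsg2)
  expect_equal(res2$chi2, oracle_chi2_2x2(res2$table), tolerance = 1e-10)
  swapped <- res2$table[2:1, ]
  expect_equal(oracle_chi2_2x2(swapped), res2$chi2, tolerance = 1e-10)

  expect_error(tsg_enrichment_test(calls, character()), "margin")
})
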