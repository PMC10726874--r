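# Age-association calling: a gene is age-associated in a tissue when BOTH the
# sex-adjusted partial Pearson correlation with age and the old-versus-young
# moderated-t contrast are significant (p < alpha, no multiplicity correction
# at this stage by design).

#' Sex-adjusted partial Pearson correlation between age and expression
#'
#' Computes the first-order partial correlation
#' \deqn{r_{ae \cdot s} = \frac{r_{ae} - r_{as} r_{es}}
#'   {\sqrt{(1 - r_{as}^2)(1 - r_{es}^2)}}}
#' where `a` is age, `e` expression and `s` sex, with a two-sided p-value from
#' the t-distribution on `n - 2` degrees of freedom.
#'
#' @param age,expr,sex Numeric vectors of equal length (`n >= 4`); `sex` is
#'   coded 0/1. A constant `sex` leaves the correlation unadjusted.
#' @return A list with `r_ae`, `r_as`, `r_es`, `r_partial`, `n`, `t_stat`,
#'   `df` and `p_value`.
#' @export
partial_pearson <- function(age, expr, sex) {
  n <- length(age)
  if (length(expr) != n || length(sex) != n)
    stop("`age`, `expr` and `sex` must have equal length")
  if (n < 4) stop("need at least 4 samples")
  if (sd(age) == 0) stop("undefined correlation: `age` is constant")
  if (sd(expr) == 0) stop("undefined correlation: `expr` is constant")
  r_ae <- cor(age, expr)
  if (sd(sex) == 0) {
    r_as <- 0; r_es <- 0
  } else {
    r_as <- cor(age, sex)
    r_es <- cor(expr, sex)
  }
  if (abs(r_as) >= 1 - 1e-12 || abs(r_es) >= 1 - 1e-12)
    stop("degenerate covariate: sex is collinear with age or expression")
  r_p <- (r_ae - r_as * r_es) / sqrt((1 - r_as^2) * (1 - r_es^2))
  r_p <- max(-1, min(1, r_p))
  df <- n - 2
  t_stat <- if (abs(r_p) >= 1) sign(r_p) * Inf
            else r_p * sqrt(df / (1 - r_p^2))
  p <- 2 * pt(abs(t_stat), df, lower.tail = FALSE)
  list(r_ae = r_ae, r_as = r_as, r_es = r_es, r_partial = r_p,
       n = n, t_stat = t_stat, df = df, p_value = p)
}

# Vectorized partial correlation over all genes of a matrix (genes x samples).
# Genes with zero variance get NA statistics (never called associated).
partial_pearson_matrix <- function(exprs, age, sex) {
  n <- length(age)
  r_ae <- suppressWarnings(as.vector(cor(t(exprs), age)))
  if (sd(sex) == 0) {
    r_as <- 0
    r_es <- rep(0, nrow(exprs))
  } else {
    r_as <- cor(age, sex)
    r_es <- suppressWarnings(as.vector(cor(t(exprs), sex)))
  }
  r_p <- (r_ae - r_as * r_es) / sqrt((1 - r_as^2) * (1 - r_es^2))
  r_p <- pmax(-1, pmin(1, r_p))
  df <- n - 2
  t_stat <- ifelse(abs(r_p) >= 1, sign(r_p) * Inf,
                   r_p * sqrt(df / (1 - r_p^2)))
  p <- 2 * pt(abs(t_stat), df, lower.tail = FALSE)
  data.frame(gene_id = rownames(exprs), r_partial = r_p, t_stat = t_stat,
             df = df, p_value = p, stringsAsFactors = FALSE)
}

#' Old-versus-young differential expression with moderated t
#'
#' Fits, per gene, a least-squares model of expression on an old/young
#' indicator (old = age >= `old_min`, young = age < `young_max`; samples in
#' between are excluded) plus sex and an intercept, and moderates the per-gene
#' residual variances by limma's empirical-Bayes shrinkage.  The indicator
#' coefficient is reported as the log fold change.  A continuous-age fit is
#' available behind `age_mode = "continuous"` (all samples, age in years as
#' the regressor).
#'
#' @param study An [expression_study()].
#' @param old_min,young_max Age cut points in years.
#' @param age_mode `"binary"` (default) or `"continuous"`.
#' @param prior_df `NULL` for empirical-Bayes moderation (the default); `0`
#'   forces ordinary least-squares t-statistics (no shrinkage).
#' @return Data frame with columns `gene_id`, `logfc` (the age coefficient),
#'   `beta_sex`, `residual_sd`, `moderated_t`, `moderated_df`, `p_value`;
#'   sample counts are attached as attributes `n_old` / `n_young`.
#' @export
de_old_young <- function(study, old_min = 60, young_max = 50,
                         age_mode = c("binary", "continuous"),
                         prior_df = NULL) {
  stopifnot(inherits(study, "expression_study"))
  age_mode <- match.arg(age_mode)
  age <- study$samples$age
  sex <- study$samples$sex
  if (age_mode == "binary") {
    keep <- age < young_max | age >= old_min
    n_old <- sum(age[keep] >= old_min)
    n_young <- sum(keep) - n_old
    if (n_old == 0 || n_young == 0)
      stop("empty age stratum: ", n_old, " old / ", n_young, " young samples")
    regressor <- as.numeric(age[keep] >= old_min)
  } else {
    keep <- rep(TRUE, length(age))
    regressor <- age
    n_old <- sum(age >= old_min); n_young <- sum(age < young_max)
  }
  sx <- sex[keep]
  design <- cbind(intercept = 1, age_term = regressor)
  if (sd(sx) > 0) design <- cbind(design, sex = sx)
  fit <- limma::lmFit(study$exprs[, keep, drop = FALSE], design)
  beta_sex <- if ("sex" %in% colnames(design)) fit$coefficients[, "sex"]
              else rep(NA_real_, nrow(fit))

  if (!is.null(prior_df) && prior_df == 0) {
    t_stat <- fit$coefficients[, "age_term"] /
      (fit$stdev.unscaled[, "age_term"] * fit$sigma)
    df_total <- rep(fit$df.residual[1], nrow(fit))
    p <- 2 * pt(abs(t_stat), df_total, lower.tail = FALSE)
  } else {
    if (all(fit$sigma == 0)) {
      warning("zero residual variance for every gene; ",
              "falling back to ordinary t-statistics")
      t_stat <- fit$coefficients[, "age_term"] /
        (fit$stdev.unscaled[, "age_term"] * pmax(fit$sigma, 1))
      df_total <- rep(fit$df.residual[1], nrow(fit))
      p <- 2 * pt(abs(t_stat), df_total, lower.tail = FALSE)
    } else {
      eb <- limma::eBayes(fit)
      t_stat <- eb$t[, "age_term"]
      df_total <- eb$df.total
      p <- eb$p.value[, "age_term"]
    }
  }
  # a gene constant across all fitted samples has 0/0 statistics: call it null
  nan <- !is.finite(t_stat)
  t_stat[nan] <- 0
  p[nan] <- 1
  res <- data.frame(gene_id = rownames(study$exprs),
                    logfc = fit$coefficients[, "age_term"],
                    beta_sex = beta_sex,
                    residual_sd = fit$sigma,
                    moderated_t = t_stat,
                    moderated_df = df_total,
                    p_value = p,
                    stringsAsFactors = FALSE)
  rownames(res) <- NULL
  attr(res, "n_old") <- n_old
  attr(res, "n_young") <- n_young
  res
}

#' Combine the two criteria into age-association calls
#'
#' A gene is age-associated when both the partial-correlation p-value and the
#' differential-expression p-value fall below `alpha`; its direction is the
#' sign of the old/young coefficient.
#'
#' @param pc_results Data frame from [partial_pearson_matrix] style output
#'   (columns `gene_id`, `r_partial`, `p_value`).
#' @param de_results Data frame from [de_old_young()].
#' @param alpha Significance level for both criteria.
#' @param tissue Optional tissue label carried into the output.
#' @return Data frame with `gene_id`, `tissue`, `is_age_associated`,
#'   `direction`, `r_partial`, `p_corr`, `logfc`, `p_de`.
#' @export
call_age_associated <- function(pc_results, de_results, alpha = 0.05,
                                tissue = NA_character_) {
  if (!setequal(pc_results$gene_id, de_results$gene_id)) {
    only_pc <- setdiff(pc_results$gene_id, de_results$gene_id)
    only_de <- setdiff(de_results$gene_id, pc_results$gene_id)
    stop("gene sets differ between the two analyses; ",
         "only in correlation: {", paste(head(only_pc, 5), collapse = ", "),
         "}; only in DE: {", paste(head(only_de, 5), collapse = ", "), "}")
  }
  m <- merge(pc_results[, c("gene_id", "r_partial", "p_value")],
             de_results[, c("gene_id", "logfc", "p_value")],
             by = "gene_id", suffixes = c("_corr", "_de"))
  assoc <- !is.na(m$p_value_corr) & !is.na(m$p_value_de) &
    m$p_value_corr < alpha & m$p_value_de < alpha
  data.frame(gene_id = m$gene_id, tissue = tissue,
             is_age_associated = assoc,
             direction = ifelse(m$logfc < 0, "down", "up"),
             r_partial = m$r_partial, p_corr = m$p_value_corr,
             logfc = m$logfc, p_de = m$p_value_de,
             stringsAsFactors = FALSE)
}

#' Per-tissue age-association driver
#'
#' Runs the sex-adjusted partial correlation (all samples) and the
#' old-versus-young moderated-t contrast for every gene of one tissue study
#' and combines them with [call_age_associated()].
#'
#' @inheritParams de_old_young
#' @param alpha Significance level applied to both criteria.
#' @return The calls table of [call_age_associated()].
#' @export
age_association_calls <- function(study, alpha = 0.05, old_min = 60,
                                  young_max = 50) {
  stopifnot(inherits(study, "expression_study"))
  pc <- partial_pearson_matrix(study$exprs, study$samples$age,
                               study$samples$sex)
  de <- de_old_young(study, old_min = old_min, young_max = young_max)
  call_age_associated(pc, de, alpha = alpha,
                      tissue = study$samples$tissue[1])
}

#' Chi-square test of tumor-suppressor enrichment among age-associated genes
#'
#' Builds the 2x2 table of {TSG, other} x {age-associated in at least one
#' tissue, not} and applies Pearson's chi-square test without continuity
#' correction.
#'
#' @param calls_across_tissues Data frame of per-tissue calls (columns
#'   `gene_id`, `is_age_associated`), stacked over tissues.
#' @param tsg_ids Character vector of tumor-suppressor gene identifiers.
#' @return List with `table` (2x2 counts), `chi2`, `df = 1` and `p_value`.
#' @export
tsg_enrichment_test <- function(calls_across_tissues, tsg_ids) {
  genes <- unique(calls_across_tissues$gene_id)
  assoc_genes <- unique(
    calls_across_tissues$gene_id[calls_across_tissues$is_age_associated])
  is_tsg <- genes %in% tsg_ids
  is_assoc <- genes %in% assoc_genes
  if (!any(is_tsg) || all(is_tsg))
    stop("empty margin: need both TSG and non-TSG genes")
  tab <- table(factor(ifelse(is_tsg, "TSG", "other"),
                      levels = c("TSG", "other")),
               factor(ifelse(is_assoc, "associated", "not"),
                      levels = c("associated", "not")))
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stop("empty margin in the 2x2 table")
  ct <- suppressWarnings(chisq.test(tab, correct = FALSE))
  list(table = tab, chi2 = unname(ct$statistic), df = 1,
       p_value = unname(ct$p.value))
}
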