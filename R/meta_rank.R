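# Per-cancer meta-analysis of dataset-level differential expression and
# cross-cancer prioritization of common targets.

#' Stouffer combination of two-sided p-values with effect signs
#'
#' Each study contributes a signed z-score
#' `z_i = qnorm(1 - p_i / 2) * sign_i`; the combined statistic is
#' `Z = sum(w_i z_i) / sqrt(sum(w_i^2))` with a two-sided p-value.
#'
#' @param p_values Two-sided p-values in (0, 1); values of exactly 0 or 1 are
#'   clipped to machine bounds with a warning.
#' @param effect_signs Vector of -1/+1.
#' @param weights Positive study weights (default: equal).
#' @return List with `z` and `p`.
#' @export
stouffer_combine <- function(p_values, effect_signs, weights = NULL) {
  k <- length(p_values)
  if (length(effect_signs) != k)
    stop("`p_values` and `effect_signs` must have equal length")
  if (is.null(weights)) weights <- rep(1, k)
  if (length(weights) != k) stop("`weights` must match `p_values` in length")
  if (any(weights <= 0)) stop("weights must be positive")
  if (!all(effect_signs %in% c(-1, 1)))
    stop("effect signs must be -1 or +1")
  if (any(p_values < 0 | p_values > 1)) stop("p-values must lie in [0, 1]")
  if (any(p_values <= 0 | p_values >= 1)) {
    warning("p-values at 0 or 1 clipped to machine bounds")
    p_values <- pmin(pmax(p_values, .Machine$double.xmin), 1 - 1e-16)
  }
  z <- qnorm(p_values / 2, lower.tail = FALSE) * effect_signs
  Z <- sum(weights * z) / sqrt(sum(weights^2))
  list(z = Z, p = 2 * pnorm(abs(Z), lower.tail = FALSE))
}

#' Combine per-dataset log fold changes
#'
#' Default `"ivw"` is inverse-variance weighting,
#' `sum(logfc / sd^2) / sum(1 / sd^2)`; `"sd_product"` is the
#' standard-deviation-weighted mean `sum(logfc * sd) / sum(sd)`, retained as
#' an alternative weighting.
#'
#' @param logfcs,sds Equal-length numeric vectors; `sds` must be positive.
#' @param method `"ivw"` or `"sd_product"`.
#' @return The combined log fold change.
#' @export
combine_logfc <- function(logfcs, sds, method = c("ivw", "sd_product")) {
  method <- match.arg(method)
  if (length(logfcs) != length(sds))
    stop("`logfcs` and `sds` must have equal length")
  if (any(sds <= 0)) stop("standard deviations must be positive")
  switch(method,
         ivw = sum(logfcs / sds^2) / sum(1 / sds^2),
         sd_product = sum(logfcs * sds) / sum(sds))
}

#' Benjamini-Hochberg q-values
#'
#' Step-up false-discovery-rate adjustment with monotonicity enforcement;
#' input order is preserved.
#'
#' @param p_values Numeric vector of p-values in [0, 1].
#' @return q-values in the input order.
#' @export
bh_fdr <- function(p_values) {
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]")
  p.adjust(p_values, method = "BH")
}

#' Case-versus-control differential expression for one dataset
#'
#' Moderated-t fit of expression on a case indicator (plus sex when it
#' varies), the dataset-level input to [meta_analyze_cancer()].
#'
#' @param study An [expression_study()] with case/control condition labels.
#' @param prior_df As in [de_old_young()].
#' @return Data frame with `gene_id`, `logfc`, `se` (posterior standard error
#'   of the log fold change), `t`, `p_value`, `n` (total sample count).
#' @export
de_case_control <- function(study, prior_df = NULL) {
  stopifnot(inherits(study, "expression_study"))
  cond <- study$samples$condition
  if (!all(cond %in% c("case", "control")))
    stop("study must contain only case/control samples")
  if (sum(cond == "case") < 2 || sum(cond == "control") < 2)
    stop("need at least 2 cases and 2 controls")
  case <- as.numeric(cond == "case")
  sx <- study$samples$sex
  design <- cbind(intercept = 1, case = case)
  if (sd(sx) > 0) design <- cbind(design, sex = sx)
  fit <- limma::lmFit(study$exprs, design)
  if (!is.null(prior_df) && prior_df == 0) {
    se <- fit$stdev.unscaled[, "case"] * fit$sigma
    t_stat <- fit$coefficients[, "case"] / se
    p <- 2 * pt(abs(t_stat), fit$df.residual[1], lower.tail = FALSE)
  } else {
    eb <- limma::eBayes(fit)
    se <- fit$stdev.unscaled[, "case"] * sqrt(eb$s2.post)
    t_stat <- eb$t[, "case"]
    p <- eb$p.value[, "case"]
  }
  nan <- !is.finite(t_stat)
  t_stat[nan] <- 0
  p[nan] <- 1
  se[!is.finite(se) | se <= 0] <- max(se[is.finite(se) & se > 0], 1e-8)
  res <- data.frame(gene_id = rownames(study$exprs),
                    logfc = fit$coefficients[, "case"],
                    se = se, t = t_stat, p_value = p,
                    n = ncol(study$exprs), stringsAsFactors = FALSE)
  rownames(res) <- NULL
  res
}

#' Meta-analyze the datasets of one cancer
#'
#' Per gene: the combined log fold change over all datasets measuring it
#' ([combine_logfc()]), a Stouffer combination of the two-sided p-values with
#' weights equal to the square root of each dataset's sample size, and a
#' Benjamini-Hochberg FDR across the genes of this cancer.
#'
#' @param de_tables List of per-dataset data frames from [de_case_control()]
#'   (columns `gene_id`, `logfc`, `se`, `p_value`, `n`).
#' @param cancer Cancer label carried into the output.
#' @param logfc_method Passed to [combine_logfc()].
#' @return Data frame with `gene_id`, `cancer`, `combined_logfc`,
#'   `stouffer_z`, `combined_p`, `fdr`, `n_datasets`.
#' @export
meta_analyze_cancer <- function(de_tables, cancer = NA_character_,
                                logfc_method = "ivw") {
  if (!length(de_tables)) stop("need at least one dataset")
  genes <- unique(unlist(lapply(de_tables, `[[`, "gene_id")))
  eps <- 1e-300
  per_gene <- lapply(genes, function(g) {
    rows <- lapply(de_tables, function(d) d[match(g, d$gene_id), , drop = FALSE])
    rows <- do.call(rbind, rows[!vapply(rows, function(r) is.na(r$gene_id),
                                        logical(1))])
    lf <- combine_logfc(rows$logfc, rows$se, method = logfc_method)
    signs <- ifelse(rows$logfc < 0, -1, 1)
    st <- suppressWarnings(
      stouffer_combine(pmin(pmax(rows$p_value, eps), 1 - 1e-16),
                       signs, weights = sqrt(rows$n)))
    c(lf = lf, z = st$z, p = st$p, k = nrow(rows))
  })
  m <- do.call(rbind, per_gene)
  data.frame(gene_id = genes, cancer = cancer,
             combined_logfc = m[, "lf"], stouffer_z = m[, "z"],
             combined_p = m[, "p"], fdr = bh_fdr(m[, "p"]),
             n_datasets = as.integer(m[, "k"]), stringsAsFactors = FALSE)
}

#' Prioritize common cancer targets across per-cancer ranked lists
#'
#' Within each novelty setting, pools the per-cancer ranked lists and orders
#' genes by (1) descending occurrence (number of cancers listing the gene),
#' (2) ascending average rank, (3) gene identifier; the top `top_n` genes per
#' setting are returned.
#'
#' @param rank_lists Data frame with columns `setting`, `cancer`, `gene_id`,
#'   `rank`; genes must be unique within each (setting, cancer) list.
#' @param top_n Number of common targets per setting.
#' @return Data frame with `setting`, `gene_id`, `occurrence`, `avg_rank`,
#'   ordered by priority within setting.
#' @export
prioritize_common_targets <- function(rank_lists, top_n = 100) {
  needed <- c("setting", "cancer", "gene_id", "rank")
  if (!all(needed %in% names(rank_lists)))
    stop("`rank_lists` needs columns: ", paste(needed, collapse = ", "))
  dup <- duplicated(rank_lists[, c("setting", "cancer", "gene_id")])
  if (any(dup))
    stop("duplicate gene within one ranked list: ",
         paste(head(unique(rank_lists$gene_id[dup]), 5), collapse = ", "))
  out <- lapply(split(rank_lists, rank_lists$setting), function(d) {
    occ <- tapply(d$cancer, d$gene_id, function(x) length(unique(x)))
    avg <- tapply(d$rank, d$gene_id, mean)
    genes <- names(occ)
    ord <- order(-occ, avg, genes)
    sel <- head(ord, top_n)
    data.frame(setting = d$setting[1], gene_id = genes[sel],
               occurrence = as.integer(occ[sel]), avg_rank = as.numeric(avg[sel]),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
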