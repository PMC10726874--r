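# Pathway dysregulation: a transparent activation/inhibition scorer (a
# documented surrogate for topology- and coexpression-weighted scorers such as
# iPANDA, with the same interface and +/-0.01 decision thresholds), the
# unidirectional multi-dataset consensus rule, the roll-up to main cellular
# processes, and the aging x cancer cross-classification.

#' Signed pathway activation score for one comparison
#'
#' Genes sharing a coexpression-module label are first collapsed to their
#' module means, then the score is the weighted mean of significance-gated log
#' fold changes, mapped onto the +/-0.01 decision scale:
#' `score = scale * sum(w * s * logFC) / sum(w)`, where `w` is the per-gene
#' topology weight (1 by default) and `s` is 1 for genes significant at
#' `alpha` and `s_relax` otherwise.  Pathway genes missing from the
#' differential-expression table are ignored.
#'
#' @param de_results Data frame with columns `gene_id`, `logfc`, `p_value`.
#' @param pathway Character vector of member genes, or a list with elements
#'   `genes` and optional `weights` (named numeric) and `modules` (named
#'   character labels).
#' @param scale Scale constant mapping typical score magnitudes onto the
#'   +/-`threshold` regime.
#' @param s_relax Significance weight for non-significant genes.
#' @param alpha Significance gate on `p_value`.
#' @param threshold Decision threshold for the activated/inhibited status.
#' @return List with `score`, `status` (`"activated"`, `"inhibited"`,
#'   `"none"`, or `"undefined"` when no member gene was measured) and
#'   `n_genes_scored`.
#' @export
pathway_activation_score <- function(de_results, pathway, scale = 0.1,
                                     s_relax = 0.1, alpha = 0.05,
                                     threshold = 0.01) {
  if (is.list(pathway) && !is.null(pathway$genes)) {
    genes <- pathway$genes
    weights <- pathway$weights
    modules <- pathway$modules
  } else {
    genes <- pathway
    weights <- NULL
    modules <- NULL
  }
  idx <- match(genes, de_results$gene_id)
  present <- !is.na(idx)
  if (!any(present))
    return(list(score = NA_real_, status = "undefined", n_genes_scored = 0L))
  genes <- genes[present]
  idx <- idx[present]
  lf <- de_results$logfc[idx]
  pv <- de_results$p_value[idx]
  w <- if (is.null(weights)) rep(1, length(genes)) else unname(weights[genes])
  if (any(!is.finite(w)) || any(w <= 0))
    stop("topology weights must be positive")
  s <- ifelse(pv < alpha, 1, s_relax)
  grp <- if (is.null(modules)) seq_along(genes) else {
    m <- unname(modules[genes])
    ifelse(is.na(m), paste0(".solo", seq_along(genes)), m)
  }
  lf_m <- tapply(lf, grp, mean)
  w_m <- tapply(w, grp, mean)
  s_m <- tapply(s, grp, mean)
  score <- scale * sum(w_m * s_m * lf_m) / sum(w_m)
  status <- if (score > threshold) "activated"
            else if (score < -threshold) "inhibited"
            else "none"
  list(score = score, status = status, n_genes_scored = length(genes))
}

#' Score every pathway of a collection against one comparison
#'
#' @inheritParams pathway_activation_score
#' @param collection A `pathway_collection`.
#' @return Data frame with `pathway_id`, `score`, `status`, `n_genes_scored`.
#' @export
score_pathways <- function(de_results, collection, scale = 0.1, s_relax = 0.1,
                           alpha = 0.05, threshold = 0.01) {
  rows <- lapply(names(collection$sets), function(id) {
    res <- pathway_activation_score(
      de_results,
      list(genes = collection$sets[[id]],
           weights = collection$weights[[id]],
           modules = if (is.null(collection$modules)) NULL
                     else collection$modules[[id]]),
      scale = scale, s_relax = s_relax, alpha = alpha, threshold = threshold)
    data.frame(pathway_id = id, score = res$score, status = res$status,
               n_genes_scored = res$n_genes_scored, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Unidirectional consensus over the datasets of one comparison group
#'
#' Counts, over ALL datasets of a cancer (or tissue group), how many score
#' above `threshold` (up) and below `-threshold` (down).  If either direction
#' reaches `min_frac` of the datasets and strictly beats the other (an exact
#' 50/50 split is unidirectional for neither and yields `"none"`), the scores
#' of the majority-direction datasets are averaged; the final status is set
#' only when that mean also clears the threshold.
#'
#' @param scores Numeric vector of per-dataset pathway scores (length >= 1).
#' @param threshold Score threshold for calling a dataset dysregulated.
#' @param min_frac Minimum fraction of datasets that must agree in direction.
#' @return List with `n_datasets`, `n_up`, `n_down`, `mean_score` (mean of the
#'   extracted majority-direction scores, `NA` if no direction) and
#'   `final_status`.
#' @export
consensus_direction <- function(scores, threshold = 0.01, min_frac = 0.5) {
  scores <- scores[!is.na(scores)]
  if (!length(scores)) stop("need at least one dataset score")
  n <- length(scores)
  up <- scores > threshold
  down <- scores < -threshold
  n_up <- sum(up); n_down <- sum(down)
  mean_score <- NA_real_
  final <- "none"
  if (n_up / n >= min_frac && n_up > n_down) {
    mean_score <- mean(scores[up])
    if (mean_score > threshold) final <- "activated"
  } else if (n_down / n >= min_frac && n_down > n_up) {
    mean_score <- mean(scores[down])
    if (mean_score < -threshold) final <- "inhibited"
  }
  list(n_datasets = n, n_up = n_up, n_down = n_down,
       mean_score = mean_score, final_status = final)
}

#' Consensus calls for every pathway across a comparison group's datasets
#'
#' @param score_table Data frame with columns `pathway_id`, `dataset_id`,
#'   `score` (one row per pathway per dataset; `NA` scores are ignored).
#' @param group Label of the cancer or tissue the datasets belong to.
#' @inheritParams consensus_direction
#' @return Data frame with one row per pathway: `pathway_id`, `group`,
#'   `n_datasets`, `n_up`, `n_down`, `mean_score`, `final_status`.
#' @export
consensus_calls <- function(score_table, group = NA_character_,
                            threshold = 0.01, min_frac = 0.5) {
  rows <- lapply(split(score_table, score_table$pathway_id), function(d) {
    cc <- consensus_direction(d$score, threshold = threshold,
                              min_frac = min_frac)
    data.frame(pathway_id = d$pathway_id[1], group = group,
               n_datasets = cc$n_datasets, n_up = cc$n_up,
               n_down = cc$n_down, mean_score = cc$mean_score,
               final_status = cc$final_status, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Roll consensus calls up to main cellular processes
#'
#' For each parent process, the percentage of its pathways called activated
#' and inhibited, over the total number of pathways in that process.
#'
#' @param consensus A data frame of consensus calls (columns `pathway_id`,
#'   `final_status`).
#' @param collection The `pathway_collection` defining the hierarchy.
#' @return Data frame with `process_name`, `percent_up`, `percent_down`,
#'   `n_pathways_total`.
#' @export
process_summary <- function(consensus, collection) {
  unknown <- setdiff(consensus$pathway_id, names(collection$process))
  if (length(unknown))
    stop("unknown pathway id(s): ", paste(head(unknown, 5), collapse = ", "))
  procs <- sort(unique(unname(collection$process)))
  totals <- table(factor(unname(collection$process), levels = procs))
  status <- setNames(consensus$final_status, consensus$pathway_id)
  rows <- lapply(procs, function(p) {
    ids <- names(collection$process)[collection$process == p]
    st <- status[intersect(ids, names(status))]
    total <- as.numeric(totals[[p]])
    data.frame(process_name = p,
               percent_up = if (total) 100 * sum(st == "activated",
                                                 na.rm = TRUE) / total else 0,
               percent_down = if (total) 100 * sum(st == "inhibited",
                                                   na.rm = TRUE) / total else 0,
               n_pathways_total = total, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Cross-classify pathways dysregulated in both aging and cancer
#'
#' For each pathway dysregulated in BOTH comparisons of a matched
#' tissue/cancer pair, assigns one of four categories: up in both,
#' down in both, up in cancer and down in aging, or down in cancer and up in
#' aging.  Per process, each category's share is reported against both the
#' process's total pathway count (`percent_of_process`) and the overlapped
#' dysregulated pathways of that process (`percent_of_overlap`).
#'
#' @param aging_calls,cancer_calls Consensus-call data frames over the same
#'   pathway universe (columns `pathway_id`, `final_status`).
#' @param collection The `pathway_collection` defining the hierarchy.
#' @return Data frame with `process_name`, `category`, `n_pathways`,
#'   `percent_of_process`, `percent_of_overlap`.
#' @export
cross_classify <- function(aging_calls, cancer_calls, collection) {
  categories <- c("up_both", "down_both", "up_cancer_down_aging",
                  "down_cancer_up_aging")
  a <- aging_calls[aging_calls$final_status %in% c("activated", "inhibited"),
                   c("pathway_id", "final_status")]
  b <- cancer_calls[cancer_calls$final_status %in% c("activated", "inhibited"),
                    c("pathway_id", "final_status")]
  m <- merge(a, b, by = "pathway_id", suffixes = c("_aging", "_cancer"))
  if (nrow(m)) {
    up_a <- m$final_status_aging == "activated"
    up_c <- m$final_status_cancer == "activated"
    m$category <- ifelse(up_a & up_c, "up_both",
                  ifelse(!up_a & !up_c, "down_both",
                  ifelse(up_c & !up_a, "up_cancer_down_aging",
                         "down_cancer_up_aging")))
    m$process <- unname(collection$process[m$pathway_id])
  }
  procs <- sort(unique(unname(collection$process)))
  totals <- table(factor(unname(collection$process), levels = procs))
  rows <- lapply(procs, function(p) {
    sub <- if (nrow(m)) m[m$process == p, , drop = FALSE] else m
    n_overlap <- nrow(sub)
    counts <- table(factor(if (n_overlap) sub$category else character(),
                           levels = categories))
    data.frame(process_name = p, category = categories,
               n_pathways = as.integer(counts),
               percent_of_process = 100 * as.integer(counts) /
                 as.numeric(totals[[p]]),
               percent_of_overlap = if (n_overlap)
                 100 * as.integer(counts) / n_overlap else rep(0, 4),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
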