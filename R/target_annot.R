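# Target annotation and classification: hallmark-of-aging mapping via GO
# keyword matching, the age-association filter, therapeutic-direction
# proposal, the four lifespan-evidence groups, and the dual-purpose list with
# tumor-suppressor exclusion.

#' Map genes to hallmarks of aging via GO term-name keywords
#'
#' A gene is linked to a hallmark when any of its GO term names contains
#' (case-insensitive substring) any keyword of that hallmark.
#'
#' @param go_annotation Data frame with columns `gene_id`, `term_name`.
#' @param keyword_map Named list with exactly the 12 hallmark keys, each a
#'   character vector of keywords (see [aging_hallmark_keywords()]).
#' @param genes Optional gene universe; genes without any annotation get zero
#'   hallmarks (with a warning).
#' @return Data frame with `gene_id`, `hallmarks` (list column) and
#'   `n_hallmarks`.
#' @export
map_hallmarks <- function(go_annotation, keyword_map, genes = NULL) {
  if (length(keyword_map) != 12 || is.null(names(keyword_map)))
    stop("`keyword_map` must be a named list with exactly the 12 hallmark keys")
  terms <- unique(go_annotation$term_name)
  terms_lc <- tolower(terms)
  term2hm <- lapply(names(keyword_map), function(h) {
    hit <- rep(FALSE, length(terms))
    for (kw in keyword_map[[h]])
      hit <- hit | grepl(tolower(kw), terms_lc, fixed = TRUE)
    terms[hit]
  })
  names(term2hm) <- names(keyword_map)
  if (is.null(genes)) genes <- unique(go_annotation$gene_id)
  missing <- setdiff(genes, go_annotation$gene_id)
  if (length(missing))
    warning(length(missing), " gene(s) have no GO annotation; zero hallmarks")
  gene_terms <- split(go_annotation$term_name, go_annotation$gene_id)
  hm_list <- lapply(genes, function(g) {
    tn <- gene_terms[[g]]
    if (is.null(tn)) return(character())
    names(keyword_map)[vapply(term2hm, function(tt) any(tn %in% tt),
                              logical(1))]
  })
  data.frame(gene_id = genes,
             hallmarks = I(hm_list),
             n_hallmarks = lengths(hm_list),
             stringsAsFactors = FALSE)
}

#' Filter common targets by age association and hallmark linkage
#'
#' Keeps a target when it is age-associated in strictly more than
#' `min_frac * tissue_count` tissues (with 47 tissues and the default 10%
#' this is at least 5 tissues) and linked to at least one hallmark of aging.
#'
#' @param common_targets Data frame with a `gene_id` column (duplicates across
#'   novelty settings are collapsed).
#' @param per_tissue_calls Stacked per-tissue calls (columns `gene_id`,
#'   `tissue`, `is_age_associated`).
#' @param hallmark_annotations Output of [map_hallmarks()].
#' @param tissue_count Total number of tissues analyzed.
#' @param min_frac Minimum fraction of tissues (strict inequality).
#' @return Data frame with `gene_id`, `n_tissues_age_associated`,
#'   `n_tissues_up`, `n_tissues_down`, `n_hallmarks`.
#' @export
filter_age_associated_targets <- function(common_targets, per_tissue_calls,
                                          hallmark_annotations, tissue_count,
                                          min_frac = 0.1) {
  if (tissue_count <= 0) stop("`tissue_count` must be positive")
  genes <- unique(common_targets$gene_id)
  assoc <- per_tissue_calls[per_tissue_calls$is_age_associated, , drop = FALSE]
  n_tiss <- tapply(assoc$tissue, assoc$gene_id,
                   function(x) length(unique(x)))
  n_up <- tapply(assoc$tissue[assoc$direction == "up"],
                 assoc$gene_id[assoc$direction == "up"],
                 function(x) length(unique(x)))
  n_down <- tapply(assoc$tissue[assoc$direction == "down"],
                   assoc$gene_id[assoc$direction == "down"],
                   function(x) length(unique(x)))
  cnt <- function(tab, g) ifelse(is.na(tab[g]), 0L, as.integer(tab[g]))
  nh <- setNames(hallmark_annotations$n_hallmarks,
                 hallmark_annotations$gene_id)
  n_hm <- ifelse(is.na(nh[genes]), 0L, nh[genes])
  out <- data.frame(gene_id = genes,
                    n_tissues_age_associated = cnt(n_tiss, genes),
                    n_tissues_up = cnt(n_up, genes),
                    n_tissues_down = cnt(n_down, genes),
                    n_hallmarks = as.integer(n_hm),
                    stringsAsFactors = FALSE)
  keep <- out$n_tissues_age_associated > min_frac * tissue_count &
    out$n_hallmarks >= 1
  out <- out[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Propose the anti-cancer therapeutic direction for one gene
#'
#' Counts the cancers where the gene is significantly up- versus
#' down-regulated (FDR < `fdr_cut`); an up-majority proposes antagonism, a
#' down-majority agonism.  An explicit override (mechanism-of-action
#' knowledge) wins when present.  Ties, or no significant cancer, yield an
#' unknown direction flagged for review.
#'
#' @param meta_results Data frame of per-cancer meta-results for one gene
#'   (columns `combined_logfc`, `fdr`; optionally `gene_id`).
#' @param overrides Optional data frame with columns `gene_id`, `direction`
#'   (and optionally `note`).
#' @param gene_id Gene identifier (taken from `meta_results` if present).
#' @param fdr_cut Significance cutoff.
#' @return List with `gene_id`, `cancer_direction` (`"antagonism"`,
#'   `"agonism"` or `NA`), `basis` (`"expression"` or `"override"`),
#'   `n_cancers_up`, `n_cancers_down`, `flagged`.
#' @export
propose_direction <- function(meta_results, overrides = NULL,
                              gene_id = NULL, fdr_cut = 0.05) {
  if (is.null(gene_id)) gene_id <- meta_results$gene_id[1]
  if (nrow(meta_results) == 0) stop("need at least one cancer meta-result")
  sig <- meta_results$fdr < fdr_cut
  n_up <- sum(sig & meta_results$combined_logfc > 0)
  n_down <- sum(sig & meta_results$combined_logfc < 0)
  if (!is.null(overrides) && gene_id %in% overrides$gene_id) {
    dir <- overrides$direction[match(gene_id, overrides$gene_id)]
    return(list(gene_id = gene_id, cancer_direction = dir,
                basis = "override", n_cancers_up = n_up,
                n_cancers_down = n_down, flagged = FALSE))
  }
  if (n_up > n_down) {
    dir <- "antagonism"; flagged <- FALSE
  } else if (n_down > n_up) {
    dir <- "agonism"; flagged <- FALSE
  } else {
    dir <- NA_character_; flagged <- TRUE
  }
  list(gene_id = gene_id, cancer_direction = dir, basis = "expression",
       n_cancers_up = n_up, n_cancers_down = n_down, flagged = flagged)
}

#' Propose directions for many genes
#'
#' @param meta_all Stacked per-cancer meta-results (columns `gene_id`,
#'   `cancer`, `combined_logfc`, `fdr`).
#' @inheritParams propose_direction
#' @return Data frame with one row per gene.
#' @export
propose_directions <- function(meta_all, overrides = NULL, fdr_cut = 0.05) {
  rows <- lapply(split(meta_all, meta_all$gene_id), function(d) {
    as.data.frame(propose_direction(d, overrides = overrides,
                                    gene_id = d$gene_id[1],
                                    fdr_cut = fdr_cut),
                  stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# Resolve a possibly multi-row evidence ledger to one row per gene.
# If both extension and shortening evidence exist, extension wins (with a
# warning) and the conflict is recorded.
resolve_ledger <- function(ledger) {
  rows <- lapply(split(ledger, ledger$gene_id), function(d) {
    effects <- unique(d$lifespan_effect)
    conflict <- all(c("extends", "shortens") %in% effects)
    effect <- if ("extends" %in% effects) "extends"
              else if ("shortens" %in% effects) "shortens"
              else if ("no_effect" %in% effects) "no_effect"
              else "none"
    dirs <- d$aging_direction[d$lifespan_effect == effect]
    dirs <- dirs[!is.na(dirs) & dirs != "unknown"]
    data.frame(gene_id = d$gene_id[1], lifespan_effect = effect,
               aging_direction = if (length(dirs)) dirs[1] else "unknown",
               conflict = conflict, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (any(out$conflict))
    warning(sum(out$conflict),
            " gene(s) with both extension and shortening evidence; ",
            "extension retained")
  rownames(out) <- NULL
  out
}

#' Classify targets into the four lifespan-evidence groups
#'
#' Group 1: lifespan-extension evidence with the same therapeutic direction
#' for anti-aging and anti-cancer treatment; Group 2: extension evidence with
#' opposite (or undetermined) direction; Group 3: shortening evidence only;
#' Group 4: no evidence or no effect.  A Group-1 gene is flagged dual-purpose
#' unless it is a tumor suppressor (antagonizing a TSG could promote
#' tumorigenesis).
#'
#' @param filtered_targets Data frame with a `gene_id` column (the
#'   age-associated targets to classify).
#' @param ledger Evidence ledger (columns `gene_id`, `lifespan_effect` in
#'   `extends`/`shortens`/`no_effect`/`none`, `aging_direction`); multiple
#'   rows per gene are resolved with extension winning over shortening.
#' @param cancer_directions Data frame with columns `gene_id`,
#'   `cancer_direction`.
#' @param tsg_ids Character vector of tumor-suppressor genes.
#' @return Data frame with `gene_id`, `group` (1-4), `lifespan_effect`,
#'   `aging_direction`, `cancer_direction`, `is_tsg`, `is_dual_purpose`.
#' @export
classify_groups <- function(filtered_targets, ledger, cancer_directions,
                            tsg_ids = character()) {
  genes <- unique(filtered_targets$gene_id)
  missing <- setdiff(genes, ledger$gene_id)
  if (length(missing))
    stop("target(s) missing from the evidence ledger: ",
         paste(head(missing, 5), collapse = ", "))
  led <- resolve_ledger(ledger[ledger$gene_id %in% genes, , drop = FALSE])
  led <- led[match(genes, led$gene_id), ]
  cdir <- cancer_directions$cancer_direction[
    match(genes, cancer_directions$gene_id)]
  same <- !is.na(cdir) & led$aging_direction != "unknown" &
    led$aging_direction == cdir
  group <- ifelse(led$lifespan_effect == "extends", ifelse(same, 1L, 2L),
           ifelse(led$lifespan_effect == "shortens", 3L, 4L))
  is_tsg <- genes %in% tsg_ids
  data.frame(gene_id = genes, group = group,
             lifespan_effect = led$lifespan_effect,
             aging_direction = led$aging_direction,
             cancer_direction = cdir,
             is_tsg = is_tsg,
             is_dual_purpose = group == 1L & !is_tsg,
             stringsAsFactors = FALSE)
}

#' Final dual-purpose target list
#'
#' Group-1 genes minus tumor suppressors, ordered by the number of tissues
#' with age-associated dysregulation (descending; alphabetical tie-break).
#'
#' @param group1 Data frame of Group-1 genes with a `gene_id` column and
#'   optionally `n_tissues_dysregulated`.
#' @param tsg_ids Character vector of tumor-suppressor genes to exclude.
#' @return The retained rows of `group1`, reordered; empty (with a warning)
#'   when every Group-1 gene is a tumor suppressor.
#' @export
propose_dual_purpose <- function(group1, tsg_ids = character()) {
  if (is.character(group1))
    group1 <- data.frame(gene_id = group1, stringsAsFactors = FALSE)
  if (!"n_tissues_dysregulated" %in% names(group1))
    group1$n_tissues_dysregulated <- 0L
  keep <- !(group1$gene_id %in% tsg_ids)
  if (!any(keep)) {
    if (nrow(group1)) warning("every Group-1 gene is a tumor suppressor")
    out <- group1[keep, , drop = FALSE]
    rownames(out) <- NULL
    return(out)
  }
  out <- group1[keep, , drop = FALSE]
  out <- out[order(-out$n_tissues_dysregulated, out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}
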