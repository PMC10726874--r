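# Hypergeometric GO biological-process enrichment of the lifespan-evidence
# groups and the term-overlap logic nominating unexplored (Group-4)
# dual-purpose candidates.

#' Upper-tail hypergeometric probability
#'
#' `P(X >= k)` for `X ~ Hypergeometric(N, K, n)`: drawing `n` genes from a
#' universe of `N` of which `K` carry the term, the probability of at least
#' `k` carriers in the draw.
#'
#' @param k Observed overlap.
#' @param K Universe genes carrying the term.
#' @param n Query size.
#' @param N Universe size.
#' @return The upper-tail p-value.
#' @export
hypergeom_upper_tail <- function(k, K, n, N) {
  if (any(c(k, K, n, N) < 0) || K > N || n > N || k > min(K, n))
    stop("inconsistent hypergeometric counts: k=", k, " K=", K,
         " n=", n, " N=", N)
  phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Hypergeometric enrichment of a gene set against term sets
#'
#' Tests every term with at least one query gene; genes outside the universe
#' are dropped from the query with a warning; term memberships are restricted
#' to the universe.  Benjamini-Hochberg FDR across the tested terms.
#'
#' @param query_genes Character vector of query genes.
#' @param term_gene_sets Named list of character vectors (e.g. GO
#'   biological-process sets from a GMT file).
#' @param universe Character vector of background genes.
#' @param fdr_cut Threshold for the `enriched` flag.
#' @return Data frame with `term_id`, `k`, `K`, `n`, `N`, `p_value`, `fdr`,
#'   `enriched`, ordered by p-value.
#' @export
enrich_gene_set <- function(query_genes, term_gene_sets, universe,
                            fdr_cut = 0.05) {
  if (!length(query_genes)) stop("empty query gene set")
  if (!length(universe)) stop("empty universe")
  universe <- unique(universe)
  outside <- setdiff(query_genes, universe)
  if (length(outside)) {
    warning(length(outside), " query gene(s) outside the universe dropped")
    query_genes <- intersect(query_genes, universe)
    if (!length(query_genes)) stop("no query gene inside the universe")
  }
  query_genes <- unique(query_genes)
  n <- length(query_genes)
  N <- length(universe)
  rows <- lapply(names(term_gene_sets), function(tid) {
    members <- intersect(term_gene_sets[[tid]], universe)
    K <- length(members)
    k <- length(intersect(query_genes, members))
    if (k == 0) return(NULL)
    data.frame(term_id = tid, k = k, K = K, n = n, N = N,
               p_value = hypergeom_upper_tail(k, K, n, N),
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) {
    return(data.frame(term_id = character(), k = integer(), K = integer(),
                      n = integer(), N = integer(), p_value = numeric(),
                      fdr = numeric(), enriched = logical(),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  out$fdr <- bh_fdr(out$p_value)
  out$enriched <- out$fdr < fdr_cut
  out <- out[order(out$p_value, out$term_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Terms enriched in lifespan extenders and Group 4 but not Group 3
#'
#' @param enriched_extenders,enriched_g3,enriched_g4 Character vectors of
#'   enriched term identifiers for the lifespan-extending genes (Groups 1+2),
#'   the lifespan-shortening genes (Group 3) and the unexplored genes
#'   (Group 4).
#' @return `(extenders` \eqn{\cap} `g4) \ g3` as a character vector.
#' @export
overlap_terms <- function(enriched_extenders, enriched_g3, enriched_g4) {
  setdiff(intersect(enriched_extenders, enriched_g4), enriched_g3)
}

#' Nominate unexplored dual-purpose candidates
#'
#' Every Group-4 gene annotated to at least one overlap term becomes a
#' candidate, with its supporting terms, ordered by the number of supporting
#' terms (descending; alphabetical tie-break).
#'
#' @param overlap_term_set Character vector of term identifiers from
#'   [overlap_terms()].
#' @param group4_genes Character vector of Group-4 genes.
#' @param go_annotation Data frame with columns `gene_id`, `term_id`.
#' @return Data frame with `gene_id`, `n_supporting` and `supporting_terms`
#'   (list column).
#' @export
candidate_genes <- function(overlap_term_set, group4_genes, go_annotation) {
  empty <- data.frame(gene_id = character(), n_supporting = integer(),
                      stringsAsFactors = FALSE)
  empty$supporting_terms <- list()
  if (!length(overlap_term_set) || !length(group4_genes)) return(empty)
  hits <- go_annotation[go_annotation$term_id %in% overlap_term_set &
                          go_annotation$gene_id %in% group4_genes,
                        c("gene_id", "term_id"), drop = FALSE]
  if (!nrow(hits)) return(empty)
  terms_by_gene <- lapply(split(hits$term_id, hits$gene_id), unique)
  genes <- names(terms_by_gene)
  out <- data.frame(gene_id = genes,
                    n_supporting = lengths(terms_by_gene),
                    stringsAsFactors = FALSE)
  out$supporting_terms <- unname(terms_by_gene)
  out <- out[order(-out$n_supporting, out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}
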