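# End-to-end orchestration: synthetic generation -> preprocessing -> per-tissue
# age association -> pathway consensus (aging and cancer) -> per-cancer
# meta-analysis -> common-target prioritization -> hallmark annotation,
# age-association filter, four-group classification, dual-purpose list ->
# enrichment-based Group-4 candidate prediction -> lifespan assay analysis.

#' Read a plain-text key/value pipeline configuration
#'
#' Lines of the form `key = value` or `key: value` (\code{#} comments and blank
#' lines ignored).  Keys matching [synth_config()] arguments configure the
#' generator; the remaining recognized keys (`alpha`, `ipanda_threshold`,
#' `consensus_frac`, `tissue_frac`, `fdr_cut`, `top_n`) become pipeline
#' options.
#'
#' @param path Configuration file.
#' @return List with elements `config` (a `synth_config`) and `options`.
#' @export
read_pipeline_config <- function(path) {
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines[grepl("[=:]", lines)])
  kv <- strsplit(lines, "\\s*[=:]\\s*")
  keys <- vapply(kv, `[`, character(1), 1)
  vals <- vapply(kv, `[`, character(1), 2)
  num <- suppressWarnings(as.numeric(vals))
  parsed <- as.list(ifelse(is.na(num), vals, num))
  parsed <- setNames(parsed, keys)
  cfg_keys <- intersect(names(parsed), names(formals(synth_config)))
  opt_keys <- intersect(names(parsed),
                        c("alpha", "ipanda_threshold", "consensus_frac",
                          "tissue_frac", "fdr_cut", "top_n"))
  unknown <- setdiff(names(parsed), c(cfg_keys, opt_keys))
  if (length(unknown))
    warning("ignoring unknown config key(s): ", paste(unknown, collapse = ", "))
  list(config = do.call(synth_config, parsed[cfg_keys]),
       options = parsed[opt_keys])
}

#' Run the full target-discovery pipeline on synthetic data
#'
#' Executes every stage on data generated from `config`, writes all
#' intermediate tables as TSV (plus GMT gene sets and a JSON report) under
#' `outdir`, and returns the report.  The report records the configuration and
#' seed, so a rerun with the same config reproduces it exactly.
#'
#' @param config A [synth_config()].
#' @param outdir Output directory (created if needed).
#' @param alpha Significance level of the age-association dual criterion.
#' @param ipanda_threshold Pathway score decision threshold.
#' @param consensus_frac Minimum unidirectional dataset fraction.
#' @param tissue_frac Minimum fraction of tissues for the age filter.
#' @param fdr_cut FDR cutoff for meta-analysis significance and enrichment.
#' @param top_n Common targets per novelty setting.
#' @param quiet Suppress progress messages.
#' @return A list of class `pipeline_report`.
#' @export
run_pipeline <- function(config = synth_config(),
                         outdir = file.path(tempdir(), "dualtarget_run"),
                         alpha = 0.05, ipanda_threshold = 0.01,
                         consensus_frac = 0.5, tissue_frac = 0.1,
                         fdr_cut = 0.05, top_n = 100, quiet = FALSE) {
  stopifnot(inherits(config, "synth_config"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (!quiet) message(sprintf(...))
  tsv <- function(df, name) {
    write_tsv_file(df, file.path(outdir, name))
    name
  }
  files <- character()

  # -- simulate ----------------------------------------------------------------
  say("simulate: %d tissues, %d cancers x %d datasets, %d genes",
      config$n_tissues, config$n_cancers, config$datasets_per_cancer,
      config$n_genes)
  collection <- generate_pathway_collection(config)
  annotations <- generate_annotations(config)
  tissues <- lapply(seq_len(config$n_tissues),
                    function(i) generate_tissue_study(config, i))
  cancers <- lapply(seq_len(config$n_cancers), function(ci)
    lapply(seq_len(config$datasets_per_cancer),
           function(di) generate_cancer_dataset(config, ci, di)))
  files <- c(files,
             tsv(hierarchy_table(collection), "pathway_hierarchy.tsv"),
             tsv(annotations$go, "go_annotation.tsv"),
             tsv(annotations$rank_lists, "target_rank_lists.tsv"),
             tsv(annotations$ledger, "evidence_ledger.tsv"))
  write_gmt(collection$sets, file.path(outdir, "pathways.gmt"))
  files <- c(files, "pathways.gmt")

  # -- preprocess + per-tissue age association ---------------------------------
  say("age association: %d tissues at alpha = %g", config$n_tissues, alpha)
  tissue_calls <- lapply(tissues, function(st) {
    st <- filter_zero_coverage(st)
    age_association_calls(st, alpha = alpha)
  })
  calls_all <- do.call(rbind, tissue_calls)
  files <- c(files, tsv(calls_all, "age_association_calls.tsv"))

  # -- pathway dysregulation ---------------------------------------------------
  say("pathway consensus: threshold %g, unidirectional fraction %g",
      ipanda_threshold, consensus_frac)
  aging_consensus <- lapply(seq_along(tissues), function(i) {
    de <- de_old_young(tissues[[i]])
    sc <- score_pathways(de, collection, alpha = alpha,
                         threshold = ipanda_threshold)
    sc$dataset_id <- tissues[[i]]$samples$dataset_id[1]
    consensus_calls(sc[, c("pathway_id", "dataset_id", "score")],
                    group = tissues[[i]]$samples$tissue[1],
                    threshold = ipanda_threshold, min_frac = consensus_frac)
  })
  cancer_de <- lapply(cancers, function(ds) lapply(ds, de_case_control))
  cancer_consensus <- lapply(seq_along(cancers), function(ci) {
    st <- do.call(rbind, lapply(seq_along(cancer_de[[ci]]), function(di) {
      sc <- score_pathways(cancer_de[[ci]][[di]], collection, alpha = alpha,
                           threshold = ipanda_threshold)
      sc$dataset_id <- sprintf("cancer%02d_ds%02d", ci, di)
      sc[, c("pathway_id", "dataset_id", "score")]
    }))
    consensus_calls(st, group = sprintf("cancer%02d", ci),
                    threshold = ipanda_threshold, min_frac = consensus_frac)
  })
  proc_aging <- do.call(rbind, lapply(aging_consensus, function(cc) {
    s <- process_summary(cc, collection); s$group <- cc$group[1]; s
  }))
  proc_cancer <- do.call(rbind, lapply(cancer_consensus, function(cc) {
    s <- process_summary(cc, collection); s$group <- cc$group[1]; s
  }))
  n_pairs <- min(config$n_tissues, config$n_cancers)
  cross <- do.call(rbind, lapply(seq_len(n_pairs), function(i) {
    x <- cross_classify(aging_consensus[[i]], cancer_consensus[[i]], collection)
    x$pair <- sprintf("tissue_%02d~cancer%02d", i, i)
    x
  }))
  files <- c(files,
             tsv(do.call(rbind, aging_consensus), "pathway_consensus_aging.tsv"),
             tsv(do.call(rbind, cancer_consensus), "pathway_consensus_cancer.tsv"),
             tsv(proc_aging, "process_summary_aging.tsv"),
             tsv(proc_cancer, "process_summary_cancer.tsv"),
             tsv(cross, "process_cross_classification.tsv"))

  # -- meta-analysis + common-target prioritization ----------------------------
  say("meta-analysis: %d cancers", config$n_cancers)
  meta <- do.call(rbind, lapply(seq_along(cancer_de), function(ci)
    meta_analyze_cancer(cancer_de[[ci]], cancer = sprintf("cancer%02d", ci))))
  common <- prioritize_common_targets(annotations$rank_lists, top_n = top_n)
  files <- c(files, tsv(meta, "meta_results.tsv"),
             tsv(common, "common_targets.tsv"))

  # -- annotation, filter, classification --------------------------------------
  say("classification: tissue fraction > %g, hallmark >= 1", tissue_frac)
  hallmarks <- suppressWarnings(
    map_hallmarks(annotations$go, annotations$hallmark_keywords,
                  genes = gene_universe(config)))
  filtered <- filter_age_associated_targets(
    common, calls_all, hallmarks, tissue_count = config$n_tissues,
    min_frac = tissue_frac)
  groups <- list()
  dual <- data.frame()
  directions <- data.frame()
  if (nrow(filtered)) {
    meta_f <- meta[meta$gene_id %in% filtered$gene_id, , drop = FALSE]
    directions <- propose_directions(meta_f, fdr_cut = fdr_cut)
    asg <- classify_groups(filtered, annotations$ledger, directions,
                           tsg_ids = annotations$tsg)
    asg <- merge(asg, filtered[, c("gene_id", "n_tissues_age_associated",
                                   "n_hallmarks")], by = "gene_id")
    g1 <- asg[asg$group == 1L, , drop = FALSE]
    g1$n_tissues_dysregulated <- g1$n_tissues_age_associated
    dual <- propose_dual_purpose(g1, tsg_ids = annotations$tsg)
    groups <- asg
    files <- c(files, tsv(asg, "group_assignments.tsv"),
               tsv(directions, "therapeutic_directions.tsv"))
    if (nrow(dual)) files <- c(files, tsv(dual, "dual_purpose_targets.tsv"))
  }
  group_sizes <- as.list(table(factor(if (length(groups)) groups$group
                                      else integer(), levels = 1:4)))
  names(group_sizes) <- paste0("group", 1:4)

  # -- enrichment-based Group-4 candidate prediction ---------------------------
  say("enrichment: hypergeometric GO biological-process overlap")
  go_bp <- annotations$go[annotations$go$namespace == "biological_process", ]
  term_sets <- split(go_bp$gene_id, go_bp$term_id)
  universe <- unique(go_bp$gene_id)
  enriched_ids <- function(genes) {
    q <- intersect(genes, universe)
    if (!length(q)) return(character())
    e <- suppressWarnings(enrich_gene_set(q, term_sets, universe,
                                          fdr_cut = fdr_cut))
    e$term_id[e$enriched]
  }
  candidates <- data.frame()
  if (length(groups) && nrow(groups)) {
    ext <- enriched_ids(groups$gene_id[groups$group %in% c(1L, 2L)])
    g3 <- enriched_ids(groups$gene_id[groups$group == 3L])
    g4_genes <- groups$gene_id[groups$group == 4L]
    g4 <- enriched_ids(g4_genes)
    ov <- overlap_terms(ext, g3, g4)
    candidates <- candidate_genes(ov, g4_genes, go_bp)
    if (nrow(candidates)) {
      flat <- candidates
      flat$supporting_terms <- vapply(candidates$supporting_terms,
                                      paste, character(1), collapse = ",")
      files <- c(files, tsv(flat, "group4_candidates.tsv"))
    }
  }

  # -- lifespan ----------------------------------------------------------------
  say("lifespan assay: %d x %d animals per arm", config$worms_per_group,
      config$n_repeats)
  assay <- generate_lifespan_assay(config)
  files <- c(files, tsv(assay, "lifespan_records.tsv"))
  life <- lifespan_summary(assay)

  report <- structure(list(
    seed = config$seed,
    config = unclass(config),
    outdir = outdir,
    files = files,
    n_age_associated_per_tissue = vapply(tissue_calls, function(d)
      sum(d$is_age_associated), numeric(1)),
    n_common_targets = nrow(common),
    n_filtered_targets = if (length(groups)) nrow(groups) else 0L,
    group_sizes = lapply(group_sizes, as.integer),
    dual_purpose = dual$gene_id,
    n_candidates = nrow(candidates),
    candidate_genes = candidates$gene_id,
    lifespan = list(control_median = life$control_median,
                    treatment_median = life$treatment_median,
                    change_percent = life$change_percent,
                    logrank_chi2 = life$logrank$chi2,
                    logrank_p = life$logrank$p_value)
  ), class = "pipeline_report")
  write_truth_json(report[setdiff(names(report), "outdir")],
                   file.path(outdir, "report.json"))
  say("done: %d files under %s", length(files) + 1, outdir)
  report
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("pipeline_report (seed", x$seed, ")\n")
  cat("  common targets:", x$n_common_targets,
      "| filtered:", x$n_filtered_targets, "\n")
  cat("  group sizes:", paste(sprintf("%s=%d", names(x$group_sizes),
                                      unlist(x$group_sizes)),
                              collapse = ", "), "\n")
  cat("  dual-purpose:", length(x$dual_purpose),
      "| group-4 candidates:", x$n_candidates, "\n")
  cat(sprintf("  lifespan: %g -> %g days (%+.1f%%), logrank p = %.3g\n",
              x$lifespan$control_median, x$lifespan$treatment_median,
              x$lifespan$change_percent, x$lifespan$logrank_p))
  invisible(x)
}
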