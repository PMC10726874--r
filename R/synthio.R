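# Synthetic-data generator.  Every pipeline input (tissue studies, cancer
# case-control datasets, pathway hierarchy, annotations, evidence ledger,
# lifespan assay) is produced with known planted truth so downstream callers
# can be tested without any download.  All randomness is drawn from named
# substreams of a single integer seed, so each generated object is a pure
# function of (config, indices) regardless of call order.

#' Synthetic study configuration
#'
#' Bundles every knob of the synthetic-data generator and validates it once.
#' The defaults describe the study conditions the rest of the package is
#' exercised under: a handful of healthy tissues with 150 donors each (ages
#' uniform on 20-79, sex balanced), one fifth of genes drifting linearly with
#' age with a slope of 0.35 expression units per decade (predominantly
#' downward, as observed in bulk aging tissue), case-control cancer cohorts of
#' 40 + 40 samples with planted log2 fold changes of mean magnitude 1, a
#' two-level pathway hierarchy of 100 pathways under 27 main cellular
#' processes, and a nematode-style lifespan assay of 90 animals per arm in 3
#' biological repeats with a control median of 19 days and a +15.8% planted
#' median extension.
#'
#' @param n_tissues,samples_per_tissue Number of healthy tissues and donors
#'   per tissue.
#' @param n_genes Size of the gene universe (shared by all generated studies).
#' @param frac_age_associated Fraction of genes given a nonzero age slope.
#' @param age_effect_size Absolute expression change per decade of age for
#'   planted age-associated genes (same units as the expression matrix, which
#'   is on a log-like scale with per-gene Gaussian noise `noise_sd`).
#' @param frac_age_down Fraction of planted age genes whose slope is negative.
#' @param sex_effect_sd Standard deviation of the per-gene additive sex effect.
#' @param noise_sd Standard deviation of the i.i.d. Gaussian noise.
#' @param n_cancers,datasets_per_cancer Number of cancers and of case-control
#'   datasets per cancer.
#' @param cases_per_dataset,controls_per_dataset Arm sizes (each must be >= 2).
#' @param frac_de_genes Fraction of genes planted as differentially expressed
#'   in each cancer (the gene set is shared across that cancer's datasets).
#' @param de_logfc_mean Mean absolute planted log2 fold change.
#' @param n_pathways,genes_per_pathway,n_processes Pathway collection shape;
#'   each pathway belongs to exactly one of the `n_processes` parent
#'   processes (default 27 main cellular processes).
#' @param frac_pathways_planted_up,frac_pathways_planted_down Fractions of
#'   pathways given a directional planted effect in each comparison.
#' @param lifespan_control_median Control-arm median lifespan in days.
#' @param lifespan_shift_percent Planted percent change of the treated median
#'   (must be > -100).
#' @param worms_per_group,n_repeats Animals per arm per repeat, and number of
#'   biological repeats.
#' @param gompertz_shape Fixed Gompertz shape (per day); the rate is solved in
#'   closed form so the target median is hit.
#' @param seed Integer seed; a fixed seed makes every generated object
#'   byte-identical across runs.
#'
#' @return A validated list of class `synth_config`.
#' @export
synth_config <- function(n_tissues = 4,
                         samples_per_tissue = 150,
                         n_genes = 2000,
                         frac_age_associated = 0.2,
                         age_effect_size = 0.35,
                         frac_age_down = 0.6,
                         sex_effect_sd = 0.5,
                         noise_sd = 1,
                         n_cancers = 3,
                         datasets_per_cancer = 4,
                         cases_per_dataset = 40,
                         controls_per_dataset = 40,
                         frac_de_genes = 0.1,
                         de_logfc_mean = 1,
                         n_pathways = 100,
                         genes_per_pathway = 20,
                         n_processes = 27,
                         frac_pathways_planted_up = 0.15,
                         frac_pathways_planted_down = 0.15,
                         lifespan_control_median = 19,
                         lifespan_shift_percent = 15.8,
                         worms_per_group = 90,
                         n_repeats = 3,
                         gompertz_shape = 0.45,
                         seed = 1L) {
  cfg <- list(n_tissues = n_tissues,
              samples_per_tissue = samples_per_tissue,
              n_genes = n_genes,
              frac_age_associated = frac_age_associated,
              age_effect_size = age_effect_size,
              frac_age_down = frac_age_down,
              sex_effect_sd = sex_effect_sd,
              noise_sd = noise_sd,
              n_cancers = n_cancers,
              datasets_per_cancer = datasets_per_cancer,
              cases_per_dataset = cases_per_dataset,
              controls_per_dataset = controls_per_dataset,
              frac_de_genes = frac_de_genes,
              de_logfc_mean = de_logfc_mean,
              n_pathways = n_pathways,
              genes_per_pathway = genes_per_pathway,
              n_processes = n_processes,
              frac_pathways_planted_up = frac_pathways_planted_up,
              frac_pathways_planted_down = frac_pathways_planted_down,
              lifespan_control_median = lifespan_control_median,
              lifespan_shift_percent = lifespan_shift_percent,
              worms_per_group = worms_per_group,
              n_repeats = n_repeats,
              gompertz_shape = gompertz_shape,
              seed = as.integer(seed))
  validate_synth_config(cfg)
  structure(cfg, class = "synth_config")
}

validate_synth_config <- function(cfg) {
  chk_count <- function(x, nm) {
    if (length(x) != 1 || !is.finite(x) || x < 1 || x != round(x))
      stop("config error: `", nm, "` must be a positive count, got ", x)
  }
  chk_frac <- function(x, nm) {
    if (length(x) != 1 || !is.finite(x) || x < 0 || x > 1)
      stop("config error: `", nm, "` must be a fraction in [0, 1], got ", x)
  }
  for (nm in c("n_tissues", "samples_per_tissue", "n_genes", "n_cancers",
               "datasets_per_cancer", "cases_per_dataset",
               "controls_per_dataset", "n_pathways", "genes_per_pathway",
               "n_processes", "worms_per_group", "n_repeats"))
    chk_count(cfg[[nm]], nm)
  for (nm in c("frac_age_associated", "frac_age_down", "frac_de_genes",
               "frac_pathways_planted_up", "frac_pathways_planted_down"))
    chk_frac(cfg[[nm]], nm)
  if (cfg$cases_per_dataset < 2 || cfg$controls_per_dataset < 2)
    stop("config error: at least 2 cases and 2 controls per dataset required")
  if (cfg$frac_pathways_planted_up + cfg$frac_pathways_planted_down > 1)
    stop("config error: planted pathway fractions sum to more than 1")
  if (cfg$n_processes > cfg$n_pathways)
    stop("config error: `n_processes` exceeds `n_pathways`")
  if (cfg$genes_per_pathway > cfg$n_genes)
    stop("config error: `genes_per_pathway` exceeds `n_genes`")
  if (cfg$sex_effect_sd < 0 || cfg$noise_sd < 0)
    stop("config error: standard deviations must be non-negative")
  if (cfg$lifespan_control_median <= 0)
    stop("config error: control median lifespan must be positive")
  if (cfg$lifespan_shift_percent <= -100)
    stop("config error: lifespan shift below -100% is impossible")
  if (cfg$gompertz_shape <= 0)
    stop("config error: Gompertz shape must be positive")
  invisible(cfg)
}

#' @export
print.synth_config <- function(x, ...) {
  cat("synth_config (seed", x$seed, ")\n")
  cat(sprintf("  tissues: %d x %d samples; genes: %d (%.0f%% age-associated)\n",
              x$n_tissues, x$samples_per_tissue, x$n_genes,
              100 * x$frac_age_associated))
  cat(sprintf("  cancers: %d x %d datasets (%d + %d per arm)\n",
              x$n_cancers, x$datasets_per_cancer, x$cases_per_dataset,
              x$controls_per_dataset))
  cat(sprintf("  pathways: %d in %d processes; lifespan: median %g d %+.1f%%\n",
              x$n_pathways, x$n_processes, x$lifespan_control_median,
              x$lifespan_shift_percent))
  invisible(x)
}

# ---- seeding -----------------------------------------------------------------

# Deterministic 31-bit substream seed from (seed, label, index); keeps every
# generated object a pure function of the config regardless of call order.
rng_stream <- function(seed, label, index = 0L) {
  chars <- utf8ToInt(label)
  h <- sum(chars * seq_along(chars)) %% 1e5
  as.integer((as.numeric(seed) %% 2147483629 * 10007 + h * 131 +
                as.numeric(index) * 7919) %% 2147483629)
}

gene_universe <- function(config) sprintf("G%05d", seq_len(config$n_genes))

pathway_ids <- function(config) sprintf("PW%04d", seq_len(config$n_pathways))

# ---- planted truth -----------------------------------------------------------

# Global age-gene truth: identical in every tissue, by design, so that a gene
# can accumulate age-association calls across tissues.
age_gene_truth <- function(config) {
  n_assoc <- round(config$frac_age_associated * config$n_genes)
  genes <- gene_universe(config)
  if (n_assoc == 0)
    return(data.frame(gene_id = character(), slope_per_year = numeric(),
                      direction = character(), stringsAsFactors = FALSE))
  withr::with_seed(rng_stream(config$seed, "age-genes"), {
    ids <- sample(genes, n_assoc)
  })
  n_down <- round(config$frac_age_down * n_assoc)
  sgn <- rep(c(-1, 1), c(n_down, n_assoc - n_down))
  data.frame(gene_id = ids,
             slope_per_year = sgn * config$age_effect_size / 10,
             direction = ifelse(sgn < 0, "down", "up"),
             stringsAsFactors = FALSE)
}

# Per-cancer differentially expressed gene set, shared by all datasets of
# that cancer.
cancer_de_truth <- function(config, cancer_index) {
  n_de <- round(config$frac_de_genes * config$n_genes)
  genes <- gene_universe(config)
  if (n_de == 0)
    return(data.frame(gene_id = character(), logfc = numeric(),
                      stringsAsFactors = FALSE))
  withr::with_seed(rng_stream(config$seed, "cancer-de", cancer_index), {
    ids <- sample(genes, n_de)
    sgn <- sample(c(-1, 1), n_de, replace = TRUE)
    mag <- abs(rnorm(n_de, config$de_logfc_mean, config$de_logfc_mean / 4))
  })
  mag <- pmax(mag, 0.25 * config$de_logfc_mean)
  data.frame(gene_id = ids, logfc = sgn * mag, stringsAsFactors = FALSE)
}

# Planted pathway directions for one comparison ("aging" tissue or "cancer").
planted_pathway_directions <- function(config, comparison, index) {
  n_up <- round(config$frac_pathways_planted_up * config$n_pathways)
  n_down <- round(config$frac_pathways_planted_down * config$n_pathways)
  if (n_up + n_down == 0)
    return(data.frame(pathway_id = character(), direction = character(),
                      stringsAsFactors = FALSE))
  withr::with_seed(
    rng_stream(config$seed, paste0("pathway-dir-", comparison), index), {
      picks <- sample(pathway_ids(config), n_up + n_down)
    })
  data.frame(pathway_id = picks,
             direction = rep(c("up", "down"), c(n_up, n_down)),
             stringsAsFactors = FALSE)
}

# Sum of planted per-gene shifts contributed by planted pathways.
pathway_gene_shift <- function(config, directions, magnitude) {
  shift <- setNames(numeric(config$n_genes), gene_universe(config))
  if (nrow(directions) == 0) return(shift)
  collection <- generate_pathway_collection(config)
  for (i in seq_len(nrow(directions))) {
    members <- collection$sets[[directions$pathway_id[i]]]
    s <- if (directions$direction[i] == "up") magnitude else -magnitude
    shift[members] <- shift[members] + s
  }
  shift
}

# ---- generators --------------------------------------------------------------

#' Generate one healthy-tissue expression study
#'
#' Donor ages are uniform on 20-79 years and sex is Bernoulli(1/2).
#' Expression is `baseline + slope * age` for planted age-associated genes,
#' plus an additive per-gene sex effect and Gaussian noise; genes belonging to
#' pathways planted for the aging comparison receive an additional age slope
#' so that pathway-level direction is recoverable.  The planted truth (age
#' genes with signed slopes, pathway directions) rides along in the study's
#' `truth` field and is never read by analysis code.
#'
#' @param config A [synth_config()].
#' @param tissue_index Tissue number (1-based).
#' @return An [expression_study()] with `platform = "rnaseq"`.
#' @export
generate_tissue_study <- function(config, tissue_index) {
  stopifnot(inherits(config, "synth_config"))
  validate_synth_config(config)
  if (tissue_index < 1 || tissue_index != round(tissue_index))
    stop("config error: `tissue_index` must be a positive integer")
  n <- config$samples_per_tissue
  genes <- gene_universe(config)
  g <- config$n_genes

  truth_age <- age_gene_truth(config)
  pdirs <- planted_pathway_directions(config, "aging", tissue_index)
  extra_slope <- pathway_gene_shift(config, pdirs,
                                    config$age_effect_size / 10)

  withr::with_seed(rng_stream(config$seed, "tissue", tissue_index), {
    ages <- round(runif(n, 20, 79))
    sex <- rbinom(n, 1, 0.5)
    baseline <- runif(g, 5, 10)
    sex_eff <- rnorm(g, 0, config$sex_effect_sd)
    noise <- matrix(rnorm(g * n, 0, config$noise_sd), g, n)
  })

  slope <- setNames(numeric(g), genes)
  if (nrow(truth_age)) slope[truth_age$gene_id] <- truth_age$slope_per_year
  slope <- slope + extra_slope

  exprs <- baseline + slope %o% ages + sex_eff %o% sex + noise
  tissue <- sprintf("tissue_%02d", tissue_index)
  dimnames(exprs) <- list(genes, sprintf("T%02dS%03d", tissue_index, seq_len(n)))
  samples <- data.frame(sample_id = colnames(exprs),
                        age = ages, sex = sex, tissue = tissue,
                        condition = "healthy", dataset_id = tissue,
                        stringsAsFactors = FALSE)
  expression_study(exprs, samples, platform = "rnaseq",
                   truth = list(age_genes = truth_age,
                                pathway_directions = pdirs))
}

#' Generate one case-control cancer dataset
#'
#' Case samples are shifted by the planted per-gene log fold change; the
#' planted DE gene set (and its signs) is shared by every dataset of the same
#' cancer.  Genes belonging to pathways planted for that cancer receive an
#' additional directional case shift.
#'
#' @param config A [synth_config()].
#' @param cancer_index,dataset_index Cancer and dataset numbers (1-based).
#' @return An [expression_study()] with case/control condition labels.
#' @export
generate_cancer_dataset <- function(config, cancer_index, dataset_index) {
  stopifnot(inherits(config, "synth_config"))
  validate_synth_config(config)
  genes <- gene_universe(config)
  g <- config$n_genes
  n_case <- config$cases_per_dataset
  n_ctrl <- config$controls_per_dataset
  n <- n_case + n_ctrl

  de <- cancer_de_truth(config, cancer_index)
  pdirs <- planted_pathway_directions(config, "cancer", cancer_index)
  shift <- setNames(numeric(g), genes)
  if (nrow(de)) shift[de$gene_id] <- de$logfc
  shift <- shift + pathway_gene_shift(config, pdirs, config$de_logfc_mean)

  withr::with_seed(
    rng_stream(config$seed, "cancer-dataset",
               cancer_index * 1000 + dataset_index), {
      ages <- round(runif(n, 40, 80))
      sex <- rbinom(n, 1, 0.5)
      baseline <- runif(g, 5, 10)
      sex_eff <- rnorm(g, 0, config$sex_effect_sd)
      noise <- matrix(rnorm(g * n, 0, config$noise_sd), g, n)
    })

  condition <- rep(c("control", "case"), c(n_ctrl, n_case))
  case_ind <- as.numeric(condition == "case")
  exprs <- baseline + shift %o% case_ind + sex_eff %o% sex + noise
  dataset_id <- sprintf("cancer%02d_ds%02d", cancer_index, dataset_index)
  dimnames(exprs) <- list(genes,
                          sprintf("C%02dD%02dS%03d", cancer_index,
                                  dataset_index, seq_len(n)))
  samples <- data.frame(sample_id = colnames(exprs),
                        age = ages, sex = sex,
                        tissue = sprintf("cancer%02d_site", cancer_index),
                        condition = condition, dataset_id = dataset_id,
                        stringsAsFactors = FALSE)
  expression_study(exprs, samples, platform = "rnaseq",
                   truth = list(de_genes = de, pathway_directions = pdirs))
}

#' Generate the pathway collection and its two-level hierarchy
#'
#' Each pathway receives `genes_per_pathway` member genes sampled without
#' replacement from the gene universe and exactly one parent process; the
#' first `n_processes` pathways are dealt one per process so every process is
#' populated.
#'
#' @param config A [synth_config()].
#' @return A `pathway_collection`: list with `sets` (named list of member gene
#'   vectors), `process` (named character, pathway -> parent process),
#'   `weights` (named list of per-gene topology weights, all 1 by default) and
#'   `modules` (optional per-gene coexpression-module labels, `NULL` here).
#' @export
generate_pathway_collection <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  validate_synth_config(config)
  ids <- pathway_ids(config)
  genes <- gene_universe(config)
  withr::with_seed(rng_stream(config$seed, "pathway-collection"), {
    sets <- lapply(ids, function(i) sample(genes, config$genes_per_pathway))
    extra <- config$n_pathways - config$n_processes
    proc_idx <- c(seq_len(config$n_processes),
                  if (extra > 0) sample.int(config$n_processes, extra,
                                            replace = TRUE))
  })
  names(sets) <- ids
  process <- setNames(sprintf("process_%02d", proc_idx), ids)
  structure(list(sets = sets, process = process,
                 weights = lapply(sets, function(g) setNames(rep(1, length(g)), g)),
                 modules = NULL),
            class = "pathway_collection")
}

#' @export
print.pathway_collection <- function(x, ...) {
  cat(sprintf("pathway_collection: %d pathways, %d processes, %d genes/pathway\n",
              length(x$sets), length(unique(x$process)),
              length(x$sets[[1]])))
  invisible(x)
}

#' Hierarchy table of a pathway collection
#'
#' @param collection A `pathway_collection`.
#' @return Data frame with columns `pathway_id`, `process_name`.
#' @export
hierarchy_table <- function(collection) {
  data.frame(pathway_id = names(collection$process),
             process_name = unname(collection$process),
             stringsAsFactors = FALSE)
}

#' Canonical hallmarks-of-aging keyword map
#'
#' The twelve hallmark categories with the Gene Ontology term-name keywords
#' used to link genes to them (case-insensitive substring match on GO term
#' names).
#'
#' @return Named list of 12 character vectors.
#' @export
aging_hallmark_keywords <- function() {
  list(
    genomic_instability = c("DNA repair", "DNA damage", "genome stability"),
    telomere_attrition = c("telomere"),
    epigenetic_alterations = c("histone modification", "chromatin remodeling",
                               "DNA methylation"),
    loss_of_proteostasis = c("protein folding", "proteasome",
                             "unfolded protein"),
    disabled_macroautophagy = c("autophagy"),
    deregulated_nutrient_sensing = c("insulin signaling", "TOR signaling",
                                     "nutrient sensing"),
    mitochondrial_dysfunction = c("mitochondri"),
    cellular_senescence = c("senescence", "cell cycle arrest"),
    stem_cell_exhaustion = c("stem cell"),
    altered_intercellular_communication = c("cell communication", "cytokine",
                                            "signal release"),
    chronic_inflammation = c("inflammatory response", "inflammation"),
    dysbiosis = c("microbi")
  )
}

#' Generate annotation tables, rank lists and the evidence ledger
#'
#' Produces every curated input the real analysis would consume from external
#' resources, with synthetic content: a gene-to-GO-term table (biological
#' process terms, some of whose names embed hallmark keywords), the 12-key
#' hallmark keyword map, a tumor-suppressor gene list, per-cancer ranked
#' target lists of length 100 for both novelty settings (enriched for that
#' cancer's planted DE genes), and a lifespan-evidence ledger whose label
#' proportions mirror a typical classified-target composition.
#'
#' @param config A [synth_config()].
#' @return List with elements `go` (data frame `gene_id`, `term_id`,
#'   `term_name`, `namespace`), `hallmark_keywords` (named list of 12),
#'   `tsg` (character vector), `rank_lists` (data frame `setting`, `cancer`,
#'   `gene_id`, `rank`) and `ledger` (data frame `gene_id`, `lifespan_effect`,
#'   `evidence_models`, `aging_direction`).
#' @export
generate_annotations <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  validate_synth_config(config)
  if (config$n_genes < 100)
    stop("config error: rank lists of length 100 need `n_genes` >= 100")
  genes <- gene_universe(config)
  hk <- aging_hallmark_keywords()

  # term pool: two names per hallmark keyword plus generic filler terms
  kw <- unlist(hk, use.names = FALSE)
  term_names <- c(paste("regulation of", kw),
                  paste0("positive regulation of ", kw, " process"),
                  sprintf("generic biological process %02d", 1:30))
  namespace <- rep("biological_process", length(term_names))
  # a few non-BP terms to exercise namespace filtering downstream
  term_names <- c(term_names, sprintf("generic molecular function %02d", 1:5))
  namespace <- c(namespace, rep("molecular_function", 5))
  term_ids <- sprintf("GO:S%06d", seq_along(term_names))

  withr::with_seed(rng_stream(config$seed, "annotations"), {
    go <- do.call(rbind, lapply(seq_along(term_ids), function(i) {
      size <- max(3L, round(config$n_genes * runif(1, 0.02, 0.08)))
      data.frame(gene_id = sample(genes, size), term_id = term_ids[i],
                 term_name = term_names[i], namespace = namespace[i],
                 stringsAsFactors = FALSE)
    }))
    tsg <- sample(genes, max(2L, round(0.05 * config$n_genes)))
    effects <- sample(c("none", "extends", "shortens", "no_effect"),
                      config$n_genes, replace = TRUE,
                      prob = c(0.50, 0.28, 0.16, 0.06))
    models_pool <- c("C. elegans", "D. melanogaster", "M. musculus")
    evidence_models <- vapply(effects, function(e) {
      if (e == "none") return("")
      paste(sort(sample(models_pool, sample.int(3, 1))), collapse = ",")
    }, character(1))
    aging_direction <- ifelse(
      effects %in% c("extends", "shortens"),
      sample(c("antagonism", "agonism"), config$n_genes, replace = TRUE),
      "unknown")
    rank_lists <- do.call(rbind, lapply(c("high_confidence", "novel"),
                                        function(setting) {
      do.call(rbind, lapply(seq_len(config$n_cancers), function(ci) {
        de <- cancer_de_truth(config, ci)
        pool <- c(sample(de$gene_id), sample(setdiff(genes, de$gene_id)))
        data.frame(setting = setting,
                   cancer = sprintf("cancer%02d", ci),
                   gene_id = pool[1:100], rank = 1:100,
                   stringsAsFactors = FALSE)
      }))
    }))
  })
  ledger <- data.frame(gene_id = genes, lifespan_effect = effects,
                       evidence_models = evidence_models,
                       aging_direction = aging_direction,
                       stringsAsFactors = FALSE)
  list(go = go, hallmark_keywords = hk, tsg = tsg,
       rank_lists = rank_lists, ledger = ledger)
}

# ---- lifespan ----------------------------------------------------------------

# Gompertz hazard h(t) = rate * exp(shape * t); closed-form rate for a target
# median m: S(m) = 1/2  =>  rate = shape * log(2) / (exp(shape * m) - 1).
gompertz_rate_for_median <- function(median_day, shape) {
  shape * log(2) / expm1(shape * median_day)
}

# inverse-CDF sampler for the same parameterization
rgompertz_inv <- function(n, shape, rate) {
  log1p(-(shape / rate) * log(runif(n))) / shape
}

#' Generate a two-arm lifespan assay
#'
#' Death times follow a Gompertz law with fixed shape; the rate is solved in
#' closed form so that the continuous median sits half a day below the target
#' and daily scoring (ceiling to whole days, as animals are checked once per
#' day) lands the discrete median on the target day.  The treated arm's target
#' median is the control median shifted by `lifespan_shift_percent`.
#'
#' @param config A [synth_config()].
#' @return Data frame with columns `animal_id`, `arm` (`control`/`treatment`),
#'   `repeat_id`, `day` (integer death day) and `event` (`"death"`); the
#'   planted target medians are attached as attribute `"truth"`.
#' @export
generate_lifespan_assay <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  validate_synth_config(config)
  m_ctrl <- config$lifespan_control_median
  m_trt <- m_ctrl * (1 + config$lifespan_shift_percent / 100)
  if (m_ctrl <= 0.5 || m_trt <= 0.5)
    stop("config error: target medians must exceed half a day")
  shape <- config$gompertz_shape
  n_per_repeat <- config$worms_per_group
  arms <- c(control = m_ctrl, treatment = m_trt)

  withr::with_seed(rng_stream(config$seed, "lifespan"), {
    records <- do.call(rbind, lapply(names(arms), function(arm) {
      rate <- gompertz_rate_for_median(arms[[arm]] - 0.5, shape)
      do.call(rbind, lapply(seq_len(config$n_repeats), function(r) {
        day <- ceiling(rgompertz_inv(n_per_repeat, shape, rate))
        data.frame(animal_id = sprintf("%s_r%d_w%03d", arm, r,
                                       seq_len(n_per_repeat)),
                   arm = arm, repeat_id = r, day = day, event = "death",
                   stringsAsFactors = FALSE)
      }))
    }))
  })
  rownames(records) <- NULL
  attr(records, "truth") <- list(control_median = m_ctrl,
                                 treatment_median = m_trt,
                                 shift_percent = config$lifespan_shift_percent)
  records
}
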