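# Container for one expression study: a gene x sample matrix plus per-sample
# metadata.  Deliberately lightweight (a validated list), in the style of
# limma's EList, so that matrices flow straight into lmFit and friends.

#' Construct an expression study
#'
#' Bundles a gene-by-sample expression matrix with its sample metadata.
#'
#' @param exprs Numeric matrix, genes in rows (rownames are gene identifiers),
#'   samples in columns.
#' @param samples Data frame with one row per column of `exprs`. Must contain
#'   columns `sample_id`, `age` (years), `sex` (0/1), `tissue`, `condition`
#'   (one of `"case"`, `"control"`, `"healthy"`) and `dataset_id`.
#' @param platform One of `"rnaseq"`, `"microarray"`, `"proteomics"`.
#' @param truth Optional list of planted-truth tables attached by the
#'   synthetic generator. Analysis code never reads it; tests do.
#'
#' @return An object of class `expression_study`: a list with elements
#'   `exprs`, `samples`, `platform` and `truth`.
#' @export
expression_study <- function(exprs, samples, platform = "rnaseq", truth = NULL) {
  if (!is.matrix(exprs) || !is.numeric(exprs))
    stop("`exprs` must be a numeric matrix")
  if (is.null(rownames(exprs)))
    stop("`exprs` must have gene identifiers as rownames")
  if (anyDuplicated(rownames(exprs)))
    stop("duplicate gene identifiers in `exprs`")
  if (!all(is.finite(exprs)))
    stop("`exprs` contains non-finite values")
  if (!is.data.frame(samples))
    stop("`samples` must be a data frame")
  if (ncol(exprs) != nrow(samples))
    stop("column count of `exprs` (", ncol(exprs),
         ") does not match metadata row count (", nrow(samples), ")")
  required <- c("sample_id", "age", "sex", "tissue", "condition", "dataset_id")
  missing <- setdiff(required, names(samples))
  if (length(missing))
    stop("`samples` lacks column(s): ", paste(missing, collapse = ", "))
  if (any(samples$age < 0)) stop("ages must be non-negative")
  bad <- setdiff(unique(samples$condition), c("case", "control", "healthy"))
  if (length(bad))
    stop("unknown condition label(s): ", paste(bad, collapse = ", "))
  platform <- match.arg(platform, c("rnaseq", "microarray", "proteomics"))
  structure(list(exprs = exprs, samples = samples, platform = platform,
                 truth = truth),
            class = "expression_study")
}

#' @export
print.expression_study <- function(x, ...) {
  cat(sprintf("expression_study: %d genes x %d samples [%s]\n",
              nrow(x$exprs), ncol(x$exprs), x$platform))
  cat(sprintf("  tissues: %s\n",
              paste(unique(x$samples$tissue), collapse = ", ")))
  cat(sprintf("  conditions: %s\n",
              paste(sprintf("%s=%d", names(table(x$samples$condition)),
                            table(x$samples$condition)), collapse = ", ")))
  if (!is.null(x$truth)) cat("  planted truth attached\n")
  invisible(x)
}

#' @export
dim.expression_study <- function(x) dim(x$exprs)

# internal: replace the matrix, keeping metadata/truth in step
replace_exprs <- function(study, exprs) {
  study$exprs <- exprs
  study
}
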