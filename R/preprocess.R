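# Normalization and filtering of expression studies.  All operations preserve
# sample order, are idempotent where the contract requires it, and return a
# new expression_study.

#' Quantile normalization
#'
#' Forces every sample (column) onto the identical value distribution: each
#' column's sorted values are replaced by the row-wise mean of all sorted
#' columns, with ties receiving the mean of the corresponding row means.
#' Delegates to [limma::normalizeQuantiles()].
#'
#' @param study An [expression_study()] with at least two samples.
#' @return The study with a quantile-normalized matrix.
#' @export
quantile_normalize <- function(study) {
  stopifnot(inherits(study, "expression_study"))
  if (ncol(study$exprs) < 2)
    stop("quantile normalization needs at least 2 samples")
  norm <- limma::normalizeQuantiles(study$exprs, ties = TRUE)
  dimnames(norm) <- dimnames(study$exprs)
  replace_exprs(study, norm)
}

#' Upper-quartile normalization
#'
#' Scales each sample so its 75th percentile of nonzero values equals the mean
#' upper quartile across samples (a dataset-internal, scale-preserving
#' reference).
#'
#' @param study An [expression_study()].
#' @return The study with rescaled columns.
#' @export
upper_quartile_normalize <- function(study) {
  stopifnot(inherits(study, "expression_study"))
  uq <- apply(study$exprs, 2, function(x) {
    nz <- x[x != 0]
    if (!length(nz)) return(0)
    quantile(nz, 0.75, names = FALSE)
  })
  bad <- which(uq <= 0)
  if (length(bad))
    stop("zero upper quartile in sample(s): ",
         paste(colnames(study$exprs)[bad], collapse = ", "))
  factors <- mean(uq) / uq
  replace_exprs(study, sweep(study$exprs, 2, factors, `*`))
}

#' Variance-stabilizing generalized-log transform
#'
#' A calibrated generalized-log transform for proteomics intensities: each
#' sample is affinely calibrated to the across-sample reference (row means) by
#' least squares, then passed through `asinh` and rescaled to the log2 scale,
#' so large-intensity differences approach log2 ratios while small intensities
#' are compressed smoothly instead of exploding.  Monotone within each sample.
#'
#' @param study An [expression_study()] with `platform == "proteomics"`.
#' @return The study with glog2-transformed values.
#' @export
vsn_transform <- function(study) {
  stopifnot(inherits(study, "expression_study"))
  if (study$platform != "proteomics")
    stop("vsn_transform expects a proteomics study, got ", study$platform)
  e <- study$exprs
  ref <- rowMeans(e)
  v <- var(ref)
  out <- e
  for (j in seq_len(ncol(e))) {
    if (is.na(v) || v == 0) {
      a <- 0; b <- 1
    } else {
      b <- cov(e[, j], ref) / v
      if (!is.finite(b) || b <= 0) {
        warning("non-positive calibration slope for sample ",
                colnames(e)[j], "; using identity calibration")
        a <- 0; b <- 1
      } else {
        a <- mean(e[, j]) - b * mean(ref)
      }
    }
    out[, j] <- asinh((e[, j] - a) / b) / log(2)
  }
  replace_exprs(study, out)
}

#' Drop genes with widespread zero coverage
#'
#' Removes genes whose value is exactly zero in at least `max_zero_fraction`
#' of samples (default: a quarter), preserving the order of survivors.
#'
#' @param study An [expression_study()].
#' @param max_zero_fraction Zero-fraction threshold; a gene with zero coverage
#'   in `>= max_zero_fraction` of samples is dropped.
#' @return The filtered study.
#' @export
filter_zero_coverage <- function(study, max_zero_fraction = 0.25) {
  stopifnot(inherits(study, "expression_study"))
  zf <- rowMeans(study$exprs == 0)
  replace_exprs(study, study$exprs[zf < max_zero_fraction, , drop = FALSE])
}

#' Keep protein-coding genes only
#'
#' @param study An [expression_study()].
#' @param annotation Data frame with columns `gene_id` and `biotype`; genes
#'   absent from the annotation are dropped.
#' @return The filtered study (possibly with zero genes, with a warning).
#' @export
filter_protein_coding <- function(study, annotation) {
  stopifnot(inherits(study, "expression_study"))
  if (!is.data.frame(annotation) || nrow(annotation) == 0)
    stop("empty biotype annotation")
  coding <- annotation$gene_id[annotation$biotype == "protein_coding"]
  keep <- rownames(study$exprs) %in% coding
  if (!any(keep)) warning("no protein-coding genes retained")
  replace_exprs(study, study$exprs[keep, , drop = FALSE])
}
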