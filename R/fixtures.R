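#' Worked-example target ledger
#'
#' A ready-made evidence ledger of 180 age-associated cancer targets used by
#' the worked examples: 30 genes with lifespan-extension evidence and a
#' concordant therapeutic direction (Group 1, of which 8 are tumor
#' suppressors), 21 extension genes with a discordant direction (Group 2),
#' 28 genes with shortening evidence only (Group 3) and 101 genes without
#' evidence or with no effect (Group 4).  The Group-1 rows carry real gene
#' symbols of well-characterized longevity/cancer regulators together with
#' their tissue-dysregulation counts and proposed therapeutic directions; the
#' Group 2-4 rows are synthetic placeholders (ids `TGT2_*`, `TGT3_*`,
#' `TGT4_*`) whose only meaningful property is their group membership, as the
#' file name indicates.
#'
#' @return Data frame with columns `gene_id`, `lifespan_effect`,
#'   `evidence_models`, `aging_direction`, `cancer_direction`, `is_tsg`,
#'   `n_tissues_dysregulated`.
#' @export
example_target_ledger <- function() {
  path <- system.file("extdata", "target_ledger_synthetic_example.tsv",
                      package = "dualtarget", mustWork = TRUE)
  read.delim(path, sep = "\t", stringsAsFactors = FALSE)
}
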