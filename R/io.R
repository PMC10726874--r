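# Plain-text serialization of every pipeline artifact: tab-separated matrices
# and metadata, GMT gene sets, hierarchy/ledger/lifespan tables, truth JSON.

write_tsv_file <- function(df, path, row_names = FALSE) {
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = row_names, col.names = TRUE)
  invisible(path)
}

read_tsv_file <- function(path, row_names = NULL) {
  read.delim(path, sep = "\t", stringsAsFactors = FALSE, row.names = row_names,
             check.names = FALSE)
}

#' Write an expression study as matrix + metadata TSV
#'
#' @param study An [expression_study()].
#' @param matrix_path,samples_path Output file paths (genes in rows, first
#'   column `gene_id`; metadata one row per sample).
#' @return Invisibly, the two paths.
#' @export
write_expression_tsv <- function(study, matrix_path, samples_path) {
  mat <- data.frame(gene_id = rownames(study$exprs), study$exprs,
                    check.names = FALSE, stringsAsFactors = FALSE)
  write_tsv_file(mat, matrix_path)
  write_tsv_file(study$samples, samples_path)
  invisible(c(matrix_path, samples_path))
}

#' Read an expression study from matrix + metadata TSV
#'
#' @param matrix_path,samples_path Files written by [write_expression_tsv()].
#' @param platform Platform label for the reconstructed study.
#' @return An [expression_study()] (without planted truth).
#' @export
read_expression_tsv <- function(matrix_path, samples_path,
                                platform = "rnaseq") {
  mat <- read_tsv_file(matrix_path)
  exprs <- as.matrix(mat[, -1, drop = FALSE])
  rownames(exprs) <- mat$gene_id
  samples <- read_tsv_file(samples_path)
  expression_study(exprs, samples, platform = platform)
}

#' Write gene sets in GMT format
#'
#' One set per line: name, description, then member genes, tab-separated.
#'
#' @param sets Named list of character vectors.
#' @param path Output file.
#' @param descriptions Optional character vector parallel to `sets`.
#' @return Invisibly, `path`.
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  if (is.null(names(sets)) || any(names(sets) == ""))
    stop("`sets` must be a named list")
  if (is.null(descriptions)) descriptions <- rep("na", length(sets))
  lines <- vapply(seq_along(sets), function(i) {
    paste(c(names(sets)[i], descriptions[i], sets[[i]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read gene sets from a GMT file
#'
#' @param path A GMT file.
#' @return Named list of character vectors; descriptions are kept in the
#'   `"descriptions"` attribute.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  sets <- lapply(fields, function(f) f[-(1:2)])
  names(sets) <- vapply(fields, `[`, character(1), 1)
  attr(sets, "descriptions") <- vapply(fields, `[`, character(1), 2)
  sets
}

#' Write / read the pathway hierarchy table
#'
#' @param collection A `pathway_collection`.
#' @param path TSV path (columns `pathway_id`, `process_name`).
#' @return Invisibly `path`; the reader returns the data frame.
#' @export
write_hierarchy_tsv <- function(collection, path) {
  write_tsv_file(hierarchy_table(collection), path)
}

#' @rdname write_hierarchy_tsv
#' @export
read_hierarchy_tsv <- function(path) read_tsv_file(path)

#' Write / read per-animal lifespan records
#'
#' @param records Data frame with columns `animal_id`, `arm`, `repeat_id`,
#'   `day`, `event`.
#' @param path TSV path.
#' @return Invisibly `path`; the reader returns the data frame.
#' @export
write_lifespan_tsv <- function(records, path) write_tsv_file(records, path)

#' @rdname write_lifespan_tsv
#' @export
read_lifespan_tsv <- function(path) read_tsv_file(path)

#' Write planted truth (or any report list) as JSON
#'
#' @param x A list.
#' @param path Output JSON path.
#' @return Invisibly, `path`.
#' @export
write_truth_json <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
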