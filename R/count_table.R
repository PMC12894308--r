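#' Genus-level count table with sample metadata
#'
#' The pipeline's entry point: a taxon x sample matrix of non-negative
#' integer sequence counts, a kingdom tag per taxon, and a treatment label
#' per sample.
#'
#' @param counts numeric matrix, taxa in rows (rownames required), samples
#'   in columns (colnames required); non-negative finite integers.
#' @param kingdom single string (recycled) or character vector of length
#'   `nrow(counts)` tagging each taxon, e.g. `"bacteria"` or `"fungi"`.
#' @param metadata data.frame with columns `sample_id` and `treatment`
#'   (optionally `replicate`) covering every sample column of `counts`.
#'
#' @return An object of class `count_table`: a list with elements `counts`,
#'   `kingdom` (named by taxon) and `metadata`.
#' @export
count_table <- function(counts, kingdom = "bacteria", metadata) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop_n2onet("counts must have taxon rownames and sample colnames", "n2onet_input_error")
  if (anyDuplicated(rownames(counts)))
    stop_n2onet("duplicate taxon IDs in counts", "n2onet_input_error")
  if (anyDuplicated(colnames(counts)))
    stop_n2onet("duplicate sample IDs in counts", "n2onet_input_error")
  if (any(!is.finite(counts)) || any(counts < 0))
    stop_n2onet("counts must be finite and non-negative", "n2onet_input_error")
  if (length(kingdom) == 1L) kingdom <- rep(kingdom, nrow(counts))
  if (length(kingdom) != nrow(counts))
    stop_n2onet("kingdom must be length 1 or nrow(counts)", "n2onet_input_error")
  names(kingdom) <- rownames(counts)
  metadata <- as.data.frame(metadata)
  if (!all(c("sample_id", "treatment") %in% names(metadata)))
    stop_n2onet("metadata needs columns sample_id and treatment", "n2onet_input_error")
  missing <- setdiff(colnames(counts), metadata$sample_id)
  if (length(missing))
    stop_n2onet(paste0("samples without metadata/treatment: ",
                       paste(missing, collapse = ", ")), "n2onet_consistency_error")
  metadata <- metadata[match(colnames(counts), metadata$sample_id), , drop = FALSE]
  rownames(metadata) <- NULL
  structure(list(counts = counts, kingdom = kingdom, metadata = metadata),
            class = "count_table")
}

#' @export
print.count_table <- function(x, ...) {
  cat(sprintf("<count_table> %d taxa (%s) x %d samples, %d treatments\n",
              nrow(x$counts), paste(unique(x$kingdom), collapse = "+"),
              ncol(x$counts), length(unique(x$metadata$treatment))))
  invisible(x)
}

#' Read / write count tables as TSV
#'
#' `read_count_table()` expects taxa in rows, a header row of sample IDs and
#' the taxon ID in the first column. `write_count_table()` writes the same
#' layout.
#'
#' @param path file path.
#' @param metadata_path TSV with `sample_id`, `treatment` (and optionally
#'   `replicate`) columns.
#' @inheritParams count_table
#' @return `read_count_table()` returns a [count_table]; the writer returns
#'   its input invisibly.
#' @export
read_count_table <- function(path, metadata_path, kingdom = "bacteria") {
  raw <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(raw[, -1, drop = FALSE])
  rownames(m) <- as.character(raw[[1]])
  meta <- utils::read.delim(metadata_path, stringsAsFactors = FALSE)
  count_table(m, kingdom = kingdom, metadata = meta)
}

#' @rdname read_count_table
#' @param table a [count_table].
#' @export
write_count_table <- function(table, path) {
  df <- data.frame(taxon = rownames(table$counts), table$counts,
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(table)
}

#' Read a genus table from a BIOM file
#'
#' Optional convenience reader for BIOM (format 2.1) feature tables, via the
#' biomformat package when it is available.
#'
#' @inheritParams read_count_table
#' @param metadata data.frame as in [count_table()].
#' @return A [count_table].
#' @export
read_biom_table <- function(path, metadata, kingdom = "bacteria") {
  if (!requireNamespace("biomformat", quietly = TRUE))
    stop_n2onet("the biomformat package is required to read BIOM files",
                "n2onet_input_error")
  b <- biomformat::read_biom(path)
  m <- as(biomformat::biom_data(b), "matrix")
  count_table(m, kingdom = kingdom, metadata = metadata)
}
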