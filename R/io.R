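#' Assemble and validate a longitudinal bulk study
#'
#' Aligns an expression matrix (genes x samples), a proportion matrix
#' (samples x cell types) and a sample metadata table by `sample_id`.
#' Proportions and metadata rows are reordered to the expression column
#' order; mismatched samples are an error.
#'
#' @param expression numeric matrix, genes as rows, samples as columns
#'   (column names are sample ids).
#' @param proportions numeric matrix, samples as rows (row names are sample
#'   ids), cell types as columns.
#' @param meta data.frame with at least `sample_id`, `subject_id`, `time`,
#'   `group`.
#' @return list of class `"bulk_study"` with aligned `expression`,
#'   `proportions`, `meta`.
#' @export
bulk_study <- function(expression, proportions, meta) {
  expression <- as.matrix(expression)
  proportions <- as.matrix(proportions)
  required <- c("sample_id", "subject_id", "time", "group")
  missing_cols <- setdiff(required, names(meta))
  if (length(missing_cols) > 0L) {
    stop("metadata is missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  ids <- colnames(expression)
  if (is.null(ids)) stop("expression matrix must have sample column names")
  if (anyDuplicated(ids)) stop("duplicated sample ids in expression matrix")
  miss_meta <- setdiff(ids, as.character(meta$sample_id))
  if (length(miss_meta) > 0L) {
    stop("sample(s) present in expression but absent from metadata: ",
         paste(utils::head(miss_meta, 5L), collapse = ", "))
  }
  if (is.null(rownames(proportions))) {
    if (nrow(proportions) != length(ids)) {
      stop("proportions lack sample row names and row count differs from",
           " the expression samples")
    }
    rownames(proportions) <- ids
  }
  miss_prop <- setdiff(ids, rownames(proportions))
  if (length(miss_prop) > 0L) {
    stop("sample(s) missing from the proportion matrix: ",
         paste(utils::head(miss_prop, 5L), collapse = ", "))
  }
  meta <- meta[match(ids, as.character(meta$sample_id)), , drop = FALSE]
  rownames(meta) <- NULL
  proportions <- proportions[ids, , drop = FALSE]
  structure(list(expression = expression, proportions = proportions,
                 meta = meta),
            class = "bulk_study")
}

#' @export
print.bulk_study <- function(x, ...) {
  cat("Longitudinal bulk study:", nrow(x$expression), "genes x",
      ncol(x$expression), "samples;",
      length(unique(x$meta$subject_id)), "subjects;",
      ncol(x$proportions), "cell types\n")
  invisible(x)
}

read_table_auto <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                    stringsAsFactors = FALSE)
}

#' Read a longitudinal bulk study from delimited text files
#'
#' Expression: first column `gene_id`, remaining columns one per sample.
#' Proportions: first column `sample_id`, remaining columns one per cell
#' type. Metadata: columns `sample_id`, `subject_id`, `time`, `group` (plus
#' covariates). TSV or CSV, detected by extension.
#'
#' @param expression_path,proportions_path,metadata_path file paths.
#' @return a [bulk_study()].
#' @export
read_study <- function(expression_path, proportions_path, metadata_path) {
  ex <- read_table_auto(expression_path)
  expression <- as.matrix(ex[, -1L, drop = FALSE])
  rownames(expression) <- as.character(ex[[1L]])
  pr <- read_table_auto(proportions_path)
  proportions <- as.matrix(pr[, -1L, drop = FALSE])
  rownames(proportions) <- as.character(pr[[1L]])
  meta <- read_table_auto(metadata_path)
  bulk_study(expression, proportions, meta)
}

#' Write a study to delimited text files
#'
#' Inverse of [read_study()]: writes `expression.tsv`, `proportions.tsv` and
#' `metadata.tsv` under `dir`.
#'
#' @param study a [bulk_study()] or [simulate_dataset()] result.
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
write_study <- function(study, dir) {
  if (inherits(study, "sim_dataset")) {
    study <- bulk_study(study$counts, study$proportions, study$meta)
  }
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ex <- data.frame(gene_id = rownames(study$expression),
                   study$expression, check.names = FALSE)
  utils::write.table(ex, file.path(dir, "expression.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  pr <- data.frame(sample_id = rownames(study$proportions),
                   study$proportions, check.names = FALSE)
  utils::write.table(pr, file.path(dir, "proportions.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(study$meta, file.path(dir, "metadata.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Filter genes by expression level, zero fraction, and variability
#'
#' Removes genes with normalized mean expression below `min_mean` (when the
#' input is on a TPM-like scale; disable with `mean_filter = FALSE` for raw
#' counts or methylation) or with a zero-count fraction of `max_zero_frac`
#' or more, then keeps the `top_cv` genes with the highest coefficient of
#' variation (sd/mean; ties at the boundary break by gene id). All criteria
#' are computed before any removal.
#'
#' @param study a [bulk_study()].
#' @param min_mean mean-expression threshold (default 1).
#' @param max_zero_frac maximum tolerated zero fraction, exclusive
#'   (default 0.20: genes with >= 20% zeros are removed).
#' @param top_cv number of genes kept by coefficient of variation (default
#'   2000, capped at the number remaining).
#' @param mean_filter apply the mean-expression threshold (default TRUE).
#' @return the filtered [bulk_study()].
#' @export
filter_genes <- function(study, min_mean = 1, max_zero_frac = 0.20,
                         top_cv = 2000L, mean_filter = TRUE) {
  stopifnot(inherits(study, "bulk_study"))
  E <- study$expression
  mu <- rowMeans(E)
  zf <- rowMeans(E == 0)
  keep <- rep(TRUE, nrow(E))
  if (mean_filter) keep <- keep & (mu >= min_mean)
  keep <- keep & (zf < max_zero_frac)
  if (!any(keep)) stop("all genes removed by the expression filters")
  cv <- ifelse(mu > 0, apply(E, 1L, stats::sd) / mu, 0)
  idx <- which(keep)
  idx <- idx[order(-cv[idx], rownames(E)[idx])]
  idx <- sort(idx[seq_len(min(top_cv, length(idx)))])
  study$expression <- E[idx, , drop = FALSE]
  study
}

#' Export a recovered subject panel as a long-format table
#'
#' @param panel a [subject_panel()] result (or plain J x K matrix).
#' @param path optional TSV path; when `NULL` the data.frame is returned
#'   only.
#' @return data.frame with columns `subject_id`, `cell_type`, `value`.
#' @export
export_panel <- function(panel, path = NULL) {
  m <- if (inherits(panel, "subject_panel")) panel$panel else as.matrix(panel)
  out <- data.frame(subject_id = rep(rownames(m), ncol(m)),
                    cell_type = rep(colnames(m), each = nrow(m)),
                    value = as.numeric(m), stringsAsFactors = FALSE)
  if (!is.null(path)) {
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  out
}
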