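#' One batch of single-cell expression data
#'
#' Container for one batch's cells-by-genes expression matrix together with
#' cell and gene identifiers, the batch identifier, and (optionally) per-cell
#' ground-truth labels used only for evaluation.
#'
#' @param values Numeric matrix, cells in rows, genes in columns. Row names
#'   are used as cell ids and column names as gene ids when `cell_ids` /
#'   `gene_ids` are not given.
#' @param batch_id Single string naming the batch.
#' @param cell_ids,gene_ids Character vectors of unique identifiers.
#' @param labels Optional per-cell labels (character), either unnamed in cell
#'   order or named by cell id.
#' @param check_negative If `TRUE` (raw data), negative entries are an error.
#'   Normalized matrices are constructed with `check_negative = FALSE`.
#' @return An object of class `ExpressionMatrix`.
#' @export
expression_matrix <- function(values, batch_id = "batch1",
                              cell_ids = rownames(values),
                              gene_ids = colnames(values),
                              labels = NULL, check_negative = TRUE) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("'values' must be a numeric matrix (cells x genes)")
  if (is.null(cell_ids)) cell_ids <- paste0("cell", seq_len(nrow(values)))
  if (is.null(gene_ids)) gene_ids <- paste0("gene", seq_len(ncol(values)))
  cell_ids <- as.character(cell_ids)
  gene_ids <- as.character(gene_ids)
  if (length(cell_ids) != nrow(values))
    stop("length(cell_ids) must equal nrow(values)")
  if (length(gene_ids) != ncol(values))
    stop("length(gene_ids) must equal ncol(values)")
  if (anyDuplicated(cell_ids))
    stop("duplicate cell ids in batch '", batch_id, "': ",
         paste(utils::head(cell_ids[duplicated(cell_ids)], 3), collapse = ", "))
  if (anyDuplicated(gene_ids))
    stop("duplicate gene ids in batch '", batch_id, "'")
  if (!all(is.finite(values)))
    stop("non-finite values in expression matrix of batch '", batch_id, "'")
  if (check_negative && any(values < 0))
    stop("negative expression values in batch '", batch_id, "'")
  if (!is.null(labels)) {
    labels <- stats::setNames(as.character(labels), names(labels))
    if (!is.null(names(labels))) {
      missing <- setdiff(cell_ids, names(labels))
      if (length(missing))
        stop("labels missing for ", length(missing), " cells (e.g. ",
             missing[1], ")")
      labels <- unname(labels[cell_ids])
    } else if (length(labels) != length(cell_ids)) {
      stop("labels must have one entry per cell")
    }
  }
  dimnames(values) <- list(cell_ids, gene_ids)
  structure(list(values = values, cell_ids = cell_ids, gene_ids = gene_ids,
                 batch_id = as.character(batch_id), labels = labels),
            class = "ExpressionMatrix")
}

#' @export
print.ExpressionMatrix <- function(x, ...) {
  cat("ExpressionMatrix '", x$batch_id, "': ", nrow(x$values), " cells x ",
      ncol(x$values), " genes", sep = "")
  if (!is.null(x$labels))
    cat("; ", length(unique(x$labels)), " label(s)", sep = "")
  cat("\n")
  invisible(x)
}

#' @export
dim.ExpressionMatrix <- function(x) dim(x$values)

#' Read an expression matrix from disk
#'
#' Dense CSV/TSV files are cells x genes with a header row of gene names and
#' the first column holding cell ids. MatrixMarket input is a directory
#' containing `matrix.mtx` plus gene (row) and cell (column) id files; by the
#' community convention the matrix on disk is genes x cells and is transposed
#' on load.
#'
#' @param path File (csv/tsv) or directory (mtx) path.
#' @param format One of `"auto"`, `"csv"`, `"tsv"`, `"mtx"`. `"auto"` picks by
#'   extension, or `"mtx"` for a directory.
#' @param batch_id Batch name; defaults to the file/directory base name.
#' @param labels_path Optional two-column file (cell_id, label), joined by id.
#' @return An [expression_matrix()].
#' @export
read_expression <- function(path, format = c("auto", "csv", "tsv", "mtx"),
                            batch_id = NULL, labels_path = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file or directory: ", path)
  if (format == "auto") {
    format <- if (dir.exists(path)) "mtx"
      else if (grepl("\\.tsv$|\\.txt$", path, ignore.case = TRUE)) "tsv"
      else "csv"
  }
  if (is.null(batch_id))
    batch_id <- sub("\\.[^.]*$", "", basename(path))
  if (format %in% c("csv", "tsv")) {
    sep <- if (format == "csv") "," else "\t"
    dt <- data.table::fread(path, sep = sep, header = TRUE,
                            data.table = FALSE, check.names = FALSE)
    if (ncol(dt) < 2) stop("expected cell-id column plus >=1 gene column: ", path)
    cell_ids <- as.character(dt[[1]])
    values <- as.matrix(dt[, -1, drop = FALSE])
    if (!is.numeric(values))
      stop("non-numeric expression values in ", path)
    rownames(values) <- cell_ids
  } else {
    values <- .read_mtx_dir(path)
  }
  labels <- if (!is.null(labels_path)) read_labels(labels_path) else NULL
  expression_matrix(values, batch_id = batch_id, labels = labels)
}

# MTX triplet directory: genes x cells on disk, transposed to cells x genes.
.read_mtx_dir <- function(dir) {
  find1 <- function(patterns, what) {
    for (p in patterns) {
      hit <- list.files(dir, pattern = p, full.names = TRUE)
      if (length(hit)) return(hit[1])
    }
    stop("no ", what, " file found in MTX directory ", dir)
  }
  mtx <- find1(c("\\.mtx$"), "matrix (.mtx)")
  genes_f <- find1(c("^genes\\.", "^features\\.", "genes", "features"), "gene id")
  cells_f <- find1(c("^barcodes\\.", "^cells\\.", "barcodes", "cells"), "cell id")
  m <- Matrix::readMM(mtx)
  genes <- data.table::fread(genes_f, header = FALSE, data.table = FALSE)[[1]]
  cells <- data.table::fread(cells_f, header = FALSE, data.table = FALSE)[[1]]
  if (nrow(m) != length(genes))
    stop("MTX row count (", nrow(m), ") != number of gene ids (",
         length(genes), ") in ", dir)
  if (ncol(m) != length(cells))
    stop("MTX column count (", ncol(m), ") != number of cell ids (",
         length(cells), ") in ", dir)
  values <- t(as.matrix(m))
  dimnames(values) <- list(as.character(cells), as.character(genes))
  values
}

#' Read a two-column (cell_id, label) file
#'
#' Accepts CSV or TSV, with or without a header line. Labels are joined to
#' cells by id downstream, never by position.
#'
#' @param path File path.
#' @return Named character vector of labels, names = cell ids.
#' @export
read_labels <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  dt <- data.table::fread(path, header = "auto", data.table = FALSE)
  if (ncol(dt) < 2) stop("label file must have two columns (cell_id, label): ", path)
  out <- as.character(dt[[2]])
  names(out) <- as.character(dt[[1]])
  if (anyDuplicated(names(out))) stop("duplicate cell ids in label file ", path)
  out
}

#' Write / read a corrected embedding
#'
#' The on-disk format is CSV with columns `cell_id`, `batch_id`,
#' `z_1` ... `z_k`, rows in the embedding's combined cell order. A
#' save/load round trip preserves values to float-formatting precision.
#'
#' @param result An `EmbeddingResult` from [extract_embedding()] (or the
#'   data.frame of a previous [read_embedding()]).
#' @param path Output CSV path.
#' @export
write_embedding <- function(result, path) {
  df <- if (is.data.frame(result)) result else result$combined
  stopifnot(all(c("cell_id", "batch_id") %in% colnames(df)))
  ok <- tryCatch({
    data.table::fwrite(df, path, sep = ",")
    TRUE
  }, error = function(e) stop("cannot write embedding to ", path, ": ",
                              conditionMessage(e)))
  invisible(ok)
}

#' @rdname write_embedding
#' @return `read_embedding` returns a data.frame with the columns above.
#' @export
read_embedding <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- data.table::fread(path, data.table = FALSE)
  if (!all(c("cell_id", "batch_id") %in% colnames(df)))
    stop("not an embedding file (missing cell_id/batch_id columns): ", path)
  df$cell_id <- as.character(df$cell_id)
  df$batch_id <- as.character(df$batch_id)
  df
}

#' Export a cross-batch similarity table as CSV
#'
#' @param table A `SimilarityTable` (see [metaneighbor_scores()]).
#' @param path Output CSV path.
#' @export
write_similarity <- function(table, path) {
  data.table::fwrite(as.data.frame(unclass(table)), path, sep = ",")
  invisible(TRUE)
}
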