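#' Construct an expression count matrix
#'
#' The universal input container of the package: an isoforms x cells matrix
#' of non-negative expression estimates together with cell group labels and
#' per-cell library sizes. Expression values need not be integers --
#' transcript-abundance estimators routinely return fractional values; tests
#' whose likelihood requires counts round internally and document it.
#'
#' @param values numeric matrix, isoforms in rows, cells in columns; no
#'   negative entries.
#' @param isoform_ids character vector of unique row identifiers; defaults to
#'   existing rownames or `iso1, iso2, ...`.
#' @param cell_ids character vector of unique column identifiers; defaults to
#'   existing colnames or `cell1, cell2, ...`.
#' @param group_labels vector of group identifiers, one per cell. Exactly two
#'   distinct labels are required by the DE tests (validated there, not here,
#'   so that null-resampling intermediates remain representable).
#' @param library_sizes positive numeric per cell; defaults to column sums.
#'   Override with generative library sizes when the truth is known (the
#'   simulator does this).
#' @return an object of class `count_matrix`: a list with fields `values`,
#'   `isoform_ids`, `cell_ids`, `group_labels`, `library_sizes`.
#' @examples
#' m <- count_matrix(matrix(c(1, 2, 0, 3), 2, 2), group_labels = c("a", "b"))
#' m$library_sizes
#' @export
count_matrix <- function(values, isoform_ids = NULL, cell_ids = NULL,
                         group_labels = NULL, library_sizes = NULL) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(isoform_ids)) {
    isoform_ids <- rownames(values)
    if (is.null(isoform_ids)) isoform_ids <- paste0("iso", seq_len(nrow(values)))
  }
  if (is.null(cell_ids)) {
    cell_ids <- colnames(values)
    if (is.null(cell_ids)) cell_ids <- paste0("cell", seq_len(ncol(values)))
  }
  isoform_ids <- as.character(isoform_ids)
  cell_ids <- as.character(cell_ids)
  if (is.null(group_labels)) group_labels <- rep("group1", ncol(values))
  group_labels <- as.character(group_labels)
  if (is.null(library_sizes)) library_sizes <- colSums(values)
  library_sizes <- as.numeric(library_sizes)
  if (length(isoform_ids) != nrow(values))
    stop("isoform_ids length (", length(isoform_ids),
         ") does not match row count (", nrow(values), ")")
  if (length(cell_ids) != ncol(values))
    stop("cell_ids length (", length(cell_ids),
         ") does not match column count (", ncol(values), ")")
  dimnames(values) <- list(isoform_ids, cell_ids)
  m <- structure(
    list(values = values, isoform_ids = isoform_ids, cell_ids = cell_ids,
         group_labels = group_labels, library_sizes = library_sizes),
    class = "count_matrix")
  validate_count_matrix(m)
  m
}

#' Validate a count matrix
#'
#' Checks the structural invariants: matching dimensions, unique ids, no
#' negative values, strictly positive library sizes.
#'
#' @param m a `count_matrix`.
#' @return `m`, invisibly, if valid; otherwise an error.
#' @export
validate_count_matrix <- function(m) {
  stopifnot(inherits(m, "count_matrix"))
  v <- m$values
  if (length(m$isoform_ids) != nrow(v))
    stop("isoform_ids length (", length(m$isoform_ids),
         ") does not match row count (", nrow(v), ")")
  if (length(m$cell_ids) != ncol(v))
    stop("cell_ids length (", length(m$cell_ids),
         ") does not match column count (", ncol(v), ")")
  if (anyDuplicated(m$isoform_ids)) stop("duplicated isoform ids")
  if (anyDuplicated(m$cell_ids)) stop("duplicated cell ids")
  if (length(m$group_labels) != ncol(v))
    stop("group_labels length does not match cell count")
  if (length(m$library_sizes) != ncol(v))
    stop("library_sizes length does not match cell count")
  if (anyNA(v)) stop("expression values contain NA")
  if (any(v < 0)) stop("negative expression values are not allowed")
  if (any(!is.finite(m$library_sizes)) || any(m$library_sizes <= 0))
    stop("library_sizes must be strictly positive and finite")
  invisible(m)
}

#' @export
print.count_matrix <- function(x, ...) {
  cat("count_matrix:", nrow(x$values), "isoforms x", ncol(x$values), "cells\n")
  tab <- table(x$group_labels)
  cat("groups:", paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  cat("library sizes: [", format(min(x$library_sizes), digits = 4), ",",
      format(max(x$library_sizes), digits = 4), "]\n")
  invisible(x)
}

#' @export
dim.count_matrix <- function(x) dim(x$values)

#' Subset the cells of a count matrix
#'
#' Keeps all isoform rows and the requested cells, carrying labels and
#' library sizes along. Used by the split machinery and null resampling.
#'
#' @param m a `count_matrix`.
#' @param cells integer indices or cell ids.
#' @param group_labels optional replacement labels for the kept cells.
#' @return a `count_matrix` over the selected cells.
#' @export
subset_cells <- function(m, cells, group_labels = NULL) {
  validate_count_matrix(m)
  if (is.character(cells)) {
    idx <- match(cells, m$cell_ids)
    if (anyNA(idx)) stop("unknown cell ids: ", paste(cells[is.na(idx)], collapse = ", "))
  } else idx <- as.integer(cells)
  count_matrix(m$values[, idx, drop = FALSE],
               isoform_ids = m$isoform_ids,
               cell_ids = m$cell_ids[idx],
               group_labels = if (is.null(group_labels)) m$group_labels[idx] else group_labels,
               library_sizes = m$library_sizes[idx])
}

#' Read an expression matrix from disk
#'
#' Two on-disk layouts are supported: a tab-separated table with a header row
#' of cell ids and the isoform ids in the first column, and Matrix Market
#' (`.mtx`) with sidecar id files `<path>.rownames` / `<path>.colnames`
#' (one id per line). An optional two-column tab-separated labels file
#' (cell id, group) attaches group labels.
#'
#' @param path file path of the matrix.
#' @param format `"tsv"` or `"mtx"`.
#' @param labels optional path of the cell-to-group labels file.
#' @param library_sizes optional numeric vector overriding the default
#'   column-sum library sizes.
#' @return a validated [count_matrix()].
#' @export
read_matrix <- function(path, format = c("tsv", "mtx"), labels = NULL,
                        library_sizes = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "tsv") {
    dt <- data.table::fread(path, sep = "\t", header = TRUE, data.table = FALSE)
    if (ncol(dt) < 2) stop("malformed tsv matrix (need id column plus cells): ", path)
    ids <- as.character(dt[[1]])
    vals <- as.matrix(dt[, -1, drop = FALSE])
    if (!is.numeric(vals)) {
      bad <- which(!vapply(dt[-1], is.numeric, logical(1)))[1]
      stop("non-numeric values in column ", bad + 1, " of ", path)
    }
    m <- try(count_matrix(vals, isoform_ids = ids, cell_ids = colnames(dt)[-1]),
             silent = TRUE)
  } else {
    vals <- as.matrix(Matrix::readMM(path))
    rn_file <- paste0(path, ".rownames")
    cn_file <- paste0(path, ".colnames")
    if (!file.exists(rn_file) || !file.exists(cn_file))
      stop("mtx sidecar id files missing: expected ", rn_file, " and ", cn_file)
    ids <- readLines(rn_file)
    cells <- readLines(cn_file)
    m <- try(count_matrix(vals, isoform_ids = ids, cell_ids = cells), silent = TRUE)
  }
  if (inherits(m, "try-error"))
    stop("validation failed for ", path, ": ", attr(m, "condition")$message)
  if (!is.null(labels)) {
    lab <- utils::read.table(labels, sep = "\t", header = FALSE,
                             col.names = c("cell_id", "group"),
                             colClasses = "character")
    idx <- match(m$cell_ids, lab$cell_id)
    if (anyNA(idx)) stop("labels file does not cover all cells: ", labels)
    m$group_labels <- lab$group[idx]
  }
  if (!is.null(library_sizes)) m$library_sizes <- as.numeric(library_sizes)
  validate_count_matrix(m)
}

#' Write an expression matrix to disk
#'
#' Inverse of [read_matrix()]; round-trips are value-identical.
#'
#' @param m a `count_matrix`.
#' @param path output file path.
#' @param format `"tsv"` or `"mtx"` (the latter writes sidecar id files).
#' @param labels optional path for a two-column cell/group labels file.
#' @return `path`, invisibly.
#' @export
write_matrix <- function(m, path, format = c("tsv", "mtx"), labels = NULL) {
  validate_count_matrix(m)
  format <- match.arg(format)
  if (format == "tsv") {
    dt <- data.table::data.table(isoform_id = m$isoform_ids)
    for (j in seq_along(m$cell_ids)) dt[[m$cell_ids[j]]] <- m$values[, j]
    data.table::fwrite(dt, path, sep = "\t")
  } else {
    Matrix::writeMM(Matrix::Matrix(m$values, sparse = TRUE), path)
    writeLines(m$isoform_ids, paste0(path, ".rownames"))
    writeLines(m$cell_ids, paste0(path, ".colnames"))
  }
  if (!is.null(labels))
    utils::write.table(data.frame(m$cell_ids, m$group_labels), labels,
                       sep = "\t", quote = FALSE, row.names = FALSE,
                       col.names = FALSE)
  invisible(path)
}

#' Counts per million
#'
#' Scales each cell to its library size: `cpm[i, j] = values[i, j] /
#' library_sizes[j] * 1e6`. When library sizes are the column sums this is
#' the usual CPM; with generative library sizes it is the simulator-true
#' normalisation. For data without transcript lengths CPM doubles as the
#' TPM surrogate used in expression stratification.
#'
#' @param m a `count_matrix`.
#' @return a numeric matrix of the same shape.
#' @export
compute_cpm <- function(m) {
  validate_count_matrix(m)
  sweep(m$values, 2, m$library_sizes, `/`) * 1e6
}

#' log2(CPM + 1)
#'
#' The input scale of the normal-theory tests. Zero expression maps to zero.
#'
#' @param m a `count_matrix`.
#' @return a numeric matrix of the same shape.
#' @export
log_cpm <- function(m) log2(compute_cpm(m) + 1)

#' Stratify isoforms by expression level
#'
#' Partitions isoforms into a high-expression and a low-expression stratum.
#' An isoform is "high" when its normalised expression exceeds `threshold`
#' in strictly more than `cell_fraction` of the cells (the conventional
#' "above 1 TPM in more than 25% of cells" rule, applied here on the CPM
#' scale); every other isoform is "low". The two strata always form a
#' disjoint partition of the isoform set.
#'
#' @param m a `count_matrix`.
#' @param threshold normalised-expression threshold (default 1).
#' @param cell_fraction fraction of cells that must exceed it, strict
#'   inequality (default 0.25).
#' @return a list with character-vector elements `high` and `low` of
#'   isoform ids.
#' @export
stratify_by_expression <- function(m, threshold = 1, cell_fraction = 0.25) {
  cpm <- compute_cpm(m)
  frac_above <- rowMeans(cpm > threshold)
  high <- frac_above > cell_fraction
  list(high = m$isoform_ids[high], low = m$isoform_ids[!high])
}
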