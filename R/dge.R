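#' Digital expression matrix
#'
#' Container for a cell-barcode x gene matrix of read counts ("tags").  The
#' chemistry carries no unique molecular identifiers, so entries are read
#' counts, not deduplicated molecules; after [normalize_tags()] entries are
#' fractional and each row sums to the normalization total.
#'
#' @param counts matrix or sparse `Matrix` with cell barcodes as row names
#'   and gene ids as column names; all entries must be >= 0.
#' @param sample_label free-text label for the sample (e.g. `"E-side"`).
#' @param normalized_total `NULL` for raw counts, otherwise the per-cell
#'   total the rows were scaled to.
#' @return An object of class `dge`.
#' @export
#' @examples
#' m <- matrix(c(3, 1, 0, 2), 2, 2,
#'             dimnames = list(c("AAAA", "CCCC"), c("g1", "g2")))
#' dge(m, sample_label = "demo")
dge <- function(counts, sample_label = NA_character_, normalized_total = NULL) {
  counts <- methods::as(methods::as(Matrix::Matrix(counts, sparse = TRUE),
                                    "generalMatrix"), "CsparseMatrix")
  if ((nrow(counts) > 0 && is.null(rownames(counts))) ||
      (ncol(counts) > 0 && is.null(colnames(counts)))) {
    stop_invalid("`counts` must have barcode row names and gene column names")
  }
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    dimnames(counts) <- list(
      if (is.null(rownames(counts))) character(0) else rownames(counts),
      if (is.null(colnames(counts))) character(0) else colnames(counts)
    )
  }
  if (anyDuplicated(rownames(counts))) stop_invalid("duplicate barcodes in `counts`")
  if (anyDuplicated(colnames(counts))) stop_invalid("duplicate genes in `counts`")
  if (length(counts@x) && min(counts@x) < 0) stop_invalid("negative counts")
  obj <- structure(
    list(counts = counts, sample_label = sample_label,
         normalized_total = normalized_total),
    class = "dge"
  )
  validate_dge(obj)
}

validate_dge <- function(x) {
  if (!is.null(x$normalized_total)) {
    rs <- Matrix::rowSums(x$counts)
    if (nrow(x$counts) > 0 &&
        any(abs(rs - x$normalized_total) > 1e-6 * x$normalized_total)) {
      stop_invalid("row sums do not match normalized_total")
    }
  }
  x
}

#' @export
print.dge <- function(x, ...) {
  cat(sprintf("dge: %d cells x %d genes [%s, %s]\n",
              nrow(x$counts), ncol(x$counts),
              ifelse(is.na(x$sample_label), "unlabelled", x$sample_label),
              if (is.null(x$normalized_total)) "raw counts"
              else sprintf("normalized to %g tags", x$normalized_total)))
  invisible(x)
}

#' @export
dim.dge <- function(x) dim(x$counts)

#' Barcodes and genes of a dge
#' @param x a `dge`.
#' @return Character vector of cell barcodes / gene ids.
#' @export
barcodes <- function(x) {
  r <- rownames(x$counts)
  if (is.null(r)) character(0) else r
}

#' @rdname barcodes
#' @export
genes <- function(x) {
  g <- colnames(x$counts)
  if (is.null(g)) character(0) else g
}

#' Subset a dge by barcode and/or gene
#' @param x a `dge`.
#' @param i,j barcode and gene indices (any form accepted by `[`).
#' @param ... ignored.
#' @export
`[.dge` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_len(nrow(x$counts))
  if (missing(j)) j <- seq_len(ncol(x$counts))
  cnt <- x$counts[i, j, drop = FALSE]
  structure(list(counts = cnt, sample_label = x$sample_label,
                 normalized_total = x$normalized_total),
            class = "dge")
}

#' Write a dge in MatrixMarket or dense TSV form
#'
#' `format = "mtx"` writes `<dir>/matrix.mtx` plus `barcodes.tsv` and
#' `genes.tsv` (the conventional sparse triplet layout); `format = "tsv"`
#' writes a single dense table with barcodes as the first column.  A
#' `meta.json` records the sample label and normalization state.
#'
#' @param x a `dge`.
#' @param path output directory (`mtx`) or file (`tsv`).
#' @param format `"mtx"` or `"tsv"`.
#' @return `path`, invisibly.
#' @export
write_dge <- function(x, path, format = c("mtx", "tsv")) {
  stopifnot(inherits(x, "dge"))
  format <- match.arg(format)
  meta <- list(sample_label = x$sample_label,
               normalized_total = x$normalized_total,
               n_cells = nrow(x$counts), n_genes = ncol(x$counts))
  if (format == "mtx") {
    dir.create(path, showWarnings = FALSE, recursive = TRUE)
    atomic_write(file.path(path, "matrix.mtx"), function(tmp) {
      Matrix::writeMM(x$counts, tmp)
    })
    atomic_write(file.path(path, "barcodes.tsv"), function(tmp) {
      writeLines(rownames(x$counts), tmp)
    })
    atomic_write(file.path(path, "genes.tsv"), function(tmp) {
      writeLines(colnames(x$counts), tmp)
    })
    atomic_write(file.path(path, "meta.json"), function(tmp) {
      jsonlite::write_json(meta, tmp, auto_unbox = TRUE, null = "null",
                           digits = NA)
    })
  } else {
    df <- as.data.frame(as.matrix(x$counts))
    df <- cbind(barcode = rownames(x$counts), df)
    atomic_write(path, function(tmp) {
      write.table(df, tmp, sep = "\t", quote = FALSE, row.names = FALSE)
    })
  }
  invisible(path)
}

#' @rdname write_dge
#' @export
read_dge <- function(path, format = c("mtx", "tsv")) {
  format <- match.arg(format)
  if (format == "mtx") {
    m <- methods::as(Matrix::readMM(file.path(path, "matrix.mtx")), "CsparseMatrix")
    rownames(m) <- readLines(file.path(path, "barcodes.tsv"))
    colnames(m) <- readLines(file.path(path, "genes.tsv"))
    meta_path <- file.path(path, "meta.json")
    meta <- if (file.exists(meta_path)) jsonlite::read_json(meta_path) else list()
    lab <- if (is.null(meta$sample_label)) NA_character_ else meta$sample_label
    dge(m, sample_label = lab, normalized_total = meta$normalized_total)
  } else {
    df <- read.delim(path, check.names = FALSE)
    m <- as.matrix(df[, -1, drop = FALSE])
    rownames(m) <- df[[1]]
    dge(m)
  }
}
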