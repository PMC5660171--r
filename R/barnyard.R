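#' Map genes to species by gene-id prefix
#'
#' Convenience for combined two-species references whose gene ids carry a
#' species namespace prefix (e.g. `HUMAN_G001`).
#'
#' @param genes character vector of gene ids.
#' @param sep separator between prefix and gene name (default `"_"`).
#' @return Named character vector mapping each gene id to its species.
#' @export
species_from_prefix <- function(genes, sep = "_") {
  setNames(sub(paste0(sep, ".*$"), "", genes), genes)
}

#' Per-barcode transcript totals by species
#'
#' For a mixed-species (barnyard) run, sums each barcode's reads over the
#' genes of each species.  Exactly two species are expected; every gene of
#' the matrix must be mapped.
#'
#' @param x a [dge()].
#' @param species_of_gene named character vector mapping every gene of `x`
#'   to one of two species (see [species_from_prefix()]).
#' @return Data frame of class `species_calls` with columns `barcode`,
#'   `reads_a`, `reads_b`, `purity`, `call` (all `NA` until
#'   [classify_species()]), plus attributes `species_a` / `species_b`.
#' @export
species_counts <- function(x, species_of_gene) {
  stopifnot(inherits(x, "dge"))
  g <- genes(x)
  unmapped <- setdiff(g, names(species_of_gene))
  if (length(unmapped)) {
    stop_invalid("genes with no species mapping: ",
                 paste(unmapped, collapse = ", "))
  }
  sp <- species_of_gene[g]
  lv <- sort(unique(sp))
  if (length(lv) != 2L) {
    stop_invalid("expected exactly 2 species, got: ", paste(lv, collapse = ", "))
  }
  a <- Matrix::rowSums(x$counts[, sp == lv[1], drop = FALSE])
  b <- Matrix::rowSums(x$counts[, sp == lv[2], drop = FALSE])
  out <- data.frame(barcode = barcodes(x), reads_a = as.numeric(a),
                    reads_b = as.numeric(b),
                    purity = rep(NA_real_, length(a)),
                    call = rep(NA_character_, length(a)),
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "species_a") <- lv[1]
  attr(out, "species_b") <- lv[2]
  class(out) <- c("species_calls", "data.frame")
  out
}

#' Call each barcode's species
#'
#' A barcode is called species A when `reads_a / (reads_a + reads_b)` is at
#' least `purity_threshold` (symmetrically for B); otherwise it is
#' `"mixed"`.  Mixed-species barcodes indicate wells that captured more than
#' one cell.  Zero-read barcodes are called `"mixed"` with `purity = NA` and
#' flagged, and should be excluded from purity statistics.
#'
#' @param calls a `species_calls` data frame from [species_counts()].
#' @param purity_threshold proportion in (0.5, 1\] (default 0.9).
#' @return The `species_calls` with `purity`, `call` and `zero_reads`
#'   columns filled in.
#' @export
classify_species <- function(calls, purity_threshold = 0.9) {
  stopifnot(inherits(calls, "species_calls"))
  if (length(purity_threshold) != 1L || purity_threshold <= 0.5 ||
      purity_threshold > 1) {
    stop_invalid("`purity_threshold` must lie in (0.5, 1]")
  }
  total <- calls$reads_a + calls$reads_b
  zero <- total == 0
  purity <- ifelse(zero, NA_real_, pmax(calls$reads_a, calls$reads_b) / total)
  frac_a <- ifelse(zero, NA_real_, calls$reads_a / total)
  call <- ifelse(zero, "mixed",
                 ifelse(frac_a >= purity_threshold, attr(calls, "species_a"),
                        ifelse(1 - frac_a >= purity_threshold,
                               attr(calls, "species_b"), "mixed")))
  calls$purity <- purity
  calls$call <- call
  calls$zero_reads <- zero
  calls
}

#' Write species calls as TSV
#' @param calls a `species_calls` data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_species_calls <- function(calls, path) {
  atomic_write(path, function(tmp) {
    write.table(as.data.frame(calls), tmp, sep = "\t", quote = FALSE,
                row.names = FALSE)
  })
  invisible(path)
}
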