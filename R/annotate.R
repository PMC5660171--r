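#' Marker rule set for cell classification
#'
#' Configuration for marker-based cell typing.  Each class rule names the
#' marker genes whose positivity identifies the class (`mode = "any"`: at
#' least one positive marker; `mode = "all"`: every marker positive).  When
#' a cell satisfies several rules the first class in `priority` wins and the
#' conflict is logged.  The epithelial/mesenchymal gene partition drives the
#' EMT trichotomy of tumour cells ([classify_emt()]).
#'
#' The default partition assigns `EPCAM` and `CDH1` to the epithelial set
#' and `ACTA2`, `VIM`, `FN1`, `ZEB1`, `THY1`, `CD44` to the mesenchymal set.
#' `CD44` and `THY1` are contested markers (both are also expressed by
#' stem-like epithelial cells); the partition is configuration, not fact.
#'
#' @param class_rules named list; each element is `list(genes =, mode =)`
#'   (mode defaults to `"any"`).  A bare character vector is shorthand for
#'   an any-of rule.
#' @param priority class evaluation order (default: order of `class_rules`).
#' @param positivity_threshold normalized-tag cutoff at or above which a
#'   gene is called positive in a cell (default 1).
#' @param epithelial_genes,mesenchymal_genes disjoint marker sets for the
#'   EMT trichotomy.
#' @param cancer_classes class labels treated as tumour cells when
#'   assigning EMT states.
#' @return An object of class `marker_rules`.
#' @export
#' @examples
#' marker_rules(list(T_cell = "CD3D", macrophage = "CD68", cancer = "EPCAM"))
marker_rules <- function(class_rules,
                         priority = names(class_rules),
                         positivity_threshold = 1,
                         epithelial_genes = c("EPCAM", "CDH1"),
                         mesenchymal_genes = c("ACTA2", "VIM", "FN1", "ZEB1",
                                               "THY1", "CD44"),
                         cancer_classes = "cancer") {
  if (!is.list(class_rules) || length(class_rules) == 0L ||
      is.null(names(class_rules)) || any(!nzchar(names(class_rules)))) {
    stop_invalid("`class_rules` must be a non-empty named list")
  }
  class_rules <- lapply(class_rules, function(r) {
    if (is.character(r)) r <- list(genes = r, mode = "any")
    if (is.null(r$mode)) r$mode <- "any"
    if (!r$mode %in% c("any", "all")) stop_invalid("rule mode must be any/all")
    if (!is.character(r$genes) || length(r$genes) == 0L ||
        any(!nzchar(r$genes))) {
      stop_invalid("every rule needs at least one non-empty gene name")
    }
    r[c("genes", "mode")]
  })
  if (!setequal(priority, names(class_rules))) {
    stop_invalid("`priority` must be a permutation of the class names")
  }
  if (length(intersect(epithelial_genes, mesenchymal_genes))) {
    stop_invalid("epithelial and mesenchymal gene sets must be disjoint")
  }
  if (length(positivity_threshold) != 1L || positivity_threshold < 0) {
    stop_invalid("`positivity_threshold` must be a single number >= 0")
  }
  structure(
    list(class_rules = class_rules, priority = priority,
         positivity_threshold = positivity_threshold,
         epithelial_genes = epithelial_genes,
         mesenchymal_genes = mesenchymal_genes,
         cancer_classes = cancer_classes),
    class = "marker_rules"
  )
}

#' Read / write marker rules as YAML
#'
#' @param path YAML file path.
#' @param rules a [marker_rules()] object.
#' @return `read_marker_rules()` returns a `marker_rules`;
#'   `write_marker_rules()` returns `path` invisibly.
#' @export
read_marker_rules <- function(path) {
  cfg <- yaml::read_yaml(path)
  do.call(marker_rules, cfg[intersect(names(cfg), names(formals(marker_rules)))])
}

#' @rdname read_marker_rules
#' @export
write_marker_rules <- function(rules, path) {
  stopifnot(inherits(rules, "marker_rules"))
  atomic_write(path, function(tmp) yaml::write_yaml(unclass(rules), tmp))
  invisible(path)
}

#' Positivity of an expression value
#'
#' A cell is positive for a gene when its (normalized) tag count is at or
#' above the threshold; the boundary is inclusive.
#'
#' @param value non-negative expression value(s), normalized tags.
#' @param threshold positivity cutoff (default 1).
#' @return Logical vector.
#' @export
is_positive <- function(value, threshold = 1) {
  if (any(value < 0, na.rm = TRUE)) stop_invalid("expression values must be >= 0")
  value >= threshold
}

# cells x genes logical positivity matrix, absent genes all-negative
positivity_matrix <- function(x, gene_set, threshold, warn_missing = TRUE) {
  present <- intersect(gene_set, genes(x))
  missing <- setdiff(gene_set, genes(x))
  if (length(missing) && warn_missing) {
    warning("marker genes absent from matrix (treated as negative): ",
            paste(missing, collapse = ", "), call. = FALSE)
  }
  m <- matrix(FALSE, nrow = nrow(x$counts), ncol = length(gene_set),
              dimnames = list(barcodes(x), gene_set))
  if (length(present)) {
    m[, present] <- as.matrix(x$counts[, present, drop = FALSE] >= threshold)
  }
  m
}

#' Classify cells by marker rules
#'
#' Evaluates every class rule on every cell; the first satisfied class in
#' the rule set's priority order is assigned, remaining cells are
#' `"unassigned"`.  Cells satisfying more than one rule are recorded in the
#' `conflicts` attribute of the result.
#'
#' @param x a [dge()] (normalized tags recommended; the positivity threshold
#'   is expressed in normalized tags).
#' @param rules a [marker_rules()].
#' @param side optional side label stored on every annotation (defaults to
#'   the matrix `sample_label`).
#' @return Data frame of class `cell_annotation` with columns `barcode`,
#'   `cell_class`, `emt_class` (initially `"none"`), `side`; attribute
#'   `conflicts` lists multi-class cells.
#' @export
classify_cells <- function(x, rules, side = NULL) {
  stopifnot(inherits(x, "dge"), inherits(rules, "marker_rules"))
  if (is.null(side)) side <- x$sample_label
  all_genes <- unique(unlist(lapply(rules$class_rules, `[[`, "genes")))
  pos <- positivity_matrix(x, all_genes, rules$positivity_threshold)
  sat <- vapply(rules$priority, function(cl) {
    r <- rules$class_rules[[cl]]
    sub <- pos[, r$genes, drop = FALSE]
    if (r$mode == "any") rowSums(sub) > 0 else rowSums(sub) == ncol(sub)
  }, logical(nrow(pos)))
  sat <- matrix(sat, nrow = nrow(pos),
                dimnames = list(barcodes(x), rules$priority))
  first <- apply(sat, 1L, function(v) {
    w <- which(v)
    if (length(w)) colnames(sat)[w[1]] else "unassigned"
  })
  n_match <- rowSums(sat)
  conflicts <- data.frame(
    barcode = barcodes(x)[n_match > 1],
    classes = apply(sat[n_match > 1, , drop = FALSE], 1L, function(v) {
      paste(colnames(sat)[v], collapse = "+")
    }),
    stringsAsFactors = FALSE, row.names = NULL
  )
  out <- data.frame(barcode = barcodes(x), cell_class = unname(first),
                    emt_class = "none", side = side,
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "conflicts") <- conflicts
  class(out) <- c("cell_annotation", "data.frame")
  out
}

#' EMT trichotomy of tumour cells
#'
#' Among cells classified as tumour cells, partitions by marker positivity
#' into: `EA` (at least one epithelial marker, no mesenchymal marker),
#' `EA_EMT` (at least one mesenchymal marker, no epithelial marker),
#' `EA_intEMT` (at least one of each), and `none` (no marker of either
#' kind).  Non-tumour cells keep `emt_class = "none"`.  The four states are
#' exhaustive and mutually exclusive over the tumour cells.
#'
#' @param annotations a `cell_annotation` from [classify_cells()].
#' @param x the [dge()] the annotations were derived from.
#' @param rules a [marker_rules()] with non-empty epithelial and mesenchymal
#'   sets.
#' @return The annotations with `emt_class` filled in.
#' @export
classify_emt <- function(annotations, x, rules) {
  stopifnot(inherits(annotations, "cell_annotation"), inherits(x, "dge"),
            inherits(rules, "marker_rules"))
  if (length(rules$epithelial_genes) == 0L ||
      length(rules$mesenchymal_genes) == 0L) {
    stop_invalid("epithelial and mesenchymal gene sets must be non-empty")
  }
  cancer <- annotations$cell_class %in% rules$cancer_classes
  if (!any(cancer)) return(annotations)
  sub <- x[match(annotations$barcode[cancer], barcodes(x)), , drop = FALSE]
  epi <- positivity_matrix(sub, rules$epithelial_genes,
                           rules$positivity_threshold, warn_missing = FALSE)
  mes <- positivity_matrix(sub, rules$mesenchymal_genes,
                           rules$positivity_threshold, warn_missing = FALSE)
  has_e <- rowSums(epi) > 0
  has_m <- rowSums(mes) > 0
  state <- ifelse(has_e & has_m, "EA_intEMT",
                  ifelse(has_e, "EA", ifelse(has_m, "EA_EMT", "none")))
  annotations$emt_class[cancer] <- state
  annotations
}

#' Write cell annotations as TSV
#' @param annotations a `cell_annotation`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(annotations, path) {
  atomic_write(path, function(tmp) {
    write.table(as.data.frame(annotations), tmp, sep = "\t", quote = FALSE,
                row.names = FALSE)
  })
  invisible(path)
}

#' Positive-cell counts per gene, stratified by cell class
#'
#' Counts, for each gene of interest (e.g. chemokines), the cells positive
#' for it within each annotated class.  The per-gene sum over classes equals
#' the unstratified positive count.
#'
#' @param x a [dge()].
#' @param gene_list genes to count.
#' @param annotations a `cell_annotation` covering the matrix barcodes.
#' @param threshold positivity cutoff (default 1).
#' @return Data frame with columns `gene`, `cell_class`, `side`,
#'   `n_positive`.
#' @export
chemokine_positive_counts <- function(x, gene_list, annotations, threshold = 1) {
  stopifnot(inherits(x, "dge"), inherits(annotations, "cell_annotation"))
  idx <- match(barcodes(x), annotations$barcode)
  if (anyNA(idx)) stop_invalid("annotations missing for some barcodes")
  pos <- positivity_matrix(x, gene_list, threshold, warn_missing = FALSE)
  strata <- interaction(annotations$cell_class[idx], annotations$side[idx],
                        sep = "\r", drop = TRUE)
  out <- do.call(rbind, lapply(gene_list, function(g) {
    n <- tapply(pos[, g], strata, sum)
    parts <- strsplit(names(n), "\r", fixed = TRUE)
    data.frame(gene = g,
               cell_class = vapply(parts, `[[`, "", 1L),
               side = vapply(parts, `[[`, "", 2L),
               n_positive = as.integer(n),
               stringsAsFactors = FALSE, row.names = NULL)
  }))
  out
}

#' Deterministic hierarchical clustering of cells
#'
#' Agglomerative clustering on log2(count + 1)-transformed expression, the
#' unsupervised grouping used to ask whether tumour subpopulations separate.
#' Parameters are recorded on the result so a run is reproducible from its
#' output.
#'
#' @param x a [dge()] with at least 2 cells.
#' @param distance distance measure for [stats::dist()] (default
#'   `"euclidean"`).
#' @param linkage agglomeration method for [stats::hclust()] (default
#'   `"ward.D2"`).
#' @param k optional number of clusters; when given, hard labels are
#'   returned in `$labels`.
#' @return List with `hclust` (the tree), `labels` (named integer vector or
#'   `NULL`) and `parameters`.
#' @export
cluster_cells <- function(x, distance = "euclidean", linkage = "ward.D2",
                          k = NULL) {
  stopifnot(inherits(x, "dge"))
  if (nrow(x$counts) < 2L) stop_invalid("clustering needs at least 2 cells")
  m <- log2(as.matrix(x$counts) + 1)
  d <- dist(m, method = distance)
  hc <- hclust(d, method = linkage)
  labels <- if (!is.null(k)) cutree(hc, k = k) else NULL
  list(hclust = hc, labels = labels,
       parameters = list(distance = distance, linkage = linkage, k = k,
                         transform = "log2(x + 1)"))
}
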