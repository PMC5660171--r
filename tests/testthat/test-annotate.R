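test_that("positivity threshold is inclusive at the boundary", {
  expect_false(is_positive(0, 1))
  expect_true(is_positive(1, 1))
  expect_true(is_positive(1.5, 1))
  expect_error(is_positive(-1, 1), ">= 0")
})

test_that("marker rules validate their configuration", {
  expect_error(marker_rules(list()), "non-empty named list")
  expect_error(marker_rules(list(T_cell = "CD3D"),
                            epithelial_genes = c("EPCAM", "VIM"),
                            mesenchymal_genes = c("VIM")), "disjoint")
  expect_error(marker_rules(list(T_cell = "CD3D"), priority = "B_cell"),
               "permutation")
  r <- marker_rules(list(T_cell = list(genes = c("CD3D", "CD3E"), mode = "all")))
  expect_identical(r$class_rules$T_cell$mode, "all")

  path <- withr::local_tempfile(fileext = ".yaml")
  write_marker_rules(r, path)
  back <- read_marker_rules(path)
  expect_identical(back$class_rules, r$class_rules)
  expect_identical(back$epithelial_genes, r$epithelial_genes)
})

test_that("cells take the first matching class in priority order", {
  m <- dge(matrix(c(5, 0, 0,    # T cell
                    0, 5, 0,    # macrophage
                    5, 5, 0,    # conflict -> T (priority)
                    0, 0, 5,    # cancer
                    0, 0, 0),   # unassigned
                  nrow = 5, byrow = TRUE,
                  dimnames = list(paste0("c", 1:5),
                                  c("CD3D", "CD68", "EPCAM"))))
  rules <- marker_rules(
    list(T_cell = "CD3D", macrophage = "CD68", cancer = "EPCAM"),
    priority = c("T_cell", "macrophage", "cancer"))
  ann <- classify_cells(m, rules, side = "E")
  expect_identical(ann$cell_class,
                   c("T_cell", "macrophage", "T_cell", "cancer", "unassigned"))
  conflicts <- attr(ann, "conflicts")
  expect_identical(conflicts$barcode, "c3")
  expect_identical(conflicts$classes, "T_cell+macrophage")
  expect_true(all(ann$side == "E"))

  # invariant to gene/column order
  ann2 <- classify_cells(m[, c(3, 1, 2)], rules, side = "E")
  expect_identical(ann2$cell_class, ann$cell_class)

  # missing rule genes warn and count as negative
  m2 <- m[, 1:2]
  expect_warning(ann3 <- classify_cells(m2, rules, side = "E"), "EPCAM")
  expect_identical(ann3$cell_class[4], "unassigned")
  expect_warning(classify_cells(m, default_rules(), side = "E"), "absent")
})

test_that("EMT trichotomy partitions tumour cells exhaustively", {
  m <- dge(matrix(c(5, 0, 0, 0,   # EPCAM only -> EA
                    5, 0, 5, 0,   # EPCAM + VIM -> EA_intEMT
                    0, 0, 5, 0,   # VIM only -> EA_EMT
                    0, 0, 0, 5),  # neither marker kind -> none
                  nrow = 4, byrow = TRUE,
                  dimnames = list(paste0("c", 1:4),
                                  c("EPCAM", "CDH1", "VIM", "OTHER001"))))
  rules <- marker_rules(list(cancer = c("EPCAM", "VIM", "OTHER001")),
                        positivity_threshold = 1)
  ann <- classify_emt(classify_cells(m, rules, side = "E"), m, rules)
  expect_identical(ann$emt_class, c("EA", "EA_intEMT", "EA_EMT", "none"))

  # property: exhaustive, mutually exclusive partition on simulated cells
  spec <- two_side_spec()
  truth <- simulate_cells(spec, 250, seed = 51)
  x <- truth$counts
  full_rules <- default_rules()
  ann <- suppressWarnings(
    classify_emt(classify_cells(x, full_rules, side = "E"), x, full_rules))
  cancer <- ann$cell_class == "cancer"
  expect_true(all(ann$emt_class[!cancer] == "none"))
  expect_true(all(ann$emt_class[cancer] %in%
                    c("EA", "EA_intEMT", "EA_EMT", "none")))
  expect_equal(sum(table(ann$emt_class[cancer])), sum(cancer))

  # brute-force oracle over the count matrix
  cnt <- as.matrix(x$counts)
  for (i in which(cancer)) {
    e <- any(cnt[ann$barcode[i], intersect(full_rules$epithelial_genes,
                                           colnames(cnt))] >= 1)
    mm <- any(cnt[ann$barcode[i], intersect(full_rules$mesenchymal_genes,
                                            colnames(cnt))] >= 1)
    want <- if (e && mm) "EA_intEMT" else if (e) "EA"
            else if (mm) "EA_EMT" else "none"
    expect_identical(ann$emt_class[i], want)
  }
})

test_that("side tables reproduce printed percentages and folds", {
  # spot rows from the published two-side distribution
  expect_equal(side_table_from_counts("FADS2", 147, 305, 55, 180,
                                      "E_over_M")$fold, 1.6)
  expect_equal(side_table_from_counts("S100B", 61, 305, 3, 180,
                                      "E_over_M")$fold, 12.0)
  expect_equal(side_table_from_counts("X", 30, 100, 54, 180,
                                      "E_over_M")$fold, 1.0)   # equal fractions
  expect_true(is.na(side_table_from_counts("X", 5, 100, 0, 180,
                                           "E_over_M")$fold))  # undefined
  expect_error(side_table_from_counts("X", 5, 0, 1, 180, "E_over_M"),
               "positive")

  # full published table: every percentage, and every fold with a nonzero
  # denominator, at the printed precision
  tab <- published_side_table()
  rep <- side_table_from_counts(tab$gene, tab$count_E, attr(tab, "total_E"),
                                tab$count_M, attr(tab, "total_M"),
                                direction = tab$direction)
  expect_identical(rep$pct_E, tab$pct_printed_E)
  expect_identical(rep$pct_M, tab$pct_printed_M)
  defined <- !is.na(rep$fold)
  expect_equal(sum(!defined), 4)   # the x/0 and 0/0 rows
  expect_equal(rep$fold[defined], tab$fold_printed[defined])
})

test_that("matrix-level side tables agree with manual counting", {
  spec <- two_side_spec()
  truth <- simulate_cells(spec, 300, seed = 61)
  x <- truth$counts
  xE <- x[truth$cells$side == "E", ]
  xM <- x[truth$cells$side == "M", ]
  tab <- side_table(xE, xM, genes = c("FADS2", "CD3D"), threshold = 1,
                    direction = "E_over_M")
  cntE <- as.matrix(xE$counts); cntM <- as.matrix(xM$counts)
  expect_equal(tab$count_E, c(sum(cntE[, "FADS2"] >= 1), sum(cntE[, "CD3D"] >= 1)))
  expect_equal(tab$count_M, c(sum(cntM[, "FADS2"] >= 1), sum(cntM[, "CD3D"] >= 1)))
  expect_equal(tab$total_E, rep(nrow(cntE), 2))
  man_fold <- beadwell:::round_half_up(
    (tab$count_E[1] / tab$total_E[1]) / (tab$count_M[1] / tab$total_M[1]), 1)
  expect_equal(tab$fold[1], man_fold)
  expect_error(side_table(xE[integer(), ], xM), "at least one cell")

  path <- withr::local_tempfile(fileext = ".tsv")
  write_side_table(tab, path)
  expect_equal(utils::read.delim(path)$count_E, tab$count_E)
})

test_that("stratified positive-cell counts conserve totals and recover rates", {
  spec <- two_side_spec()
  truth <- simulate_cells(spec, 500, seed = 71)
  x <- truth$counts
  ann <- structure(
    data.frame(barcode = truth$cells$barcode,
               cell_class = truth$cells$class, emt_class = "none",
               side = truth$cells$side, stringsAsFactors = FALSE),
    class = c("cell_annotation", "data.frame"))
  out <- chemokine_positive_counts(x, c("CCL4", "OTHER001"), ann, threshold = 1)

  # conservation: sum over strata equals the unstratified count
  cnt <- as.matrix(x$counts)
  for (g in c("CCL4", "OTHER001")) {
    expect_equal(sum(out$n_positive[out$gene == g]), sum(cnt[, g] >= 1))
  }
  # all-zero gene gives zero everywhere
  x0 <- x
  x0$counts[, "OTHER001"] <- 0
  out0 <- chemokine_positive_counts(x0, "OTHER001", ann)
  expect_true(all(out0$n_positive == 0))

  # CCL4 positive in 30% of M-side T cells by construction
  sel <- out$gene == "CCL4" & out$cell_class == "T_cell" & out$side == "M"
  n_tm <- sum(truth$cells$class == "T_cell" & truth$cells$side == "M")
  obs <- out$n_positive[sel] / n_tm
  expect_lt(abs(obs - 0.30), 3 * sqrt(0.3 * 0.7 / n_tm))
})

test_that("hierarchical clustering is deterministic and separates classes", {
  m <- rbind(cbind(matrix(50, 10, 10), matrix(0, 10, 10)),
             cbind(matrix(0, 10, 10), matrix(50, 10, 10))) + 1
  rownames(m) <- sprintf("c%02d", 1:20)
  colnames(m) <- sprintf("g%02d", 1:20)
  truth_lab <- rep(c(1, 2), each = 10)
  x <- dge(m)
  cl <- cluster_cells(x, k = 2)
  expect_equal(mclust::adjustedRandIndex(cl$labels, truth_lab), 1)

  # identical cells sit at distance zero
  two <- dge(matrix(c(1, 2, 1, 2), 2, 2, byrow = TRUE,
                    dimnames = list(c("a", "b"), c("g1", "g2"))))
  expect_equal(cluster_cells(two, k = 1)$hclust$height, 0)

  # permutation of input order relabels but does not regroup
  perm <- c(seq(2, 20, by = 2), seq(1, 19, by = 2))
  cl2 <- cluster_cells(x[perm, ], k = 2)
  expect_equal(mclust::adjustedRandIndex(cl2$labels[rownames(m)],
                                         cl$labels[rownames(m)]), 1)
  expect_error(cluster_cells(x[1, ]), "at least 2")
})

test_that("annotations export as TSV", {
  ann <- structure(
    data.frame(barcode = "b1", cell_class = "cancer", emt_class = "EA",
               side = "E", stringsAsFactors = FALSE),
    class = c("cell_annotation", "data.frame"))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_annotations(ann, path)
  expect_identical(utils::read.delim(path)$emt_class, "EA")
})
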