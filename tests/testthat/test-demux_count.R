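test_that("barcode extraction applies the prefix and rejection rules", {
  r <- extract_barcodes("ACGTACGTACGTAAACCC")
  expect_identical(r$barcode, "ACGTACGTACGT")
  expect_identical(r$status, "ok")

  r <- extract_barcodes(c("ACGTNCGTACGTAAA", "ACGT"))
  expect_identical(r$status, c("ambiguous-base", "too-short"))
  expect_true(all(is.na(r$barcode)))

  wl <- c("AAAAAAAAAAAA", "CCCCCCCCCCCC", "GGGGGGGGGGGG")
  r <- extract_barcodes("AAAAAAAAAAAATTT", whitelist = wl)
  expect_identical(r$status, "ok")
  r <- extract_barcodes("AAAAAAAAAAATTTT", whitelist = wl, max_mismatch = 0)
  expect_identical(r$status, "no-match")
})

test_that("Hamming-1 correction matches the neighbor-enumeration oracle", {
  wl <- sample_library(40, 12, seed = 77)$barcodes
  # keep only well-separated codes (pairwise distance > 2) so corrections
  # are unambiguous by construction
  hd <- function(a, b) sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
  keep <- wl[1]
  for (b in wl[-1]) if (all(vapply(keep, hd, 2L, b = b) > 2)) keep <- c(keep, b)
  expect_gt(length(keep), 5)

  for (true_bc in keep[1:5]) {
    for (pos in c(1L, 6L, 12L)) {
      chars <- strsplit(true_bc, "")[[1]]
      alt <- setdiff(c("A", "C", "G", "T"), chars[pos])[1]
      chars[pos] <- alt
      mutated <- paste(chars, collapse = "")
      # oracle: enumerate all Hamming-1 neighbors of the mutated code
      nb <- beadwell:::hamming1_neighbors(mutated)
      expect_identical(intersect(nb, keep), true_bc)
      r <- extract_barcodes(paste0(mutated, "AAAA"), whitelist = keep,
                            max_mismatch = 1)
      expect_identical(r$status, "corrected")
      expect_identical(r$barcode, true_bc)
    }
  }

  # ambiguous correction: two whitelist codes both at distance 1
  wl2 <- c("AAAAAAAAAAAA", "CAAAAAAAAAAC")
  query <- "CAAAAAAAAAAA"  # distance 1 from both
  r <- extract_barcodes(paste0(query, "GG"), whitelist = wl2, max_mismatch = 1)
  expect_identical(r$status, "ambiguous-correction")
  # distance 2 from everything -> no match even with correction
  r <- extract_barcodes("GGAAAAAAAAAATT", whitelist = wl2, max_mismatch = 1)
  expect_identical(r$status, "no-match")
})

test_that("toy aligner assigns unique substrings and rejects ambiguity", {
  shared <- strrep("ACGT", 30)
  tx <- structure(
    data.frame(
      gene_id = c("HUMAN_G001", "HUMAN_G002", "HUMAN_G003"),
      species = "HUMAN",
      sequence = c(paste0(strrep("A", 100), "CCCTTTGGGAAACCCTTTGGG"),
                   paste0(shared, strrep("G", 50)),
                   paste0(shared, strrep("T", 50))),
      stringsAsFactors = FALSE),
    class = c("toy_transcriptome", "data.frame"))
  reads <- c("CCCTTTGGGAAACCCTTTGGG",   # unique to G001
             substr(shared, 1, 20),     # present in G002 and G003
             "NNNNACGTACGTACGTACGT",    # ambiguous base
             strrep("C", 20))           # matches nothing
  out <- assign_genes_toy(reads, tx)
  expect_identical(out, c("HUMAN_G001", "unassigned", "unassigned",
                          "unassigned"))
})

test_that("SAM-based gene assignment keeps unique mapped reads only", {
  sam <- withr::local_tempfile(fileext = ".sam")
  writeLines(c(
    "@HD\tVN:1.6\tSO:unsorted",
    "@SQ\tSN:HUMAN_G001\tLN:500",
    "@SQ\tSN:HUMAN_G002\tLN:500",
    "r1\t0\tHUMAN_G001\t10\t42\t20M\t*\t0\t0\tACGTACGTACGTACGTACGT\t*",
    "r2\t4\t*\t0\t0\t*\t*\t0\t0\tACGTACGTACGTACGTACGT\t*",
    "r3\t0\tHUMAN_G001\t10\t1\t20M\t*\t0\t0\tACGTACGTACGTACGTACGT\t*",
    "r3\t256\tHUMAN_G002\t10\t1\t20M\t*\t0\t0\tACGTACGTACGTACGTACGT\t*",
    "r4\t0\tHUMAN_G002\t5\t42\t20M\t*\t0\t0\tACGTACGTACGTACGTACGT\t*",
    "r4\t256\tHUMAN_G002\t99\t1\t20M\t*\t0\t0\tACGTACGTACGTACGTACGT\t*"
  ), sam)
  out <- assign_genes_sam(sam)
  got <- setNames(out$gene, out$qname)
  expect_identical(got[["r1"]], "HUMAN_G001")
  expect_identical(got[["r2"]], "unassigned")
  expect_identical(got[["r3"]], "unassigned")   # two genes -> discarded
  expect_identical(got[["r4"]], "HUMAN_G002")   # two hits, one gene -> kept

  bad <- withr::local_tempfile(fileext = ".sam")
  writeLines(c("@SQ\tSN:g\tLN:10", "broken line"), bad)
  expect_error(suppressWarnings(assign_genes_sam(bad)), "malformed SAM")
})

test_that("count_matrix tallies read pairs per (barcode, gene)", {
  empty <- count_matrix(character(), character())
  expect_equal(dim(empty), c(0L, 0L))
  m <- count_matrix(c("b1", "b1", "b1", "b1"), c("g1", "g1", "g1", "g2"))
  expect_equal(as.numeric(m$counts["b1", c("g1", "g2")]), c(3, 1))
})

test_that("cell QC uses strict thresholds and refuses normalized input", {
  genes <- sprintf("g%03d", 1:500)
  boundary_reads <- setNames(rep(40, 500), genes)          # 20,000 reads exactly
  boundary_genes <- setNames(c(rep(60, 400), rep(0, 100)), genes) # 400 genes
  passing <- setNames(rep(50, 500), genes)                 # 25,000 reads, 500 genes
  failing <- setNames(c(rep(3, 300), rep(0, 200)), genes)
  m <- dge(rbind(at_reads = boundary_reads, at_genes = boundary_genes,
                 pass = passing, fail = failing))
  kept <- call_cells(m, min_reads = 20000, min_genes = 400)
  expect_identical(barcodes(kept), "pass")

  norm <- normalize_tags(m)
  expect_error(call_cells(norm), "unnormalized")

  # retained set equals brute-force filtering of the totals
  spec <- two_side_spec()
  truth <- simulate_cells(spec, 80, seed = 3)
  reads <- Matrix::rowSums(truth$counts$counts)
  ngene <- Matrix::rowSums(truth$counts$counts > 0)
  for (thr in list(c(20, 5), c(40, 10))) {
    kept <- call_cells(truth$counts, min_reads = thr[1], min_genes = thr[2])
    expect_identical(barcodes(kept),
                     barcodes(truth$counts)[reads > thr[1] & ngene > thr[2]])
  }
})

test_that("top-N and knee selection rank barcodes by depth", {
  m <- dge(matrix(c(100, 10, 50, 5, 1, 0.5), ncol = 2,
                  dimnames = list(c("b1", "b2", "b3"), c("g1", "g2"))))
  expect_identical(barcodes(top_barcodes(m, 2)), c("b1", "b3"))
  totals <- c(rep(5000, 50), 2000, round(seq(120, 100, length.out = 400)))
  expect_lt(abs(knee_point(totals) - 51), 3)
})

test_that("tag normalization scales rows exactly and keeps fractions", {
  m <- dge(matrix(c(1, 2, 3, 300000, 0, 0), nrow = 2, byrow = TRUE,
                  dimnames = list(c("b1", "b2"), c("g1", "g2", "g3"))))
  n <- normalize_tags(m, 300000)
  expect_equal(as.numeric(n$counts["b1", ]), c(50000, 100000, 150000))
  expect_equal(as.numeric(n$counts["b2", ]), c(300000, 0, 0))  # unchanged row
  expect_equal(n$normalized_total, 300000)
  rs <- Matrix::rowSums(n$counts)
  expect_true(all(abs(rs - 300000) <= 1e-6 * 300000))

  zero <- dge(matrix(c(1, 0), 2, 1,
                     dimnames = list(c("keep", "empty"), "g1")))
  expect_error(normalize_tags(zero), "empty")
})

test_that("error-free pipeline reproduces the ground truth exactly", {
  tx <- make_toy_transcriptome(30, seed = 5)
  spec <- barnyard_spec(tx)
  truth <- simulate_cells(spec, 30, seed = 11)
  r1 <- withr::local_tempfile(fileext = ".fastq")
  r2 <- withr::local_tempfile(fileext = ".fastq")
  emit_fastq_pairs(truth, tx, error_rate = 0, seed = 12,
                   r1_path = r1, r2_path = r2)
  res <- run_pipeline(r1, r2, transcriptome = tx,
                      whitelist = truth$cells$barcode,
                      min_reads = 0, min_genes = 0, normalize_total = NULL)
  want <- align_counts(truth$counts$counts, barcodes(truth$counts),
                       genes(truth$counts))
  got <- align_counts(res$raw$counts, barcodes(truth$counts),
                      genes(truth$counts))
  expect_identical(got, want)
  expect_true(res$report$conservation_ok)
  expect_equal(res$report$n_assigned + res$report$n_barcode_rejected +
                 res$report$n_gene_unassigned, res$report$n_read_pairs)
})

test_that("matrix outputs are byte-identical across reruns and round-trip", {
  tx <- make_toy_transcriptome(10, seed = 6)
  spec <- barnyard_spec(tx)
  truth <- simulate_cells(spec, 10, seed = 2)
  r1 <- withr::local_tempfile(fileext = ".fastq")
  r2 <- withr::local_tempfile(fileext = ".fastq")
  emit_fastq_pairs(truth, tx, error_rate = 0, seed = 3,
                   r1_path = r1, r2_path = r2)
  out1 <- withr::local_tempdir()
  out2 <- withr::local_tempdir()
  for (out in c(out1, out2)) {
    res <- run_pipeline(r1, r2, transcriptome = tx, min_reads = 0,
                        min_genes = 0, normalize_total = NULL)
    write_dge(res$raw, file.path(out, "mat"), format = "mtx")
  }
  h1 <- tools::md5sum(file.path(out1, "mat", "matrix.mtx"))
  h2 <- tools::md5sum(file.path(out2, "mat", "matrix.mtx"))
  expect_identical(unname(h1), unname(h2))

  back <- read_dge(file.path(out1, "mat"), format = "mtx")
  res <- run_pipeline(r1, r2, transcriptome = tx, min_reads = 0,
                      min_genes = 0, normalize_total = NULL)
  expect_equal(as.matrix(back$counts), as.matrix(res$raw$counts))

  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_dge(res$raw, tsv, format = "tsv")
  back2 <- read_dge(tsv, format = "tsv")
  expect_equal(as.matrix(back2$counts), as.matrix(res$raw$counts))
})

test_that("pipeline consumes external SAM alignments keyed by read name", {
  tx <- make_toy_transcriptome(5, seed = 9)
  spec <- barnyard_spec(tx)
  truth <- simulate_cells(spec, 6, seed = 4)
  r1 <- withr::local_tempfile(fileext = ".fastq")
  r2 <- withr::local_tempfile(fileext = ".fastq")
  emit_fastq_pairs(truth, tx, error_rate = 0, seed = 5,
                   r1_path = r1, r2_path = r2)
  # build the SAM from the known truth via the toy aligner's answers
  fq2 <- read_fastq(r2)
  gene <- assign_genes_toy(fq2$sequence, tx)
  expect_true(all(gene != "unassigned"))  # error-free reads all map uniquely
  sam <- withr::local_tempfile(fileext = ".sam")
  writeLines(c(
    "@HD\tVN:1.6\tSO:unsorted",
    sprintf("@SQ\tSN:%s\tLN:%d", tx$gene_id, nchar(tx$sequence)),
    sprintf("%s\t0\t%s\t1\t42\t%dM\t*\t0\t0\t%s\t*",
            fq2$id, gene, nchar(fq2$sequence), fq2$sequence)
  ), sam)
  res <- run_pipeline(r1, r2, sam_path = sam, min_reads = 0, min_genes = 0,
                      normalize_total = NULL)
  want <- align_counts(truth$counts$counts, barcodes(truth$counts),
                       genes(truth$counts))
  got <- align_counts(res$raw$counts, barcodes(truth$counts),
                      genes(truth$counts))
  expect_identical(got, want)
})
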