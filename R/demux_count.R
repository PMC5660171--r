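hamming1_neighbors <- function(barcode) {
  chars <- strsplit(barcode, "", fixed = TRUE)[[1]]
  out <- character(0)
  for (p in seq_along(chars)) {
    for (b in setdiff(DNA_BASES, chars[p])) {
      v <- chars
      v[p] <- b
      out <- c(out, paste(v, collapse = ""))
    }
  }
  out
}

#' Extract cell barcodes from read-1 sequences
#'
#' The cell barcode is the first `barcode_len` nt of read 1.  Without a
#' whitelist the prefix is returned as-is.  With a whitelist, a prefix is
#' accepted on exact match, or — when `max_mismatch = 1` — corrected to a
#' whitelist barcode at Hamming distance 1 provided that correction is
#' unique.  Rejection reasons: `"too-short"` (read shorter than the
#' barcode), `"ambiguous-base"` (non-ACGT base in the barcode window),
#' `"no-match"`, `"ambiguous-correction"`.
#'
#' @param reads character vector of read-1 sequences.
#' @param barcode_len barcode length (default 12).
#' @param whitelist optional `barcode_library` or character vector of valid
#'   barcodes.
#' @param max_mismatch 0 or 1 whitelist mismatches tolerated.
#' @return Data frame with columns `barcode` (`NA` when rejected) and
#'   `status` (`"ok"`, `"corrected"`, or a rejection reason).
#' @export
#' @examples
#' extract_barcodes("ACGTACGTACGTAAAA")
extract_barcodes <- function(reads, barcode_len = 12L, whitelist = NULL,
                             max_mismatch = 0L) {
  barcode_len <- assert_count(barcode_len, "barcode_len")
  if (!max_mismatch %in% c(0L, 1L)) stop_invalid("`max_mismatch` must be 0 or 1")
  if (inherits(whitelist, "barcode_library")) whitelist <- whitelist$barcodes
  n <- length(reads)
  barcode <- rep(NA_character_, n)
  status <- rep(NA_character_, n)

  too_short <- nchar(reads) < barcode_len
  status[too_short] <- "too-short"
  prefix <- substr(reads, 1L, barcode_len)
  bad_base <- !too_short & grepl("[^ACGT]", prefix)
  status[bad_base] <- "ambiguous-base"
  ok <- !too_short & !bad_base

  if (is.null(whitelist)) {
    barcode[ok] <- prefix[ok]
    status[ok] <- "ok"
  } else {
    hit <- ok & prefix %in% whitelist
    barcode[hit] <- prefix[hit]
    status[hit] <- "ok"
    miss <- ok & !hit
    if (max_mismatch == 0L) {
      status[miss] <- "no-match"
    } else if (any(miss)) {
      u <- unique(prefix[miss])
      corr <- vapply(u, function(b) {
        m <- intersect(hamming1_neighbors(b), whitelist)
        if (length(m) == 1L) m
        else if (length(m) == 0L) "no-match"
        else "ambiguous-correction"
      }, character(1))
      res <- corr[prefix[miss]]
      fail <- res %in% c("no-match", "ambiguous-correction")
      barcode[miss][!fail] <- res[!fail]
      status[miss][!fail] <- "corrected"
      status[miss][fail] <- res[fail]
    }
  }
  data.frame(barcode = barcode, status = status, stringsAsFactors = FALSE)
}

#' Assign reads to genes by exact substring match (toy aligner)
#'
#' Each read is assigned to the transcript that contains it as an exact
#' substring.  Reads matching no transcript, more than one gene, or
#' containing non-ACGT bases are `"unassigned"`.  This replaces an external
#' aligner for the self-contained synthetic workflow; real alignments are
#' consumed through [assign_genes_sam()].
#'
#' @param reads character vector of read-2 sequences.
#' @param transcriptome a [make_toy_transcriptome()] result (or any
#'   `toy_transcriptome`).
#' @return Character vector of gene ids or `"unassigned"`, one per read.
#' @export
assign_genes_toy <- function(reads, transcriptome) {
  stopifnot(inherits(transcriptome, "toy_transcriptome"))
  n <- length(reads)
  out <- rep("unassigned", n)
  clean <- !is.na(reads) & nzchar(reads) & !grepl("[^ACGT]", reads)
  if (!any(clean)) return(out)
  subj <- Biostrings::DNAStringSet(setNames(transcriptome$sequence,
                                            transcriptome$gene_id))
  idx_clean <- which(clean)
  u <- unique(reads[idx_clean])
  gene_of_u <- rep(NA_character_, length(u))
  for (w in unique(nchar(u))) {
    sel <- which(nchar(u) == w)
    pd <- Biostrings::PDict(Biostrings::DNAStringSet(u[sel]))
    hits <- Biostrings::vwhichPDict(pd, subj)
    # invert: pattern index -> transcript indices
    pat <- unlist(hits, use.names = FALSE)
    tx <- rep(seq_along(hits), lengths(hits))
    if (length(pat)) {
      gene_hit <- split(transcriptome$gene_id[tx], pat)
      uniq <- vapply(gene_hit, function(g) {
        g <- unique(g)
        if (length(g) == 1L) g else "unassigned"
      }, character(1))
      gene_of_u[sel[as.integer(names(uniq))]] <- uniq
    }
  }
  gene_of_u[is.na(gene_of_u)] <- "unassigned"
  out[idx_clean] <- gene_of_u[match(reads[idx_clean], u)]
  out
}

#' Assign reads to genes from a SAM alignment stream
#'
#' Consumes a text SAM file produced by an external aligner run against a
#' transcript reference whose sequence names are gene ids.  Unmapped reads
#' are `"unassigned"`; a read whose alignments (primary plus
#' secondary/supplementary) touch more than one gene is `"unassigned"`
#' (multi-mapped reads are discarded rather than fractionally assigned).
#'
#' @param sam_path path to a SAM file.
#' @return Data frame with columns `qname` and `gene` (gene id or
#'   `"unassigned"`), one row per distinct read name.
#' @export
assign_genes_sam <- function(sam_path) {
  if (!file.exists(sam_path)) stop_invalid("SAM file not found: ", sam_path)
  bam <- tryCatch(
    Rsamtools::asBam(sam_path, destination = tempfile(), indexDestination = FALSE),
    error = function(e) stop_invalid("malformed SAM (", sam_path, "): ",
                                     conditionMessage(e))
  )
  on.exit(unlink(c(bam, paste0(bam, ".bai"))), add = TRUE)
  # htslib silently stops at an unparseable record; detect the shortfall and
  # report the first offending line
  all_lines <- readLines(sam_path)
  n_header <- sum(startsWith(all_lines, "@"))
  n_body <- sum(!startsWith(all_lines, "@") & nzchar(all_lines))
  n_records <- Rsamtools::countBam(bam)$records
  if (n_records < n_body) {
    stop_invalid(sprintf("malformed SAM record at line %d of %s",
                         n_header + n_records + 1L, sam_path))
  }
  aln <- Rsamtools::scanBam(
    bam, param = Rsamtools::ScanBamParam(what = c("qname", "flag", "rname"))
  )[[1]]
  qname <- aln$qname
  mapped <- !bitwAnd(aln$flag, 4L)
  gene <- as.character(aln$rname)
  per_read <- tapply(ifelse(mapped, gene, NA_character_), qname, function(g) {
    g <- unique(g[!is.na(g)])
    if (length(g) == 1L) g else "unassigned"
  })
  data.frame(qname = names(per_read), gene = as.character(per_read),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Build a digital expression matrix from (barcode, gene) assignments
#'
#' Counts read pairs per (barcode, gene).  No UMI collapsing exists in this
#' chemistry: entries are read counts.
#'
#' @param barcode,gene equal-length character vectors, one entry per
#'   assigned read.
#' @param sample_label optional label stored on the matrix.
#' @return A raw-count [dge()].
#' @export
count_matrix <- function(barcode, gene, sample_label = NA_character_) {
  stopifnot(length(barcode) == length(gene))
  if (length(barcode) == 0L) {
    return(dge(matrix(0, 0, 0, dimnames = list(character(), character())),
               sample_label = sample_label))
  }
  fb <- factor(barcode)
  fg <- factor(gene)
  m <- Matrix::sparseMatrix(
    i = as.integer(fb), j = as.integer(fg), x = 1,
    dims = c(nlevels(fb), nlevels(fg)),
    dimnames = list(levels(fb), levels(fg))
  )
  dge(m, sample_label = sample_label)
}

#' Cell QC: retain barcodes above read and gene thresholds
#'
#' Keeps barcodes with strictly more than `min_reads` total reads AND
#' strictly more than `min_genes` detected genes (the "more than 20,000
#' reads and more than 400 genes per cell" rule; boundary barcodes are
#' excluded).
#'
#' @param x a raw-count [dge()] (normalized matrices are refused).
#' @param min_reads minimum total reads, exclusive (default 20,000).
#' @param min_genes minimum detected genes, exclusive (default 400).
#' @return The filtered `dge`.
#' @export
call_cells <- function(x, min_reads = 20000L, min_genes = 400L) {
  stopifnot(inherits(x, "dge"))
  if (!is.null(x$normalized_total)) {
    stop_invalid("call_cells() requires a raw (unnormalized) matrix")
  }
  min_reads <- assert_count(min_reads, "min_reads", min = 0L)
  min_genes <- assert_count(min_genes, "min_genes", min = 0L)
  reads <- Matrix::rowSums(x$counts)
  ngene <- Matrix::rowSums(x$counts > 0)
  keep <- reads > min_reads & ngene > min_genes
  x[keep, , drop = FALSE]
}

#' Keep the N barcodes with the most reads
#'
#' Whitelist-free cell selection: ranks barcodes by total read count and
#' retains the top `n` (ties broken by barcode order for determinism).
#'
#' @param x a raw-count [dge()].
#' @param n number of barcodes to keep.
#' @return The filtered `dge`.
#' @export
top_barcodes <- function(x, n) {
  stopifnot(inherits(x, "dge"))
  n <- assert_count(n, "n", min = 0L)
  reads <- Matrix::rowSums(x$counts)
  ord <- order(-reads, rownames(x$counts))
  keep <- sort(ord[seq_len(min(n, length(ord)))])
  x[keep, , drop = FALSE]
}

#' Knee point of the barcode rank curve
#'
#' Simple knee detection on the log-log rank/count curve: the rank with
#' maximal distance from the chord joining the curve's endpoints.  Offered
#' as an alternative to a fixed `top_barcodes()` cutoff.
#'
#' @param x a raw-count [dge()] or a numeric vector of per-barcode totals.
#' @return The estimated number of cells (integer rank).
#' @export
knee_point <- function(x) {
  totals <- if (inherits(x, "dge")) Matrix::rowSums(x$counts) else x
  totals <- sort(totals[totals > 0], decreasing = TRUE)
  if (length(totals) < 3L) return(length(totals))
  lx <- log10(seq_along(totals))
  ly <- log10(totals)
  x1 <- lx[1]; y1 <- ly[1]
  x2 <- lx[length(lx)]; y2 <- ly[length(ly)]
  d <- abs((y2 - y1) * lx - (x2 - x1) * ly + x2 * y1 - y2 * x1) /
    sqrt((y2 - y1)^2 + (x2 - x1)^2)
  which.max(d)
}

#' Normalize each cell to a fixed tag total
#'
#' Scales every row so its sum equals `total` (default 300,000 tags per
#' cell).  Values become fractional; no rounding is applied so the row sums
#' are exact.
#'
#' @param x a [dge()] whose rows all have positive totals.
#' @param total target per-cell tag total.
#' @return The normalized `dge` with `normalized_total` recorded.
#' @export
normalize_tags <- function(x, total = 300000) {
  stopifnot(inherits(x, "dge"))
  if (length(total) != 1L || !is.numeric(total) || total <= 0) {
    stop_invalid("`total` must be a single positive number")
  }
  rs <- Matrix::rowSums(x$counts)
  if (any(rs == 0)) {
    stop_invalid("zero-total barcode(s): ",
                 paste(rownames(x$counts)[rs == 0], collapse = ", "))
  }
  m <- Matrix::Diagonal(x = total / rs) %*% x$counts
  dimnames(m) <- dimnames(x$counts)
  dge(m, sample_label = x$sample_label, normalized_total = total)
}

#' Run the demultiplex-and-count pipeline on paired FASTQ
#'
#' Chains barcode extraction (read 1), gene assignment (read 2 via the toy
#' exact-substring aligner, or an external SAM stream keyed by read name),
#' read counting, optional cell selection, QC and tag normalization.
#'
#' @param r1_path,r2_path paired FASTQ files (read 2 unused when `sam_path`
#'   is given).
#' @param transcriptome a `toy_transcriptome` for the built-in aligner, or
#'   `NULL` when `sam_path` is supplied.
#' @param sam_path optional SAM file of read-2 alignments.
#' @param whitelist optional barcode whitelist (`barcode_library`, character
#'   vector, or path to a whitelist file).
#' @param max_mismatch whitelist mismatches tolerated (0 or 1).
#' @param top_cells optional whitelist-free selection: keep this many
#'   barcodes by read count before QC.
#' @param min_reads,min_genes QC thresholds (strict), see [call_cells()].
#' @param normalize_total per-cell tag total, see [normalize_tags()];
#'   `NULL` skips normalization.
#' @param sample_label label stored on the matrices.
#' @return List with `raw`, `qc`, `normalized` ([dge()] objects; `normalized`
#'   is `NULL` when normalization is skipped) and `report` (read-conservation
#'   ledger and parameters).
#' @export
run_pipeline <- function(r1_path, r2_path, transcriptome = NULL,
                         sam_path = NULL, whitelist = NULL, max_mismatch = 0L,
                         top_cells = NULL, min_reads = 20000L,
                         min_genes = 400L, normalize_total = 300000,
                         sample_label = NA_character_) {
  if (is.character(whitelist) && length(whitelist) == 1L &&
      file.exists(whitelist)) {
    whitelist <- read_whitelist(whitelist)
  }
  r1 <- read_fastq(r1_path)
  bx <- extract_barcodes(r1$sequence, whitelist = whitelist,
                         max_mismatch = max_mismatch)
  n_total <- nrow(r1)

  if (!is.null(sam_path)) {
    asg <- assign_genes_sam(sam_path)
    gene <- asg$gene[match(r1$id, asg$qname)]
    gene[is.na(gene)] <- "unassigned"
  } else {
    if (is.null(transcriptome)) {
      stop_invalid("supply either `transcriptome` or `sam_path`")
    }
    r2 <- read_fastq(r2_path)
    if (!identical(r1$id, r2$id)) {
      r2 <- r2[match(r1$id, r2$id), , drop = FALSE]
      if (anyNA(r2$id)) stop_invalid("read-1/read-2 name mismatch")
    }
    gene <- assign_genes_toy(r2$sequence, transcriptome)
  }

  barcode_ok <- !is.na(bx$barcode)
  gene_ok <- gene != "unassigned"
  use <- barcode_ok & gene_ok
  raw <- count_matrix(bx$barcode[use], gene[use], sample_label = sample_label)
  selected <- if (!is.null(top_cells)) top_barcodes(raw, top_cells) else raw
  qc <- call_cells(selected, min_reads = min_reads, min_genes = min_genes)
  normalized <- if (!is.null(normalize_total) && nrow(qc$counts) > 0) {
    normalize_tags(qc, normalize_total)
  } else NULL

  rejected <- table(factor(bx$status[!barcode_ok]))
  report <- list(
    n_read_pairs = n_total,
    n_assigned = sum(use),
    n_barcode_rejected = sum(!barcode_ok),
    barcode_rejection_reasons = as.list(rejected),
    n_gene_unassigned = sum(barcode_ok & !gene_ok),
    conservation_ok =
      sum(use) + sum(!barcode_ok) + sum(barcode_ok & !gene_ok) == n_total,
    n_barcodes_raw = nrow(raw$counts),
    n_cells_qc = nrow(qc$counts),
    parameters = list(
      max_mismatch = max_mismatch, top_cells = top_cells,
      min_reads = min_reads, min_genes = min_genes,
      normalize_total = normalize_total,
      whitelist_used = !is.null(whitelist),
      aligner = if (is.null(sam_path)) "toy-substring" else "sam",
      order = "count -> select -> qc -> normalize"
    )
  )
  list(raw = raw, qc = qc, normalized = normalized, report = report)
}
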