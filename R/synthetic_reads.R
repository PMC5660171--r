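random_dna <- function(n, len) {
  vapply(len, function(l) {
    paste(sample(DNA_BASES, l, replace = TRUE), collapse = "")
  }, character(1))
}

transcript_kmers <- function(seqs, k) {
  lapply(seqs, function(s) {
    n <- nchar(s) - k + 1L
    if (n < 1L) return(character())
    unique(substring(s, seq_len(n), seq_len(n) + k - 1L))
  })
}

#' Generate a toy two-species transcriptome
#'
#' Random transcript sequences standing in for a combined reference (e.g.
#' human + mouse RefSeq mRNA).  Species are encoded as gene-id prefixes
#' (`HUMAN_G001`, `MOUSE_G001`, ...).  Sequences are resampled until no
#' `unique_kmer`-mer is shared between two transcripts, which makes
#' exact-substring read assignment unambiguous by construction.
#'
#' @param n_genes_per_species transcripts per species.
#' @param length_range integer range of transcript lengths (nt).
#' @param species character vector of species prefixes (>= 1).
#' @param unique_kmer k-mer size that must be transcript-specific
#'   (default 25); set to `NULL` to skip the check.
#' @param seed integer seed.
#' @return An object of class `toy_transcriptome`: data frame with columns
#'   `gene_id`, `species`, `sequence`.
#' @export
#' @examples
#' tx <- make_toy_transcriptome(5, seed = 1)
#' head(tx$gene_id)
make_toy_transcriptome <- function(n_genes_per_species, length_range = c(400L, 600L),
                                   species = c("HUMAN", "MOUSE"),
                                   unique_kmer = 25L, seed = 1L) {
  n_genes_per_species <- assert_count(n_genes_per_species, "n_genes_per_species")
  stopifnot(length(length_range) == 2L, length_range[1] >= 50,
            length_range[2] >= length_range[1], length(species) >= 1L)
  out <- with_seed(seed, {
    n_total <- n_genes_per_species * length(species)
    lens <- sample(length_range[1]:length_range[2], n_total, replace = TRUE)
    seqs <- random_dna(n_total, lens)
    if (!is.null(unique_kmer)) {
      for (iter in 1:50) {
        km <- transcript_kmers(seqs, unique_kmer)
        all_k <- unlist(km, use.names = FALSE)
        dup <- unique(all_k[duplicated(all_k)])
        if (length(dup) == 0L) break
        bad <- which(vapply(km, function(x) any(x %in% dup), logical(1)))
        # keep the first offender of each clash, resample the rest
        bad <- bad[-1]
        if (length(bad) == 0L) bad <- which.max(lengths(km))
        seqs[bad] <- random_dna(length(bad), lens[bad])
      }
    }
    seqs
  })
  ids <- as.vector(vapply(species, function(sp) {
    sprintf("%s_G%03d", sp, seq_len(n_genes_per_species))
  }, character(n_genes_per_species)))
  structure(
    data.frame(gene_id = ids,
               species = rep(species, each = n_genes_per_species),
               sequence = out, stringsAsFactors = FALSE),
    class = c("toy_transcriptome", "data.frame")
  )
}

#' Write / read a toy transcriptome as FASTA
#'
#' @param tx a `toy_transcriptome`.
#' @param path FASTA file path.
#' @return `write_transcriptome()` returns `path` invisibly;
#'   `read_transcriptome()` returns a `toy_transcriptome` with species
#'   recovered from the gene-id prefix.
#' @export
write_transcriptome <- function(tx, path) {
  stopifnot(inherits(tx, "toy_transcriptome"))
  set <- Biostrings::DNAStringSet(setNames(tx$sequence, tx$gene_id))
  atomic_write(path, function(tmp) Biostrings::writeXStringSet(set, tmp))
  invisible(path)
}

#' @rdname write_transcriptome
#' @export
read_transcriptome <- function(path) {
  set <- Biostrings::readDNAStringSet(path)
  ids <- names(set)
  structure(
    data.frame(gene_id = ids,
               species = sub("_.*$", "", ids),
               sequence = as.character(set), stringsAsFactors = FALSE),
    class = c("toy_transcriptome", "data.frame")
  )
}

#' Describe a simulated cell population
#'
#' Defines the classes of cells a synthetic experiment contains.  Each class
#' carries a tissue side (e.g. `"E"` / `"M"`), a species, a mixing
#' proportion, and per-gene positivity probabilities: a cell of the class
#' expresses a gene with the class's probability for that gene, and an
#' expressed gene receives `1 + Poisson(frags_per_gene - 1)` cDNA fragments.
#'
#' @param genes character vector of gene ids the population can express.
#' @param classes data frame with columns `name`, `class`, `side`,
#'   `species`, `prop` (mixing proportions; normalized internally).
#' @param positivity matrix of expression probabilities with one row per
#'   class (`rownames = classes$name`) and one column per gene.  Genes not
#'   covered default to `base_positivity`.
#' @param base_positivity default per-gene expression probability.
#' @param frags_per_gene mean fragment count of an expressed gene (>= 1).
#' @param doublet_rate probability that a barcode actually captures two
#'   cells (classes redrawn independently; counts are summed).
#' @return An object of class `population_spec`.
#' @export
population_spec <- function(genes, classes, positivity = NULL,
                            base_positivity = 0.3, frags_per_gene = 4,
                            doublet_rate = 0) {
  stopifnot(is.character(genes), length(genes) >= 1L,
            is.data.frame(classes),
            all(c("name", "class", "side", "species", "prop") %in% names(classes)))
  if (anyDuplicated(classes$name)) stop_invalid("duplicate class names")
  if (any(classes$prop < 0) || sum(classes$prop) <= 0) {
    stop_invalid("class proportions must be non-negative and sum > 0")
  }
  base_positivity <- assert_proportion(base_positivity, "base_positivity")
  doublet_rate <- assert_proportion(doublet_rate, "doublet_rate")
  if (frags_per_gene < 1) stop_invalid("`frags_per_gene` must be >= 1")
  P <- matrix(base_positivity, nrow = nrow(classes), ncol = length(genes),
              dimnames = list(classes$name, genes))
  if (!is.null(positivity)) {
    if (is.null(rownames(positivity)) || is.null(colnames(positivity))) {
      stop_invalid("`positivity` must have class row names and gene column names")
    }
    if (!all(rownames(positivity) %in% classes$name)) {
      stop_invalid("`positivity` rows must match class names")
    }
    if (!all(colnames(positivity) %in% genes)) {
      stop_invalid("`positivity` columns must be in `genes`")
    }
    if (any(positivity < 0) || any(positivity > 1)) {
      stop_invalid("positivity probabilities must lie in [0, 1]")
    }
    P[rownames(positivity), colnames(positivity)] <- positivity
  }
  structure(
    list(genes = genes, classes = classes, positivity = P,
         frags_per_gene = frags_per_gene, doublet_rate = doublet_rate),
    class = "population_spec"
  )
}

draw_profile <- function(spec, class_idx) {
  p <- spec$positivity[class_idx, ]
  pos <- runif(length(p)) < p
  counts <- integer(length(p))
  if (any(pos)) {
    counts[pos] <- 1L + rpois(sum(pos), spec$frags_per_gene - 1)
  }
  counts
}

#' Simulate ground-truth single cells
#'
#' Draws `n_cells` cells from a [population_spec()]: each cell gets a unique
#' 12-nt barcode, a class (hence side and species), and an integer fragment
#' count per gene.  With probability `doublet_rate` a barcode receives the
#' summed profile of two independently drawn cells (a multiplet), and its
#' species label becomes `"mixed"` when the two cells disagree.
#'
#' @param spec a [population_spec()].
#' @param n_cells number of barcodes to simulate (0 allowed).
#' @param seed integer seed.
#' @param barcode_len barcode length (default 12).
#' @return An object of class `ground_truth`: list with `cells` (data frame:
#'   `barcode`, `class`, `side`, `species`, `is_doublet`), `counts` (a [dge()]
#'   of true fragment counts) and `spec`.
#' @export
simulate_cells <- function(spec, n_cells, seed = 1L, barcode_len = 12L) {
  stopifnot(inherits(spec, "population_spec"))
  n_cells <- assert_count(n_cells, "n_cells", min = 0L)
  n_class <- nrow(spec$classes)
  out <- with_seed(seed, {
    bc <- index_to_barcode(sample.int(4^barcode_len, n_cells, replace = FALSE),
                           barcode_len)
    cls1 <- sample.int(n_class, n_cells, replace = TRUE,
                       prob = spec$classes$prop)
    is_dbl <- runif(n_cells) < spec$doublet_rate
    cls2 <- ifelse(is_dbl,
                   sample.int(n_class, n_cells, replace = TRUE,
                              prob = spec$classes$prop),
                   NA_integer_)
    counts <- matrix(0L, nrow = n_cells, ncol = length(spec$genes),
                     dimnames = list(bc, spec$genes))
    for (i in seq_len(n_cells)) {
      v <- draw_profile(spec, cls1[i])
      if (is_dbl[i]) v <- v + draw_profile(spec, cls2[i])
      counts[i, ] <- v
    }
    list(bc = bc, cls1 = cls1, cls2 = cls2, is_dbl = is_dbl, counts = counts)
  })
  sp1 <- spec$classes$species[out$cls1]
  sp2 <- ifelse(out$is_dbl, spec$classes$species[out$cls2], sp1)
  cells <- data.frame(
    barcode = out$bc,
    class = spec$classes$class[out$cls1],
    side = spec$classes$side[out$cls1],
    species = ifelse(sp1 == sp2, sp1, "mixed"),
    is_doublet = out$is_dbl,
    stringsAsFactors = FALSE
  )
  cnt <- if (n_cells > 0) dge(out$counts) else
    dge(matrix(0, 0, length(spec$genes),
               dimnames = list(character(), spec$genes)))
  structure(list(cells = cells, counts = cnt, spec = spec),
            class = "ground_truth")
}

#' @export
print.ground_truth <- function(x, ...) {
  cat(sprintf("ground_truth: %d cells, %d genes, %d total fragments\n",
              nrow(x$cells), length(x$spec$genes), sum(x$counts$counts)))
  invisible(x)
}

#' Write ground truth as TSV
#' @param truth a `ground_truth`.
#' @param path output TSV path (cell table; counts are written next to it
#'   as `<path>.counts.tsv`).
#' @return `path`, invisibly.
#' @export
write_ground_truth <- function(truth, path) {
  stopifnot(inherits(truth, "ground_truth"))
  atomic_write(path, function(tmp) {
    write.table(truth$cells, tmp, sep = "\t", quote = FALSE, row.names = FALSE)
  })
  write_dge(truth$counts, paste0(path, ".counts.tsv"), format = "tsv")
  invisible(path)
}

apply_substitutions <- function(seqs, rate) {
  if (rate <= 0 || length(seqs) == 0L) return(seqs)
  widths <- nchar(seqs)
  n_err <- rbinom(length(seqs), widths, rate)
  hit <- which(n_err > 0L)
  for (i in hit) {
    pos <- sample.int(widths[i], n_err[i])
    chars <- strsplit(seqs[i], "", fixed = TRUE)[[1]]
    for (p in pos) {
      chars[p] <- sample(setdiff(DNA_BASES, chars[p]), 1L)
    }
    seqs[i] <- paste(chars, collapse = "")
  }
  seqs
}

#' Default layout of read 1
#'
#' Read 1 starts with the 12-nt cell barcode; the remainder of the read is a
#' fixed downstream primer/anchor sequence from the capture oligo.  The
#' anchor content is configurable and defaults to the 3' flank of the bead
#' oligo.
#'
#' @param barcode_len barcode length (default 12).
#' @param anchor fixed sequence following the barcode on read 1.
#' @param read1_len total read-1 length; the barcode + anchor string is
#'   truncated or A-padded to this length.
#' @param read2_len read-2 (cDNA) length.
#' @param capture_window read-2 start positions are drawn uniformly from the
#'   final `capture_window` nt of the transcript, modeling 3' bias from
#'   oligo-dT capture.
#' @return An object of class `read_layout`.
#' @export
read_layout <- function(barcode_len = 12L,
                        anchor = "ACATAGGCCGTCTTCAGCCGCTGAGACTGCC",
                        read1_len = 43L, read2_len = 75L,
                        capture_window = 300L) {
  barcode_len <- assert_count(barcode_len, "barcode_len")
  read1_len <- assert_count(read1_len, "read1_len")
  read2_len <- assert_count(read2_len, "read2_len")
  capture_window <- assert_count(capture_window, "capture_window")
  if (read1_len < barcode_len) stop_invalid("read1_len must cover the barcode")
  if (capture_window < read2_len) stop_invalid("capture_window must be >= read2_len")
  if (nzchar(anchor)) assert_dna(anchor, "anchor")
  structure(list(barcode_len = barcode_len, anchor = anchor,
                 read1_len = read1_len, read2_len = read2_len,
                 capture_window = capture_window),
            class = "read_layout")
}

#' Emit paired FASTQ for a simulated experiment
#'
#' One read pair per ground-truth cDNA fragment.  Read 1 carries the cell
#' barcode at offset 0 followed by the fixed anchor; read 2 is a
#' `read2_len`-nt substring of the assigned transcript with a 3'-biased
#' start.  Optional uniform substitution errors are applied to both reads.
#' Qualities are constant Phred+33 `"I"` (Q40).
#'
#' @param truth a [simulate_cells()] result.
#' @param transcriptome a [make_toy_transcriptome()] result containing every
#'   gene of the truth with transcripts at least `read2_len` nt long.
#' @param layout a [read_layout()].
#' @param error_rate per-base substitution probability (both reads).
#' @param seed integer seed.
#' @param r1_path,r2_path output FASTQ paths.
#' @return List with `r1`, `r2` (paths) and `n_pairs`.
#' @export
emit_fastq_pairs <- function(truth, transcriptome, layout = read_layout(),
                             error_rate = 0, seed = 1L,
                             r1_path, r2_path) {
  stopifnot(inherits(truth, "ground_truth"),
            inherits(transcriptome, "toy_transcriptome"),
            inherits(layout, "read_layout"))
  error_rate <- assert_proportion(error_rate, "error_rate")
  trip <- Matrix::summary(truth$counts$counts)
  gene_ids <- genes(truth$counts)[trip$j]
  missing <- setdiff(unique(gene_ids), transcriptome$gene_id)
  if (length(missing)) {
    stop_invalid("genes absent from transcriptome: ",
                 paste(missing, collapse = ", "))
  }
  tx_seq <- setNames(transcriptome$sequence, transcriptome$gene_id)
  bc_frag <- rep(barcodes(truth$counts)[trip$i], trip$x)
  gene_frag <- rep(gene_ids, trip$x)
  n <- length(bc_frag)

  reads <- with_seed(seed, {
    seqs <- tx_seq[gene_frag]
    L <- nchar(seqs)
    short <- L < layout$read2_len
    if (any(short)) {
      stop_invalid("transcripts shorter than read2_len: ",
                   paste(unique(gene_frag[short]), collapse = ", "))
    }
    lo <- pmax(1L, L - layout$capture_window + 1L)
    hi <- L - layout$read2_len + 1L
    start <- lo + floor(runif(n) * (pmax(hi, lo) - lo + 1L))
    start <- pmin(start, hi)
    r2 <- substr(seqs, start, start + layout$read2_len - 1L)
    r1 <- paste0(bc_frag, layout$anchor,
                 strrep("A", max(0L, layout$read1_len - layout$barcode_len -
                                   nchar(layout$anchor))))
    r1 <- substr(r1, 1L, layout$read1_len)
    list(r1 = apply_substitutions(r1, error_rate),
         r2 = apply_substitutions(unname(r2), error_rate))
  })

  ids <- sprintf("frag%07d", seq_len(n))
  write_fastq(ids, reads$r1, r1_path)
  write_fastq(ids, reads$r2, r2_path)
  list(r1 = r1_path, r2 = r2_path, n_pairs = n)
}

write_fastq <- function(ids, seqs, path) {
  set <- Biostrings::DNAStringSet(setNames(seqs, ids))
  qual <- Biostrings::BStringSet(setNames(strrep("I", nchar(seqs)), ids))
  atomic_write(path, function(tmp) {
    Biostrings::writeXStringSet(set, tmp, format = "fastq", qualities = qual,
                                compress = grepl("\\.gz$", path))
  })
  invisible(path)
}

#' Read a FASTQ file
#'
#' @param path FASTQ path (gzip accepted).
#' @return Data frame with columns `id`, `sequence`, `quality`.
#' @export
read_fastq <- function(path) {
  set <- Biostrings::readDNAStringSet(path, format = "fastq",
                                      with.qualities = TRUE)
  data.frame(id = sub(" .*$", "", names(set)),
             sequence = as.character(set),
             quality = as.character(S4Vectors::mcols(set)$qualities),
             stringsAsFactors = FALSE, row.names = NULL)
}
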