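#' Microwell occupancy probability
#'
#' Probability that a given well receives exactly `k` cells when cells settle
#' independently and uniformly into a large number of wells, i.e. the Poisson
#' pmf `exp(-lambda) * lambda^k / k!` at the mean occupancy `lambda`
#' (cells per well).
#'
#' @param lambda mean number of cells per well (>= 0).
#' @param k occupancy (integer >= 0), vectorized.
#' @return Probability (or vector of probabilities).
#' @export
#' @examples
#' occupancy_pmf(0.05, 0:3)
occupancy_pmf <- function(lambda, k) {
  if (length(lambda) != 1L || !is.numeric(lambda) || is.na(lambda) || lambda < 0) {
    stop_invalid("`lambda` must be a single number >= 0")
  }
  if (!is.numeric(k) || anyNA(k) || any(k < 0) || any(k != floor(k))) {
    stop_invalid("`k` must contain non-negative integers")
  }
  dpois(k, lambda)
}

#' Fraction of deposited cells that land alone in a well
#'
#' For a cell that has settled into some well, the probability that no other
#' cell shares that well.  In the Poisson limit this is `exp(-lambda)` where
#' `lambda` is the cell:well ratio; at the 1:20 ratio used on a microwell
#' slide (`lambda = 0.05`) it evaluates to 0.951, i.e. 95% of cells are
#' deposited one cell per well.  When finite counts are supplied the exact
#' finite-population form `(1 - 1/n_wells)^(n_cells - 1)` is used instead.
#'
#' @param ratio mean cells per well (`lambda`). Ignored when both `n_cells`
#'   and `n_wells` are given.
#' @param n_cells,n_wells optional finite counts of deposited cells and of
#'   wells; when supplied the exact form is returned.
#' @return Proportion in \[0, 1\].
#' @export
#' @examples
#' singlet_fraction_of_cells(0.05)                       # 0.9512
#' singlet_fraction_of_cells(n_cells = 8000, n_wells = 160000)
singlet_fraction_of_cells <- function(ratio = NULL, n_cells = NULL, n_wells = NULL) {
  if (!is.null(n_cells) && !is.null(n_wells)) {
    n_cells <- assert_count(n_cells, "n_cells", min = 0L)
    n_wells <- assert_count(n_wells, "n_wells", min = 1L)
    if (n_cells == 0L) return(1)
    return((1 - 1 / n_wells)^(n_cells - 1))
  }
  if (is.null(ratio) || length(ratio) != 1L || !is.numeric(ratio) ||
      is.na(ratio) || ratio < 0) {
    stop_invalid("`ratio` must be a single number >= 0")
  }
  exp(-ratio)
}

#' Specification of a cell-loading experiment
#'
#' @param n_cells number of input cells applied to the slide.
#' @param n_wells number of microwells on the slide (default 160,000, the
#'   capacity of one slide).
#' @param seeding_efficiency fraction of input cells that settle into wells
#'   (default 0.9, the measured seeding efficiency).
#' @param bead_occupancy fraction of wells carrying a bead.  Bead loading is
#'   squeegeed to one bead per well, so the default is 1 (deterministic full
#'   occupancy).
#' @param seed integer seed.
#' @return An object of class `loading_spec`.
#' @export
loading_spec <- function(n_cells = 10000L, n_wells = 160000L,
                         seeding_efficiency = 0.9, bead_occupancy = 1,
                         seed = 1L) {
  n_cells <- assert_count(n_cells, "n_cells", min = 0L)
  n_wells <- assert_count(n_wells, "n_wells", min = 1L)
  seeding_efficiency <- assert_proportion(seeding_efficiency, "seeding_efficiency")
  bead_occupancy <- assert_proportion(bead_occupancy, "bead_occupancy")
  structure(
    list(n_cells = n_cells, n_wells = n_wells,
         seeding_efficiency = seeding_efficiency,
         bead_occupancy = bead_occupancy, seed = seed),
    class = "loading_spec"
  )
}

#' Simulate gravity loading of cells into microwells
#'
#' Each input cell survives Bernoulli thinning with probability
#' `seeding_efficiency` and is then assigned to a uniformly random well.
#' The returned histogram counts wells by their occupancy `k`.
#'
#' @param spec a [loading_spec()].
#' @return An object of class `occupancy_histogram`: list with `counts_by_k`
#'   (named integer vector, names are occupancies `k` starting at 0),
#'   `n_deposited`, `n_wells`, `lambda` (realized cells/well), and `spec`.
#' @export
#' @examples
#' h <- simulate_loading(loading_spec(n_cells = 10000, seed = 7))
#' loading_summary(h)
simulate_loading <- function(spec) {
  stopifnot(inherits(spec, "loading_spec"))
  res <- with_seed(spec$seed, {
    n_dep <- rbinom(1L, spec$n_cells, spec$seeding_efficiency)
    wells <- if (n_dep > 0L) sample.int(spec$n_wells, n_dep, replace = TRUE) else integer()
    list(n_dep = n_dep, wells = wells)
  })
  occ <- tabulate(res$wells, nbins = spec$n_wells)
  kmax <- if (length(occ)) max(occ) else 0L
  counts_by_k <- tabulate(occ + 1L, nbins = kmax + 1L)
  names(counts_by_k) <- 0:kmax
  structure(
    list(counts_by_k = counts_by_k, n_deposited = res$n_dep,
         n_wells = spec$n_wells, lambda = res$n_dep / spec$n_wells,
         spec = spec),
    class = "occupancy_histogram"
  )
}

#' Summary statistics of an occupancy histogram
#'
#' @param hist an `occupancy_histogram` from [simulate_loading()].
#' @return One-row data frame with the realized `lambda`, the fractions of
#'   deposited cells in singlet and multiplet wells, and the fraction of
#'   occupied wells that hold one cell.
#' @export
loading_summary <- function(hist) {
  stopifnot(inherits(hist, "occupancy_histogram"))
  k <- as.integer(names(hist$counts_by_k))
  wells_k <- as.numeric(hist$counts_by_k)
  cells_k <- k * wells_k
  n_cells <- sum(cells_k)
  singlet_cells <- if (n_cells > 0) sum(cells_k[k == 1L]) / n_cells else NA_real_
  occupied <- sum(wells_k[k >= 1L])
  data.frame(
    n_deposited = hist$n_deposited,
    n_wells = hist$n_wells,
    lambda = hist$lambda,
    singlet_fraction_cells = singlet_cells,
    multiplet_fraction_cells = if (is.na(singlet_cells)) NA_real_ else 1 - singlet_cells,
    singlet_fraction_occupied_wells = if (occupied > 0) sum(wells_k[k == 1L]) / occupied else NA_real_
  )
}

#' @export
print.occupancy_histogram <- function(x, ...) {
  s <- loading_summary(x)
  cat(sprintf(
    "occupancy_histogram: %d cells deposited in %d wells (lambda = %.4f)\n",
    x$n_deposited, x$n_wells, x$lambda))
  cat(sprintf("  singlet fraction of cells: %.4f\n", s$singlet_fraction_cells))
  invisible(x)
}

#' Write an occupancy histogram as TSV
#'
#' Two-column table (`k`, `wells`) followed by no header comment; summary
#' statistics are written to `<path>.summary.tsv`.
#'
#' @param hist an `occupancy_histogram`.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_occupancy <- function(hist, path) {
  stopifnot(inherits(hist, "occupancy_histogram"))
  df <- data.frame(k = as.integer(names(hist$counts_by_k)),
                   wells = as.integer(hist$counts_by_k))
  atomic_write(path, function(tmp) {
    write.table(df, tmp, sep = "\t", quote = FALSE, row.names = FALSE)
  })
  atomic_write(paste0(path, ".summary.tsv"), function(tmp) {
    write.table(loading_summary(hist), tmp, sep = "\t", quote = FALSE,
                row.names = FALSE)
  })
  invisible(path)
}
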