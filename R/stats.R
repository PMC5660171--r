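mwu_statistic <- function(x, y) {
  n1 <- length(x)
  r <- rank(c(x, y))
  sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
}

#' Mann-Whitney U test
#'
#' Rank-sum test for two independent samples, the pairwise comparison used
#' throughout for positive-cell and expression contrasts.  The statistic is
#' computed from midranks (ties allowed).  `mode = "exact"` enumerates all
#' `choose(n1 + n2, n1)` group labelings of the pooled sample and returns
#' the exact two-sided permutation p-value; `mode = "approx"` uses the
#' normal approximation with tie-corrected variance and a 0.5 continuity
#' correction.  `mode = "auto"` picks exact when `n1 + n2 <= 16`.
#'
#' @param x,y numeric samples (each non-empty).
#' @param mode `"auto"`, `"exact"` or `"approx"`.
#' @return An object of class `mwu_test`: list with `statistic` (U of the
#'   first sample), `n1`, `n2`, `p_value`, `method`.
#' @export
#' @examples
#' mann_whitney_u(c(1, 2), c(3, 4), mode = "exact")$p_value  # 1/3
mann_whitney_u <- function(x, y, mode = c("auto", "exact", "approx")) {
  mode <- match.arg(mode)
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) < 1L || length(y) < 1L || anyNA(x) || anyNA(y)) {
    stop_invalid("both samples must be non-empty and free of NA")
  }
  n1 <- length(x); n2 <- length(y); N <- n1 + n2
  if (mode == "auto") mode <- if (N <= 16L) "exact" else "approx"
  u <- mwu_statistic(x, y)
  m <- n1 * n2 / 2

  if (mode == "exact") {
    pooled <- c(x, y)
    r <- rank(pooled)
    offset <- n1 * (n1 + 1) / 2
    labelings <- combn(N, n1)
    u_all <- colSums(matrix(r[labelings], nrow = n1)) - offset
    # the permutation distribution of U is symmetric about n1*n2/2
    p <- mean(abs(u_all - m) >= abs(u - m) - 1e-9)
  } else {
    ties <- table(c(x, y))
    sigma2 <- n1 * n2 / 12 * ((N + 1) - sum(ties^3 - ties) / (N * (N - 1)))
    if (sigma2 <= 0) {
      p <- 1  # all observations identical
    } else {
      z <- max(0, abs(u - m) - 0.5) / sqrt(sigma2)
      p <- min(1, 2 * pnorm(-z))
    }
  }
  structure(list(statistic = u, n1 = n1, n2 = n2, p_value = p, method = mode),
            class = "mwu_test")
}

#' @export
print.mwu_test <- function(x, ...) {
  cat(sprintf("Mann-Whitney U test (%s): U = %g (n1 = %d, n2 = %d), p = %.4g\n",
              x$method, x$statistic, x$n1, x$n2, x$p_value))
  invisible(x)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up false-discovery-rate correction of a vector of p-values,
#' validating the inputs and delegating to [stats::p.adjust()] with
#' `method = "BH"`.
#'
#' @param p_values numeric vector of p-values in (0, 1].
#' @return q-values in the original order.
#' @export
bh_fdr <- function(p_values) {
  if (length(p_values) == 0L) return(numeric(0))
  if (anyNA(p_values) || any(p_values <= 0) || any(p_values > 1)) {
    stop_invalid("p-values must lie in (0, 1]")
  }
  p.adjust(p_values, method = "BH")
}

#' Pearson correlation on log-transformed expression
#'
#' Correlation of `log(value + pseudocount)`, the transform used when
#' comparing single-cell profiles with bulk libraries or replicate
#' experiments.
#'
#' @param x,y non-negative expression vectors of equal length (>= 2).
#' @param pseudocount added before the log (default 1).
#' @return Pearson correlation in \[-1, 1\].
#' @export
pearson_log <- function(x, y, pseudocount = 1) {
  if (length(x) != length(y) || length(x) < 2L) {
    stop_invalid("`x` and `y` must have equal length >= 2")
  }
  if (anyNA(x) || anyNA(y) || any(x < 0) || any(y < 0)) {
    stop_invalid("expression values must be non-negative and free of NA")
  }
  lx <- log(x + pseudocount)
  ly <- log(y + pseudocount)
  if (stats::var(lx) == 0 || stats::var(ly) == 0) {
    stop_invalid("undefined correlation: zero variance after log transform")
  }
  cor(lx, ly)
}

#' Per-gene two-side comparison with FDR correction
#'
#' Runs [mann_whitney_u()] for each gene between two expression matrices
#' (e.g. the two tissue sides) and adjusts the p-values with [bh_fdr()].
#'
#' @param x,y [dge()] objects sharing the genes in `genes`.
#' @param genes genes to test (default: intersection).
#' @param mode test mode passed to [mann_whitney_u()].
#' @return Data frame with columns `gene`, `u`, `p_value`, `q_value`.
#' @export
compare_sides <- function(x, y, genes = NULL, mode = "approx") {
  stopifnot(inherits(x, "dge"), inherits(y, "dge"))
  if (is.null(genes)) genes <- intersect(colnames(x$counts), colnames(y$counts))
  if (length(genes) == 0L) stop_invalid("no shared genes to compare")
  res <- lapply(genes, function(g) {
    t <- mann_whitney_u(as.numeric(x$counts[, g]), as.numeric(y$counts[, g]),
                        mode = mode)
    data.frame(gene = g, u = t$statistic, p_value = t$p_value)
  })
  out <- do.call(rbind, res)
  out$q_value <- bh_fdr(out$p_value)
  out
}
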