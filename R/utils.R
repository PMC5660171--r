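#' @importFrom stats dpois rbinom rpois runif cor pnorm setNames dist hclust cutree p.adjust
#' @importFrom utils read.delim write.table combn
NULL

DNA_BASES <- c("A", "C", "G", "T")

stop_invalid <- function(...) {
  stop(..., call. = FALSE)
}

assert_count <- function(x, name, min = 1L) {
  if (length(x) != 1L || !is.numeric(x) || is.na(x) || x != floor(x) || x < min) {
    stop_invalid(sprintf("`%s` must be a single integer >= %d", name, min))
  }
  as.integer(x)
}

assert_proportion <- function(x, name) {
  if (length(x) != 1L || !is.numeric(x) || is.na(x) || x < 0 || x > 1) {
    stop_invalid(sprintf("`%s` must be a single number in [0, 1]", name))
  }
  as.numeric(x)
}

assert_dna <- function(x, name) {
  if (!is.character(x) || anyNA(x) || any(grepl("[^ACGT]", x))) {
    stop_invalid(sprintf("`%s` must contain only A/C/G/T characters", name))
  }
  x
}

#' Round half away from zero
#'
#' Printed tables in this field round 0.5 up rather than to even, so the
#' side-table percentages and folds use explicit half-up rounding instead of
#' [base::round()].
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return `x` rounded to `digits` places, ties away from zero.
#' @keywords internal
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# Seeded evaluation that restores the caller's RNG state afterwards.
with_seed <- function(seed, code) {
  seed <- assert_count(seed, "seed", min = 0L)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Write a file atomically: render to a sibling temp path, then rename.
atomic_write <- function(path, writer) {
  tmp <- paste0(path, ".tmp", Sys.getpid())
  on.exit(if (file.exists(tmp)) unlink(tmp), add = TRUE)
  writer(tmp)
  if (!file.rename(tmp, path)) {
    stop_invalid("failed to move temporary file into place for ", path)
  }
  invisible(path)
}
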