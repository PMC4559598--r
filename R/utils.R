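#' @keywords internal
"_PACKAGE"

#' @importFrom stats cor cor.test qt pt qnorm pbinom rnorm rpois runif rlnorm
#'   sd var
#' @importFrom utils head read.table write.table
NULL

# Evaluate `expr` under a local RNG state seeded with `seed`, restoring the
# caller's .Random.seed afterwards. All stochastic operations in the package
# route their randomness through this so no call touches global RNG state.
with_local_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("`seed` must be a single integer", call. = FALSE)
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  expr
}

# Derive a per-stage seed from a master seed, kept inside 32-bit integer range.
derive_seed <- function(seed, offset) {
  as.integer((as.double(seed) * 48271 + offset) %% 2147483647)
}

#' Upper-triangle edge index table
#'
#' Canonical edge ordering used throughout the package: all unordered region
#' pairs (i, j) with i < j, row-major over the upper triangle.
#'
#' @param n Number of regions.
#' @return Integer matrix with columns `i` and `j` (1-based indices) and one
#'   row per unordered pair, in canonical order.
#' @export
edge_index <- function(n) {
  stopifnot(n >= 2)
  idx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  ord <- order(idx[, "row"], idx[, "col"])
  out <- cbind(i = idx[ord, "row"], j = idx[ord, "col"])
  rownames(out) <- NULL
  out
}

# Extract upper-triangle values of a symmetric matrix in canonical edge order.
upper_values <- function(m) {
  n <- nrow(m)
  ei <- edge_index(n)
  m[cbind(ei[, 1], ei[, 2])]
}

# Rebuild a symmetric matrix (zero diagonal) from canonical edge-order values.
matrix_from_upper <- function(values, n) {
  m <- matrix(0, n, n)
  ei <- edge_index(n)
  m[cbind(ei[, 1], ei[, 2])] <- values
  m[cbind(ei[, 2], ei[, 1])] <- values
  m
}

#' Temporal mean and variability of a series
#'
#' The shared kernel behind all temporal statistics: arithmetic mean over
#' windows and the unbiased (n - 1) sample variance. Every edge-level and
#' metric-level temporal summary in the package reduces to this kernel, so
#' the two conventions cannot drift apart.
#'
#' @param x Numeric vector (one value per sliding window).
#' @param variability Either `"var"` (sample variance, the default) or
#'   `"std"` (its square root). All sign-level conclusions are invariant to
#'   this monotone choice.
#' @return Named list with components `mean` and `variability`.
#' @export
temporal_stats <- function(x, variability = c("var", "std")) {
  variability <- match.arg(variability)
  if (length(x) < 2L) {
    stop("temporal variability is undefined for fewer than 2 windows",
         call. = FALSE)
  }
  m <- mean(x)
  v <- sum((x - m)^2) / (length(x) - 1L)
  if (variability == "std") v <- sqrt(v)
  list(mean = m, variability = v)
}

check_square_symmetric <- function(m, tol = 1e-10, what = "matrix") {
  if (!is.matrix(m) || nrow(m) != ncol(m)) {
    stop(what, " must be a square matrix", call. = FALSE)
  }
  if (anyNA(m)) stop(what, " contains missing values", call. = FALSE)
  d <- max(abs(m - t(m)))
  if (d > tol) {
    stop(what, " is not symmetric (max |m - t(m)| = ",
         format(d, digits = 3), ")", call. = FALSE)
  }
  invisible(TRUE)
}
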