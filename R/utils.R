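#' Evaluate an expression with a temporary RNG seed
#'
#' Runs `expr` under `set.seed(seed)` and restores the caller's RNG state
#' afterwards, so seeded components do not perturb the global random stream.
#'
#' @param seed Integer seed.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    stop("seed must be a single finite number")
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
  })
  set.seed(as.integer(seed))
  expr
}

# Derive a bounded child seed from a base seed and stream labels.
# Keeps results reproducible per (seed, label...) while staying < 2^31.
derive_seed <- function(seed, ...) {
  parts <- c(seed, ...)
  x <- 0
  for (p in parts) x <- (x * 69069 + as.numeric(p) %% 1e6) %% 2147483629
  as.integer(x) + 1L
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Euclidean distances from one point set (n x 3) to a single point (length 3).
dist_to_point <- function(pts, p) {
  sqrt((pts[, 1] - p[1])^2 + (pts[, 2] - p[2])^2 + (pts[, 3] - p[3])^2)
}

# Centered moving sum along the first dimension of a matrix/vector with a
# window of `width` samples (odd); edges use partial windows.
running_sum <- function(x, width) {
  if (width <= 1L) return(x)
  x <- as.matrix(x)
  n <- nrow(x)
  h <- (width - 1L) %/% 2L
  cs <- apply(x, 2, cumsum)
  cs <- rbind(matrix(0, 1, ncol(x)), as.matrix(cs))
  lo <- pmax(0L, seq_len(n) - h - 1L)
  hi <- pmin(n, seq_len(n) + h)
  out <- cs[hi + 1L, , drop = FALSE] - cs[lo + 1L, , drop = FALSE]
  out
}
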