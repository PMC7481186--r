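# Internal helpers shared across modules.

# Canonical category order used everywhere (rows/cols of 3x3 matrices,
# trajectory keyframes, ROI profiles).
CATEGORIES <- c("human_face", "illusory_face", "matched_object")

#' Evaluate code with a temporary RNG seed
#'
#' Runs `code` under `set.seed(seed)` and restores the caller's RNG state
#' afterwards, so seeded generators never perturb the global random stream.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1)
  }
  old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  code
}

# Derive a stage seed from a master seed; stays below 2^31 - 1.
derive_seed <- function(master, offset) {
  ((as.integer(master) %% 100000L) * 20011L + as.integer(offset) * 7919L) %%
    2147483647L
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

check_no_na <- function(x, what) {
  if (anyNA(x)) stopf("'%s' contains missing values", what)
  if (is.numeric(x) && !all(is.finite(x))) {
    stopf("'%s' contains non-finite values", what)
  }
  invisible(x)
}

# Validate a 3x3 (or n x n) category-distance matrix: symmetric, zero
# diagonal, nonnegative. Errors name the offending cell.
check_distance_matrix <- function(d, what = "delta", tol = 1e-10) {
  if (!is.matrix(d) || nrow(d) != ncol(d)) {
    stopf("'%s' must be a square matrix", what)
  }
  check_no_na(d, what)
  for (i in seq_len(nrow(d))) {
    if (abs(d[i, i]) > tol) stopf("'%s[%d,%d]' must be zero", what, i, i)
    for (j in seq_len(ncol(d))) {
      if (d[i, j] < -tol) stopf("'%s[%d,%d]' is negative", what, i, j)
      if (abs(d[i, j] - d[j, i]) > tol) {
        stopf("'%s[%d,%d]' differs from '%s[%d,%d]' (not symmetric)",
              what, i, j, what, j, i)
      }
    }
  }
  invisible(d)
}

# Torgerson double centering: B = -1/2 J D2 J with J = I - 11'/n.
double_center <- function(d2) {
  n <- nrow(d2)
  rm <- rowMeans(d2)
  cm <- colMeans(d2)
  gm <- mean(d2)
  -0.5 * (d2 - outer(rm, rep(1, n)) - outer(rep(1, n), cm) + gm)
}

# Strict lower triangle, row-major, of a square matrix. This is the single
# canonical RDM vectorization used by every RDM-RDM statistic in the package.
lower_tri_vec <- function(m) {
  n <- nrow(m)
  out <- numeric(n * (n - 1) / 2)
  k <- 1L
  for (i in seq_len(n)[-1]) {
    cnt <- i - 1L
    out[k:(k + cnt - 1L)] <- m[i, seq_len(cnt)]
    k <- k + cnt
  }
  out
}
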