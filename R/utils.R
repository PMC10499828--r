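#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement between two labellings of the same observations.
#' Used throughout the test-suite to score subtype recovery against simulated
#' ground truth.
#'
#' @param a,b label vectors of equal length (any atomic type; compared as
#'   factors).
#' @return A single number in \eqn{[-1, 1]}; 1 means identical partitions,
#'   0 is the expectation under random labelling.
#' @examples
#' adjusted_rand_index(c(1, 1, 2, 2), c("a", "a", "b", "b"))
#' @export
adjusted_rand_index <- function(a, b) {
  if (length(a) != length(b)) stop("`a` and `b` must have equal length")
  if (length(a) < 2L) stop("need at least 2 observations")
  tab <- table(a, b)
  n <- sum(tab)
  sum_comb <- function(x) sum(choose(x, 2))
  sij <- sum_comb(tab)
  si <- sum_comb(rowSums(tab))
  sj <- sum_comb(colSums(tab))
  expected <- si * sj / choose(n, 2)
  max_index <- (si + sj) / 2
  if (max_index == expected) return(1) # both partitions trivial
  (sij - expected) / (max_index - expected)
}

# Moore-Penrose pseudo-inverse via SVD; used for the log-rank covariance when
# the (k-1)-dim block is numerically singular (e.g. a group with no events).
pseudo_inverse <- function(m, tol = sqrt(.Machine$double.eps)) {
  s <- svd(m)
  keep <- s$d > tol * max(s$d, 0)
  if (!any(keep)) return(matrix(0, ncol(m), nrow(m)))
  s$v[, keep, drop = FALSE] %*% (t(s$u[, keep, drop = FALSE]) / s$d[keep])
}

# Stop unless all named columns are present; error names the first missing one.
check_columns <- function(df, cols, what = "table") {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0L) {
    stop(sprintf("%s is missing required column(s): %s", what,
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  invisible(df)
}

# Restore the caller's RNG state on exit so seeded generators do not perturb
# the global random stream.
local_seed <- function(seed, envir = parent.frame()) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_seed) get(".Random.seed", envir = globalenv()) else NULL
  do.call(on.exit, list(quote({
    if (!is.null(.tmesub_old_seed)) {
      assign(".Random.seed", .tmesub_old_seed, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }), add = TRUE), envir = envir)
  assign(".tmesub_old_seed", old, envir = envir)
  set.seed(seed)
  invisible(seed)
}
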