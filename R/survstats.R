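#' Kaplan-Meier product-limit estimate
#'
#' Nonparametric survival curve from right-censored records, computed per
#' group: at each distinct event time the curve drops by the factor
#' `1 - d/n`; censored-only times only shrink the risk set.
#'
#' @param records data.frame with `time` (>= 0), `event` (1 event /
#'   0 censored) and optionally `group`.
#' @param group optional name of the grouping column (default `"group"` when
#'   present, otherwise a single group).
#' @return object of class `km_fit`: data.frame with `group`, `time`,
#'   `n_risk`, `n_event`, `n_censor`, `surv` (one row per distinct time).
#' @seealso [km_at()] to evaluate the step function.
#' @export
km_estimate <- function(records, group = if ("group" %in% names(records)) "group" else NULL) {
  check_columns(records, c("time", "event"), "survival records")
  if (nrow(records) == 0L) stop("no survival records")
  if (any(!is.finite(records$time)) || any(records$time < 0)) {
    stop("times must be finite and >= 0")
  }
  grp <- if (is.null(group)) rep("all", nrow(records)) else as.character(records[[group]])
  out <- do.call(rbind, lapply(split(seq_len(nrow(records)), grp), function(ix) {
    tm <- records$time[ix]
    ev <- as.integer(records$event[ix])
    ts <- sort(unique(tm))
    n_risk <- vapply(ts, function(t) sum(tm >= t), integer(1))
    n_event <- vapply(ts, function(t) sum(tm == t & ev == 1L), integer(1))
    n_censor <- vapply(ts, function(t) sum(tm == t & ev == 0L), integer(1))
    surv <- cumprod(1 - n_event / n_risk)
    data.frame(group = grp[ix][1], time = ts, n_risk = n_risk,
               n_event = n_event, n_censor = n_censor, surv = surv,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  class(out) <- c("km_fit", "data.frame")
  out
}

#' Evaluate a Kaplan-Meier curve
#'
#' @param fit a [km_estimate()] result.
#' @param times numeric vector of evaluation times.
#' @param group group to evaluate (default: the single group in the fit).
#' @return survival probabilities S(t) (S(0) = 1; right-continuous steps).
#' @export
km_at <- function(fit, times, group = unique(fit$group)) {
  if (length(group) != 1L) stop("specify one group")
  sub <- fit[fit$group == group, , drop = FALSE]
  vapply(times, function(t) {
    below <- sub$time <= t
    if (!any(below)) 1 else sub$surv[max(which(below))]
  }, numeric(1))
}

#' Weighted log-rank family test
#'
#' K-sample test for equality of survival curves.  At each distinct event
#' time the per-group observed-minus-expected event counts are accumulated
#' with weight 1 (`"logrank"`) or the total number at risk
#' (`"gehan"`, the Gehan-Breslow-Wilcoxon generalization); the covariance
#' uses the hypergeometric variance formula (tie-corrected), and the
#' statistic is referred to a chi-squared distribution with
#' `groups - 1` degrees of freedom (upper tail).
#'
#' @param records data.frame with `time`, `event`, `group` (>= 2 groups,
#'   each with >= 1 record).
#' @param weight_scheme `"logrank"` or `"gehan"`.
#' @return object of class `wlr_test`: list with `statistic`, `df`,
#'   `p_value`, `observed`, `expected` (weighted, per group),
#'   `weight_scheme`.
#' @export
weighted_logrank <- function(records, weight_scheme = c("logrank", "gehan")) {
  weight_scheme <- match.arg(weight_scheme)
  check_columns(records, c("time", "event", "group"), "survival records")
  grp <- factor(records$group)
  k <- nlevels(grp)
  if (k < 2L) stop("need at least 2 groups")
  tm <- records$time
  ev <- as.integer(records$event)
  if (any(!is.finite(tm)) || any(tm < 0)) stop("times must be finite and >= 0")
  event_times <- sort(unique(tm[ev == 1L]))
  U <- numeric(k)
  V <- matrix(0, k, k)
  O <- numeric(k)
  E <- numeric(k)
  if (length(event_times) == 0L) {
    warning("no events in any group; statistic 0, p = 1")
    return(structure(list(statistic = 0, df = k - 1L, p_value = 1,
                          observed = O, expected = E,
                          weight_scheme = weight_scheme), class = "wlr_test"))
  }
  for (t in event_times) {
    at_risk <- tm >= t
    n_t <- sum(at_risk)
    n_jt <- tabulate(grp[at_risk], nbins = k)
    d_t <- sum(tm == t & ev == 1L)
    d_jt <- tabulate(grp[tm == t & ev == 1L], nbins = k)
    w <- if (weight_scheme == "gehan") n_t else 1
    e_jt <- n_jt * d_t / n_t
    U <- U + w * (d_jt - e_jt)
    O <- O + w * d_jt
    E <- E + w * e_jt
    if (n_t > 1L) {
      hyper <- d_t * (n_t - d_t) / (n_t - 1)
      v_t <- hyper * (diag(n_jt, k) * n_t - outer(n_jt, n_jt)) / n_t^2
      V <- V + w^2 * v_t
    }
  }
  idx <- seq_len(k - 1L)
  Vsub <- V[idx, idx, drop = FALSE]
  inv <- tryCatch(solve(Vsub), error = function(e) pseudo_inverse(Vsub))
  statistic <- drop(t(U[idx]) %*% inv %*% U[idx])
  statistic <- max(statistic, 0)
  structure(list(statistic = statistic, df = k - 1L,
                 p_value = stats::pchisq(statistic, df = k - 1L, lower.tail = FALSE),
                 observed = stats::setNames(O, levels(grp)),
                 expected = stats::setNames(E, levels(grp)),
                 weight_scheme = weight_scheme),
            class = "wlr_test")
}

#' Pearson chi-squared test of association
#'
#' Pearson chi-squared statistic on an r x c contingency table with
#' `(r-1)(c-1)` degrees of freedom; no continuity correction by default.
#'
#' @param table matrix of non-negative integer counts with positive margins.
#' @param correct apply Yates continuity correction (2x2 only).
#' @return list with `statistic`, `df`, `p_value`.
#' @export
chi_squared_association <- function(table, correct = FALSE) {
  table <- as.matrix(table)
  if (any(table < 0)) stop("counts must be non-negative")
  if (any(rowSums(table) == 0) || any(colSums(table) == 0)) {
    stop("all row and column margins must be positive")
  }
  res <- suppressWarnings(stats::chisq.test(table, correct = correct))
  list(statistic = unname(res$statistic), df = unname(res$parameter),
       p_value = unname(res$p.value))
}

#' Odds ratio with Woolf confidence interval
#'
#' For a 2x2 table `[[a, b], [c, d]]` (rows = groups, columns =
#' outcome/no-outcome), `OR = (a/b) / (c/d)` with the Woolf log-scale
#' confidence interval.  Alternatively the odds ratio can be reconstructed
#' from two printed proportions: `odds_ratio(p1 = , n1 = , p2 = , n2 = )`
#' computes `OR = (p1/(1-p1)) / (p2/(1-p2))` with the interval evaluated at
#' the implied (possibly non-integer) cell counts.
#'
#' @param table 2x2 count matrix, or `NULL` when proportions are given.
#' @param p1,n1,p2,n2 outcome proportions and group sizes.
#' @param correction add 0.5 to every cell when a zero cell makes the odds
#'   undefined (flagged in the result); without it a zero cell is an error.
#' @param conf_level confidence level for the Woolf interval.
#' @return list with `or`, `conf_int`, `cells`, `corrected`.
#' @export
odds_ratio <- function(table = NULL, p1 = NULL, n1 = NULL, p2 = NULL, n2 = NULL,
                       correction = FALSE, conf_level = 0.95) {
  if (is.null(table)) {
    if (is.null(p1) || is.null(n1) || is.null(p2) || is.null(n2)) {
      stop("supply either a 2x2 table or (p1, n1, p2, n2)")
    }
    cells <- c(a = p1 * n1, b = (1 - p1) * n1, c = p2 * n2, d = (1 - p2) * n2)
  } else {
    table <- as.matrix(table)
    if (!all(dim(table) == c(2L, 2L))) stop("odds ratio needs a 2x2 table")
    cells <- c(a = table[1, 1], b = table[1, 2], c = table[2, 1], d = table[2, 2])
  }
  corrected <- FALSE
  if (any(cells == 0)) {
    if (!correction) {
      stop("zero cell makes the odds undefined; set correction = TRUE for the 0.5 adjustment")
    }
    cells <- cells + 0.5
    corrected <- TRUE
  }
  or <- (cells["a"] / cells["b"]) / (cells["c"] / cells["d"])
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  se <- sqrt(sum(1 / cells))
  ci <- exp(log(or) + c(-1, 1) * z * se)
  list(or = unname(or), conf_int = unname(ci), cells = cells,
       corrected = corrected)
}

#' Tumor volume from caliper diameters
#'
#' The modified-ellipsoid caliper formula
#' \eqn{V = L \times S^2 / 2} with the large diameter `L` and small diameter
#' `S` in millimetres; volume in cubic millimetres.  If `S > L` the inputs
#' are swapped with a warning.
#'
#' @param large_diameter,small_diameter caliper diameters (mm, >= 0);
#'   vectorized.
#' @return tumor volume(s) in mm^3.
#' @examples
#' tumor_volume(20, 20)  # 4000 mm^3, the 2 x 2 cm institutional limit
#' @export
tumor_volume <- function(large_diameter, small_diameter) {
  if (any(large_diameter < 0) || any(small_diameter < 0)) {
    stop("diameters must be >= 0")
  }
  swap <- small_diameter > large_diameter
  if (any(swap)) {
    warning("small diameter exceeds large diameter; swapping")
    tmp <- large_diameter[swap]
    large_diameter[swap] <- small_diameter[swap]
    small_diameter[swap] <- tmp
  }
  large_diameter * small_diameter^2 / 2
}

#' Convert tumor-growth curves to threshold-crossing survival records
#'
#' Adapter for feeding longitudinal volume measurements to a survival test:
#' each subject's event time is the first day its volume reaches
#' `threshold_mm3`; subjects never reaching it are censored at their last
#' measurement.  (How published growth curves were fed to a
#' Gehan-Breslow-Wilcoxon comparison is unstated; time-to-threshold is this
#' package's documented convention.)
#'
#' @param volumes data.frame with `id`, `day`, `volume_mm3`, `group`.
#' @param threshold_mm3 volume threshold defining the event.
#' @return survival-record data.frame (`id`, `time`, `event`, `group`)
#'   suitable for [weighted_logrank()].
#' @export
volume_threshold_records <- function(volumes, threshold_mm3) {
  check_columns(volumes, c("id", "day", "volume_mm3", "group"), "volume table")
  if (threshold_mm3 <= 0) stop("threshold_mm3 must be positive")
  out <- do.call(rbind, lapply(split(volumes, volumes$id), function(sub) {
    sub <- sub[order(sub$day), , drop = FALSE]
    hit <- which(sub$volume_mm3 >= threshold_mm3)
    data.frame(id = sub$id[1],
               time = if (length(hit)) sub$day[hit[1]] else max(sub$day),
               event = as.integer(length(hit) > 0),
               group = sub$group[1], stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
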