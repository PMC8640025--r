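# Empirical-null false-discovery-rate selection on absolute scores.
#
# Model: |score| ~ eta0 * HalfNormal(sigma0) + (1 - eta0) * f_alt, with the
# mixture density estimated nonparametrically by a Grenander (monotone
# decreasing) estimator. The half-normal scale is fitted by truncated
# maximum likelihood on the sub-threshold scores so that genuine signals do
# not inflate the null.

# Truncated half-normal ML: maximize the likelihood of {a_i <= x0} under a
# half-normal conditioned on [0, x0].
fit_truncated_halfnormal <- function(a0, x0, lower, upper) {
  nll <- function(sig) {
    -sum(stats::dnorm(a0, 0, sig, log = TRUE)) +
      length(a0) * log(2 * stats::pnorm(x0 / sig) - 1)
  }
  stats::optimize(nll, interval = c(lower, upper))$minimum
}

#' Fit an empirical null to a vector of scores
#'
#' Treats the scores as correlation-scale statistics whose null component is
#' a zero-mean normal (half-normal on absolute values). The scale is fitted
#' by truncated maximum likelihood below a censoring threshold chosen
#' iteratively: starting from a robust (median-based) scale, the threshold
#' is placed at the null 97.5% quantile and the fit repeated until the
#' scale stabilises, a pragmatic version of the false-non-discovery-rate
#' censoring heuristic. The null proportion is the count below threshold
#' over the null mass below threshold.
#'
#' @param scores numeric vector of at least 50 scores (signed; absolute
#'   values are modelled).
#' @return list with `null_scale` (half-normal sigma), `eta0` (estimated
#'   null proportion in `[0, 1]`) and `threshold` (censoring point).
#' @export
fit_empirical_null <- function(scores) {
  a <- abs(as.numeric(scores))
  p <- length(a)
  if (p < 50L)
    stop_user("need at least 50 scores for density estimation (got %d); use a p-value based fallback",
              p)
  if (anyNA(a) || any(!is.finite(a))) stop_user("scores must be finite")
  if (max(a) - min(a) <= .Machine$double.eps * max(a, 1))
    stop_user("scores are all equal; no distribution to fit")
  sig <- stats::median(a) / stats::qnorm(0.75)
  if (sig <= 0) sig <- stats::quantile(a[a > 0], 0.5) / stats::qnorm(0.75)
  for (it in seq_len(25L)) {
    x0 <- sig * stats::qnorm(0.975)
    a0 <- a[a <= x0]
    if (length(a0) < 10L) {  # threshold collapsed; widen
      x0 <- stats::quantile(a, 0.5)
      a0 <- a[a <= x0]
    }
    new <- fit_truncated_halfnormal(a0, x0, sig / 100, max(a) * 2)
    done <- abs(new - sig) < 1e-8 * sig
    sig <- new
    if (done) break
  }
  x0 <- sig * stats::qnorm(0.975)
  eta0 <- clip(mean(a <= x0) / (2 * stats::pnorm(x0 / sig) - 1), 0, 1)
  list(null_scale = sig, eta0 = eta0, threshold = x0)
}

# Grenander estimator of a decreasing density on [0, Inf): the left slope
# of the least concave majorant of the ECDF. Returns a function evaluating
# the density.
grenander_density <- function(a) {
  n <- length(a)
  u <- sort(unique(a))
  Fx <- cumsum(tabulate(match(sort(a), u))) / n
  px <- c(0, u); py <- c(0, Fx)
  # least concave majorant via upper hull (slopes strictly decreasing)
  hull <- c(1L)
  for (i in 2:length(px)) {
    while (length(hull) >= 2L) {
      k <- length(hull)
      s1 <- (py[i] - py[hull[k]]) / (px[i] - px[hull[k]])
      s2 <- (py[hull[k]] - py[hull[k - 1L]]) / (px[hull[k]] - px[hull[k - 1L]])
      if (s1 >= s2) hull <- hull[-k] else break
    }
    hull <- c(hull, i)
  }
  hx <- px[hull]; hy <- py[hull]
  slopes <- diff(hy) / diff(hx)
  function(x) {
    i <- findInterval(x, hx, left.open = TRUE)
    i <- clip(i, 1L, length(slopes))
    slopes[i]
  }
}

#' Select features at a target false discovery rate
#'
#' Converts a score table into a selected set. The tail-area false
#' discovery rate of a feature with absolute score `a` is
#' `Fdr(a) = eta0 * P0(|S| >= a) / Phat(|S| >= a)` (null exceedance mass
#' from the fitted half-normal over empirical exceedance mass), monotonised
#' to be non-increasing in `a` and capped at 1; the local fdr is
#' `eta0 * f0(a) / f(a)` with `f` the Grenander estimate of the mixture
#' density. Features with tail Fdr at or below `fdr_level` are selected.
#'
#' @param table an `ecar_scores` data frame (from [ecar_scores()]), or any
#'   data frame with `feature_id` and `score` columns, or a numeric vector
#'   of scores.
#' @param fdr_level target false discovery rate in `(0, 1]` (default 0.05).
#' @param null optional pre-fitted null from [fit_empirical_null()].
#' @return a `data.frame` of class `ecar_selection` with columns
#'   `feature_id`, `score`, `statistic` (absolute score), `local_fdr`,
#'   `tail_fdr` and `selected`, plus attributes `null_scale`, `eta0` and
#'   `fdr_level`.
#' @export
select_features <- function(table, fdr_level = 0.05, null = NULL) {
  if (is.numeric(table))
    table <- data.frame(feature_id = names(table) %||%
                          sprintf("f%d", seq_along(table)),
                        score = as.numeric(table))
  if (!all(c("feature_id", "score") %in% names(table)))
    stop_user("'table' needs feature_id and score columns")
  if (!is.numeric(fdr_level) || length(fdr_level) != 1L ||
      fdr_level <= 0 || fdr_level > 1)
    stop_user("fdr_level must be in (0, 1]")
  a <- abs(table$score)
  p <- length(a)
  if (is.null(null)) null <- fit_empirical_null(table$score)
  sig <- null$null_scale; eta0 <- null$eta0

  # tail Fdr, monotone non-increasing in |score|
  o <- order(-a)                                 # most significant first
  surv0 <- 2 * stats::pnorm(a[o] / sig, lower.tail = FALSE)
  # empirical P(|S| >= a_(k)); equal scores share their largest exceedance
  exceed <- ave(seq_len(p) / p, a[o], FUN = max)
  raw <- clip(eta0 * surv0 / exceed, 0, 1)
  tail_fdr <- numeric(p)
  tail_fdr[o] <- rev(cummin(rev(raw)))           # monotonise (BH-style)

  f <- grenander_density(a)
  f0 <- 2 * stats::dnorm(a, 0, sig)
  local_fdr <- clip(eta0 * f0 / pmax(f(a), .Machine$double.xmin), 0, 1)

  out <- data.frame(feature_id = table$feature_id,
                    score = table$score,
                    statistic = a,
                    local_fdr = local_fdr,
                    tail_fdr = tail_fdr,
                    selected = tail_fdr <= fdr_level,
                    stringsAsFactors = FALSE)
  structure(out, class = c("ecar_selection", "data.frame"),
            null_scale = sig, eta0 = eta0, fdr_level = fdr_level)
}

#' @export
print.ecar_selection <- function(x, ...) {
  cat(sprintf(
    "FDR selection: %d of %d features at level %g (null scale %.4g, eta0 %.3f)\n",
    sum(x$selected), nrow(x), attr(x, "fdr_level"),
    attr(x, "null_scale"), attr(x, "eta0")))
  sel <- x[x$selected, ]
  if (nrow(sel)) print.data.frame(sel[order(-sel$statistic), ],
                                  row.names = FALSE)
  invisible(x)
}
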