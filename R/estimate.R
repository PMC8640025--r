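# Data-driven estimates of the signal proportion R^2 and the sparsity s,
# the two inputs of the alpha-tuning simulation.

# Lasso path with penalty chosen by generalized cross-validation,
# GCV(lambda) = RSS / (n (1 - df/n)^2), df = number of nonzero coefficients.
# Returns the glmnet fit and the index of the chosen lambda.
gcv_lasso <- function(X, y, dfmax = NULL) {
  n <- nrow(X)
  fit <- glmnet::glmnet(X, y, family = "gaussian", alpha = 1,
                        nlambda = 100L, dfmax = dfmax %||% (n - 1L))
  pred <- stats::predict(fit, newx = X)
  rss <- colSums((y - pred)^2)
  df <- fit$df
  ok <- df < n & (is.null(dfmax) | df <= (dfmax %||% Inf))
  if (!any(ok)) return(list(fit = fit, index = 1L))
  gcv <- rss / (n * (1 - df / n)^2)
  gcv[!ok] <- Inf
  list(fit = fit, index = which.min(gcv))
}

lasso_support <- function(fit, index) {
  b <- fit$beta[, index]
  which(b != 0)
}

#' Estimate the signal proportion R-squared by refitted cross-validation
#'
#' Splits the samples into two halves; on each half a lasso (penalty by
#' generalized cross-validation, support capped at a quarter of the full
#' sample size) proposes a candidate support, and the *other* half refits
#' ordinary least squares on that support to estimate the residual
#' variance. The two variance estimates are averaged,
#' `R2 = 1 - sigma2 / var(y)`, the split is repeated `repeats` times, and
#' the mean is clipped to `[0.01, 0.99]`. Separating selection from
#' variance estimation avoids the downward bias of refitting on the
#' selecting half.
#'
#' @param x an `ecar_fm` or raw matrix.
#' @param y numeric outcome.
#' @param repeats number of random splits averaged (default 5).
#' @param seed integer seed for the splits.
#' @return a single value in `[0.01, 0.99]`.
#' @export
estimate_r2 <- function(x, y, repeats = 5L, seed = 1L) {
  fm <- standardize(x)
  if (fm$n < 20L) stop_user("refitted cross-validation needs at least 20 samples")
  y <- as.numeric(y)
  if (length(y) != fm$n) stop_user("outcome length mismatch")
  X <- fm$values
  vy <- stats::var(y)
  half_var <- function(sel, est) {
    cap <- max(1L, floor(length(est) / 2))
    g <- gcv_lasso(X[sel, , drop = FALSE], y[sel], dfmax = cap)
    supp <- lasso_support(g$fit, g$index)
    if (length(supp) > cap) {
      b <- abs(g$fit$beta[supp, g$index])
      supp <- supp[order(-b)][seq_len(cap)]
    }
    ye <- y[est]
    if (!length(supp)) return(stats::var(ye))
    f <- stats::lm.fit(cbind(1, X[est, supp, drop = FALSE]), ye)
    sum(f$residuals^2) / max(1L, length(est) - length(supp) - 1L)
  }
  set.seed(seed)
  r2s <- vapply(seq_len(repeats), function(r) {
    perm <- sample(fm$n)
    h1 <- perm[seq_len(fm$n %/% 2)]
    h2 <- setdiff(perm, h1)
    s2 <- (half_var(h1, h2) + half_var(h2, h1)) / 2
    1 - s2 / vy
  }, numeric(1L))
  clip(mean(r2s), 0.01, 0.99)
}

#' Estimate the number of influential features
#'
#' The cardinality of the support of a lasso fit whose penalty is chosen by
#' generalized cross-validation over the regularisation path. Returns at
#' least 1 (with a warning when the chosen support is empty).
#'
#' @inheritParams estimate_r2
#' @return a positive integer.
#' @export
estimate_s <- function(x, y) {
  fm <- standardize(x)
  y <- as.numeric(y)
  if (length(y) != fm$n) stop_user("outcome length mismatch")
  g <- gcv_lasso(fm$values, y)
  s <- length(lasso_support(g$fit, g$index))
  if (s < 1L) {
    warning("lasso selected no features; using s = 1")
    s <- 1L
  }
  s
}
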