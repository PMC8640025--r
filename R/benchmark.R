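# Competitor scoring methods and the evaluation protocols used to compare
# them: PR-AUC of the importance ranking, true-positive paths, and
# train/test MSE of top-ranked features.

#' Area under the precision-recall curve of an importance ranking
#'
#' Features are ranked by decreasing absolute score (ties broken by feature
#' index) and the ranked list is swept from the top; the area is computed
#' by step-function summation, i.e. average precision: the mean of the
#' precision at the rank of each truly influential feature.
#'
#' @param scores numeric score vector, or an `ecar_scores` table.
#' @param truth logical vector marking the truly influential features.
#' @return a single value in `[0, 1]`.
#' @export
pr_auc <- function(scores, truth) {
  if (inherits(scores, "ecar_scores") || is.data.frame(scores)) {
    o <- order(scores$rank)
  } else {
    o <- order(-abs(scores), seq_along(scores))
  }
  truth <- as.logical(truth)
  if (length(truth) != length(o)) stop_user("scores/truth length mismatch")
  if (!any(truth)) stop_user("truth contains no positives")
  tp <- cumsum(truth[o])
  prec <- tp / seq_along(tp)
  mean(prec[truth[o]])
}

#' True-positive path of a ranking
#'
#' @inheritParams pr_auc
#' @return integer vector whose k-th entry is the number of truly
#'   influential features among the top k.
#' @export
tp_path <- function(scores, truth) {
  if (inherits(scores, "ecar_scores") || is.data.frame(scores)) {
    o <- order(scores$rank)
  } else {
    o <- order(-abs(scores), seq_along(scores))
  }
  cumsum(as.logical(truth)[o])
}

method_score <- function(method, feature_ids, scores, rank = NULL) {
  structure(data.frame(feature_id = feature_ids,
                       score = as.numeric(scores),
                       rank = rank %||% rank_by_abs(scores),
                       stringsAsFactors = FALSE),
            class = c("ecar_method_score", "data.frame"),
            method = method)
}

#' Sure independence screening scores
#'
#' Absolute marginal Pearson correlation with the outcome; yields the same
#' ranking as [ecar_scores()] at `alpha = 0`.
#'
#' @inheritParams marginal_correlations
#' @return a method-score data frame (`feature_id`, `score`, `rank`).
#' @export
sis_scores <- function(x, y) {
  fm <- standardize(x)
  r <- marginal_correlations(fm, y)
  method_score("SIS", fm$feature_ids, abs(r))
}

#' Penalized-regression importance scores (two-stage ranking)
#'
#' Fits ridge (penalty by fivefold cross-validation) or lasso (penalty by
#' generalized cross-validation) and ranks features by absolute
#' coefficient. Because the lasso zeroes most coefficients, features
#' outside its support are appended in seeded random order after the
#' support, mirroring the convention that the lasso "chooses genes
#' randomly" once its selected set is exhausted.
#'
#' @inheritParams marginal_correlations
#' @param kind `"ridge"` or `"lasso"`.
#' @param seed seed for the cross-validation folds and the lasso tail
#'   order.
#' @return a method-score data frame.
#' @export
penalized_scores <- function(x, y, kind = c("ridge", "lasso"), seed = 1L) {
  kind <- match.arg(kind)
  fm <- standardize(x)
  y <- as.numeric(y)
  if (length(y) != fm$n) stop_user("outcome length mismatch")
  set.seed(seed)
  if (kind == "ridge") {
    cv <- glmnet::cv.glmnet(fm$values, y, alpha = 0, nfolds = 5L)
    b <- drop(stats::coef(cv, s = "lambda.min"))[-1L]
    if (all(b == 0)) stop_user("degenerate ridge fit: all coefficients zero")
    return(method_score("ridge", fm$feature_ids, abs(b)))
  }
  g <- gcv_lasso(fm$values, y)
  b <- abs(g$fit$beta[, g$index])
  supp <- which(b > 0)
  tail_feats <- setdiff(seq_len(fm$p), supp)
  ranked <- c(supp[order(-b[supp])],
              if (length(tail_feats) > 1L) sample(tail_feats) else tail_feats)
  rk <- integer(fm$p); rk[ranked] <- seq_len(fm$p)
  method_score("lasso", fm$feature_ids, b, rank = rk)
}

# Lasso support of exactly q features: take the largest path lambda giving
# q nonzero coefficients; if the path jumps over q, bisect on lambda, and
# as a last resort truncate the smallest support exceeding q to its q
# largest absolute coefficients.
lasso_exact_q <- function(X, y, q) {
  n <- nrow(X); p <- ncol(X)
  fit <- glmnet::glmnet(X, y, alpha = 1, nlambda = 100L, dfmax = q + 10L)
  df <- fit$df
  hit <- which(df == q)
  if (length(hit)) {
    b <- fit$beta[, hit[1L]]
    return(which(b != 0))
  }
  lo_i <- which(df < q); hi_i <- which(df > q)
  if (!length(hi_i)) {    # path ended early; refit at tiny lambda
    hi <- min(fit$lambda) / 100
  } else hi <- fit$lambda[min(hi_i)]
  lo <- if (length(lo_i)) fit$lambda[max(lo_i)] else max(fit$lambda) * 10
  for (it in seq_len(40L)) {
    mid <- sqrt(lo * hi)
    b <- as.matrix(glmnet::glmnet(X, y, alpha = 1, lambda = mid)$beta)[, 1L]
    k <- sum(b != 0)
    if (k == q) return(which(b != 0))
    if (k < q) lo <- mid else hi <- mid
  }
  b <- as.matrix(glmnet::glmnet(X, y, alpha = 1, lambda = hi)$beta)[, 1L]
  supp <- which(b != 0)
  if (length(supp) < q) stop_user("could not reach a lasso support of size %d", q)
  supp[order(-abs(b[supp]))][seq_len(q)]
}

#' Stability-selection scores
#'
#' Draws `n_subsamples` half-samples without replacement and runs a lasso
#' on each with its penalty tuned so that exactly
#' `q = round(sqrt(v * p * (2 * pi_cut - 1)))` features enter the model;
#' the score of a feature is its selection frequency. With the defaults
#' `v = 2.5`, `pi_cut = 0.7` this is the error-control calibration linking
#' the per-subsample selection count to the expected number of false
#' positives.
#'
#' @inheritParams marginal_correlations
#' @param n_subsamples number of half-sample draws (default 100).
#' @param v target expected number of false positives.
#' @param pi_cut selection-frequency cutoff entering the calibration.
#' @param seed integer seed.
#' @return a method-score data frame; attribute `q` records the
#'   per-subsample selection count.
#' @export
stability_selection_scores <- function(x, y, n_subsamples = 100L, v = 2.5,
                                       pi_cut = 0.7, seed = 1L) {
  fm <- standardize(x)
  y <- as.numeric(y)
  if (length(y) != fm$n) stop_user("outcome length mismatch")
  q <- round(sqrt(v * fm$p * (2 * pi_cut - 1)))
  half <- fm$n %/% 2L
  if (q > min(half - 1L, fm$p))
    stop_user("q = %d exceeds what a half-sample of %d can support", q, half)
  counts <- numeric(fm$p)
  set.seed(seed)
  for (b in seq_len(n_subsamples)) {
    sub <- sample(fm$n, half)
    supp <- lasso_exact_q(fm$values[sub, , drop = FALSE], y[sub], q)
    counts[supp] <- counts[supp] + 1
  }
  out <- method_score("stability_selection", fm$feature_ids,
                      counts / n_subsamples)
  attr(out, "q") <- q
  out
}

#' Importance scores for one named method
#'
#' Dispatcher used by the benchmark runner and the CLI.
#'
#' @inheritParams marginal_correlations
#' @param method one of `"ecar"`, `"car"`, `"sis"`, `"ridge"`, `"lasso"`,
#'   `"stability"`, `"rnd"` (seeded random permutation baseline).
#' @param alpha exponent for `"ecar"`.
#' @param seed seed for the stochastic methods.
#' @return a method-score data frame.
#' @export
method_scores <- function(x, y, method, alpha = 0.5, seed = 1L) {
  fm <- standardize(x)
  switch(method,
         ecar = {
           t <- ecar_scores(fm, y, alpha = alpha)
           out <- method_score("ECAR", t$feature_id, t$score, rank = t$rank)
           attr(out, "alpha") <- alpha
           out
         },
         car = {
           t <- car_scores(fm, y)
           method_score("CAR", t$feature_id, t$score, rank = t$rank)
         },
         sis = sis_scores(fm, y),
         ridge = penalized_scores(fm, y, "ridge", seed = seed),
         lasso = penalized_scores(fm, y, "lasso", seed = seed),
         stability = stability_selection_scores(fm, y, seed = seed),
         rnd = {
           set.seed(seed)
           method_score("RND", fm$feature_ids, stats::runif(fm$p))
         },
         stop_user("unknown method '%s'", method))
}

#' Test-set MSE of models built on top-ranked features
#'
#' For each random 2/3-1/3 train/test split and each `k`, fits the
#' evaluator (penalty by fivefold cross-validation on the training fold)
#' on the `k` top-ranked features and records the test mean squared error;
#' results are averaged over `n_splits` splits. Also reports the base
#' performance using all features.
#'
#' @inheritParams marginal_correlations
#' @param ranking integer rank vector (1 = most important) or a
#'   method-score data frame.
#' @param k_values numbers of top features to evaluate.
#' @param evaluator `"lasso"` or `"ridge"`.
#' @param n_splits number of random splits (default 10).
#' @param seed integer seed.
#' @return list with `mse_by_k` (named numeric) and `base_mse`.
#' @export
evaluate_mse <- function(x, y, ranking, k_values = c(5L, 10L, 20L, 30L),
                         evaluator = c("lasso", "ridge"), n_splits = 10L,
                         seed = 1L) {
  evaluator <- match.arg(evaluator)
  fm <- standardize(x)
  y <- as.numeric(y)
  if (is.data.frame(ranking)) ranking <- ranking$rank
  if (length(ranking) != fm$p) stop_user("ranking length mismatch")
  ord <- order(ranking)
  av <- if (evaluator == "lasso") 1 else 0
  fit_predict <- function(tr, te, cols, foldid) {
    ytr <- y[tr]
    if (stats::var(ytr) < .Machine$double.eps) return(rep(mean(ytr), length(te)))
    Xtr <- fm$values[tr, cols, drop = FALSE]
    if (length(cols) < 2L) {
      f <- stats::lm.fit(cbind(1, Xtr), ytr)
      return(drop(cbind(1, fm$values[te, cols, drop = FALSE]) %*% f$coefficients))
    }
    cv <- glmnet::cv.glmnet(Xtr, ytr, alpha = av, foldid = foldid)
    drop(stats::predict(cv, newx = fm$values[te, cols, drop = FALSE],
                        s = "lambda.min"))
  }
  set.seed(seed)
  res <- matrix(NA_real_, n_splits, length(k_values) + 1L)
  for (r in seq_len(n_splits)) {
    tr <- sample(fm$n, round(2 * fm$n / 3))
    te <- setdiff(seq_len(fm$n), tr)
    # one fold assignment per split so k = p reproduces the base fit exactly
    foldid <- sample(rep(1:5, length.out = length(tr)))
    for (j in seq_along(k_values)) {
      # only the set matters to the fit; sorted columns keep glmnet's
      # coordinate descent deterministic wrt the ranking's order
      cols <- sort(ord[seq_len(min(k_values[j], fm$p))])
      res[r, j] <- mean((y[te] - fit_predict(tr, te, cols, foldid))^2)
    }
    res[r, length(k_values) + 1L] <-
      mean((y[te] - fit_predict(tr, te, seq_len(fm$p), foldid))^2)
  }
  m <- colMeans(res)
  list(mse_by_k = stats::setNames(m[seq_along(k_values)], k_values),
       base_mse = m[length(k_values) + 1L])
}

#' Run a full simulation benchmark scenario
#'
#' Repeatedly draws a block compound-symmetry design and calibrated
#' response, scores every requested method, and summarises PR-AUC (median
#' and SD over replicates) and the pointwise-median true-positive path.
#'
#' @param spec an `ecar_block_spec`.
#' @param r_squared target R-squared of the simulated responses.
#' @param s number of influential features.
#' @param placement `"first_block"` or `"anywhere"`.
#' @param methods character vector of method names (see [method_scores()]).
#' @param reps number of replicate datasets.
#' @param alpha exponent used for the `"ecar"` method (typically the median
#'   from [alpha_calibration_study()] or [estimate_alpha()]).
#' @param coefficient_distribution passed to [make_response()].
#' @param seed master seed.
#' @param path_max truncate stored true-positive paths at this many top
#'   features (default 100).
#' @return list of class `ecar_benchmark`: `pr_auc_median`, `pr_auc_sd`
#'   (named by method), `tp_path_median` (matrix, methods x path_max),
#'   `pr_auc` (reps x methods matrix) and the scenario parameters.
#' @export
run_scenario <- function(spec = block_design_spec(), r_squared = 0.6,
                         s = 30L,
                         placement = c("first_block", "anywhere"),
                         methods = c("ecar", "car", "sis"),
                         reps = 100L, alpha = 0.5,
                         coefficient_distribution = "uniform01",
                         seed = 1L, path_max = 100L) {
  placement <- match.arg(placement)
  path_max <- min(path_max, spec$p)
  auc <- matrix(NA_real_, reps, length(methods),
                dimnames = list(NULL, methods))
  paths <- array(NA_real_, c(reps, length(methods), path_max))
  for (r in seq_len(reps)) {
    cs <- child_seed(seed, r)
    spec_r <- block_design_spec(spec$n, spec$p, spec$n_blocks,
                                spec$within_rho, seed = cs)
    fm <- make_block_design(spec_r)
    resp <- make_response(fm, s = s, r_squared = r_squared,
                          placement = placement, n_blocks = spec$n_blocks,
                          coefficient_distribution = coefficient_distribution,
                          seed = child_seed(cs, 1L))
    for (j in seq_along(methods)) {
      ms <- method_scores(fm, resp$y, methods[j], alpha = alpha,
                          seed = child_seed(cs, j + 1L))
      auc[r, j] <- pr_auc(rank_to_score(ms$rank), resp$truth)
      paths[r, j, ] <- tp_path(rank_to_score(ms$rank), resp$truth)[seq_len(path_max)]
    }
  }
  structure(list(pr_auc_median = apply(auc, 2L, stats::median),
                 pr_auc_sd = apply(auc, 2L, stats::sd),
                 tp_path_median = apply(paths, c(2L, 3L), stats::median),
                 pr_auc = auc,
                 r_squared = r_squared, s = s, placement = placement,
                 methods = methods, alpha = alpha, reps = reps, seed = seed),
            class = "ecar_benchmark")
}

# Convert a rank vector into a score whose |.|-ordering reproduces it, so
# pr_auc/tp_path honour method-specific tie-breaking (e.g. the lasso's
# random tail).
rank_to_score <- function(rank) {
  p <- length(rank)
  (p - rank + 1) / p
}

#' @export
print.ecar_benchmark <- function(x, ...) {
  cat(sprintf("Benchmark: R2 = %g, s = %d, placement = %s, %d replicates\n",
              x$r_squared, x$s, x$placement, x$reps))
  print(data.frame(method = x$methods,
                   pr_auc_median = round(x$pr_auc_median, 4),
                   pr_auc_sd = round(x$pr_auc_sd, 4)),
        row.names = FALSE)
  invisible(x)
}
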