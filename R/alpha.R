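#' Default exponent grid
#'
#' The 21 equally spaced points 0, 0.05, ..., 1 over which the adjustment
#' exponent alpha is tuned.
#'
#' @param k number of grid points (endpoints included).
#' @return strictly increasing numeric vector in `[0, 1]`.
#' @export
alpha_grid <- function(k = 21L) {
  if (k < 1L) stop_user("grid needs at least one point")
  if (k == 1L) return(0.5)
  seq(0, 1, length.out = k)
}

check_grid <- function(grid) {
  if (!is.numeric(grid) || !length(grid) || anyNA(grid) ||
      any(grid < 0 | grid > 1) || is.unsorted(grid, strictly = TRUE))
    stop_user("grid must be strictly increasing values in [0, 1]")
  grid
}

#' Response-simulation design for alpha tuning
#'
#' @param r_squared target coefficient of determination, strictly in (0, 1).
#' @param s number of influential features (positive integer).
#' @param coefficient_distribution distribution of the nonzero coefficients:
#'   `"uniform01"` (U(0,1), the default used throughout tuning),
#'   `"standard_normal"`, or `"folded_normal"` (|N(0,1)|); the latter two
#'   exist for sensitivity analysis.
#' @param seed optional integer seed.
#' @param support_pool optional integer vector of candidate influential
#'   indices (default: all features).
#' @return a list of class `ecar_sim_design`.
#' @export
simulation_design <- function(r_squared, s,
                              coefficient_distribution = c("uniform01",
                                                           "standard_normal",
                                                           "folded_normal"),
                              seed = NULL, support_pool = NULL) {
  coefficient_distribution <- match.arg(coefficient_distribution)
  if (!is.numeric(r_squared) || length(r_squared) != 1L ||
      r_squared <= 0 || r_squared >= 1)
    stop_user("r_squared must be strictly inside (0, 1)")
  s <- as.integer(s)
  if (is.na(s) || s < 1L) stop_user("s must be a positive integer")
  structure(list(r_squared = r_squared, s = s,
                 coefficient_distribution = coefficient_distribution,
                 seed = seed, support_pool = support_pool),
            class = "ecar_sim_design")
}

draw_coefficients <- function(s, distribution) {
  switch(distribution,
         uniform01 = stats::runif(s),
         standard_normal = stats::rnorm(s),
         folded_normal = abs(stats::rnorm(s)))
}

#' Simulate a Gaussian linear response with calibrated noise
#'
#' Draws a support of size `s` from the design's pool, nonzero coefficients
#' from its distribution, and Gaussian noise with variance
#' `sigma2 = (1 - R2) * ||X beta||^2 / (n * R2)`, which makes the population
#' R-squared (`||X beta||^2 / (||X beta||^2 + n sigma2)`) equal the target
#' exactly.
#'
#' @param x an `ecar_fm` or raw matrix.
#' @param design an `ecar_sim_design` from [simulation_design()].
#' @return list with `y`, `truth` (logical), `beta`, `sigma2`, `r_squared`.
#' @export
simulate_response <- function(x, design) {
  stopifnot(inherits(design, "ecar_sim_design"))
  fm <- standardize(x)
  pool <- design$support_pool %||% seq_len(fm$p)
  pool <- as.integer(pool)
  if (any(pool < 1L | pool > fm$p)) stop_user("support pool out of range")
  if (design$s > length(pool))
    stop_user("s = %d exceeds the %d candidate features", design$s, length(pool))
  if (!is.null(design$seed)) set.seed(design$seed)
  idx <- if (length(pool) == 1L) pool else sample(pool, design$s)
  beta <- numeric(fm$p)
  beta[idx] <- draw_coefficients(design$s, design$coefficient_distribution)
  mu <- drop(fm$values %*% beta)
  ss <- sum(mu^2)
  sigma2 <- (1 - design$r_squared) * ss / (fm$n * design$r_squared)
  y <- mu + stats::rnorm(fm$n, sd = sqrt(sigma2))
  list(y = y, truth = beta != 0, beta = beta, sigma2 = sigma2,
       r_squared = design$r_squared)
}

# Shared inner loop: given a cached decomposition of X, simulate one
# response and return the grid alpha maximizing PR-AUC of the |score|
# ranking against the simulated truth (ties -> smallest alpha).
best_alpha_from_decomp <- function(fm, dec, design, grid) {
  sim <- simulate_response(fm, design)
  ys <- standardize_response(sim$y, fm)
  rxy <- clip(drop(crossprod(fm$values, ys)) / (fm$n - 1), -1, 1)
  sc <- grid_scores_svd(dec, rxy, grid)
  aucs <- apply(sc, 2L, pr_auc, truth = sim$truth)
  grid[which.max(aucs)]
}

#' Best exponent for a single simulated replicate
#'
#' Simulates one response on the observed design, scores every feature at
#' every grid exponent (one decomposition, re-powered per alpha), and
#' returns the grid alpha with the highest PR-AUC against the simulated
#' truth. Ties go to the smallest alpha.
#'
#' @inheritParams simulate_response
#' @param grid exponent grid (see [alpha_grid()]).
#' @return a single grid value.
#' @export
best_alpha_one_replicate <- function(x, design, grid = alpha_grid()) {
  fm <- standardize(x)
  grid <- check_grid(grid)
  best_alpha_from_decomp(fm, svd_decomp(fm), design, grid)
}

#' Estimate the correlation-adjustment exponent alpha
#'
#' The tuning procedure: holding the observed design fixed, simulate `B`
#' responses at the (estimated or supplied) signal strength `r_squared` and
#' sparsity `s` -- support redrawn uniformly over all features each
#' replicate -- and record for each the grid alpha maximizing PR-AUC. The
#' estimate is the median of the `B` best values.
#'
#' @param x an `ecar_fm` or raw matrix.
#' @param r_squared optional known/assumed R-squared; estimated from `y` by
#'   [estimate_r2()] when `NULL`.
#' @param s optional number of influential features; estimated by
#'   [estimate_s()] when `NULL`.
#' @param y outcome vector, required only when `r_squared` or `s` must be
#'   estimated.
#' @param B number of simulated replicates (default 100).
#' @param grid exponent grid.
#' @param seed master seed; each replicate uses a derived child seed, so
#'   results do not depend on execution order.
#' @param coefficient_distribution passed to [simulation_design()].
#' @return list of class `ecar_alpha`: `grid`, `best_alphas` (length B),
#'   `median`, `sd`, and the `r_squared` and `s` actually used.
#' @export
estimate_alpha <- function(x, r_squared = NULL, s = NULL, y = NULL,
                           B = 100L, grid = alpha_grid(), seed = 1L,
                           coefficient_distribution = "uniform01") {
  fm <- standardize(x)
  grid <- check_grid(grid)
  B <- as.integer(B)
  if (B < 1L) stop_user("B must be at least 1")
  if (is.null(r_squared) || is.null(s)) {
    if (is.null(y))
      stop_user("supply 'y' so that r_squared and s can be estimated, or give both")
    if (is.null(r_squared)) r_squared <- estimate_r2(fm, y, seed = seed)
    if (is.null(s)) s <- estimate_s(fm, y)
  }
  dec <- svd_decomp(fm)
  best <- vapply(seq_len(B), function(i) {
    design <- simulation_design(r_squared, s,
                                coefficient_distribution = coefficient_distribution,
                                seed = child_seed(seed, i))
    best_alpha_from_decomp(fm, dec, design, grid)
  }, numeric(1L))
  structure(list(grid = grid, best_alphas = best,
                 median = stats::median(best), sd = stats::sd(best),
                 r_squared = r_squared, s = s, B = B, seed = seed),
            class = "ecar_alpha")
}

#' @export
print.ecar_alpha <- function(x, ...) {
  cat(sprintf(
    "alpha estimate: median %.3f (sd %.3f) over %d replicates [R2 = %.3g, s = %d]\n",
    x$median, if (is.na(x$sd)) 0 else x$sd, x$B, x$r_squared, x$s))
  invisible(x)
}

#' Calibration study of the exponent on fresh simulated designs
#'
#' The simulation-study protocol behind the reference alpha medians: each
#' replicate draws a fresh block compound-symmetry design, a fresh response
#' at the target R-squared with support drawn from all features, and
#' records the PR-AUC-maximizing grid alpha. Differs from
#' [estimate_alpha()] only in redrawing the design every replicate.
#'
#' @param r_squared target R-squared of the simulated responses.
#' @param s number of influential features (default 30).
#' @param B number of replicate datasets (default 100).
#' @param spec an `ecar_block_spec` describing the design (default: the
#'   n = 200, p = 600, two-block, rho = 0.25 benchmark design).
#' @param grid exponent grid.
#' @param seed master seed (replicates use derived child seeds).
#' @param coefficient_distribution passed to [simulation_design()].
#' @return an `ecar_alpha` object.
#' @export
alpha_calibration_study <- function(r_squared, s = 30L, B = 100L,
                                    spec = block_design_spec(),
                                    grid = alpha_grid(), seed = 1L,
                                    coefficient_distribution = "uniform01") {
  grid <- check_grid(grid)
  B <- as.integer(B)
  if (B < 1L) stop_user("B must be at least 1")
  best <- vapply(seq_len(B), function(i) {
    cs <- child_seed(seed, i)
    spec_i <- block_design_spec(spec$n, spec$p, spec$n_blocks,
                                spec$within_rho, seed = cs)
    fm <- make_block_design(spec_i)
    design <- simulation_design(r_squared, s,
                                coefficient_distribution = coefficient_distribution,
                                seed = child_seed(cs, 1L))
    best_alpha_from_decomp(fm, svd_decomp(fm), design, grid)
  }, numeric(1L))
  structure(list(grid = grid, best_alphas = best,
                 median = stats::median(best), sd = stats::sd(best),
                 r_squared = r_squared, s = s, B = B, seed = seed),
            class = "ecar_alpha")
}
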