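#' Specification of a block compound-symmetry design
#'
#' The reference simulation design: `n` multivariate-normal samples whose
#' correlation matrix is block diagonal with equal-sized compound-symmetry
#' blocks (unit diagonal, common within-block correlation `within_rho`,
#' zero between blocks). Defaults are the benchmark setting: n = 200,
#' p = 600, two blocks, rho = 0.25.
#'
#' @param n number of samples.
#' @param p number of features; must be divisible by `n_blocks`.
#' @param n_blocks number of equal blocks.
#' @param within_rho common within-block correlation, in
#'   `(-1/(block_size - 1), 1)` so the block is positive definite.
#' @param seed optional integer seed used by [make_block_design()].
#' @return a list of class `ecar_block_spec`.
#' @export
block_design_spec <- function(n = 200L, p = 600L, n_blocks = 2L,
                              within_rho = 0.25, seed = NULL) {
  n <- as.integer(n); p <- as.integer(p); n_blocks <- as.integer(n_blocks)
  if (n < 3L) stop_user("n must be at least 3")
  if (p < 1L || p %% n_blocks != 0L)
    stop_user("p (%d) must be a positive multiple of n_blocks (%d)", p, n_blocks)
  bs <- p %/% n_blocks
  lo <- if (bs > 1L) -1 / (bs - 1) else -1
  if (within_rho >= 1 || within_rho <= lo)
    stop_user("within_rho = %g gives a non-positive-definite block (need %g < rho < 1)",
              within_rho, lo)
  structure(list(n = n, p = p, n_blocks = n_blocks, within_rho = within_rho,
                 block_size = bs, seed = seed),
            class = "ecar_block_spec")
}

#' Simulate a block compound-symmetry feature matrix
#'
#' Draws n iid rows from N(0, Sigma) with Sigma as described in
#' [block_design_spec()]. For nonnegative `within_rho` the draw uses the
#' exact one-factor representation `sqrt(rho) g_b + sqrt(1 - rho) z`
#' (`g_b` a per-block common factor); otherwise a per-block Cholesky
#' factorisation. The result is returned standardized.
#'
#' @param spec an `ecar_block_spec`.
#' @return an `ecar_fm` with feature ids `f1 ... fp`.
#' @export
make_block_design <- function(spec = block_design_spec()) {
  stopifnot(inherits(spec, "ecar_block_spec"))
  if (!is.null(spec$seed)) set.seed(spec$seed)
  n <- spec$n; p <- spec$p; rho <- spec$within_rho; bs <- spec$block_size
  if (rho >= 0) {
    g <- matrix(stats::rnorm(n * spec$n_blocks), n, spec$n_blocks)
    X <- sqrt(1 - rho) * matrix(stats::rnorm(n * p), n, p) +
      sqrt(rho) * g[, rep(seq_len(spec$n_blocks), each = bs), drop = FALSE]
  } else {
    Sb <- matrix(rho, bs, bs); diag(Sb) <- 1
    L <- chol(Sb)
    X <- matrix(0, n, p)
    for (b in seq_len(spec$n_blocks)) {
      cols <- ((b - 1L) * bs + 1L):(b * bs)
      X[, cols] <- matrix(stats::rnorm(n * bs), n, bs) %*% L
    }
  }
  colnames(X) <- sprintf("f%d", seq_len(p))
  standardize(X)
}

#' Simulate a linear response on a given design
#'
#' Generates `y = X beta + eps` with `s` influential features drawn from a
#' placement pool, nonzero coefficients from the requested distribution,
#' and `eps ~ N(0, sigma2 I)` with
#' `sigma2 = (1 - R2) * t(beta) X'X beta / (n * R2)` so that the population
#' coefficient of determination equals `r_squared` exactly.
#'
#' @param x an `ecar_fm` (or raw matrix).
#' @param s number of influential features.
#' @param r_squared target R-squared, strictly inside (0, 1).
#' @param placement `"first_block"` (influential features confined to the
#'   first `p / n_blocks` features) or `"anywhere"`.
#' @param n_blocks number of blocks used to delimit the first block.
#' @param coefficient_distribution `"uniform01"` (default), `"standard_normal"`
#'   or `"folded_normal"`.
#' @param seed optional integer seed.
#' @return a list with `y` (numeric response), `truth` (logical length p),
#'   `beta`, `sigma2` and `r_squared`.
#' @export
make_response <- function(x, s = 30L, r_squared = 0.6,
                          placement = c("first_block", "anywhere"),
                          n_blocks = 2L,
                          coefficient_distribution = "uniform01",
                          seed = NULL) {
  fm <- standardize(x)
  placement <- match.arg(placement)
  pool <- if (placement == "first_block") seq_len(fm$p %/% n_blocks)
          else seq_len(fm$p)
  design <- simulation_design(r_squared = r_squared, s = s,
                              coefficient_distribution = coefficient_distribution,
                              seed = seed, support_pool = pool)
  simulate_response(fm, design)
}

#' Load and filter a semi-synthetic expression design
#'
#' Reads an expression matrix (samples in rows, genes in columns, delimited
#' text with a header), applies the semi-synthetic preprocessing recipe:
#' drop genes with zero expression in strictly more than 20% of samples,
#' keep the `top_k_variance` genes with the largest variance, transform with
#' `log(x + 1)`, and standardize.
#'
#' @param path file path (`.csv` comma-separated, otherwise tab).
#' @param top_k_variance number of genes to retain.
#' @param max_zero_fraction drop genes whose fraction of zero entries
#'   exceeds this.
#' @return an `ecar_fm`.
#' @export
load_semisynthetic_design <- function(path, top_k_variance = 1000L,
                                      max_zero_fraction = 0.2) {
  m <- read_feature_matrix(path)
  zfrac <- colMeans(m == 0)
  m <- m[, zfrac <= max_zero_fraction, drop = FALSE]
  if (ncol(m) < top_k_variance)
    stop_user("only %d genes survive the zero-expression filter; %d requested",
              ncol(m), top_k_variance)
  v <- apply(m, 2L, stats::var)
  keep <- order(v, decreasing = TRUE)[seq_len(top_k_variance)]
  standardize(log1p(m[, sort(keep), drop = FALSE]))
}
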