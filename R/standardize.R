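#' Standardize a feature matrix
#'
#' Centers every column to mean zero and scales to unit sample standard
#' deviation (denominator `n - 1`). All downstream score computations assume
#' standardized features, so this is the canonical entry point of the
#' pipeline.
#'
#' @param x numeric matrix (or data frame coercible to one), samples in rows,
#'   features in columns. Column names are used as feature identifiers;
#'   unnamed columns get `f1 ... fp`.
#' @param feature_ids optional character vector overriding column names.
#' @return an object of class `ecar_fm`: a list with elements `values`
#'   (the standardized n x p matrix), `feature_ids`, `n` and `p`.
#' @examples
#' X <- standardize(matrix(rnorm(60), 10, 6))
#' colMeans(X$values)        # ~ 0
#' apply(X$values, 2, sd)    # 1
#' @export
standardize <- function(x, feature_ids = NULL) {
  if (inherits(x, "ecar_fm")) return(x)
  if (is.data.frame(x)) x <- as.matrix(x)
  if (!is.matrix(x) || !is.numeric(x))
    stop_user("'x' must be a numeric matrix (samples x features)")
  n <- nrow(x); p <- ncol(x)
  if (n < 3L) stop_user("need at least 3 samples, got %d", n)
  if (p < 1L) stop_user("need at least 1 feature")
  ids <- feature_ids %||% colnames(x) %||% sprintf("f%d", seq_len(p))
  if (length(ids) != p) stop_user("feature_ids has length %d, expected %d",
                                  length(ids), p)
  if (anyNA(x)) {
    idx <- which(is.na(x), arr.ind = TRUE)[1L, ]
    stop_user("missing value at row %d, column %d (feature '%s')",
              idx[1L], idx[2L], ids[idx[2L]])
  }
  ctr <- colMeans(x)
  xc <- sweep(x, 2L, ctr)
  sds <- sqrt(colSums(xc^2) / (n - 1))
  zero <- which(sds < .Machine$double.eps^0.5 * (abs(ctr) + 1))
  if (length(zero))
    stop_user("feature '%s' has zero variance and cannot be standardized",
              ids[zero[1L]])
  v <- sweep(xc, 2L, sds, "/")
  dimnames(v) <- list(rownames(x), ids)
  structure(list(values = v, feature_ids = as.character(ids), n = n, p = p),
            class = "ecar_fm")
}

#' @export
print.ecar_fm <- function(x, ...) {
  cat(sprintf("Standardized feature matrix: %d samples x %d features\n",
              x$n, x$p))
  invisible(x)
}

# Validate an outcome vector against a feature matrix; returns the
# standardized response (mean 0, unit sd). Correlation-based scores are
# invariant to this, but simulation and CLI code rely on the scaling.
standardize_response <- function(y, fm) {
  y <- as.numeric(y)
  if (length(y) != fm$n)
    stop_user("outcome has length %d but the design has %d samples",
              length(y), fm$n)
  if (!all(is.finite(y))) stop_user("outcome contains non-finite values")
  s <- stats::sd(y)
  if (s < .Machine$double.eps^0.5 * (abs(mean(y)) + 1))
    stop_user("outcome is constant; correlations are undefined")
  (y - mean(y)) / s
}
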