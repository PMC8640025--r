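# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a reproducible child seed from a master seed
#'
#' Replicate loops draw one child seed per replicate so that results are
#' independent of execution order (and hence parallelisable). Values stay
#' below 2^31 - 1.
#'
#' @param master integer master seed.
#' @param i replicate index (1-based).
#' @return an integer seed.
#' @keywords internal
child_seed <- function(master, i) {
  as.integer((as.double(master) * 1009 + as.double(i) * 7919) %% 2147483629L)
}

clip <- function(x, lo, hi) pmin(pmax(x, lo), hi)

stop_user <- function(...) {
  stop(structure(class = c("ecar_user_error", "error", "condition"),
                 list(message = sprintf(...), call = sys.call(-1))))
}
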