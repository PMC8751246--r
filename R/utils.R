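#' @keywords internal
logit <- function(p) stats::qlogis(p)

#' @keywords internal
clip_prob <- function(p, eps = 1e-12) pmin(pmax(p, eps), 1 - eps)

#' Derive a reproducible child seed
#'
#' Deterministic counter-based splitting of a master seed into per-task child
#' seeds, so that simulation, tuning, and stochastic fitting draw from
#' disjoint streams. All arithmetic stays below 2^31 - 1.
#'
#' @param master integer master seed.
#' @param ... one or more non-negative integer indices (e.g. setting index,
#'   repetition, stream id).
#' @return a single integer seed in `[0, 2^31 - 2]`.
#' @export
child_seed <- function(master, ...) {
  idx <- c(...)
  m <- 2147483647
  h <- as.double(master) %% m
  mults <- c(2654435761, 97531, 224737, 1299709, 15485863, 32452843)
  for (i in seq_along(idx)) {
    mult <- mults[((i - 1L) %% length(mults)) + 1L]
    # double-precision modular arithmetic is exact below 2^53
    h <- (h * 31 + (as.double(idx[i]) %% m) * (mult %% 65536)) %% m
    h <- (h * 37 + 17) %% m
  }
  as.integer(h)
}

#' @keywords internal
`%||%` <- function(a, b) if (is.null(a)) b else a

#' @keywords internal
stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

#' @keywords internal
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
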