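`%||%` <- function(x, y) if (is.null(x)) y else x

#' Derive a child seed from a global seed
#'
#' All stochastic components of the package draw their seeds from a single
#' integer through this map, so that one global seed reproduces every
#' sub-generator. The stream index separates independent consumers.
#'
#' @param seed integer global seed.
#' @param stream nonnegative integer stream index.
#' @return An integer seed below 2^31.
#' @export
child_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.numeric(stream))
  # Weyl-style mixing keeps distinct (seed, stream) pairs distinct and the
  # result inside the 32-bit range set.seed() accepts.
  as.integer((abs(seed) * 48271 + stream * 10007 + 1) %% 2147483629)
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

stop_config <- function(...) {
  stop(sprintf(...), call. = FALSE)
}

check_correlation_matrix <- function(R, name = "correlation matrix", tol = 1e-8) {
  if (!is.matrix(R) || nrow(R) != ncol(R)) {
    stop_config("%s must be a square matrix", name)
  }
  if (max(abs(R - t(R))) > tol) stop_config("%s must be symmetric", name)
  if (max(abs(diag(R) - 1)) > tol) stop_config("%s must have unit diagonal", name)
  ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-6) stop_config("%s must be positive semi-definite", name)
  invisible(TRUE)
}
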