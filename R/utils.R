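# Internal helpers shared across modules.

#' Derive a child seed from a pipeline seed
#'
#' A single pipeline seed fans out deterministically to per-stage seeds so
#' that any stage can be re-run in isolation and reproduce its output.
#' The mixer is a fixed affine map modulo 2^31 - 1; it is not
#' cryptographic, only collision-poor across the handful of stage indices
#' used here.
#'
#' @param seed integer master seed.
#' @param stage integer stage index (>= 0).
#' @return an integer seed in `[1, 2^31 - 2]`.
#' @export
derive_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.numeric(stage))
  m <- 2147483647 # 2^31 - 1 (Mersenne prime)
  s <- (abs(as.double(seed)) %% m)
  for (st in as.integer(stage)) {
    s <- (s * 48271 + st + 1) %% m
  }
  as.integer(max(1, s))
}

# Run code with a temporary RNG state when a seed is given; restore the
# caller's RNG state afterwards. With seed = NULL the global stream is used.
with_seed <- function(seed, code) {
  if (is.null(seed)) {
    return(force(code))
  }
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

stop_invalid <- function(...) {
  stop(..., call. = FALSE)
}

# Symmetry / zero-diagonal checks used by the network constructors.
check_symmetric_zero_diag <- function(m, what = "matrix", tol = 1e-10) {
  if (!is.matrix(m) || nrow(m) != ncol(m)) {
    stop_invalid(what, " must be a square matrix")
  }
  if (max(abs(m - t(m))) > tol) {
    stop_invalid(what, " must be symmetric")
  }
  if (max(abs(diag(m))) > tol) {
    stop_invalid(what, " must have a zero diagonal")
  }
  invisible(TRUE)
}

default_region_names <- function(n) {
  # Generic hemisphere + index labels; no anatomical claim.
  half <- ceiling(n / 2)
  nm <- c(sprintf("l-R%03d", seq_len(half)), sprintf("r-R%03d", seq_len(n - half)))
  nm[seq_len(n)]
}
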