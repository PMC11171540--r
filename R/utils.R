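#' @keywords internal
"_PACKAGE"

# assert helper: stop with caller-friendly message
abort_if <- function(cond, msg, class = "savehsi_error") {
  if (isTRUE(cond)) {
    stop(structure(class = c(class, "error", "condition"),
                   list(message = msg, call = sys.call(-1))))
  }
  invisible(NULL)
}

#' Run an expression with a fixed RNG seed, restoring prior RNG state
#'
#' All stochastic generators in the package route their randomness through
#' this helper so that a single explicit seed fully determines the output and
#' the caller's RNG stream is left untouched.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  abort_if(!is.numeric(seed) || length(seed) != 1L || !is.finite(seed),
           "`seed` must be a single finite number")
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# svd-based pseudo-inverse with a rank-revealing relative tolerance.
# Returns the pinv; attr "rank" carries the numerical rank.
pinv <- function(A, tol = 1e-10) {
  s <- svd(A)
  keep <- s$d > tol * max(s$d, 0)
  r <- sum(keep)
  if (r == 0L) {
    out <- matrix(0, ncol(A), nrow(A))
  } else {
    out <- s$v[, keep, drop = FALSE] %*%
      (t(s$u[, keep, drop = FALSE]) / s$d[keep])
  }
  attr(out, "rank") <- r
  out
}

# simple timestamped logger used by the CLI; quiet unless option set
save_log <- function(..., verbose = getOption("savehsi.verbose", FALSE)) {
  if (isTRUE(verbose)) {
    message(format(Sys.time(), "[%H:%M:%S] "), ...)
  }
  invisible(NULL)
}
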