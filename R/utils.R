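# Internal helpers shared across modules.

#' Signal a structured package error
#'
#' All user-facing errors in the package carry the condition class
#' `"pertcycle_error"` plus a specific subclass, so callers can
#' `tryCatch()` on the kind of failure rather than on message text.
#'
#' @param msg message string.
#' @param class specific condition subclass.
#' @param data optional named list of machine-readable details.
#' @noRd
pc_stop <- function(msg, class = "pertcycle_error", data = list()) {
  cond <- structure(
    class = c(class, "pertcycle_error", "error", "condition"),
    list(message = msg, call = sys.call(-1), data = data)
  )
  stop(cond)
}

#' Derive a component seed from a root seed
#'
#' All randomness in the package flows from one root seed, split per
#' component by hashing a tag string.  Result is kept inside the 32-bit
#' integer range.
#' @noRd
derive_seed <- function(seed, tag) {
  codes <- utf8ToInt(tag)
  h <- sum(codes * seq_along(codes))
  as.integer((abs(as.numeric(seed)) * 48271 + h * 97 + 1) %% 2147483629)
}

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Coerce a numeric vector to a 1-row matrix; pass matrices through.
as_row_matrix <- function(x) {
  if (is.matrix(x)) x else matrix(x, nrow = 1L)
}

check_finite <- function(x, what) {
  if (!all(is.finite(x)))
    pc_stop(sprintf("non-finite values in %s", what), "pertcycle_nonfinite")
  invisible(x)
}
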