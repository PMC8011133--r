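#' @keywords internal
"_PACKAGE"

# Run expr with a temporary RNG state seeded from `seed`, restoring the
# caller's .Random.seed afterwards. All stochastic code in the package goes
# through this so that library use never clobbers the user's RNG stream.
with_local_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}

# Deterministically derive a child seed from a parent seed and index path.
# Kept strictly below 2^31 - 1 so it is always a valid R integer.
derive_seed <- function(seed, ...) {
  idx <- c(...)
  s <- as.double(seed) %% 2147483647
  for (i in idx) {
    s <- (s * 48271 + as.double(i) * 2654435761) %% 2147483647
  }
  as.integer(s)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

assert_that <- function(cond, fmt, ...) {
  if (!isTRUE(cond)) stopf(fmt, ...)
  invisible(TRUE)
}

# Sample standard deviation with a guard for length-1 input.
sd_or_zero <- function(x) if (length(x) < 2L) 0 else stats::sd(x)

`%||%` <- function(a, b) if (is.null(a)) b else a
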