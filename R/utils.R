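#' @keywords internal
"_PACKAGE"

#' @importFrom stats density prcomp quantile rnorm runif setNames wilcox.test bw.nrd plogis
#' @importFrom utils head tail read.table write.table
NULL

# Draw n independent sub-seeds from a master seed.  Every stochastic routine
# in the package takes an explicit seed; routines that need several
# independent random streams (e.g. edge and feature perturbation inside one
# spec) derive them through this helper so a single master seed controls the
# whole run.  Sub-seeds stay below 2^31 - 1 (R integers are 32-bit).
seed_stream <- function(seed, n) {
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(as.integer(seed))
  sample.int(.Machine$integer.max - 1L, n)
}

get_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
}

restore_rng_state <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", state, envir = globalenv())
  }
  invisible(NULL)
}

# Run expr with the RNG seeded to `seed`, restoring the caller's RNG state
# afterwards so seeded package routines never disturb user code.
with_seed <- function(seed, expr) {
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(as.integer(seed))
  expr
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

assert_that <- function(cond, fmt, ...) {
  if (!isTRUE(cond)) stopf(fmt, ...)
  invisible(TRUE)
}
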