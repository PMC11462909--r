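#' @keywords internal
"_PACKAGE"

`%||%` <- function(a, b) if (is.null(a)) b else a

# Validation failures get their own condition class so the CLI can map them
# to exit code 2 while genuine bugs stay exit code 1.
stop_validation <- function(fmt, ...) {
  msg <- if (length(list(...))) sprintf(fmt, ...) else fmt
  stop(structure(
    class = c("beadrank_validation_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

is_validation_error <- function(e) inherits(e, "beadrank_validation_error")

# Run code under a fixed seed, restoring the caller's RNG state afterwards.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop_validation("seed must be a single integer")
  }
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
  set.seed(as.integer(seed))
  code
}

# Derive n independent child seeds from one master seed, so each stochastic
# sub-operation has its own stream and adding operations never shifts
# earlier draws.
derive_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

match_direction <- function(direction) {
  if (is.null(direction) || length(direction) != 1L || is.na(direction)) {
    stop_validation("direction must be \"larger_better\" or \"smaller_better\"")
  }
  d <- switch(as.character(direction),
    larger_better = , larger = , higher = "larger_better",
    smaller_better = , smaller = , lower = "smaller_better",
    stop_validation("unknown direction '%s'", direction)
  )
  d
}

direction_sign <- function(direction) {
  if (identical(direction, "larger_better")) 1 else -1
}

check_labels <- function(labels, what = "treatment") {
  labels <- as.character(labels)
  if (length(labels) == 0L) stop_validation("at least one %s required", what)
  if (anyNA(labels) || any(!nzchar(labels))) {
    stop_validation("%s labels must be non-empty", what)
  }
  if (anyDuplicated(labels)) stop_validation("duplicate %s", what)
  labels
}

# Snap values a hair outside [0,1] (floating-point residue) back onto the
# interval; anything further out is the caller's error to handle.
clamp_unit <- function(x, tol = 1e-9) {
  x[x > 1 & x <= 1 + tol] <- 1
  x[x < 0 & x >= -tol] <- 0
  x
}

fmt_num <- function(x) sprintf("%.17g", x)
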