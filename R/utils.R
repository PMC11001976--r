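# Internal validation and RNG helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

stop2 <- function(...) stop(..., call. = FALSE)

assert_scalar <- function(x, field) {
  if (length(x) != 1L || is.na(x)) {
    stop2("field '", field, "' must be a single non-missing value")
  }
}

assert_count <- function(x, field, min = 1L) {
  assert_scalar(x, field)
  if (!is.numeric(x) || x != as.integer(x) || x < min) {
    stop2("field '", field, "' must be an integer >= ", min, " (got ", x, ")")
  }
  invisible(as.integer(x))
}

assert_positive <- function(x, field) {
  assert_scalar(x, field)
  if (!is.numeric(x) || x <= 0) {
    stop2("field '", field, "' must be a positive real (got ", x, ")")
  }
  invisible(as.numeric(x))
}

assert_nonnegative <- function(x, field) {
  assert_scalar(x, field)
  if (!is.numeric(x) || x < 0) {
    stop2("field '", field, "' must be a nonnegative real (got ", x, ")")
  }
  invisible(as.numeric(x))
}

assert_prob <- function(x, field) {
  assert_scalar(x, field)
  if (!is.numeric(x) || x < 0 || x > 1) {
    stop2("field '", field, "' must be a probability in [0, 1] (got ", x, ")")
  }
  invisible(as.numeric(x))
}

#' Derive a stage sub-seed from a master seed
#'
#' All randomness in the pipeline flows from a single master seed; each stage
#' draws from a sub-seed derived deterministically as
#' `(master * 2099 + 9973 * offset) mod (2^31 - 1)`, so stages can be
#' regenerated independently of one another.
#'
#' @param master integer master seed.
#' @param offset integer stage offset (each pipeline stage uses a fixed one).
#' @return An integer seed in `[0, 2^31 - 1)`.
#' @export
derive_seed <- function(master, offset = 0L) {
  master <- assert_count(master, "seed", min = 0L)
  offset <- assert_count(offset, "offset", min = 0L)
  as.integer((as.double(master) * 2099 + 9973 * as.double(offset)) %% 2147483647)
}

# Run `expr` under `seed`, restoring the caller's RNG state afterwards.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}
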