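# Internal helpers shared across modules.

#' @importFrom methods new validObject is
#' @importFrom stats optim pt pnorm var sd rnorm predict fisher.test
#' @importFrom utils read.table write.table packageVersion
NULL

# Run `expr` under a temporary RNG state seeded with `seed`; the caller's
# RNG state is restored afterwards so simulations do not perturb user code.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      old <- get(".Random.seed", envir = globalenv())
      on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    } else {
      on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
    }
    set.seed(as.integer(seed))
  }
  force(expr)
}

# Deterministically derive a per-stage seed from the pipeline root seed.
# Kept below 2^31 so it is always a valid R integer.
split_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 131L + offset) %% .Machine$integer.max)
}

stop_config <- function(field, msg) {
  stop(sprintf("invalid configuration: field '%s' %s", field, msg),
       call. = FALSE)
}

check_count <- function(x, field, min = 1L) {
  if (length(x) != 1L || !is.numeric(x) || is.na(x) || x != round(x) ||
      x < min) {
    stop_config(field, sprintf("must be a single integer >= %d", min))
  }
  invisible(as.integer(x))
}

check_prob <- function(x, field) {
  if (length(x) != 1L || !is.numeric(x) || is.na(x) || x < 0 || x > 1) {
    stop_config(field, "must be a single number in [0, 1]")
  }
  invisible(as.numeric(x))
}

# Newton inversion of the trigamma function, needed by the method-of-moments
# fit of the variance prior (cf. the inverse-chi-square hierarchy used for
# moderated t-statistics). Solves trigamma(y) = x for y > 0.
trigamma_inverse <- function(x) {
  stopifnot(is.numeric(x), all(x > 0))
  y <- 0.5 + 1 / x
  for (i in seq_len(50L)) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, deriv = 2L)
    y <- y + dif
    if (max(abs(dif / y)) < 1e-10) break
  }
  y
}
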