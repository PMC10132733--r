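#' @importFrom stats rnbinom rlnorm runif rgamma rmultinom
#'   pnorm pchisq cor median var glm.fit
#'   poisson
#' @importFrom utils head read.delim write.table
NULL

# Evaluate `expr` under a private RNG stream seeded with `seed`, restoring
# (or removing) the caller's .Random.seed afterwards.  All package
# randomness goes through this so no function perturbs global RNG state.
with_seed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(as.integer(seed))
  expr
}

# Derive a child seed from a parent seed and a stream label, keeping the
# result inside the 32-bit integer range.
child_seed <- function(seed, stream) {
  (as.numeric(seed) * 48271 + stream) %% 2147483587 + 1
}

stop_lenbias <- function(..., class) {
  stop(structure(
    class = c(class, "lenbias_error", "error", "condition"),
    list(message = paste0(...), call = sys.call(-1))
  ))
}

check_scalar_count <- function(x, name, min = 0L) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < min ||
      x != trunc(x)) {
    stop_lenbias(name, " must be a single integer >= ", min,
                 class = "lenbias_invalid_argument")
  }
  invisible(as.integer(x))
}
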