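# Shared helpers: validation, deterministic seed substreams, rank AUC.

abort_if <- function(cond, msg, ...) {
  if (cond) stop(sprintf(msg, ...), call. = FALSE)
}

#' Derive a named seed substream
#'
#' Maps a base seed and a stream name to an integer in `[1, 2^31 - 2]` via a
#' multiplicative string hash, so that independent components (phantom
#' sampling, weight init, reparameterization draws, batching, perturbations)
#' consume isolated streams: changing how one stream is consumed never shifts
#' another.
#'
#' @param seed integer base seed.
#' @param name character stream label, e.g. `"phantom"`, `"init"`,
#'   `"reparam.12"`.
#' @return an integer seed.
#' @export
substream_seed <- function(seed, name) {
  abort_if(!is.numeric(seed) || length(seed) != 1L || !is.finite(seed),
           "seed must be a single finite number")
  m <- 2147483647 # 2^31 - 1, Mersenne prime
  h <- as.double(seed %% m)
  for (code in utf8ToInt(name)) h <- (h * 31 + code) %% m
  as.integer(h %% (m - 1)) + 1L
}

#' Seed the global random number generator from a named substream
#'
#' Convenience for scripts: seeds R's RNG with the `"global"` substream of
#' the run seed. Package internals never rely on the global RNG state —
#' every component draws from its own [substream_seed()] stream — so two
#' runs with the same seed produce identical artifacts regardless of what
#' the session does between calls.
#'
#' @param seed integer run seed.
#' @return the derived substream seed, invisibly.
#' @export
set_global_seed <- function(seed) {
  s <- substream_seed(seed, "global")
  set.seed(s)
  invisible(s)
}

# Evaluate `expr` under a given seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' Rank-based area under the ROC curve
#'
#' Computes AUC as the Mann-Whitney rank statistic, so the value is invariant
#' to any strictly monotone transform of the scores.
#'
#' @param scores numeric scores (higher = more positive).
#' @param positive logical or 0/1 vector of the same length.
#' @return AUC in `[0, 1]`, or `NA` if either class is absent.
#' @export
auc_rank <- function(scores, positive) {
  positive <- as.logical(positive)
  abort_if(length(scores) != length(positive), "scores and labels differ in length")
  n1 <- sum(positive); n0 <- sum(!positive)
  if (n1 == 0L || n0 == 0L) return(NA_real_)
  r <- rank(scores)
  (sum(r[positive]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# softplus, numerically safe
softplus <- function(x) ifelse(x > 30, x, log1p(exp(x)))

`%||%` <- function(a, b) if (is.null(a)) b else a
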