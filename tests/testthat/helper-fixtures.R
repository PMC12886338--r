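# Shared fixtures: small deterministic phantoms, models, and numeric
# gradient checking against the autodiff tape.

tiny_cohort <- function(n_subjects = 24, seed = 7, ...) {
  sample_cohort(phantom_config(n_subjects = n_subjects, seed = seed, ...))
}

tiny_model <- function(seed = 2, ...) init_model(model_config(...), seed = seed)

# A linear zero-bias decoder model: decode is exactly [z_a z_d] %*% W.
linear_zero_bias_model <- function(d_a = 3, d_d = 3, image_size = 8, seed = 4) {
  m <- init_model(model_config(d_a = d_a, d_d = d_d, image_size = image_size,
                               hidden_dec = 0), seed = seed)
  m$params$dec_b[] <- 0
  m
}

# central finite differences of f (scalar-valued, matrix argument)
numeric_grad <- function(f, x, h = 1e-5) {
  g <- x * 0
  for (i in seq_along(x)) {
    xp <- x; xp[i] <- xp[i] + h
    xm <- x; xm[i] <- xm[i] - h
    g[i] <- (f(xp) - f(xm)) / (2 * h)
  }
  g
}

# check autodiff gradient of `build(node)` (returning a scalar node) at x
expect_grad_matches <- function(build, x, tol = 1e-4) {
  node <- ad_param(x)
  out <- build(node)
  ad_backward(out)
  g_ad <- ad_grad(node)
  g_num <- numeric_grad(function(v) ad_value(build(v))[1L], x)
  scale <- max(abs(g_num), 1e-8)
  expect_lt(max(abs(g_ad - g_num)) / scale, tol)
}
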