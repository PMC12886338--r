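# Alignment-side terms: kernel MMD machinery, the contrastive family,
# running Gaussian statistics, invariance KL, counterfactual consistency,
# gradient reversal, and the total objective.

test_that("median_bandwidth enumerates pairwise distances", {
  expect_equal(median_bandwidth(rbind(c(0, 0), c(2, 0))), 2)
  expect_equal(median_bandwidth(matrix(c(0, 1, 3), 3, 1)), 2) # {1, 2, 3} -> 2
  x <- matrix(rnorm(10), 5, 2)
  expect_equal(median_bandwidth(3 * x), 3 * median_bandwidth(x))
  expect_warning(h <- median_bandwidth(matrix(1, 4, 2)), "coincide")
  expect_equal(h, 1)
  expect_error(median_bandwidth(matrix(0, 1, 2)), "at least 2")
})

test_that("mmd2 matches the hand-expanded kernel sum and is symmetric", {
  set.seed(21)
  p <- matrix(rnorm(12), 6, 2)
  expect_equal(ad_value(mmd2(p, p, 1.3))[1], 0, tolerance = 1e-12)
  u <- matrix(c(1, 2), 1, 2); v <- matrix(c(4, -2), 1, 2)
  h <- 1.7
  expect_equal(ad_value(mmd2(u, v, h))[1],
               2 - 2 * exp(-sum((u - v)^2) / (2 * h^2)), tolerance = 1e-12)
  q <- matrix(rnorm(8), 4, 2)
  expect_lt(abs(ad_value(mmd2(p, q, 1))[1] - ad_value(mmd2(q, p, 1))[1]), 1e-12)
  expect_gte(ad_value(mmd2(p, q, 1))[1], -1e-12)
  expect_error(mmd2(p[0, , drop = FALSE], q, 1), "non-empty")
  # the linear kernel reduces the discrepancy to the raw mean-difference norm
  expect_equal(ad_value(mmd2(p, q, 1, kernel = "linear"))[1],
               sum((colMeans(p) - colMeans(q))^2), tolerance = 1e-12)
})

test_that("stratified MMD sums weighted pairwise terms and skips degenerate cells", {
  set.seed(22)
  z <- matrix(rnorm(24), 12, 2)
  s3 <- rep(c("a", "b", "c"), each = 4)
  h <- median_bandwidth(z)
  oracle <- 0
  for (pair in list(c("a", "b"), c("a", "c"), c("b", "c"))) {
    zi <- z[s3 == pair[1], ]; zj <- z[s3 == pair[2], ]
    w <- (2 * 4 * 4 / 8) / 12
    oracle <- oracle + w * ad_value(mmd2(zi, zj, h))[1]
  }
  expect_equal(ad_value(loss_mmd_strata(z, s3))[1], oracle, tolerance = 1e-12)
  expect_message(v <- loss_mmd_strata(z, rep("a", 12)), "skipping")
  expect_equal(ad_value(v)[1], 0)
  # two strata with identical empirical samples align perfectly
  z2 <- rbind(z[1:4, ], z[1:4, ])
  expect_equal(ad_value(loss_mmd_strata(z2, rep(c("a", "b"), each = 4)))[1], 0,
               tolerance = 1e-12)
})

test_that("conditional alignment reduces to per-class pairwise MMDs", {
  set.seed(23)
  z <- matrix(rnorm(32), 16, 2)
  y <- rep(c(0, 1), each = 8)
  s <- rep(c("a", "b"), 8)
  oracle <- 0
  for (k in c(0, 1)) {
    zk <- z[y == k, ]; sk <- s[y == k]
    hk <- median_bandwidth(zk)
    oracle <- oracle + ad_value(mmd2(zk[sk == "a", ], zk[sk == "b", ], hk))[1]
  }
  expect_equal(ad_value(loss_cond_align(z, y, s))[1], oracle, tolerance = 1e-12)
  # one class, two subgroups: reduces to that class's mmd2
  one <- loss_cond_align(z[y == 0, ], rep(0, 8), s[y == 0])
  hk <- median_bandwidth(z[y == 0, ])
  expect_equal(ad_value(one)[1],
               ad_value(mmd2(z[y == 0 & s == "a", ], z[y == 0 & s == "b", ], hk))[1])
  # identical subgroups align to zero
  zz <- rbind(z[1:4, ], z[1:4, ])
  expect_equal(ad_value(loss_cond_align(zz, rep(0, 8), rep(c("a", "b"), each = 4)))[1],
               0, tolerance = 1e-12)
  expect_message(v <- loss_cond_align(z, y, rep("a", 16)), "skipping")
  expect_equal(ad_value(v)[1], 0)
})

supcon_oracle <- function(z, y, tau) {
  zn <- z / sqrt(rowSums(z^2))
  n <- nrow(z)
  total <- 0; pairs <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j || y[i] != y[j]) next
    denom <- 0
    for (a in setdiff(seq_len(n), i)) denom <- denom + exp(sum(zn[i, ] * zn[a, ]) / tau)
    total <- total - log(exp(sum(zn[i, ] * zn[j, ]) / tau) / denom)
    pairs <- pairs + 1
  }
  if (pairs == 0) 0 else total / pairs
}

test_that("supervised contrastive loss matches the worked value and the double loop", {
  e <- rbind(c(1, 0), c(0, 1), c(1, 0))
  y <- c(0, 1, 0)
  expect_equal(ad_value(loss_supcon(e, y, tau = 1))[1], log(1 + exp(1)) - 1,
               tolerance = 1e-12)
  # scale invariance through internal normalization
  expect_equal(ad_value(loss_supcon(5 * e, y, 1))[1],
               ad_value(loss_supcon(e, y, 1))[1])
  # identical lone pair: the positive is the entire denominator
  expect_equal(ad_value(loss_supcon(rbind(c(1, 1), c(1, 1)), c(0, 0), 0.5))[1], 0)
  set.seed(24)
  for (rep in 1:5) {
    z <- matrix(rnorm(20), 10, 2)
    y <- sample(0:2, 10, replace = TRUE)
    expect_equal(ad_value(loss_supcon(z, y, 0.4))[1], supcon_oracle(z, y, 0.4),
                 tolerance = 1e-8)
  }
  expect_error(loss_supcon(e, y, 0), "tau")
})

test_that("stability loss has the chi-square moment and is seeded", {
  z <- matrix(0, 1e4, 8)
  v <- ad_value(loss_stability(z, 0.1, seed = 5))[1]
  expect_lt(abs(v - 0.08) / 0.08, 0.05)
  expect_equal(v, ad_value(loss_stability(z, 0.1, seed = 5))[1])
  expect_false(v == ad_value(loss_stability(z, 0.1, seed = 6))[1])
  expect_equal(ad_value(loss_stability(z, 0, seed = 5))[1], 0)
  # gradient flows through z against the detached perturbation:
  # grad = (2/n)(z - z_tilde) = -(2/n) eps, so sum(grad^2) = (4/n) * loss
  zn <- ad_param(matrix(c(0.5, 1, -0.3, 0.2), 2, 2))
  out <- loss_stability(zn, 0.3, seed = 11)
  ad_backward(out)
  g <- ad_grad(zn)
  expect_gt(sum(g^2), 0)
  expect_equal(sum(g^2), (4 / 2) * ad_value(out)[1], tolerance = 1e-10)
})

hard_oracle <- function(z, y, tau, hard_k) {
  zn <- z / sqrt(rowSums(z^2))
  sims <- zn %*% t(zn)
  n <- nrow(z)
  vals <- c()
  for (i in seq_len(n)) {
    pos <- setdiff(which(y == y[i]), i)
    neg <- which(y != y[i])
    if (length(pos) == 0 || length(neg) == 0) next
    s_star <- min(sims[i, pos])
    hard <- sort(sims[i, neg], decreasing = TRUE)[seq_len(min(hard_k, length(neg)))]
    vals <- c(vals, -log(exp(s_star / tau) /
                           (exp(s_star / tau) + sum(exp(hard / tau)))))
  }
  if (length(vals) == 0) 0 else mean(vals)
}

test_that("hardness-aware contrastive loss matches its closed evaluation and oracle", {
  # anchor + identical positive + orthogonal negative, tau = 1
  z <- rbind(c(1, 0), c(1, 0), c(0, 1))
  y <- c(0, 0, 1)
  # both class-0 anchors contribute -log(e / (e + 1)); the negative has no positive
  expect_equal(ad_value(loss_hard_contrastive(z, y, 1, 1))[1],
               -log(exp(1) / (exp(1) + 1)), tolerance = 1e-12)
  # separability limit: positive at +1, negatives at -1, tiny temperature
  z2 <- rbind(c(1, 0), c(1, 0), c(-1, 0))
  expect_lt(ad_value(loss_hard_contrastive(z2, y, 0.01, 5))[1], 1e-12)
  set.seed(25)
  for (rep in 1:5) {
    zz <- matrix(rnorm(24), 12, 2)
    yy <- sample(0:2, 12, replace = TRUE)
    expect_equal(ad_value(loss_hard_contrastive(zz, yy, 0.5, 12))[1],
                 hard_oracle(zz, yy, 0.5, 12), tolerance = 1e-8)
    expect_equal(ad_value(loss_hard_contrastive(zz, yy, 0.5, 3))[1],
                 hard_oracle(zz, yy, 0.5, 3), tolerance = 1e-8)
  }
  expect_error(loss_hard_contrastive(z, y, -1, 1), "tau")
})

test_that("EMA centers follow the hand-rolled recursion and the center loss is exact", {
  st <- class_stats(d = 2, n_classes = 2, n_strata = 2, ema_decay = 0.8)
  set.seed(26)
  oracle <- matrix(NA_real_, 2, 2)
  for (b in 1:6) {
    z <- matrix(rnorm(12), 6, 2)
    y <- rep(0:1, 3)
    st <- update_centers(z, y, st)
    for (k in 0:1) {
      bm <- colMeans(z[y == k, , drop = FALSE])
      oracle[k + 1, ] <- if (anyNA(oracle[k + 1, ])) bm else 0.8 * oracle[k + 1, ] + 0.2 * bm
    }
  }
  expect_equal(st$centers, oracle, tolerance = 1e-10)
  # decay -> 0 makes centers the current batch means
  st0 <- class_stats(2, 2, 2, ema_decay = 1e-12)
  z <- matrix(rnorm(8), 4, 2); y <- c(0, 0, 1, 1)
  st0 <- update_centers(z, y, update_centers(matrix(rnorm(8), 4, 2), y, st0))
  expect_equal(st0$centers[1, ], colMeans(z[y == 0, ]), tolerance = 1e-10)
  # embeddings at their class centers cost nothing
  expect_equal(ad_value(loss_center(st$centers[c(1, 2, 1), ], c(0, 1, 0), st))[1], 0)
  expect_message(loss_center(matrix(rnorm(4), 2, 2), c(0, 1),
                             class_stats(2, 2, 2)), "lazily")
})

test_that("Gaussian running statistics shrink to positive-definite covariances", {
  st <- class_stats(d = 3, n_classes = 2, n_strata = 2, shrink_alpha = 1)
  set.seed(27)
  z <- matrix(rnorm(30), 10, 3)
  st <- update_gaussian_stats(z, rep(0, 10), rep(0:1, 5), st)
  S <- st$class_cov[[1]]
  expect_equal(S, diag(sum(diag(S)) / 3, 3), tolerance = 1e-12) # full shrinkage
  # constant embeddings: mean converges to the constant, covariance to a
  # positive identity floor; always Cholesky-factorizable
  st2 <- class_stats(d = 2, n_classes = 1, n_strata = 1, shrink_alpha = 0.1)
  zc <- matrix(1.5, 8, 2)
  for (b in 1:50) st2 <- update_gaussian_stats(zc, rep(0, 8), rep(0, 8), st2)
  expect_equal(st2$class_mean[1, ], c(1.5, 1.5))
  expect_true(all(eigen(st2$class_cov[[1]])$values > 0))
  expect_silent(chol(st2$class_cov[[1]]))
  # fuzzed updates stay positive-definite
  st3 <- class_stats(d = 4, n_classes = 2, n_strata = 2, shrink_alpha = 0.05)
  for (b in 1:10) {
    z <- matrix(rnorm(48), 12, 4)
    st3 <- update_gaussian_stats(z, sample(0:1, 12, TRUE), sample(0:1, 12, TRUE), st3)
  }
  for (k in 1:2) expect_silent(chol(st3$class_cov[[k]]))
})

test_that("invariance KL matches the closed form and Monte Carlo", {
  st <- class_stats(d = 1, n_classes = 1, n_strata = 2)
  st$class_mean[1, ] <- 0; st$class_cov[[1]] <- matrix(1)
  st$cell_mean[[1]][[1]] <- 1; st$cell_cov[[1]][[1]] <- matrix(1)
  st$class_count[1] <- 100; st$cell_count[1, 1] <- 50
  expect_equal(ad_value(loss_invariance(st))[1], 0.5)
  # Monte-Carlo cross-check of KL(N(1,1) || N(0,1))
  set.seed(28)
  z <- rnorm(1e5, 1, 1)
  mc <- mean(dnorm(z, 1, 1, log = TRUE) - dnorm(z, 0, 1, log = TRUE))
  expect_lt(abs(0.5 - mc) / 0.5, 0.02)
  # adding the second cell with identical stats adds nothing
  st$cell_mean[[1]][[2]] <- 0; st$cell_cov[[1]][[2]] <- matrix(1)
  st$cell_count[1, 2] <- 50
  expect_equal(ad_value(loss_invariance(st))[1], 0.5)
  # relabeling strata leaves the total unchanged
  st_sw <- st
  st_sw$cell_mean[[1]] <- st$cell_mean[[1]][2:1]
  st_sw$cell_cov[[1]] <- st$cell_cov[[1]][2:1]
  st_sw$cell_count[1, ] <- st$cell_count[1, 2:1]
  expect_equal(ad_value(loss_invariance(st_sw))[1], ad_value(loss_invariance(st))[1])
})

test_that("counterfactual consistency takes the within-batch minimum", {
  cf <- matrix(0, 1, 4)
  t1 <- matrix(1, 1, 4)      # squared distance 4
  t2 <- matrix(1.5, 1, 4)    # squared distance 9
  expect_equal(ad_value(loss_counterfactual(cf, rbind(t1, t2)))[1], 4)
  expect_equal(ad_value(loss_counterfactual(cf, rbind(cf, t1)))[1], 0)
  far <- matrix(100, 1, 4)
  expect_lte(ad_value(loss_counterfactual(cf, rbind(t1, t2, far)))[1],
             ad_value(loss_counterfactual(cf, rbind(t1, t2)))[1])
  expect_message(v <- loss_counterfactual(cf, matrix(0, 0, 4)), "empty")
  expect_equal(ad_value(v)[1], 0)
})

test_that("domain confusion reverses the encoder gradient exactly", {
  m <- init_model(model_config(d_d = 3, n_strata = 2, domain_confusion = TRUE), seed = 6)
  set.seed(29)
  z <- matrix(rnorm(12), 4, 3)
  s <- c(0, 1, 0, 1)
  # uniform predictions with zeroed head: loss log(2)
  m0 <- m; m0$params$W_dom[] <- 0; m0$params$b_dom[] <- 0
  expect_equal(ad_value(domain_confusion_loss(m0, z, s, 1))[1], log(2))
  # encoder-side gradient is -strength times the unreversed gradient
  grad_at <- function(strength) {
    zn <- ad_param(z)
    ad_backward(domain_confusion_loss(m, zn, s, strength))
    ad_grad(zn)
  }
  g1 <- grad_at(1)
  expect_equal(grad_at(2.5), 2.5 * g1, tolerance = 1e-12)
  expect_equal(grad_at(0), 0 * g1)
  # numerically: unreversed gradient of the head loss
  g_num <- numeric_grad(function(zz) {
    logits <- sweep(zz %*% m$params$W_dom, 2, -m$params$b_dom, "-")
    p <- exp(logits - apply(logits, 1, max))
    p <- p / rowSums(p)
    -mean(log(p[cbind(1:4, s + 1)]))
  }, z)
  expect_equal(g1, -g_num, tolerance = 1e-4)
  m_off <- init_model(model_config(d_d = 3), seed = 6)
  expect_error(domain_confusion_loss(m_off, z, s), "disabled")
})

test_that("the total objective is an exact weighted sum of its terms", {
  set.seed(30)
  terms <- as.list(stats::setNames(as.numeric(runif(9)),
                   c("task", "mmd", "cond", "supcon", "stability", "hard",
                     "center", "invariance", "counterfactual")))
  w <- loss_weights(lambda1 = 0.3, lambda2 = 0.2, lambda3 = 0.7, lambda4 = 0.15,
                    lambda5 = 0.05, lambda_stab = 0.9, lambda_hard = 0.4,
                    lambda_center = 0.25, lambda_m = 1.1, lambda_c = 0.8)
  contrastive <- terms$supcon + 0.9 * terms$stability + 0.4 * terms$hard + 0.25 * terms$center
  oracle <- terms$task + 0.3 * 1.1 * terms$mmd + 0.2 * 0.8 * terms$cond +
    0.7 * contrastive + 0.15 * terms$invariance + 0.05 * terms$counterfactual
  expect_equal(ad_value(total_cdaa(terms, w))[1], oracle, tolerance = 1e-12)
  # zero top-level weights reduce the total to the task bundle
  w0 <- loss_weights(lambda1 = 0, lambda2 = 0, lambda3 = 0, lambda4 = 0, lambda5 = 0)
  expect_equal(ad_value(total_cdaa(terms, w0))[1], terms$task)
  # doubling the weights adds exactly the original weighted sum
  w2 <- loss_weights(lambda1 = 0.6, lambda2 = 0.4, lambda3 = 1.4, lambda4 = 0.3,
                     lambda5 = 0.1, lambda_stab = 0.9, lambda_hard = 0.4,
                     lambda_center = 0.25, lambda_m = 1.1, lambda_c = 0.8)
  expect_equal(ad_value(total_cdaa(terms, w2))[1] - ad_value(total_cdaa(terms, w))[1],
               oracle - terms$task, tolerance = 1e-12)
  expect_error(total_cdaa(terms[-2], w), "missing term 'mmd'")
})

test_that("weight containers validate their constraints", {
  expect_error(loss_weights(tau = -1), "tau")
  expect_error(loss_weights(sigma2 = 0), "sigma2")
  expect_error(loss_weights(ema_decay = 1), "ema_decay")
  expect_error(loss_weights(shrink_alpha = 2), "shrink_alpha")
  expect_error(loss_weights(lambda3 = -0.1), "lambda3")
})
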