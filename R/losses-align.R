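# Causal disease-aware alignment: stratified kernel MMD, conditional
# alignment, the supervised-contrastive family with hard-negative mining and
# EMA centers, Gaussian-KL causal invariance on running statistics,
# counterfactual consistency, the optional gradient-reversal domain-confusion
# branch, and the total objective.

#' Median-heuristic kernel bandwidth
#'
#' Median of the pairwise Euclidean distances (self-pairs excluded). Falls
#' back to 1 with a warning when all points coincide.
#'
#' @param x embedding matrix `n x d`, n >= 2.
#' @return positive scalar bandwidth.
#' @export
median_bandwidth <- function(x) {
  x <- ad_detach(x)
  abort_if(nrow(x) < 2L, "median_bandwidth needs at least 2 embeddings")
  h <- stats::median(stats::dist(x))
  if (h == 0) {
    warning("all embeddings coincide; falling back to bandwidth 1")
    h <- 1
  }
  h
}

# pairwise squared distances, node-capable
pairwise_sqdist <- function(x, y) {
  xv <- ad_value(x); yv <- ad_value(y)
  rx <- ad_rowsums(ad_mul(x, x))
  ry <- ad_rowsums(ad_mul(y, y))
  cross <- ad_mul(ad_matmul(x, ad_t(y)), -2)
  ad_add(ad_add(ad_matmul(rx, matrix(1, 1L, nrow(yv))), cross),
         ad_matmul(matrix(1, nrow(xv), 1L), ad_t(ry)))
}

rbf_kernel <- function(x, y, bandwidth) {
  ad_exp(ad_mul(pairwise_sqdist(x, y), -1 / (2 * bandwidth^2)))
}

#' Squared maximum mean discrepancy (biased V-statistic)
#'
#' `mean(K(P,P)) + mean(K(Q,Q)) - 2 mean(K(P,Q))`. With the default RBF
#' kernel `k(u, v) = exp(-||u - v||^2 / (2 h^2))` this is a characteristic
#' (distribution-sensitive) discrepancy; the `linear` kernel reduces it to
#' the squared distance between raw sample means, useful for comparing the
#' kernel and raw-moment readings of distribution alignment.
#'
#' @param sample_p,sample_q embedding matrices with a common column count.
#' @param bandwidth RBF bandwidth `h` (> 0), e.g. from [median_bandwidth()];
#'   ignored by the linear kernel.
#' @param kernel `"rbf"` or `"linear"`.
#' @return scalar, >= 0 up to floating-point error; symmetric in its samples.
#' @export
mmd2 <- function(sample_p, sample_q, bandwidth, kernel = c("rbf", "linear")) {
  kernel <- match.arg(kernel)
  pv <- ad_value(sample_p); qv <- ad_value(sample_q)
  abort_if(nrow(pv) == 0L || nrow(qv) == 0L, "mmd2 requires non-empty samples")
  abort_if(ncol(pv) != ncol(qv), "mmd2 samples must share dimension")
  kern <- if (kernel == "rbf") {
    abort_if(bandwidth <= 0, "bandwidth must be > 0")
    function(a, b) rbf_kernel(a, b, bandwidth)
  } else {
    function(a, b) ad_matmul(a, ad_t(b))
  }
  ad_add(ad_sub(ad_mean(kern(sample_p, sample_p)),
                ad_mul(ad_mean(kern(sample_p, sample_q)), 2)),
         ad_mean(kern(sample_q, sample_q)))
}

zero_like_scalar <- function(...) {
  if (any(vapply(list(...), is_adnode, logical(1)))) ad_param(matrix(0, 1L, 1L))
  else matrix(0, 1L, 1L)
}

rows_of <- function(z, idx) ad_rows(z, idx)

#' Stratified marginal alignment loss
#'
#' Sum of pairwise squared MMDs of the disease-code distribution across
#' strata. Each unordered stratum pair is weighted by the harmonic mean of
#' the two cell sizes divided by the batch size, which downweights tiny cells
#' and is bounded above by 1. The RBF bandwidth is the median heuristic on
#' the pooled usable embeddings. Strata with fewer than `min_cell` samples
#' are skipped; with fewer than two usable strata the loss is 0.
#'
#' @param z_d disease-code batch `n x d`.
#' @param strata stratum label per row.
#' @param min_cell minimum usable cell size.
#' @return scalar.
#' @export
loss_mmd_strata <- function(z_d, strata, min_cell = 2L) {
  zv <- ad_value(z_d)
  n <- nrow(zv)
  abort_if(length(strata) != n, "one stratum label per row required")
  tab <- table(strata)
  usable <- names(tab)[tab >= min_cell]
  if (length(usable) < 2L) {
    message("loss_mmd_strata: fewer than 2 usable strata; skipping")
    return(zero_like_scalar(z_d))
  }
  keep <- strata %in% usable
  h <- median_bandwidth(zv[keep, , drop = FALSE])
  total <- zero_like_scalar(z_d)
  for (i in seq_along(usable)) {
    for (j in seq_along(usable)) {
      if (j <= i) next
      idx_i <- which(strata == usable[i]); idx_j <- which(strata == usable[j])
      w <- (2 * length(idx_i) * length(idx_j) / (length(idx_i) + length(idx_j))) / n
      total <- ad_add(total, ad_mul(mmd2(rows_of(z_d, idx_i), rows_of(z_d, idx_j), h), w))
    }
  }
  total
}

#' Class-conditional alignment loss
#'
#' Within each diagnosis class, the plain sum of squared MMDs between every
#' unordered pair of stratum subgroups (kernel mean-embedding distances),
#' with the median-heuristic bandwidth computed on that class's pooled
#' embeddings. Cells with fewer than `min_cell` samples are skipped.
#'
#' @param z_d disease-code batch `n x d`.
#' @param y class labels per row.
#' @param strata stratum labels per row.
#' @param min_cell minimum usable cell size.
#' @return scalar.
#' @export
loss_cond_align <- function(z_d, y, strata, min_cell = 2L) {
  zv <- ad_value(z_d)
  abort_if(length(y) != nrow(zv) || length(strata) != nrow(zv),
           "labels and strata must have one entry per row")
  total <- zero_like_scalar(z_d)
  any_term <- FALSE
  for (k in unique(y)) {
    in_k <- which(y == k)
    tab <- table(strata[in_k])
    usable <- names(tab)[tab >= min_cell]
    if (length(usable) < 2L) next
    keep <- in_k[strata[in_k] %in% usable]
    h <- median_bandwidth(zv[keep, , drop = FALSE])
    for (i in seq_along(usable)) {
      for (j in seq_along(usable)) {
        if (j <= i) next
        idx_i <- in_k[strata[in_k] == usable[i]]
        idx_j <- in_k[strata[in_k] == usable[j]]
        total <- ad_add(total, mmd2(rows_of(z_d, idx_i), rows_of(z_d, idx_j), h))
        any_term <- TRUE
      }
    }
  }
  if (!any_term) message("loss_cond_align: no class with 2 usable subgroups; skipping")
  total
}

# L2-normalize rows (node-capable); eps guards zero rows
l2_normalize_rows <- function(z, eps = 1e-12) {
  nrm <- ad_sqrt(ad_add(ad_rowsums(ad_mul(z, z)), eps))
  ad_rowscale(z, ad_recip(nrm))
}

#' Supervised contrastive loss
#'
#' Embeddings are L2-normalized, similarities are cosine. For each anchor i
#' with positive set P(i) (same label, not i) the loss is
#' `-log( exp(s_ij / tau) / sum_{a != i} exp(s_ia / tau) )`, averaged over all
#' (anchor, positive) pairs; anchors without positives contribute nothing.
#'
#' @param z_d embedding batch `n x d`, n >= 2.
#' @param y labels per row.
#' @param tau temperature (> 0).
#' @return scalar, >= 0.
#' @export
loss_supcon <- function(z_d, y, tau) {
  abort_if(tau <= 0, "tau must be > 0")
  zv <- ad_value(z_d)
  n <- nrow(zv)
  abort_if(n < 2L, "loss_supcon needs a batch of >= 2")
  abort_if(length(y) != n, "one label per row required")
  zn <- l2_normalize_rows(z_d)
  logits <- ad_mul(ad_matmul(zn, ad_t(zn)), 1 / tau)
  off_diag <- matrix(1, n, n) - diag(n)
  denom <- ad_rowsums(ad_mul(ad_exp(logits), off_diag))
  log_denom <- ad_log(denom)
  pairs <- which(outer(y, y, "==") & off_diag == 1, arr.ind = TRUE)
  if (nrow(pairs) == 0L) {
    message("loss_supcon: no positive pairs in batch; skipping")
    return(zero_like_scalar(z_d))
  }
  num <- ad_gather(logits, pairs)
  ad_mean(ad_sub(ad_rows(log_denom, pairs[, 1L]), num))
}

#' Perturbation stability loss
#'
#' Draws `z_tilde = z + eps`, `eps ~ N(0, sigma^2 I)`, and returns the batch
#' mean of `||z - z_tilde||^2`. The perturbed copy is detached, so gradients
#' flow through the model's `z` only.
#'
#' @param z_d embedding batch `n x d`.
#' @param sigma_stab perturbation SD (>= 0).
#' @param seed integer seed for the draw.
#' @return scalar; its expectation is `sigma_stab^2 * d`.
#' @export
loss_stability <- function(z_d, sigma_stab, seed = 1L) {
  abort_if(sigma_stab < 0, "sigma_stab must be >= 0")
  zv <- ad_value(z_d)
  abort_if(any(!is.finite(zv)), "non-finite embeddings")
  if (sigma_stab == 0) return(zero_like_scalar(z_d))
  eps <- with_seed(substream_seed(seed, "stability"),
                   matrix(stats::rnorm(length(zv), sd = sigma_stab), nrow(zv), ncol(zv)))
  diff <- ad_sub(z_d, ad_detach(z_d) + eps)
  ad_mean(ad_rowsums(ad_mul(diff, diff)))
}

#' Hardness-aware contrastive loss
#'
#' For each anchor, the hardest positive `j*` is the minimum-cosine-similarity
#' positive and `H(i)` holds the `hard_k` most similar negatives; the term is
#' `-log( exp(s* / tau) / (exp(s* / tau) + sum_{h in H(i)} exp(s_h / tau)) )`,
#' averaged over anchors that have at least one positive and one negative.
#'
#' @param z_d embedding batch `n x d`.
#' @param y labels per row.
#' @param tau temperature (> 0).
#' @param hard_k negatives mined per anchor.
#' @return scalar.
#' @export
loss_hard_contrastive <- function(z_d, y, tau, hard_k = 5L) {
  abort_if(tau <= 0, "tau must be > 0")
  zv <- ad_value(z_d)
  n <- nrow(zv)
  abort_if(length(y) != n, "one label per row required")
  zn <- l2_normalize_rows(z_d)
  logits <- ad_mul(ad_matmul(zn, ad_t(zn)), 1 / tau)
  sims <- ad_value(logits) # mining happens on detached similarities
  sel <- matrix(0, n, n)   # 1 on (i, j*) and (i, h in H(i))
  star <- matrix(NA_integer_, 0L, 2L)
  anchors <- integer(0)
  for (i in seq_len(n)) {
    pos <- setdiff(which(y == y[i]), i)
    neg <- which(y != y[i])
    if (length(pos) == 0L || length(neg) == 0L) next
    j_star <- pos[which.min(sims[i, pos])]
    hard <- neg[order(sims[i, neg], decreasing = TRUE)][seq_len(min(hard_k, length(neg)))]
    sel[i, j_star] <- 1
    sel[i, hard] <- 1
    star <- rbind(star, c(i, j_star))
    anchors <- c(anchors, i)
  }
  if (length(anchors) == 0L) {
    message("loss_hard_contrastive: no anchor with both a positive and a negative")
    return(zero_like_scalar(z_d))
  }
  denom <- ad_rowsums(ad_mul(ad_exp(logits), sel))
  terms <- ad_sub(ad_log(ad_rows(denom, anchors)), ad_gather(logits, star))
  ad_mean(terms)
}

#' Running class statistics for centers and Gaussian invariance
#'
#' Holds the exponential-moving-average class centers of the disease code and
#' the per-class / per-(class, stratum) running Gaussian statistics with
#' shrinkage.
#'
#' @param d embedding dimension.
#' @param n_classes number of classes K.
#' @param n_strata number of strata.
#' @param ema_decay EMA decay in (0, 1).
#' @param shrink_alpha covariance shrinkage intensity in [0, 1].
#' @param var_floor lower bound on the shrinkage target variance, keeping the
#'   shrunk covariance positive-definite even for degenerate batches.
#' @return a `class_stats` object.
#' @export
class_stats <- function(d, n_classes, n_strata, ema_decay = 0.9,
                        shrink_alpha = 0.1, var_floor = 1e-3) {
  abort_if(ema_decay <= 0 || ema_decay >= 1, "ema_decay must be in (0, 1)")
  abort_if(shrink_alpha < 0 || shrink_alpha > 1, "shrink_alpha must be in [0, 1]")
  s <- list(d = as.integer(d), n_classes = as.integer(n_classes),
            n_strata = as.integer(n_strata),
            centers = matrix(NA_real_, n_classes, d),
            class_mean = matrix(NA_real_, n_classes, d),
            class_cov = rep(list(NULL), n_classes),
            cell_mean = rep(list(vector("list", n_strata)), n_classes),
            cell_cov = rep(list(vector("list", n_strata)), n_classes),
            class_count = rep(0, n_classes),
            cell_count = matrix(0, n_classes, n_strata),
            ema_decay = ema_decay, shrink_alpha = shrink_alpha,
            var_floor = var_floor)
  # cell_mean/cell_cov: list over classes of lists over strata
  s$cell_mean <- lapply(seq_len(n_classes), function(k) vector("list", n_strata))
  s$cell_cov <- lapply(seq_len(n_classes), function(k) vector("list", n_strata))
  class(s) <- "class_stats"
  s
}

#' Center loss toward EMA class centers
#'
#' Batch mean of `||z_i - mu_{y_i}||^2` with centers treated as constants.
#' Classes whose center is not yet initialized are lazily set to the batch
#' class mean (and a message is emitted).
#'
#' @param z_d embedding batch.
#' @param y labels per row (0-based).
#' @param stats a `class_stats` object.
#' @return scalar.
#' @export
loss_center <- function(z_d, y, stats) {
  zv <- ad_value(z_d)
  y <- as.integer(y)
  centers <- stats$centers
  for (k in unique(y)) {
    if (anyNA(centers[k + 1L, ])) {
      message(sprintf("loss_center: lazily initializing center of class %d", k))
      centers[k + 1L, ] <- colMeans(zv[y == k, , drop = FALSE])
    }
  }
  diff <- ad_sub(z_d, centers[y + 1L, , drop = FALSE])
  ad_mean(ad_rowsums(ad_mul(diff, diff)))
}

#' Update EMA class centers
#'
#' `mu_k <- decay * mu_k + (1 - decay) * batch_class_mean`; uninitialized
#' classes are set to the batch class mean. The update is a pure statistics
#' update outside any gradient path.
#'
#' @param z_d numeric embedding batch.
#' @param y labels (0-based).
#' @param stats a `class_stats` object.
#' @return the updated `class_stats`.
#' @export
update_centers <- function(z_d, y, stats) {
  zv <- ad_detach(z_d)
  y <- as.integer(y)
  for (k in unique(y)) {
    bm <- colMeans(zv[y == k, , drop = FALSE])
    old <- stats$centers[k + 1L, ]
    stats$centers[k + 1L, ] <- if (anyNA(old)) bm else
      stats$ema_decay * old + (1 - stats$ema_decay) * bm
  }
  stats
}

shrink_cov <- function(S, alpha, var_floor) {
  d <- nrow(S)
  target <- max(sum(diag(S)) / d, var_floor)
  (1 - alpha) * S + alpha * target * diag(d)
}

ema_blend <- function(old, new, decay) if (is.null(old) || anyNA(old)) new else decay * old + (1 - decay) * new

#' Update running Gaussian statistics
#'
#' EMA-updates the per-class and per-(class, stratum) means and covariances of
#' the disease code, then applies shrinkage
#' `Sigma <- (1 - alpha) Sigma + alpha (tr(Sigma)/d) I` (with a small variance
#' floor on the target), guaranteeing positive-definite covariances for
#' `alpha > 0`.
#'
#' @param z_d numeric embedding batch.
#' @param y class labels (0-based).
#' @param strata stratum labels (0-based).
#' @param stats a `class_stats` object.
#' @return the updated `class_stats`.
#' @export
update_gaussian_stats <- function(z_d, y, strata, stats) {
  zv <- ad_detach(z_d)
  y <- as.integer(y); strata <- as.integer(strata)
  ml_cov <- function(m) {
    c0 <- sweep(m, 2L, colMeans(m))
    crossprod(c0) / nrow(m)
  }
  for (k in unique(y)) {
    zk <- zv[y == k, , drop = FALSE]
    stats$class_mean[k + 1L, ] <- ema_blend(stats$class_mean[k + 1L, ], colMeans(zk), stats$ema_decay)
    if (nrow(zk) >= 2L) {
      blended <- ema_blend(stats$class_cov[[k + 1L]], ml_cov(zk), stats$ema_decay)
      stats$class_cov[[k + 1L]] <- shrink_cov(blended, stats$shrink_alpha, stats$var_floor)
    }
    stats$class_count[k + 1L] <- stats$class_count[k + 1L] + nrow(zk)
    for (s in unique(strata[y == k])) {
      zks <- zv[y == k & strata == s, , drop = FALSE]
      stats$cell_mean[[k + 1L]][[s + 1L]] <-
        ema_blend(stats$cell_mean[[k + 1L]][[s + 1L]], colMeans(zks), stats$ema_decay)
      if (nrow(zks) >= 2L) {
        blended <- ema_blend(stats$cell_cov[[k + 1L]][[s + 1L]], ml_cov(zks), stats$ema_decay)
        stats$cell_cov[[k + 1L]][[s + 1L]] <- shrink_cov(blended, stats$shrink_alpha, stats$var_floor)
      }
      stats$cell_count[k + 1L, s + 1L] <- stats$cell_count[k + 1L, s + 1L] + nrow(zks)
    }
  }
  stats
}

gauss_kl <- function(mu0, S0, mu1, S1) {
  # KL( N(mu0, S0) || N(mu1, S1) ), closed form
  d <- length(mu0)
  ch1 <- chol(S1); ch0 <- chol(S0)
  inv1 <- chol2inv(ch1)
  dm <- mu1 - mu0
  0.5 * (sum(diag(inv1 %*% S0)) + drop(t(dm) %*% inv1 %*% dm) - d +
           2 * sum(log(diag(ch1))) - 2 * sum(log(diag(ch0))))
}

#' Causal invariance loss over running statistics
#'
#' `sum_k sum_s KL( N(mu_{k,s}, Sigma_{k,s}) || N(mu_k, Sigma_k) )` in the
#' multivariate-Gaussian closed form, over cells whose sample count reaches
#' `min_count` and whose class statistics are valid.
#'
#' @param stats a `class_stats` object.
#' @param min_count inclusion floor on cell/class counts.
#' @return scalar, >= 0.
#' @export
loss_invariance <- function(stats, min_count = 2L) {
  total <- 0
  for (k in seq_len(stats$n_classes)) {
    if (stats$class_count[k] < min_count || is.null(stats$class_cov[[k]]) ||
        anyNA(stats$class_mean[k, ])) next
    for (s in seq_len(stats$n_strata)) {
      if (stats$cell_count[k, s] < min_count || is.null(stats$cell_cov[[k]][[s]]) ||
          is.null(stats$cell_mean[[k]][[s]])) next
      total <- total + gauss_kl(stats$cell_mean[[k]][[s]], stats$cell_cov[[k]][[s]],
                                stats$class_mean[k, ], stats$class_cov[[k]])
    }
  }
  matrix(total, 1L, 1L)
}

#' Counterfactual consistency loss
#'
#' Mean over counterfactual images of the minimum squared pixel distance to
#' any real target-class image in the batch (within-batch approximation of
#' the minimum over the full target set).
#'
#' @param cf_images counterfactual batch `m x D`.
#' @param target_class_images real target-class batch `r x D`.
#' @return scalar; 0 with a logged skip when the target set is empty.
#' @export
loss_counterfactual <- function(cf_images, target_class_images) {
  tv <- ad_detach(target_class_images)
  cv <- ad_value(cf_images)
  if (is.null(tv) || nrow(tv) == 0L) {
    message("loss_counterfactual: empty target set; skipping")
    return(zero_like_scalar(cf_images))
  }
  abort_if(ncol(tv) != ncol(cv), "counterfactual and target images differ in size")
  # nearest real target per counterfactual, mined on values
  d2 <- outer(rowSums(cv^2), rep(1, nrow(tv))) - 2 * cv %*% t(tv) +
    outer(rep(1, nrow(cv)), rowSums(tv^2))
  j <- max.col(-d2, ties.method = "first")
  diff <- ad_sub(cf_images, tv[j, , drop = FALSE])
  ad_mean(ad_rowsums(ad_mul(diff, diff)))
}

#' Domain-confusion loss with gradient reversal
#'
#' Cross-entropy of a linear stratum classifier on `z_d`. On the backward
#' pass the gradient reaching the encoder through `z_d` is multiplied by
#' `-reversal_strength`, while the classifier head receives the ordinary
#' gradient.
#'
#' @param model a `neurofact_model` with `domain_confusion = TRUE`.
#' @param z_d embedding batch.
#' @param strata stratum labels (0-based).
#' @param reversal_strength non-negative reversal scale.
#' @return scalar cross-entropy.
#' @export
domain_confusion_loss <- function(model, z_d, strata, reversal_strength = 1) {
  abort_if(!isTRUE(model$config$domain_confusion),
           "domain-confusion branch is disabled in this model's config")
  abort_if(reversal_strength < 0, "reversal_strength must be >= 0")
  strata <- as.integer(strata)
  zr <- ad_grad_reverse(z_d, reversal_strength)
  logits <- ad_addbias(ad_matmul(zr, model$params$W_dom), model$params$b_dom)
  ls <- ad_log_softmax(logits)
  picked <- ad_gather(ls, cbind(seq_along(strata), strata + 1L))
  ad_neg(ad_mean(picked))
}

#' Age-decoupling penalty on the disease code
#'
#' Squared norm of the batch covariance between `z_d` and the standardized
#' age, `||Cov(z_d, t_std)||^2`. The linear-readout counterpart of
#' [loss_fisher_sep()] for the continuous confounder: a ridge probe predicts
#' age from `z_d` exactly through these covariances, so the penalty strips
#' age information beyond what the (age-correlated) disease severity itself
#' carries.
#'
#' @param z_d disease-code batch `n x d`.
#' @param t ages (any location/scale; standardized within the batch).
#' @return scalar, >= 0.
#' @export
loss_age_decouple <- function(z_d, t) {
  zv <- ad_value(z_d)
  n <- nrow(zv)
  abort_if(length(t) != n, "one age per row required")
  if (n < 2L || stats::sd(t) == 0) return(zero_like_scalar(z_d))
  ts <- (t - mean(t)) / stats::sd(t)
  cz <- ad_sub(z_d, ad_matmul(matrix(1, n, 1L),
                              ad_mul(ad_matmul(matrix(1, 1L, n), z_d), 1 / n)))
  cv <- ad_mul(ad_matmul(matrix(ts / n, 1L, n), cz), 1)
  ad_sum(ad_mul(cv, cv))
}

#' Fisher-separability penalty on a latent code
#'
#' The within-class-whitened between-class scatter of `z_a`:
#' `sum_k (n_k/n) (m_k - m)' W^-1 (m_k - m)`, where `m_k` are batch class
#' means and `W` is the (detached, shrinkage-floored) pooled within-class
#' covariance. This is the population quantity a linear discriminant probe
#' exploits, so driving it down makes the anatomy code uninformative about
#' diagnosis under any linear readout. Gradients flow through the class
#' means; the whitening matrix is treated as a per-batch constant.
#'
#' @param z_a anatomy-code batch `n x d`.
#' @param y class labels (0-based).
#' @param shrink shrinkage intensity toward `(tr(W)/d) I` for the whitener.
#' @return scalar, >= 0.
#' @export
loss_fisher_sep <- function(z_a, y, shrink = 0.1) {
  zv <- ad_value(z_a)
  n <- nrow(zv); d <- ncol(zv)
  abort_if(length(y) != n, "one label per row required")
  classes <- unique(y)
  if (length(classes) < 2L) {
    message("loss_fisher_sep: single class in batch; skipping")
    return(zero_like_scalar(z_a))
  }
  # pooled within-class covariance on values, shrunk to stay invertible
  W <- matrix(0, d, d)
  for (k in classes) {
    zk <- zv[y == k, , drop = FALSE]
    if (nrow(zk) >= 2L) {
      c0 <- sweep(zk, 2L, colMeans(zk))
      W <- W + crossprod(c0)
    }
  }
  W <- W / n
  W <- shrink_cov(W, shrink, 1e-3)
  Winv <- chol2inv(chol(W))
  grand <- ad_mul(ad_matmul(matrix(1, 1L, n), z_a), 1 / n)
  total <- zero_like_scalar(z_a)
  for (k in classes) {
    idx <- which(y == k)
    mk <- ad_mul(ad_matmul(matrix(1, 1L, length(idx)), ad_rows(z_a, idx)),
                 1 / length(idx))
    dk <- ad_sub(mk, grand)
    qk <- ad_matmul(ad_matmul(dk, Winv), ad_t(dk))
    total <- ad_add(total, ad_mul(qk, length(idx) / n))
  }
  total
}

#' Adversarial diagnosis loss on the anatomy code
#'
#' Cross-entropy of a linear diagnosis classifier on `z_a`, with gradient
#' reversal toward the encoder: the head learns to read any disease signal
#' left in the anatomy code, and the encoder is driven to remove it. This
#' enforces the disease invariance of `z_a` the same way the domain-confusion
#' branch enforces the site invariance of `z_d` — one mechanism, two
#' applications.
#'
#' @param model a `neurofact_model` with `class_adversary = TRUE`.
#' @param z_a anatomy-code batch.
#' @param y class labels (0-based).
#' @param reversal_strength non-negative reversal scale.
#' @return scalar cross-entropy.
#' @export
class_adversary_loss <- function(model, z_a, y, reversal_strength = 1) {
  abort_if(!isTRUE(model$config$class_adversary),
           "class-adversary branch is disabled in this model's config")
  abort_if(reversal_strength < 0, "reversal_strength must be >= 0")
  y <- as.integer(y)
  zr <- ad_grad_reverse(z_a, reversal_strength)
  logits <- ad_addbias(ad_matmul(zr, model$params$W_adv), model$params$b_adv)
  ls <- ad_log_softmax(logits)
  picked <- ad_gather(ls, cbind(seq_along(y), y + 1L))
  ad_neg(ad_mean(picked))
}

.cdaa_terms <- c("task", "mmd", "cond", "supcon", "stability", "hard",
                 "center", "invariance", "counterfactual")

#' Total alignment-augmented objective
#'
#' `L = L_task + lambda1 * lambda_m * L_MMD + lambda2 * lambda_c * L_cond +
#' lambda3 * L_contrastive + lambda4 * L_inv + lambda5 * L_cf`, where
#' `L_contrastive = L_con + lambda_stab * L_stab + lambda_hard * L_hard +
#' lambda_center * L_center`. An optional `domain` term is added unweighted
#' (its effective strength is the reversal scale).
#'
#' @param terms named list holding `task`, `mmd`, `cond`, `supcon`,
#'   `stability`, `hard`, `center`, `invariance`, `counterfactual`, and
#'   optionally `domain` (scalars or autodiff nodes).
#' @param weights a [loss_weights()].
#' @return scalar total of the same kind as the inputs.
#' @export
total_cdaa <- function(terms, weights) {
  stopifnot(inherits(weights, "loss_weights"))
  missing <- setdiff(.cdaa_terms, names(terms))
  abort_if(length(missing) > 0L, "total_cdaa: missing term '%s'", missing[1L])
  contrastive <- ad_add(terms$supcon,
                        ad_add(ad_mul(terms$stability, weights$lambda_stab),
                               ad_add(ad_mul(terms$hard, weights$lambda_hard),
                                      ad_mul(terms$center, weights$lambda_center))))
  total <- ad_add(terms$task,
                  ad_add(ad_mul(terms$mmd, weights$lambda1 * weights$lambda_m),
                         ad_add(ad_mul(terms$cond, weights$lambda2 * weights$lambda_c),
                                ad_add(ad_mul(contrastive, weights$lambda3),
                                       ad_add(ad_mul(terms$invariance, weights$lambda4),
                                              ad_mul(terms$counterfactual, weights$lambda5))))))
  if (!is.null(terms$domain)) total <- ad_add(total, terms$domain)
  if (!is.null(terms$domain_a)) total <- ad_add(total, terms$domain_a)
  total
}
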