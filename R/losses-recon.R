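# Reconstruction-side and supervision-side loss terms.
#
# Reduction convention, used everywhere: a norm over an image or latent means
# the SUM of squares over its entries, and each loss is the MEAN of those
# per-sample sums over the batch. The temporal term divides by the number of
# contributing visit pairs. Every term accepts plain matrices or autodiff
# nodes and returns a scalar of the same kind.

#' Composite-objective coefficients
#'
#' Every coefficient of the training objective. The top level combines
#' `L_task + lambda1*L_MMD + lambda2*L_cond + lambda3*L_contrastive +
#' lambda4*L_inv + lambda5*L_cf`; the contrastive block combines
#' `L_con + lambda_stab*L_stab + lambda_hard*L_hard + lambda_center*L_center`;
#' `lambda_m`/`lambda_c` scale the marginal and conditional alignment terms
#' inside their slots (both default 1, composing multiplicatively with
#' `lambda1`/`lambda2`).
#'
#' @param sigma2 Gaussian likelihood variance of the decoder (> 0).
#' @param lambda_a,lambda_d weights of the pathway-specific reconstruction
#'   fidelity terms.
#' @param w_add,w_decorr,w_kl,w_cls,w_age,w_smooth weights of the additive
#'   constraint, decorrelation, KL, classification, age-regression and
#'   temporal terms inside the task bundle.
#' @param w_xcov weight of the cross-covariance decoupling penalty between
#'   the two latent codes ([loss_cross_cov()]).
#' @param w_adv weight of the adversarial diagnosis head on the anatomy code
#'   ([class_adversary_loss()]).
#' @param w_fisher weight of the Fisher-separability penalty on the anatomy
#'   code w.r.t. diagnosis ([loss_fisher_sep()]).
#' @param w_fisher_strata weight of the Fisher-separability penalty on the
#'   disease code w.r.t. strata (site invariance under linear probes). This
#'   penalty belongs to the stratified-alignment group: its effective weight
#'   is `lambda1 * lambda_m * w_fisher_strata`, so ablating `lambda1` removes
#'   it together with the kernel MMD term.
#' @param w_tcov weight of the age-decoupling penalty on the disease code
#'   ([loss_age_decouple()]).
#' @param lambda_m,lambda_c marginal/conditional alignment trade-off.
#' @param tau contrastive temperature (> 0).
#' @param sigma_stab perturbation SD of the stability term (>= 0).
#' @param lambda_stab,lambda_hard,lambda_center contrastive sub-weights.
#' @param lambda1,lambda2,lambda3,lambda4,lambda5 top-level alignment weights.
#' @param gamma temporal decay rate (1/years) of the exponential-decay
#'   smoothness mode.
#' @param ema_decay decay of all running statistics, in (0, 1).
#' @param shrink_alpha covariance shrinkage intensity in [0, 1].
#' @param hard_k number of hard negatives mined per anchor.
#' @param reversal_strength gradient-reversal scale of the optional
#'   domain-confusion branch.
#' @return a `loss_weights` list.
#' @export
loss_weights <- function(sigma2 = 1, lambda_a = 0, lambda_d = 0,
                         w_add = 1, w_decorr = 1e-4, w_kl = 2,
                         w_cls = 30, w_age = 5, w_smooth = 0.1, w_xcov = 30,
                         w_adv = 0, w_fisher = 5, w_fisher_strata = 50, w_tcov = 20,
                         lambda_m = 1, lambda_c = 1,
                         tau = 0.1, sigma_stab = 0.1,
                         lambda_stab = 1, lambda_hard = 0.5, lambda_center = 0.1,
                         lambda1 = 0.1, lambda2 = 0.1, lambda3 = 0.5,
                         lambda4 = 0.1, lambda5 = 0.2,
                         gamma = 1, ema_decay = 0.9, shrink_alpha = 0.1,
                         hard_k = 5L, reversal_strength = 1) {
  w <- list(sigma2 = sigma2, lambda_a = lambda_a, lambda_d = lambda_d,
            w_add = w_add, w_decorr = w_decorr, w_kl = w_kl, w_cls = w_cls,
            w_age = w_age, w_smooth = w_smooth, w_xcov = w_xcov, w_adv = w_adv,
            w_fisher = w_fisher, w_fisher_strata = w_fisher_strata,
            w_tcov = w_tcov, lambda_m = lambda_m,
            lambda_c = lambda_c, tau = tau, sigma_stab = sigma_stab,
            lambda_stab = lambda_stab, lambda_hard = lambda_hard,
            lambda_center = lambda_center, lambda1 = lambda1, lambda2 = lambda2,
            lambda3 = lambda3, lambda4 = lambda4, lambda5 = lambda5,
            gamma = gamma, ema_decay = ema_decay, shrink_alpha = shrink_alpha,
            hard_k = as.integer(hard_k), reversal_strength = reversal_strength)
  abort_if(w$tau <= 0, "tau must be > 0")
  abort_if(w$sigma2 <= 0, "sigma2 must be > 0")
  abort_if(w$ema_decay <= 0 || w$ema_decay >= 1, "ema_decay must be in (0, 1)")
  abort_if(w$shrink_alpha < 0 || w$shrink_alpha > 1, "shrink_alpha must be in [0, 1]")
  nonneg <- setdiff(names(w), c("tau", "sigma2", "ema_decay", "shrink_alpha"))
  for (nm in nonneg) abort_if(w[[nm]] < 0, "%s must be >= 0", nm)
  class(w) <- "loss_weights"
  w
}

same_shape <- function(a, b, what) {
  abort_if(!identical(dim(ad_value(a)), dim(ad_value(b))),
           "shape mismatch in %s", what)
}

# batch mean of per-row sums of squares
mean_rowss <- function(x) ad_mean(ad_rowsums(ad_mul(x, x)))

#' Gaussian reconstruction loss
#'
#' Negative Gaussian log-likelihood up to its additive constant:
#' `||x - x_hat||^2 / (2 sigma2)`, pixel-summed, batch-averaged.
#'
#' @param x,x_hat image batches `n x D`.
#' @param sigma2 likelihood variance (> 0).
#' @return scalar.
#' @export
loss_recon <- function(x, x_hat, sigma2 = 1) {
  abort_if(sigma2 <= 0, "sigma2 must be > 0")
  same_shape(x, x_hat, "loss_recon")
  ad_mul(mean_rowss(ad_sub(x, x_hat)), 1 / (2 * sigma2))
}

#' KL divergence of both latent branches to the standard normal prior
#'
#' Diagonal-Gaussian closed form, summed over the two branches and their
#' dimensions, batch-averaged.
#'
#' @param latent a `latent_code` (needs mu_a, logvar_a, mu_d, logvar_d).
#' @return scalar, always >= 0.
#' @export
loss_kl <- function(latent) {
  for (f in c("mu_a", "logvar_a", "mu_d", "logvar_d")) {
    abort_if(any(!is.finite(ad_value(latent[[f]]))), "non-finite posterior parameter %s", f)
  }
  kl_branch <- function(mu, lv) {
    term <- ad_sub(ad_add(ad_mul(mu, mu), ad_exp(lv)), ad_add(lv, 1))
    ad_mul(ad_mean(ad_rowsums(term)), 0.5)
  }
  ad_add(kl_branch(latent$mu_a, latent$logvar_a),
         kl_branch(latent$mu_d, latent$logvar_d))
}

#' Additive composition constraint
#'
#' Batch mean of the pixel-summed squared residual between the full
#' reconstruction and the sum of the two pathway reconstructions.
#'
#' @param x_hat,x_hat_a,x_hat_d image batches `n x D`.
#' @return scalar.
#' @export
loss_additive <- function(x_hat, x_hat_a, x_hat_d) {
  same_shape(x_hat, x_hat_a, "loss_additive")
  same_shape(x_hat, x_hat_d, "loss_additive")
  mean_rowss(ad_sub(x_hat, ad_add(x_hat_a, x_hat_d)))
}

#' Augmented reconstruction loss
#'
#' `mean(||x - x_hat||^2 + lambda_a ||x - x_hat_a||^2 + lambda_d ||x - x_hat_d||^2)`.
#'
#' @param x,x_hat,x_hat_a,x_hat_d image batches `n x D`.
#' @param lambda_a,lambda_d non-negative pathway weights.
#' @return scalar.
#' @export
loss_rec_aug <- function(x, x_hat, x_hat_a, x_hat_d, lambda_a, lambda_d) {
  abort_if(lambda_a < 0 || lambda_d < 0, "lambda_a and lambda_d must be >= 0")
  same_shape(x, x_hat, "loss_rec_aug")
  same_shape(x, x_hat_a, "loss_rec_aug")
  same_shape(x, x_hat_d, "loss_rec_aug")
  ad_add(mean_rowss(ad_sub(x, x_hat)),
         ad_add(ad_mul(mean_rowss(ad_sub(x, x_hat_a)), lambda_a),
                ad_mul(mean_rowss(ad_sub(x, x_hat_d)), lambda_d)))
}

#' Pixel-space decorrelation penalty
#'
#' Batch mean of the squared per-sample inner product of the two pathway
#' reconstructions.
#'
#' @param x_hat_a,x_hat_d image batches `n x D`.
#' @return scalar.
#' @export
loss_decorr <- function(x_hat_a, x_hat_d) {
  same_shape(x_hat_a, x_hat_d, "loss_decorr")
  ip <- ad_rowsums(ad_mul(x_hat_a, x_hat_d))
  ad_mean(ad_mul(ip, ip))
}

#' Cross-entropy classification loss
#'
#' Batch mean of `-log p(y | z_d)` given softmax probabilities.
#'
#' @param probs matrix `n x K` of class probabilities (rows sum to 1).
#' @param y integer labels in `0..K-1`.
#' @return scalar, >= 0.
#' @export
loss_cls <- function(probs, y) {
  pv <- ad_value(probs)
  y <- as.integer(y)
  abort_if(length(y) != nrow(pv), "one label per row required")
  abort_if(any(y < 0L) || any(y >= ncol(pv)), "label out of range 0..K-1")
  picked <- ad_gather(probs, cbind(seq_along(y), y + 1L))
  ad_neg(ad_mean(ad_log(picked)))
}

#' Age regression loss
#' Batch mean squared error between predicted and true ages.
#' @param pred column matrix or vector of predictions.
#' @param t true ages, same length.
#' @return scalar.
#' @export
loss_age <- function(pred, t) {
  pv <- ad_value(pred)
  abort_if(length(pv) != length(t), "pred and t differ in length")
  d <- ad_sub(pred, matrix(as.numeric(t), ncol = 1L))
  ad_mean(ad_mul(d, d))
}

#' Cross-covariance decoupling penalty
#'
#' Squared Frobenius norm of the batch cross-covariance between the two
#' latent codes, `||Cov(z_a, z_d)||_F^2`. A light-weight surrogate for low
#' mutual information between the pathways: it drives every linearly shared
#' factor (e.g. disease severity mirrored into the anatomy code, or age
#' mirrored into the disease code) out of one of the two codes, which is what
#' keeps linear leakage probes near chance.
#'
#' @param z_a,z_d latent batches `n x d_a`, `n x d_d` (n >= 2).
#' @return scalar, >= 0; exactly 0 for batchwise uncorrelated codes.
#' @export
loss_cross_cov <- function(z_a, z_d) {
  n <- nrow(ad_value(z_a))
  abort_if(n < 2L, "loss_cross_cov needs a batch of >= 2")
  abort_if(nrow(ad_value(z_d)) != n, "z_a and z_d must have equal batch sizes")
  center <- function(z) {
    mu <- ad_mul(ad_matmul(matrix(1, 1L, n), z), 1 / n)
    ad_sub(z, ad_matmul(matrix(1, n, 1L), mu))
  }
  C <- ad_mul(ad_matmul(ad_t(center(z_a)), center(z_d)), 1 / n)
  ad_sum(ad_mul(C, C))
}

# index pairs of within-subject visits; adjacent consecutive pairs or all pairs
subject_pairs <- function(subject, time, adjacent = TRUE) {
  ord <- order(subject, time)
  i1 <- integer(0); i2 <- integer(0)
  for (s in unique(subject)) {
    idx <- ord[subject[ord] == s]
    if (length(idx) < 2L) next
    if (adjacent) {
      i1 <- c(i1, idx[-length(idx)]); i2 <- c(i2, idx[-1L])
    } else {
      cmb <- utils::combn(idx, 2L)
      i1 <- c(i1, cmb[1L, ]); i2 <- c(i2, cmb[2L, ])
    }
  }
  cbind(i1, i2)
}

#' Temporal coherence loss
#'
#' Penalizes within-subject latent displacement. In `adjacent` mode, the sum
#' of `||dz_d||^2 + ||dz_a||^2` over consecutive visit pairs; in `exp_decay`
#' mode, over all within-subject pairs weighted by `exp(-gamma |t - t'|)`.
#' Either way the sum is divided by the number of contributing pairs; subjects
#' with a single scan contribute nothing.
#'
#' @param z_a,z_d latent batches `n x d`.
#' @param subject subject identifier per row.
#' @param time visit time (years) per row.
#' @param mode `"adjacent"` or `"exp_decay"`.
#' @param gamma decay rate for `exp_decay` (1/years).
#' @return scalar.
#' @export
loss_smooth <- function(z_a, z_d, subject, time,
                        mode = c("adjacent", "exp_decay"), gamma = 1) {
  mode <- tryCatch(match.arg(mode),
                   error = function(e) stop("unknown smoothness mode", call. = FALSE))
  n <- nrow(ad_value(z_a))
  abort_if(length(subject) != n || length(time) != n,
           "subject and time must have one entry per row")
  pairs <- subject_pairs(subject, time, adjacent = (mode == "adjacent"))
  if (nrow(pairs) == 0L) {
    return(if (is_adnode(z_a) || is_adnode(z_d)) ad_param(matrix(0, 1L, 1L)) else matrix(0, 1L, 1L))
  }
  dz_a <- ad_sub(ad_rows(z_a, pairs[, 2L]), ad_rows(z_a, pairs[, 1L]))
  dz_d <- ad_sub(ad_rows(z_d, pairs[, 2L]), ad_rows(z_d, pairs[, 1L]))
  ss <- ad_add(ad_rowsums(ad_mul(dz_a, dz_a)), ad_rowsums(ad_mul(dz_d, dz_d)))
  if (mode == "exp_decay") {
    wts <- exp(-gamma * abs(time[pairs[, 2L]] - time[pairs[, 1L]]))
    ss <- ad_mul(ss, matrix(wts, ncol = 1L))
  }
  ad_mean(ss)
}
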