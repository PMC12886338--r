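# The dual-pathway variational network.
#
# A shared fully-connected encoder bifurcates into Gaussian posterior heads
# for the anatomy code z_a and the disease code z_d; a shared decoder maps
# (z_a, z_d) back to pixel space. Pathway-isolated decoding silences one
# branch with the zero vector. A softmax head classifies diagnosis from z_d
# only; a linear head regresses age from z_a only, so pathway isolation of the
# supervision is structural, not learned. All forward functions run on plain
# matrices (evaluation) or on autodiff nodes (training) through the same code.

#' Network configuration
#'
#' @param d_a anatomy latent dimension (>= 1).
#' @param d_d disease latent dimension (>= 1).
#' @param image_size pixels per side of the square input.
#' @param n_classes number of diagnosis classes K.
#' @param hidden_enc encoder hidden width (single tanh layer).
#' @param hidden_dec decoder hidden width; 0 gives a purely linear decoder.
#' @param n_strata number of strata the optional domain-confusion head can see.
#' @param domain_confusion enable the gradient-reversal stratum head?
#' @param class_adversary enable the gradient-reversal diagnosis head on the
#'   anatomy code (enforces disease invariance of `z_a`)?
#' @return a `model_config` list.
#' @export
model_config <- function(d_a = 4L, d_d = 4L, image_size = 16L, n_classes = 3L,
                         hidden_enc = 32L, hidden_dec = 0L,
                         n_strata = 2L, domain_confusion = FALSE,
                         class_adversary = FALSE) {
  cfg <- list(d_a = as.integer(d_a), d_d = as.integer(d_d),
              image_size = as.integer(image_size), n_classes = as.integer(n_classes),
              hidden_enc = as.integer(hidden_enc), hidden_dec = as.integer(hidden_dec),
              n_strata = as.integer(n_strata), domain_confusion = isTRUE(domain_confusion),
              class_adversary = isTRUE(class_adversary))
  abort_if(cfg$d_a < 1L || cfg$d_d < 1L, "latent dims must be >= 1")
  abort_if(cfg$n_classes < 2L, "n_classes must be >= 2")
  abort_if(cfg$hidden_enc < 1L, "hidden_enc must be >= 1")
  abort_if(cfg$hidden_dec < 0L, "hidden_dec must be >= 0")
  class(cfg) <- "model_config"
  cfg
}

glorot <- function(n_in, n_out) {
  matrix(stats::rnorm(n_in * n_out, sd = sqrt(1 / n_in)), n_in, n_out)
}

#' Initialize network weights
#'
#' @param cfg a [model_config()].
#' @param seed integer seed for the weight draws.
#' @return a `neurofact_model`: list with `config` and a named `params` list
#'   of weight matrices.
#' @export
init_model <- function(cfg, seed = 1L) {
  stopifnot(inherits(cfg, "model_config"))
  D <- cfg$image_size^2
  h <- cfg$hidden_enc
  dz <- cfg$d_a + cfg$d_d
  params <- with_seed(substream_seed(seed, "init"), {
    p <- list(
      enc_W1 = glorot(D, h),        enc_b1 = matrix(0, 1L, h),
      W_mu_a = glorot(h, cfg$d_a),  b_mu_a = matrix(0, 1L, cfg$d_a),
      W_lv_a = 0.1 * glorot(h, cfg$d_a), b_lv_a = matrix(-2, 1L, cfg$d_a),
      W_mu_d = glorot(h, cfg$d_d),  b_mu_d = matrix(0, 1L, cfg$d_d),
      W_lv_d = 0.1 * glorot(h, cfg$d_d), b_lv_d = matrix(-2, 1L, cfg$d_d),
      W_cls = glorot(cfg$d_d, cfg$n_classes), b_cls = matrix(0, 1L, cfg$n_classes),
      W_age = glorot(cfg$d_a, 1L),  b_age = matrix(0, 1L, 1L)
    )
    if (cfg$hidden_dec > 0L) {
      p$dec_W1 <- glorot(dz, cfg$hidden_dec); p$dec_b1 <- matrix(0, 1L, cfg$hidden_dec)
      p$dec_W2 <- glorot(cfg$hidden_dec, D);  p$dec_b2 <- matrix(0, 1L, D)
    } else {
      p$dec_W <- glorot(dz, D); p$dec_b <- matrix(0, 1L, D)
    }
    if (cfg$domain_confusion) {
      p$W_dom <- glorot(cfg$d_d, cfg$n_strata); p$b_dom <- matrix(0, 1L, cfg$n_strata)
    }
    if (cfg$class_adversary) {
      p$W_adv <- glorot(cfg$d_a, cfg$n_classes); p$b_adv <- matrix(0, 1L, cfg$n_classes)
    }
    p
  })
  structure(list(config = cfg, params = params, age_loc = 0, age_scale = 1),
            class = "neurofact_model")
}

check_images <- function(model, x) {
  x <- ad_value(x)
  D <- model$config$image_size^2
  abort_if(ncol(x) != D,
           "expected %d pixels per image (image_size %d), got %d columns",
           D, model$config$image_size, ncol(x))
  x
}

# logvar soft clamp keeps posteriors numerically sane without killing gradients
soft_clamp <- function(x, limit = 6) ad_mul(ad_tanh(ad_mul(x, 1 / limit)), limit)

# Forward encoder over matrices or nodes. `p` may hold nodes (training) or
# plain matrices. eps_* are plain matrices (the reparameterization draws).
encode_forward <- function(p, x, eps_a, eps_d, limit = 6) {
  h <- ad_tanh(ad_addbias(ad_matmul(x, p$enc_W1), p$enc_b1))
  mu_a <- ad_addbias(ad_matmul(h, p$W_mu_a), p$b_mu_a)
  lv_a <- soft_clamp(ad_addbias(ad_matmul(h, p$W_lv_a), p$b_lv_a), limit)
  mu_d <- ad_addbias(ad_matmul(h, p$W_mu_d), p$b_mu_d)
  lv_d <- soft_clamp(ad_addbias(ad_matmul(h, p$W_lv_d), p$b_lv_d), limit)
  z_a <- ad_add(mu_a, ad_mul(ad_exp(ad_mul(lv_a, 0.5)), eps_a))
  z_d <- ad_add(mu_d, ad_mul(ad_exp(ad_mul(lv_d, 0.5)), eps_d))
  list(mu_a = mu_a, logvar_a = lv_a, mu_d = mu_d, logvar_d = lv_d,
       z_a = z_a, z_d = z_d, eps_a = eps_a, eps_d = eps_d)
}

#' Encode an image batch to dual-pathway posteriors
#'
#' Returns the Gaussian posterior parameters of both branches and the
#' reparameterized samples `z_k = mu_k + exp(logvar_k / 2) * eps_k`. With
#' `sample = FALSE` the draws are zero, so `z_k == mu_k` exactly.
#'
#' @param model a `neurofact_model`.
#' @param x numeric matrix `n x D` of flattened images.
#' @param sample draw reparameterization noise?
#' @param seed integer seed for the draws (required when `sample = TRUE`).
#' @return a `latent_code` list: mu/logvar/z/eps for both branches.
#' @export
encode <- function(model, x, sample = FALSE, seed = 1L) {
  x <- check_images(model, x)
  n <- nrow(x)
  cfg <- model$config
  if (sample) {
    eps <- with_seed(substream_seed(seed, "reparam"), {
      list(a = matrix(stats::rnorm(n * cfg$d_a), n, cfg$d_a),
           d = matrix(stats::rnorm(n * cfg$d_d), n, cfg$d_d))
    })
  } else {
    eps <- list(a = matrix(0, n, cfg$d_a), d = matrix(0, n, cfg$d_d))
  }
  out <- encode_forward(model$params, x, eps$a, eps$d)
  class(out) <- "latent_code"
  out
}

decode_forward <- function(p, z_a, z_d, hidden_dec) {
  zin <- ad_cbind(z_a, z_d)
  if (hidden_dec > 0L) {
    h <- ad_tanh(ad_addbias(ad_matmul(zin, p$dec_W1), p$dec_b1))
    ad_addbias(ad_matmul(h, p$dec_W2), p$dec_b2)
  } else {
    ad_addbias(ad_matmul(zin, p$dec_W), p$dec_b)
  }
}

#' Decode latent codes to images
#' @param model a `neurofact_model`.
#' @param z_a matrix `n x d_a`; @param z_d matrix `n x d_d`.
#' @return matrix `n x D` of reconstructed pixels.
#' @export
decode <- function(model, z_a, z_d) {
  cfg <- model$config
  abort_if(ncol(ad_value(z_a)) != cfg$d_a, "z_a must have %d columns", cfg$d_a)
  abort_if(ncol(ad_value(z_d)) != cfg$d_d, "z_d must have %d columns", cfg$d_d)
  decode_forward(model$params, z_a, z_d, cfg$hidden_dec)
}

#' Pathway-isolated decoding
#'
#' `anatomy` decodes `(z, 0)`, `disease` decodes `(0, z)`, where 0 is the zero
#' vector of the silenced branch.
#'
#' @param model a `neurofact_model`.
#' @param z latent matrix with the named pathway's dimension.
#' @param pathway `"anatomy"` or `"disease"`.
#' @return matrix `n x D`.
#' @export
decode_pathway <- function(model, z, pathway = c("anatomy", "disease")) {
  pathway <- tryCatch(match.arg(pathway),
                      error = function(e) stop("unknown pathway tag", call. = FALSE))
  cfg <- model$config
  n <- nrow(ad_value(z))
  if (pathway == "anatomy") {
    abort_if(ncol(ad_value(z)) != cfg$d_a, "anatomy pathway expects %d dims", cfg$d_a)
    decode(model, z, matrix(0, n, cfg$d_d))
  } else {
    abort_if(ncol(ad_value(z)) != cfg$d_d, "disease pathway expects %d dims", cfg$d_d)
    decode(model, matrix(0, n, cfg$d_a), z)
  }
}

#' Class probabilities from the disease code
#' @param model a `neurofact_model`.
#' @param z_d matrix `n x d_d`.
#' @return matrix `n x K` of softmax probabilities (rows sum to 1).
#' @export
classify <- function(model, z_d) {
  cfg <- model$config
  abort_if(ncol(ad_value(z_d)) != cfg$d_d, "z_d must have %d columns", cfg$d_d)
  logits <- ad_addbias(ad_matmul(z_d, model$params$W_cls), model$params$b_cls)
  ad_exp(ad_log_softmax(logits))
}

#' Age estimate from the anatomy code
#'
#' The linear head regresses age on a standardized scale; the model's stored
#' training-cohort location/scale map the head output back to years.
#'
#' @param model a `neurofact_model`.
#' @param z_a matrix `n x d_a`.
#' @return column matrix `n x 1` of predicted ages (years).
#' @export
predict_age <- function(model, z_a) {
  cfg <- model$config
  abort_if(ncol(ad_value(z_a)) != cfg$d_a, "z_a must have %d columns", cfg$d_a)
  raw <- ad_addbias(ad_matmul(z_a, model$params$W_age), model$params$b_age)
  ad_add(ad_mul(raw, model$age_scale %||% 1), model$age_loc %||% 0)
}

#' Counterfactual decoding by disease-code shift
#'
#' Decodes `g(z_a, z_d + delta)`; with `delta` the difference of class
#' centers, this synthesizes how a subject's scan would look under the target
#' class while preserving their anatomy code.
#'
#' @param model a `neurofact_model`.
#' @param z_a,z_d latent matrices.
#' @param delta length-`d_d` shift (or `n x d_d` matrix).
#' @return matrix `n x D`.
#' @export
counterfactual_decode <- function(model, z_a, z_d, delta) {
  cfg <- model$config
  zdv <- ad_value(z_d)
  if (!is.matrix(delta) || nrow(delta) == 1L) {
    delta <- matrix(as.numeric(delta), nrow(zdv), cfg$d_d, byrow = TRUE)
  }
  abort_if(ncol(delta) != cfg$d_d, "delta must have %d entries per row", cfg$d_d)
  decode(model, z_a, ad_add(z_d, delta))
}
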