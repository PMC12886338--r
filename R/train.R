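# Stratified batching, the Adam training loop over the autodiff tape, and
# checkpointing.

#' Optimizer configuration
#' @param epochs training epochs.
#' @param batch_size scans per batch (>= 8).
#' @param learning_rate Adam step size.
#' @param clip_norm global gradient-norm clip.
#' @return an `optim_config` list.
#' @export
optim_config <- function(epochs = 30L, batch_size = 64L,
                         learning_rate = 2e-3, clip_norm = 5) {
  cfg <- list(epochs = as.integer(epochs), batch_size = as.integer(batch_size),
              learning_rate = learning_rate, clip_norm = clip_norm)
  abort_if(cfg$epochs < 1L, "epochs must be >= 1")
  abort_if(cfg$batch_size < 8L, "batch_size must be >= 8")
  abort_if(cfg$learning_rate <= 0, "learning_rate must be > 0")
  class(cfg) <- "optim_config"
  cfg
}

#' Subject-level train/validation/test split
#'
#' 70/15/15 split at the subject level, stratified by diagnosis so every
#' partition keeps the class mix; all scans of a subject land in one
#' partition.
#'
#' @param ds a `phantom_dataset`.
#' @param seed integer seed.
#' @return list of integer row-index vectors `train`, `val`, `test`.
#' @export
split_subjects <- function(ds, seed = 1L) {
  meta <- ds$meta
  subj <- unique(meta[, c("subject_id", "diagnosis")])
  assign_split <- with_seed(substream_seed(seed, "split"), {
    out <- character(nrow(subj))
    for (k in unique(subj$diagnosis)) {
      ids <- sample(which(subj$diagnosis == k))
      n <- length(ids)
      n_tr <- round(0.70 * n); n_va <- round(0.15 * n)
      out[ids[seq_len(n_tr)]] <- "train"
      out[ids[n_tr + seq_len(min(n_va, n - n_tr))]] <- "val"
      out[ids[out[ids] == ""]] <- "test"
    }
    out
  })
  part <- stats::setNames(assign_split, subj$subject_id)
  list(train = which(part[as.character(meta$subject_id)] == "train"),
       val = which(part[as.character(meta$subject_id)] == "val"),
       test = which(part[as.character(meta$subject_id)] == "test"))
}

#' Stratified batch composition
#'
#' Partitions the scans of `rows` into batches of roughly `batch_size`,
#' keeping each subject's scans together (so within-subject visit pairs are
#' co-batched for the temporal term) and spreading every (class, site) cell
#' round-robin across batches so each batch sees at least two classes and two
#' strata whenever the data do.
#'
#' @param ds a `phantom_dataset`.
#' @param batch_size target scans per batch (>= 8).
#' @param seed integer seed; composition is deterministic per seed.
#' @param rows optional row subset (default: all scans).
#' @return list of integer row-index vectors partitioning `rows`.
#' @export
make_batches <- function(ds, batch_size, seed = 1L, rows = NULL) {
  abort_if(batch_size < 8L, "batch_size must be >= 8")
  meta <- ds$meta
  if (is.null(rows)) rows <- seq_len(nrow(meta))
  if (batch_size >= length(rows)) {
    warning("batch_size >= available scans; returning one full batch")
    return(list(rows))
  }
  sub <- meta[rows, , drop = FALSE]
  subj_tab <- unique(sub[, c("subject_id", "diagnosis", "site")])
  n_batches <- max(1L, round(length(rows) / batch_size))
  assign <- with_seed(substream_seed(seed, "batches"), {
    a <- integer(0); ids <- integer(0)
    offset <- 0L
    cells <- split(subj_tab$subject_id,
                   interaction(subj_tab$diagnosis, subj_tab$site, drop = TRUE))
    for (cell in cells) {
      cell <- sample(cell)
      a <- c(a, ((seq_along(cell) - 1L + offset) %% n_batches) + 1L)
      ids <- c(ids, cell)
      offset <- offset + length(cell)
    }
    stats::setNames(a, ids)
  })
  batches <- lapply(seq_len(n_batches), function(b) {
    rows[sub$subject_id %in% as.integer(names(assign)[assign == b])]
  })
  batches[lengths(batches) > 0L]
}

# pull batch columns from the dataset
batch_data <- function(ds, idx, x_all = NULL) {
  m <- ds$meta[idx, , drop = FALSE]
  x <- if (is.null(x_all)) dataset_matrix(ds)[idx, , drop = FALSE] else x_all[idx, , drop = FALSE]
  list(x = x, y = m$diagnosis, age = m$age, site = m$site,
       subject = m$subject_id, visit = m$visit_index)
}

grad_global_norm <- function(grads) sqrt(sum(vapply(grads, function(g) sum(g^2), numeric(1))))

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0), v = lapply(params, function(p) p * 0), t = 0L)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  for (nm in names(params)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    mhat <- state$m[[nm]] / (1 - beta1^state$t)
    vhat <- state$v[[nm]] / (1 - beta2^state$t)
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}

# Forward pass + every objective term on one batch. `p` holds nodes during
# training or plain matrices for (deterministic) evaluation of the objective.
cdaa_forward <- function(p, cfg, batch, weights, stats, seed, step,
                         sample = TRUE, age_loc = 0, age_scale = 1) {
  n <- nrow(batch$x)
  if (sample) {
    eps <- with_seed(substream_seed(seed, paste0("reparam.", step)), {
      list(a = matrix(stats::rnorm(n * cfg$d_a), n, cfg$d_a),
           d = matrix(stats::rnorm(n * cfg$d_d), n, cfg$d_d))
    })
  } else {
    eps <- list(a = matrix(0, n, cfg$d_a), d = matrix(0, n, cfg$d_d))
  }
  lat <- encode_forward(p, batch$x, eps$a, eps$d)
  x_hat <- decode_forward(p, lat$z_a, lat$z_d, cfg$hidden_dec)
  x_hat_a <- decode_forward(p, lat$z_a, matrix(0, n, cfg$d_d), cfg$hidden_dec)
  x_hat_d <- decode_forward(p, matrix(0, n, cfg$d_a), lat$z_d, cfg$hidden_dec)
  probs <- ad_exp(ad_log_softmax(ad_addbias(ad_matmul(lat$z_d, p$W_cls), p$b_cls)))
  age_pred <- ad_addbias(ad_matmul(lat$z_a, p$W_age), p$b_age)
  age_std <- (batch$age - age_loc) / age_scale

  recon <- loss_recon(batch$x, x_hat, weights$sigma2)
  kl <- loss_kl(lat)
  add <- loss_additive(x_hat, x_hat_a, x_hat_d)
  fid_a <- ad_mean(ad_rowsums({ d <- ad_sub(batch$x, x_hat_a); ad_mul(d, d) }))
  fid_d <- ad_mean(ad_rowsums({ d <- ad_sub(batch$x, x_hat_d); ad_mul(d, d) }))
  decorr <- loss_decorr(x_hat_a, x_hat_d)
  cls <- loss_cls(probs, batch$y)
  age <- loss_age(age_pred, age_std)
  smooth <- loss_smooth(lat$z_a, lat$z_d, batch$subject, batch$age)
  xcov <- if (n >= 2L) loss_cross_cov(lat$z_a, lat$z_d) else zero_like_scalar(lat$z_a)
  fisher <- loss_fisher_sep(lat$z_a, batch$y)
  fisher_s <- loss_fisher_sep(lat$z_d, batch$site)
  tcov <- loss_age_decouple(lat$z_d, batch$age)

  task <- ad_add(recon,
    ad_add(ad_mul(kl, weights$w_kl),
    ad_add(ad_mul(add, weights$w_add),
    ad_add(ad_mul(fid_a, weights$lambda_a),
    ad_add(ad_mul(fid_d, weights$lambda_d),
    ad_add(ad_mul(decorr, weights$w_decorr),
    ad_add(ad_mul(cls, weights$w_cls),
    ad_add(ad_mul(age, weights$w_age),
    ad_add(ad_mul(smooth, weights$w_smooth),
    ad_add(ad_mul(xcov, weights$w_xcov),
    ad_add(ad_mul(fisher, weights$w_fisher),
           ad_mul(tcov, weights$w_tcov))))))))))))

  # the Fisher subgroup-separability penalty is part of the stratified
  # alignment group: it shares the marginal-alignment weight lambda1, so the
  # lambda1 = 0 ablation removes the whole site-invariance pressure
  mmd <- ad_add(loss_mmd_strata(lat$z_d, batch$site),
                ad_mul(fisher_s, weights$w_fisher_strata))
  cond <- loss_cond_align(lat$z_d, batch$y, batch$site)
  supcon <- if (length(unique(batch$y)) >= 1L && n >= 2L)
    loss_supcon(lat$z_d, batch$y, weights$tau) else zero_like_scalar(lat$z_d)
  stab <- loss_stability(lat$z_d, weights$sigma_stab,
                         substream_seed(seed, paste0("stab.", step)))
  hard <- loss_hard_contrastive(lat$z_d, batch$y, weights$tau, weights$hard_k)
  center <- loss_center(lat$z_d, batch$y, stats)
  inv <- loss_invariance(stats)

  cf <- zero_like_scalar(lat$z_d)
  dis_classes <- setdiff(unique(batch$y), 0L)
  if (length(dis_classes) > 0L && any(batch$y == 0L) &&
      !anyNA(stats$centers[1L, ])) {
    tgt <- dis_classes[which.max(tabulate(match(batch$y, dis_classes)))]
    if (!anyNA(stats$centers[tgt + 1L, ])) {
      ctrl <- which(batch$y == 0L)
      delta <- stats$centers[tgt + 1L, ] - stats$centers[1L, ]
      z_a_c <- ad_rows(lat$z_a, ctrl)
      z_d_c <- ad_add(ad_rows(lat$z_d, ctrl),
                      matrix(delta, length(ctrl), cfg$d_d, byrow = TRUE))
      cf_img <- decode_forward(p, z_a_c, z_d_c, cfg$hidden_dec)
      cf <- loss_counterfactual(cf_img, batch$x[batch$y == tgt, , drop = FALSE])
    }
  }

  terms <- list(task = task, mmd = mmd, cond = cond, supcon = supcon,
                stability = stab, hard = hard, center = center,
                invariance = inv, counterfactual = cf)
  if (cfg$domain_confusion) {
    zr <- ad_grad_reverse(lat$z_d, weights$reversal_strength)
    logits <- ad_addbias(ad_matmul(zr, p$W_dom), p$b_dom)
    picked <- ad_gather(ad_log_softmax(logits), cbind(seq_len(n), batch$site + 1L))
    terms$domain <- ad_neg(ad_mean(picked))
  }
  if (cfg$class_adversary) {
    zr_a <- ad_grad_reverse(lat$z_a, weights$reversal_strength)
    logits_a <- ad_addbias(ad_matmul(zr_a, p$W_adv), p$b_adv)
    picked_a <- ad_gather(ad_log_softmax(logits_a), cbind(seq_len(n), batch$y + 1L))
    terms$domain_a <- ad_mul(ad_neg(ad_mean(picked_a)), weights$w_adv)
  }
  total <- total_cdaa(terms, weights)
  logged <- c(lapply(terms, function(t) ad_value(t)[1L]),
              list(recon = ad_value(recon)[1L], kl = ad_value(kl)[1L],
                   additive = ad_value(add)[1L], decorr = ad_value(decorr)[1L],
                   cls = ad_value(cls)[1L], age = ad_value(age)[1L],
                   smooth = ad_value(smooth)[1L], xcov = ad_value(xcov)[1L],
                   fisher = ad_value(fisher)[1L],
                   fisher_strata = ad_value(fisher_s)[1L],
                   tcov = ad_value(tcov)[1L],
                   total = ad_value(total)[1L]))
  list(total = total, latent = lat, logged = logged)
}

#' Train the dual-pathway model with the alignment objective
#'
#' Runs the full training protocol: subject-level 70/15/15 split, stratified
#' batches, reparameterized forward passes, the complete composite objective,
#' Adam with global-norm clipping, EMA center and Gaussian statistics updates
#' after every step, per-step logging of every term, and selection of the
#' checkpoint with the best deterministic validation total.
#'
#' @param ds a `phantom_dataset`.
#' @param model_cfg a [model_config()] (image size and class count must match
#'   the dataset).
#' @param weights a [loss_weights()].
#' @param optim an [optim_config()].
#' @param seed integer seed governing split, init, batching, and all draws.
#' @return a `neurofact_checkpoint`: list with `model` (best weights),
#'   `weights`, `stats`, `optim`, `seed`, `split`, `history` (long-format
#'   data.frame: step, epoch, term, value), and `best` (epoch, val_total).
#' @export
train <- function(ds, model_cfg = model_config(), weights = loss_weights(),
                  optim = optim_config(), seed = 1L) {
  stopifnot(inherits(ds, "phantom_dataset"), inherits(model_cfg, "model_config"),
            inherits(weights, "loss_weights"), inherits(optim, "optim_config"))
  abort_if(model_cfg$image_size != ds$config$image_size,
           "model image_size %d != dataset image_size %d",
           model_cfg$image_size, ds$config$image_size)
  split <- split_subjects(ds, seed)
  x_all <- dataset_matrix(ds)
  model <- init_model(model_cfg, seed)
  age_loc <- mean(ds$meta$age[split$train])
  age_scale <- stats::sd(ds$meta$age[split$train])
  if (!is.finite(age_scale) || age_scale == 0) age_scale <- 1
  stats_run <- class_stats(model_cfg$d_d, model_cfg$n_classes, model_cfg$n_strata,
                           weights$ema_decay, weights$shrink_alpha)
  params <- model$params
  opt_state <- adam_init(params)
  history <- list()
  step <- 0L
  best <- list(val_total = Inf, params = params, stats = stats_run, epoch = 0L)
  val_batch <- batch_data(ds, split$val, x_all)

  for (epoch in seq_len(optim$epochs)) {
    batches <- make_batches(ds, optim$batch_size,
                            seed = substream_seed(seed, paste0("epoch.", epoch)),
                            rows = split$train)
    for (idx in batches) {
      step <- step + 1L
      batch <- batch_data(ds, idx, x_all)
      nodes <- lapply(params, ad_param)
      out <- suppressMessages(
        cdaa_forward(nodes, model_cfg, batch, weights, stats_run, seed, step,
                     sample = TRUE, age_loc = age_loc, age_scale = age_scale))
      bad <- vapply(out$logged, function(v) !is.finite(v), logical(1))
      abort_if(any(bad), "non-finite loss term '%s' at step %d",
               names(out$logged)[bad][1L], step)
      ad_backward(out$total)
      grads <- lapply(nodes, ad_grad)
      gn <- grad_global_norm(grads)
      if (gn > optim$clip_norm) grads <- lapply(grads, function(g) g * optim$clip_norm / gn)
      upd <- adam_step(params, grads, opt_state, optim$learning_rate)
      params <- upd$params; opt_state <- upd$state
      zd_val <- ad_value(out$latent$z_d)
      stats_run <- update_centers(zd_val, batch$y, stats_run)
      stats_run <- update_gaussian_stats(zd_val, batch$y, batch$site, stats_run)
      history[[length(history) + 1L]] <- data.frame(
        step = step, epoch = epoch, term = names(out$logged),
        value = unlist(out$logged), row.names = NULL)
    }
    # deterministic validation total for model selection
    val <- suppressMessages(
      cdaa_forward(params, model_cfg, val_batch, weights, stats_run, seed,
                   step = -epoch, sample = FALSE,
                   age_loc = age_loc, age_scale = age_scale))
    history[[length(history) + 1L]] <- data.frame(
      step = step, epoch = epoch, term = "val_total",
      value = val$logged$total, row.names = NULL)
    if (val$logged$total < best$val_total) {
      best <- list(val_total = val$logged$total, params = params,
                   stats = stats_run, epoch = epoch)
    }
  }
  model$params <- best$params
  model$age_loc <- age_loc
  model$age_scale <- age_scale
  ckpt <- list(model = model, weights = weights, stats = best$stats,
               optim = optim, seed = seed, split = split,
               history = do.call(rbind, history),
               best = list(epoch = best$epoch, val_total = best$val_total))
  class(ckpt) <- "neurofact_checkpoint"
  ckpt
}

.ckpt_members <- c("model", "weights", "stats", "optim", "seed", "split", "history")

#' Save / load a training checkpoint
#' @param ckpt a `neurofact_checkpoint`.
#' @param path file path.
#' @return `path` (save) or the checkpoint (load).
#' @export
save_checkpoint <- function(ckpt, path) {
  stopifnot(inherits(ckpt, "neurofact_checkpoint"))
  saveRDS(unclass(ckpt), path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  abort_if(!file.exists(path), "no checkpoint at '%s'", path)
  payload <- readRDS(path)
  for (m in .ckpt_members) {
    abort_if(is.null(payload[[m]]), "checkpoint is missing member '%s'", m)
  }
  class(payload) <- "neurofact_checkpoint"
  payload
}
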