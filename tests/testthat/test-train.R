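# Batching, the training loop, the evaluation harness, and checkpoint I/O.

test_that("batches partition the data, are deterministic, and cover cells", {
  ds <- sample_cohort(phantom_config(n_subjects = 64, n_classes = 2,
                                     visits_per_subject = c(1, 2), seed = 51))
  b1 <- make_batches(ds, 16, seed = 3)
  b2 <- make_batches(ds, 16, seed = 3)
  expect_identical(b1, b2)
  all_rows <- sort(unlist(b1))
  expect_identical(all_rows, seq_len(nrow(ds$meta)))      # no duplicates, no gaps
  # each batch carries every (class, site) cell of a balanced 2x2 cohort
  for (b in b1) {
    cells <- unique(paste(ds$meta$diagnosis[b], ds$meta$site[b]))
    expect_equal(length(cells), 4L)
  }
  # a subject's scans stay together
  for (b in b1) {
    subj <- ds$meta$subject_id[b]
    for (s in unique(subj)) {
      expect_equal(sum(ds$meta$subject_id == s), sum(subj == s))
    }
  }
  expect_warning(one <- make_batches(ds, 10000, seed = 1), "one full batch")
  expect_equal(one[[1]], seq_len(nrow(ds$meta)))
  expect_error(make_batches(ds, 4, seed = 1), "batch_size")
})

test_that("training is seeded, reducible, and logs every term", {
  ds <- tiny_cohort(n_subjects = 40, seed = 52)
  oc <- optim_config(epochs = 2, batch_size = 16)
  t0 <- Sys.time()
  ck1 <- train(ds, model_config(d_a = 4, d_d = 4), loss_weights(), oc, seed = 9)
  elapsed <- as.numeric(Sys.time() - t0, units = "secs")
  expect_lt(elapsed, 60) # smoke benchmark at small scale
  ck2 <- train(ds, model_config(d_a = 4, d_d = 4), loss_weights(), oc, seed = 9)
  expect_identical(ck1$history, ck2$history) # bit-identical trajectories
  expect_false(identical(
    ck1$history,
    train(ds, model_config(d_a = 4, d_d = 4), loss_weights(), oc, seed = 10)$history))
  expect_true(all(c("task", "mmd", "cond", "supcon", "stability", "hard", "center",
                    "invariance", "counterfactual", "recon", "kl", "cls", "age",
                    "total", "val_total") %in% ck1$history$term))
  # with every auxiliary weight zeroed, the total equals the bare
  # reconstruction term throughout
  w0 <- loss_weights(w_kl = 0, w_add = 0, lambda_a = 0, lambda_d = 0,
                     w_decorr = 0, w_cls = 0, w_age = 0, w_smooth = 0,
                     w_xcov = 0, w_fisher = 0, w_fisher_strata = 0, w_tcov = 0,
                     lambda1 = 0, lambda2 = 0, lambda3 = 0, lambda4 = 0,
                     lambda5 = 0, sigma_stab = 0)
  ck0 <- train(ds, model_config(d_a = 4, d_d = 4), w0, oc, seed = 9)
  h <- ck0$history
  tot <- h$value[h$term == "total"]
  rec <- h$value[h$term == "recon"]
  expect_equal(tot, rec, tolerance = 1e-12)
})

test_that("the split is subject-level 70/15/15 and disjoint", {
  ds <- tiny_cohort(n_subjects = 100, seed = 53)
  sp <- split_subjects(ds, seed = 2)
  subj_of <- function(rows) unique(ds$meta$subject_id[rows])
  expect_length(intersect(subj_of(sp$train), subj_of(sp$test)), 0)
  expect_length(intersect(subj_of(sp$train), subj_of(sp$val)), 0)
  expect_equal(sort(unname(unlist(sp))), seq_len(nrow(ds$meta)))
  expect_equal(length(subj_of(sp$train)), 70, tolerance = 0.05)
})

test_that("evaluation reports chance-level metrics for an untrained model", {
  ds <- sample_cohort(phantom_config(n_subjects = 80, n_classes = 2, seed = 54))
  ck <- train(ds, model_config(d_a = 4, d_d = 4, n_classes = 2),
              loss_weights(), optim_config(epochs = 1, batch_size = 64), seed = 7)
  # overwrite with freshly initialized (untrained) weights
  ck$model$params <- init_model(model_config(d_a = 4, d_d = 4, n_classes = 2),
                                seed = 99)$params
  r <- evaluate(ck, ds, "test")
  expect_lt(abs(r$class_accuracy - 0.5), 0.25)
  expect_true(r$auc >= 0 && r$auc <= 1)
})

test_that("oracle latents hit the ceiling", {
  # inject the true generative factors as the latent code of a linear model:
  # recovery metrics must saturate
  ds <- tiny_cohort(n_subjects = 60, seed = 55)
  z_a <- cbind(ds$truth$age_score, ds$meta$site)
  z_d <- cbind(ds$truth$disease_severity * (ds$meta$diagnosis == 1),
               ds$truth$disease_severity * (ds$meta$diagnosis == 2))
  # age probe on oracle anatomy code; the GP residual inside the age score
  # bounds the attainable correlation near sqrt(1 / (1 + gp_variance))
  fit <- lm(ds$meta$age ~ z_a)
  expect_gt(cor(fitted(fit), ds$meta$age), 0.9)
  # class readout from oracle disease code
  pred <- apply(z_d, 1, function(r) if (all(r == 0)) 0 else which.max(r))
  expect_equal(mean(pred == ds$meta$diagnosis), 1)
})

test_that("reports and checkpoints round-trip through disk", {
  ds <- tiny_cohort(n_subjects = 30, seed = 56)
  ck <- train(ds, model_config(d_a = 4, d_d = 4),
              loss_weights(), optim_config(epochs = 1, batch_size = 16), seed = 4)
  r <- evaluate(ck, ds, "test")
  path <- tempfile(fileext = ".json")
  write_report(r, path)
  back <- read_report(path)
  for (nm in names(unclass(r))) {
    if (is.na(r[[nm]])) expect_true(is.na(back[[nm]]))
    else expect_equal(back[[nm]], as.numeric(r[[nm]]), tolerance = 1e-12)
  }
  cpath <- tempfile(fileext = ".rds")
  save_checkpoint(ck, cpath)
  ck_back <- load_checkpoint(cpath)
  expect_identical(ck_back$model$params, ck$model$params)
  payload <- readRDS(cpath); payload$stats <- NULL; saveRDS(payload, cpath)
  expect_error(load_checkpoint(cpath), "member 'stats'")
})

test_that("counterfactual evaluation has sane baselines and linear geometry", {
  ds <- tiny_cohort(n_subjects = 60, seed = 57)
  ck <- train(ds, model_config(d_a = 4, d_d = 4),
              loss_weights(), optim_config(epochs = 2, batch_size = 32), seed = 8)
  rows <- ck$split$test
  # a null intervention scores whatever plain reconstructions score
  ck0 <- ck
  ck0$stats$centers[2, ] <- ck0$stats$centers[1, ] # delta forced to zero
  null_rate <- run_counterfactual_eval(ck0, ds, rows, 0, 1)
  x <- dataset_matrix(ds)[rows, ]
  y <- ds$meta$diagnosis[rows]
  lat <- encode(ck$model, x, sample = FALSE)
  rec <- decode(ck$model, lat$mu_a, lat$mu_d)[y == 0, , drop = FALSE]
  m0 <- colMeans(x[y == 0, , drop = FALSE]); m1 <- colMeans(x[y == 1, , drop = FALSE])
  base_rate <- mean(rowSums(sweep(rec, 2, m1)^2) < rowSums(sweep(rec, 2, m0)^2))
  expect_equal(null_rate, base_rate)
  expect_error(run_counterfactual_eval(ck, ds, rows[y == 0], 0, 1), "target class")
  # analytic geometry: with a linear decoder whose disease block reproduces
  # the class-mean image difference, every shifted control lands nearer the
  # target mean
  side <- ds$config$image_size
  m <- linear_zero_bias_model(d_a = 2, d_d = 2, image_size = side)
  m$params$dec_W[] <- 0
  m$params$dec_W[3, ] <- m1 - m0 # disease dim 1 renders the mean shift
  m$params$dec_b[] <- m0         # baseline decodes to the control mean
  ckl <- ck; ckl$model <- m
  ckl$stats$centers <- matrix(0, 3, 2)
  ckl$stats$centers[2, ] <- c(1, 0)
  # encode is irrelevant here: force mu to zero by zeroing encoder weights
  for (nm in grep("^(enc|W_mu|b_mu|W_lv|b_lv)", names(m$params), value = TRUE))
    ckl$model$params[[nm]][] <- 0
  rate <- run_counterfactual_eval(ckl, ds, rows, 0, 1)
  expect_equal(rate, 1)
})

test_that("temporal regularization shrinks adjacent-visit displacement", {
  ds <- sample_cohort(phantom_config(n_subjects = 80, visits_per_subject = c(2, 3), seed = 58))
  oc <- optim_config(epochs = 6, batch_size = 32)
  r_on <- evaluate(train(ds, model_config(d_a = 4, d_d = 4),
                         loss_weights(w_smooth = 1), oc, seed = 3), ds, "test")
  r_off <- evaluate(train(ds, model_config(d_a = 4, d_d = 4),
                          loss_weights(w_smooth = 0), oc, seed = 3), ds, "test")
  expect_lte(r_on$mean_adjacent_displacement, r_off$mean_adjacent_displacement * 1.1)
})
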