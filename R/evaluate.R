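# Evaluation harness: factor recovery, leakage probes, site invariance,
# trajectory smoothness, and counterfactual quality. Probes are deliberately
# linear (ridge / LDA) so they measure information content of the frozen
# latents rather than adding capacity; they are fit on one half of the
# evaluation split's subjects and scored on the other half.

ridge_fit <- function(X, y, lambda = 1) {
  Xc <- scale(X); yc <- y - mean(y)
  Xc[!is.finite(Xc)] <- 0
  beta <- solve(crossprod(Xc) + lambda * diag(ncol(Xc)), crossprod(Xc, yc))
  list(beta = beta, center = attr(Xc, "scaled:center"),
       scl = attr(Xc, "scaled:scale"), y_mean = mean(y))
}

ridge_predict <- function(fit, X) {
  Xc <- sweep(sweep(X, 2L, fit$center), 2L, ifelse(fit$scl == 0, 1, fit$scl), "/")
  drop(Xc %*% fit$beta) + fit$y_mean
}

balanced_accuracy <- function(truth, pred) {
  classes <- unique(truth)
  mean(vapply(classes, function(k) mean(pred[truth == k] == k), numeric(1)))
}

# linear class probe: LDA when feasible, majority vote otherwise
lda_probe <- function(X_tr, y_tr, X_te, y_te) {
  if (length(unique(y_tr)) < 2L) return(NA_real_)
  fit <- tryCatch(suppressWarnings(MASS::lda(X_tr, grouping = factor(y_tr))),
                  error = function(e) NULL)
  if (is.null(fit)) return(NA_real_)
  pred <- as.character(stats::predict(fit, X_te)$class)
  balanced_accuracy(as.character(y_te), pred)
}

split_half_subjects <- function(subjects, seed) {
  ids <- sort(unique(subjects))
  half <- with_seed(substream_seed(seed, "probe_half"),
                    sample(ids, floor(length(ids) / 2)))
  list(a = subjects %in% half, b = !(subjects %in% half))
}

f1_score <- function(tp, fp, fn) {
  if (2 * tp + fp + fn == 0) return(NA_real_)
  2 * tp / (2 * tp + fp + fn)
}

#' Counterfactual evaluation by class-mean proximity
#'
#' For every source-class scan in the split, shifts its disease code by the
#' difference of EMA class centers (target minus source), decodes, and marks
#' success when the synthesized image is closer (squared pixel distance) to
#' the target-class mean image than to the source-class mean image.
#'
#' @param ckpt a `neurofact_checkpoint`.
#' @param ds the `phantom_dataset`.
#' @param rows row indices of the evaluation split.
#' @param source_class,target_class class labels (0-based).
#' @return success fraction in `[0, 1]`.
#' @export
run_counterfactual_eval <- function(ckpt, ds, rows, source_class = 0L, target_class = 1L) {
  model <- ckpt$model
  x <- dataset_matrix(ds)[rows, , drop = FALSE]
  y <- ds$meta$diagnosis[rows]
  abort_if(!any(y == source_class), "source class %d absent from split", source_class)
  abort_if(!any(y == target_class), "target class %d absent from split", target_class)
  centers <- ckpt$stats$centers
  abort_if(anyNA(centers[source_class + 1L, ]) || anyNA(centers[target_class + 1L, ]),
           "class centers unavailable for the requested classes")
  lat <- encode(model, x, sample = FALSE)
  src <- which(y == source_class)
  delta <- centers[target_class + 1L, ] - centers[source_class + 1L, ]
  cf <- counterfactual_decode(model, lat$mu_a[src, , drop = FALSE],
                              lat$mu_d[src, , drop = FALSE], delta)
  mean_src <- colMeans(x[y == source_class, , drop = FALSE])
  mean_tgt <- colMeans(x[y == target_class, , drop = FALSE])
  d_src <- rowSums(sweep(cf, 2L, mean_src)^2)
  d_tgt <- rowSums(sweep(cf, 2L, mean_tgt)^2)
  mean(d_tgt < d_src)
}

#' Evaluate a checkpoint on a dataset split
#'
#' Encodes the split with posterior means and reports factor recovery
#' (age Pearson r from z_a, classification metrics from z_d), leakage probes
#' (ridge age-from-z_d, LDA class-from-z_a), stratum invariance (between-site
#' squared MMD of z_d and an LDA stratum probe), counterfactual success, and
#' the mean adjacent-visit latent displacement. Classification metrics are
#' `NA` when the split carries a single class.
#'
#' @param ckpt a `neurofact_checkpoint`.
#' @param ds the `phantom_dataset` the checkpoint was trained on.
#' @param split one of `"test"`, `"val"`, `"train"`, or a vector of row
#'   indices disjoint from the training subjects.
#' @param seed seed for the probe half-split.
#' @return an `eval_report` (named list of scalars).
#' @export
evaluate <- function(ckpt, ds, split = "test", seed = 1L) {
  stopifnot(inherits(ckpt, "neurofact_checkpoint"))
  rows <- if (is.character(split)) ckpt$split[[match.arg(split, c("test", "val", "train"))]] else as.integer(split)
  model <- ckpt$model
  x <- dataset_matrix(ds)[rows, , drop = FALSE]
  meta <- ds$meta[rows, , drop = FALSE]
  lat <- encode(model, x, sample = FALSE)
  z_a <- lat$mu_a; z_d <- lat$mu_d

  age_pred <- as.vector(predict_age(model, z_a))
  age_r <- suppressWarnings(stats::cor(age_pred, meta$age))

  multi_class <- length(unique(meta$diagnosis)) > 1L
  probs <- classify(model, z_d)
  pred <- max.col(probs, ties.method = "first") - 1L
  if (multi_class) {
    acc <- mean(pred == meta$diagnosis)
    aucs <- vapply(sort(unique(meta$diagnosis)), function(k) {
      auc_rank(probs[, k + 1L], meta$diagnosis == k)
    }, numeric(1))
    auc <- mean(aucs, na.rm = TRUE)
    pos_true <- meta$diagnosis > 0L; pos_pred <- pred > 0L
    tp <- sum(pos_true & pos_pred); fp <- sum(!pos_true & pos_pred)
    fn <- sum(pos_true & !pos_pred); tn <- sum(!pos_true & !pos_pred)
    sens <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
    spec <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
    f1 <- f1_score(tp, fp, fn)
  } else {
    acc <- auc <- sens <- spec <- f1 <- NA_real_
  }

  halves <- split_half_subjects(meta$subject_id, seed)
  leak_age <- NA_real_
  leak_cls <- NA_real_
  strat_acc <- NA_real_
  if (sum(halves$a) >= 4L && sum(halves$b) >= 4L) {
    fit <- ridge_fit(z_d[halves$a, , drop = FALSE], meta$age[halves$a])
    leak_age <- suppressWarnings(
      stats::cor(ridge_predict(fit, z_d[halves$b, , drop = FALSE]), meta$age[halves$b]))
    if (multi_class) {
      leak_cls <- lda_probe(z_a[halves$a, , drop = FALSE], meta$diagnosis[halves$a],
                            z_a[halves$b, , drop = FALSE], meta$diagnosis[halves$b])
    }
    if (length(unique(meta$site)) > 1L) {
      strat_acc <- lda_probe(z_d[halves$a, , drop = FALSE], meta$site[halves$a],
                             z_d[halves$b, , drop = FALSE], meta$site[halves$b])
    }
  }

  site_mmd <- NA_real_
  sites <- sort(unique(meta$site))
  if (length(sites) >= 2L) {
    s1 <- z_d[meta$site == sites[1L], , drop = FALSE]
    s2 <- z_d[meta$site == sites[2L], , drop = FALSE]
    if (nrow(s1) >= 2L && nrow(s2) >= 2L) {
      site_mmd <- ad_value(mmd2(s1, s2, median_bandwidth(z_d)))[1L]
    }
  }

  cf_rate <- NA_real_
  dis <- setdiff(sort(unique(meta$diagnosis)), 0L)
  if (length(dis) > 0L && any(meta$diagnosis == 0L) && !anyNA(ckpt$stats$centers[1L, ])) {
    tgt <- dis[which.max(tabulate(match(meta$diagnosis, dis)))]
    if (!anyNA(ckpt$stats$centers[tgt + 1L, ])) {
      cf_rate <- run_counterfactual_eval(ckpt, ds, rows, 0L, tgt)
    }
  }

  pairs <- subject_pairs(meta$subject_id, meta$age, adjacent = TRUE)
  disp <- if (nrow(pairs) > 0L) {
    dz <- cbind(z_a, z_d)[pairs[, 2L], , drop = FALSE] -
      cbind(z_a, z_d)[pairs[, 1L], , drop = FALSE]
    mean(sqrt(rowSums(dz^2)))
  } else NA_real_

  report <- list(age_pearson_r = age_r, class_accuracy = acc, auc = auc,
                 f1 = f1, sensitivity = sens, specificity = spec,
                 leakage_age_from_zd = leak_age, leakage_class_from_za = leak_cls,
                 site_mmd2 = site_mmd, stratum_probe_accuracy = strat_acc,
                 counterfactual_success_rate = cf_rate,
                 mean_adjacent_displacement = disp,
                 n_scans = length(rows))
  class(report) <- "eval_report"
  report
}

#' Write / read an evaluation report as JSON
#' @param report an `eval_report`.
#' @param path JSON file path.
#' @return `path` (write) or the report (read).
#' @export
write_report <- function(report, path) {
  stopifnot(inherits(report, "eval_report"))
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA,
                       na = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname write_report
#' @export
read_report <- function(path) {
  abort_if(!file.exists(path), "no report at '%s'", path)
  raw <- jsonlite::read_json(path)
  report <- lapply(raw, function(v) if (is.null(v)) NA_real_ else as.numeric(v))
  class(report) <- "eval_report"
  report
}
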