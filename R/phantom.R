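# Longitudinal phantom simulator.
#
# Each scan is an additive composition of fixed spatial patterns:
#   x = template + age_score * A + disease_severity * D_y + S_site + noise,
# with per-subject age scores and disease severities following smooth
# Gaussian-process trajectories over visit times. Because the generative
# factors are known exactly, factor recovery, leakage, site invariance and
# counterfactual quality can all be scored against ground truth.

#' Phantom cohort configuration
#'
#' Defines the study conditions for a synthetic longitudinal cohort. Defaults
#' are the standard phantom used throughout the package: 300 subjects, three
#' diagnostic classes (one control, two disease), two imaging sites, 16x16
#' images, one to four visits per subject.
#'
#' @param n_subjects number of subjects.
#' @param image_size pixels per side (square images), at least 8.
#' @param n_classes number of diagnosis classes K >= 2; class 0 is control.
#' @param n_strata number of imaging sites (>= 2).
#' @param visits_per_subject integer range `c(min, max)` of visits.
#' @param age_range baseline age range in years, `c(lo, hi)`.
#' @param gp_lengthscale squared-exponential kernel lengthscale in years for
#'   the latent trajectories.
#' @param gp_variance marginal variance of the trajectory process.
#' @param disease_effect_size amplitude (image-intensity units) of the
#'   class-specific disease patterns.
#' @param site_effect_size amplitude of the per-site patterns.
#' @param noise_sd i.i.d. Gaussian pixel noise SD.
#' @param age_disease_confound correlation in `[0, 1)` between the latent
#'   drivers of baseline age and diagnosis (Gaussian copula).
#' @param include_sex add a second, independent stratum axis (sex)?
#' @param seed integer seed; the cohort is a deterministic function of the
#'   full configuration including this seed.
#' @return a `phantom_config` list.
#' @export
phantom_config <- function(n_subjects = 300L,
                           image_size = 16L,
                           n_classes = 3L,
                           n_strata = 2L,
                           visits_per_subject = c(1L, 4L),
                           age_range = c(55, 85),
                           gp_lengthscale = 8,
                           gp_variance = 0.1,
                           disease_effect_size = 1.5,
                           site_effect_size = 0.8,
                           noise_sd = 0.1,
                           age_disease_confound = 0.3,
                           include_sex = FALSE,
                           seed = 1L) {
  cfg <- list(n_subjects = as.integer(n_subjects), image_size = as.integer(image_size),
              n_classes = as.integer(n_classes), n_strata = as.integer(n_strata),
              visits_per_subject = as.integer(visits_per_subject),
              age_range = as.numeric(age_range),
              gp_lengthscale = as.numeric(gp_lengthscale),
              gp_variance = as.numeric(gp_variance),
              disease_effect_size = as.numeric(disease_effect_size),
              site_effect_size = as.numeric(site_effect_size),
              noise_sd = as.numeric(noise_sd),
              age_disease_confound = as.numeric(age_disease_confound),
              include_sex = isTRUE(include_sex),
              seed = as.integer(seed))
  validate_phantom_config(cfg)
  class(cfg) <- "phantom_config"
  cfg
}

validate_phantom_config <- function(cfg) {
  abort_if(cfg$n_classes < 2L, "n_classes must be >= 2, got %d", cfg$n_classes)
  abort_if(cfg$image_size < 8L, "image_size must be >= 8, got %d", cfg$image_size)
  abort_if(cfg$n_strata < 2L, "n_strata must be >= 2, got %d", cfg$n_strata)
  abort_if(cfg$noise_sd < 0, "noise_sd must be >= 0")
  abort_if(cfg$age_disease_confound < 0 || cfg$age_disease_confound >= 1,
           "age_disease_confound must be in [0, 1)")
  abort_if(length(cfg$visits_per_subject) != 2L ||
             cfg$visits_per_subject[1L] > cfg$visits_per_subject[2L] ||
             cfg$visits_per_subject[1L] < 1L,
           "visits_per_subject must be a non-empty integer range c(min, max) with min >= 1")
  abort_if(cfg$n_subjects < 1L, "n_subjects must be >= 1")
  abort_if(diff(cfg$age_range) <= 0, "age_range must satisfy lo < hi")
  abort_if(cfg$gp_lengthscale <= 0, "gp_lengthscale must be > 0")
  abort_if(cfg$gp_variance < 0, "gp_variance must be >= 0")
  invisible(cfg)
}

#' Draw one Gaussian-process trajectory
#'
#' One draw from a zero-mean Gaussian process with squared-exponential kernel
#' `k(t, t') = variance * exp(-(t - t')^2 / (2 * lengthscale^2))` evaluated at
#' the given times.
#'
#' @param times sorted (strictly non-decreasing is not enough for distinct
#'   draws but is accepted) numeric vector of times in years.
#' @param lengthscale kernel lengthscale (> 0), years.
#' @param variance marginal variance (>= 0).
#' @param seed integer seed; the draw is deterministic given it.
#' @return numeric vector of the same length as `times`.
#' @export
sample_gp_trajectory <- function(times, lengthscale, variance, seed) {
  abort_if(any(!is.finite(times)), "times must be finite")
  abort_if(is.unsorted(times), "times must be sorted ascending")
  abort_if(lengthscale <= 0, "lengthscale must be > 0")
  abort_if(variance < 0, "variance must be >= 0")
  n <- length(times)
  if (n == 0L) return(numeric(0))
  if (variance == 0) return(rep(0, n))
  d2 <- outer(times, times, function(a, b) (a - b)^2)
  K <- variance * exp(-d2 / (2 * lengthscale^2)) + diag(1e-10 * variance, n)
  L <- t(chol(K))
  with_seed(seed, as.vector(L %*% stats::rnorm(n)))
}

#' Render one phantom scan
#'
#' `image = template + age_score * age_pattern + disease_severity *
#' disease_pattern + site_indicator * site_pattern + noise`, with i.i.d.
#' Gaussian pixel noise.
#'
#' @param template,age_pattern,disease_pattern,site_pattern numeric matrices
#'   of identical shape.
#' @param age_score,disease_severity,site_indicator scalar factor loadings.
#' @param noise_sd pixel noise SD (>= 0).
#' @param seed integer seed for the noise draw.
#' @return a numeric matrix of the template's shape.
#' @export
render_scan <- function(template, age_pattern, disease_pattern, site_pattern,
                        age_score, disease_severity, site_indicator,
                        noise_sd, seed) {
  dims <- dim(template)
  for (p in list(age_pattern, disease_pattern, site_pattern)) {
    abort_if(!identical(dim(p), dims), "all patterns must share the template's shape")
  }
  abort_if(noise_sd < 0, "noise_sd must be >= 0")
  img <- template + age_score * age_pattern + disease_severity * disease_pattern +
    site_indicator * site_pattern
  if (noise_sd > 0) {
    img <- img + with_seed(seed, matrix(stats::rnorm(length(img), sd = noise_sd),
                                        dims[1L], dims[2L]))
  }
  img
}

# Smooth random pattern: a few signed Gaussian bumps, unit Frobenius norm.
make_blob_pattern <- function(size, n_blobs = 3L) {
  g <- seq(0, 1, length.out = size)
  img <- matrix(0, size, size)
  for (b in seq_len(n_blobs)) {
    cx <- stats::runif(1); cy <- stats::runif(1)
    w <- stats::runif(1, 0.08, 0.25)
    amp <- sample(c(-1, 1), 1L) * stats::runif(1, 0.5, 1)
    img <- img + amp * outer(g, g, function(x, y) exp(-((x - cx)^2 + (y - cy)^2) / (2 * w^2)))
  }
  img / sqrt(sum(img^2))
}

flat_cor <- function(a, b) stats::cor(as.vector(a), as.vector(b))

# Fixed spatial patterns. Disease patterns are redrawn until their spatial
# correlation with the age pattern (and with each other) is below 0.3, so
# that the age/disease factorization is identifiable.
make_patterns <- function(cfg, seed) {
  with_seed(seed, {
    template <- 2 * make_blob_pattern(cfg$image_size, 5L) +
      matrix(0.5, cfg$image_size, cfg$image_size)
    age_pattern <- make_blob_pattern(cfg$image_size, 3L)
    disease <- list()
    for (k in seq_len(cfg$n_classes - 1L)) {
      repeat {
        cand <- make_blob_pattern(cfg$image_size, 3L)
        ok <- abs(flat_cor(cand, age_pattern)) < 0.3
        if (ok && length(disease) > 0L) {
          ok <- all(vapply(disease, function(d) abs(flat_cor(cand, d)) < 0.3, logical(1)))
        }
        if (ok) break
      }
      disease[[k]] <- cfg$disease_effect_size * cand
    }
    sites <- lapply(seq_len(cfg$n_strata), function(s) {
      cfg$site_effect_size * make_blob_pattern(cfg$image_size, 3L)
    })
    list(template = template, age_pattern = age_pattern,
         disease_patterns = disease, site_patterns = sites)
  })
}

#' Sample a full phantom cohort
#'
#' Subjects are assigned a diagnosis and site; diagnosis is confounded with
#' baseline age through a Gaussian copula with correlation
#' `age_disease_confound`. Each subject receives 1..max visits at roughly
#' yearly spacing; the age score is standardized age plus a GP residual, and
#' disease severity is exactly 0 for controls and a positive, non-decreasing
#' softplus-GP trajectory for disease classes.
#'
#' @param cfg a [phantom_config()].
#' @return a `phantom_dataset`: list with `images` (array
#'   `n_scans x H x W`), `meta` (data.frame: subject_id, visit_index, age,
#'   diagnosis, site, and optionally sex), `truth` (per-scan age_score and
#'   disease_severity plus the fixed patterns) and `config`.
#' @export
sample_cohort <- function(cfg) {
  validate_phantom_config(cfg)
  pat <- make_patterns(cfg, substream_seed(cfg$seed, "patterns"))
  rho <- cfg$age_disease_confound
  lo <- cfg$age_range[1L]; hi <- cfg$age_range[2L]
  K <- cfg$n_classes

  subj <- with_seed(substream_seed(cfg$seed, "subjects"), {
    u1 <- stats::rnorm(cfg$n_subjects)
    u2 <- rho * u1 + sqrt(1 - rho^2) * stats::rnorm(cfg$n_subjects)
    diagnosis <- pmin(K - 1L, floor(stats::pnorm(u2) * K))
    site <- sample(0:(cfg$n_strata - 1L), cfg$n_subjects, replace = TRUE)
    sex <- if (cfg$include_sex) sample(0:1, cfg$n_subjects, replace = TRUE) else NULL
    n_visits <- sample(seq(cfg$visits_per_subject[1L], cfg$visits_per_subject[2L]),
                       cfg$n_subjects, replace = TRUE)
    gaps <- lapply(n_visits, function(nv) if (nv > 1L) stats::runif(nv - 1L, 0.8, 1.2) else numeric(0))
    span <- vapply(gaps, sum, numeric(1))
    baseline <- lo + stats::pnorm(u1) * pmax(hi - lo - span, 0)
    list(diagnosis = diagnosis, site = site, sex = sex,
         n_visits = n_visits, gaps = gaps, baseline = baseline)
  })

  sd_age <- diff(cfg$age_range) / sqrt(12) # SD of a uniform baseline age
  mid_age <- mean(cfg$age_range)

  rows <- list(); imgs <- list(); a_list <- list(); d_list <- list()
  for (i in seq_len(cfg$n_subjects)) {
    nv <- subj$n_visits[i]
    ages <- subj$baseline[i] + cumsum(c(0, subj$gaps[[i]]))
    y <- subj$diagnosis[i]
    gp_a <- sample_gp_trajectory(ages, cfg$gp_lengthscale, cfg$gp_variance,
                                 substream_seed(cfg$seed, paste0("gp_age.", i)))
    a_score <- (ages - mid_age) / sd_age + gp_a
    if (y == 0L) {
      sev <- rep(0, nv)
    } else {
      traj <- with_seed(substream_seed(cfg$seed, paste0("sev_base.", i)), {
        b0 <- stats::rnorm(1, 0.5, 0.5)
        slope <- abs(stats::rnorm(1, 0.3, 0.1))
        c(b0, slope)
      })
      gp_d <- sample_gp_trajectory(ages, cfg$gp_lengthscale, cfg$gp_variance,
                                   substream_seed(cfg$seed, paste0("gp_sev.", i)))
      sev <- cummax(softplus(traj[1L] + traj[2L] * (ages - ages[1L]) + gp_d))
    }
    d_pat <- if (y == 0L) pat$disease_patterns[[1L]] * 0 else pat$disease_patterns[[y]]
    for (j in seq_len(nv)) {
      imgs[[length(imgs) + 1L]] <- render_scan(
        pat$template, pat$age_pattern, d_pat, pat$site_patterns[[subj$site[i] + 1L]],
        a_score[j], sev[j], 1, cfg$noise_sd,
        substream_seed(cfg$seed, paste0("noise.", i, ".", j)))
      rows[[length(rows) + 1L]] <- data.frame(
        subject_id = i, visit_index = j - 1L, age = ages[j],
        diagnosis = y, site = subj$site[i],
        sex = if (cfg$include_sex) subj$sex[i] else NA_integer_)
    }
    a_list[[i]] <- a_score; d_list[[i]] <- sev
  }
  meta <- do.call(rbind, rows)
  if (!cfg$include_sex) meta$sex <- NULL
  n <- nrow(meta)
  images <- array(0, dim = c(n, cfg$image_size, cfg$image_size))
  for (r in seq_len(n)) images[r, , ] <- imgs[[r]]
  ds <- list(images = images, meta = meta,
             truth = list(age_score = unlist(a_list), disease_severity = unlist(d_list),
                          template = pat$template, age_pattern = pat$age_pattern,
                          disease_patterns = pat$disease_patterns,
                          site_patterns = pat$site_patterns),
             config = cfg)
  class(ds) <- "phantom_dataset"
  ds
}

#' Flatten dataset images to a scans-by-pixels matrix
#' @param ds a `phantom_dataset`.
#' @return numeric matrix `n_scans x (H*W)`.
#' @export
dataset_matrix <- function(ds) {
  d <- dim(ds$images)
  matrix(ds$images, nrow = d[1L], ncol = d[2L] * d[3L])
}

.dataset_members <- c("images", "meta", "truth", "config")

#' Write a phantom dataset to disk
#'
#' Stores the full dataset (images, metadata, hidden truth tables, config) in
#' a single RDS archive, plus a sibling `<stem>_meta.csv` with the metadata
#' table for external tools. The round trip through [read_dataset()] is
#' exact.
#'
#' @param ds a `phantom_dataset`.
#' @param path output file path (conventionally `.rds`).
#' @return `path`, invisibly.
#' @export
write_dataset <- function(ds, path) {
  stopifnot(inherits(ds, "phantom_dataset"))
  payload <- unclass(ds)
  payload$format_version <- 1L
  saveRDS(payload, path)
  csv <- paste0(tools::file_path_sans_ext(path), "_meta.csv")
  utils::write.csv(ds$meta, csv, row.names = FALSE)
  invisible(path)
}

#' Read a phantom dataset written by [write_dataset()]
#' @param path archive path.
#' @return a `phantom_dataset`.
#' @export
read_dataset <- function(path) {
  abort_if(!file.exists(path), "no dataset archive at '%s'", path)
  payload <- readRDS(path)
  abort_if(!is.list(payload), "archive at '%s' is not a dataset", path)
  for (m in .dataset_members) {
    abort_if(is.null(payload[[m]]), "dataset archive is missing member '%s'", m)
  }
  ds <- payload[.dataset_members]
  class(ds$config) <- "phantom_config"
  class(ds) <- "phantom_dataset"
  ds
}
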