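# YAML run configuration with strict parsing: unknown keys are errors, so a
# typo in a loss-weight name can never silently zero out a term.

.config_sections <- c("phantom", "model", "cdaa", "optim", "seed", "out")

build_section <- function(values, constructor, section) {
  values <- values %||% list()
  known <- setdiff(names(formals(constructor)), "...")
  unknown <- setdiff(names(values), known)
  abort_if(length(unknown) > 0L, "unknown key '%s' in config section '%s'",
           unknown[1L], section)
  do.call(constructor, values)
}

#' Assemble a full run configuration
#'
#' @param phantom list of [phantom_config()] overrides.
#' @param model list of [model_config()] overrides.
#' @param cdaa list of [loss_weights()] overrides.
#' @param optim list of [optim_config()] overrides.
#' @param seed integer run seed (also the phantom seed unless that section
#'   sets its own).
#' @param out output directory (optional).
#' @return a `run_config` with every default resolved.
#' @export
run_config <- function(phantom = list(), model = list(), cdaa = list(),
                       optim = list(), seed = 1L, out = NULL) {
  if (is.null(phantom$seed)) phantom$seed <- seed
  cfg <- list(phantom = build_section(phantom, phantom_config, "phantom"),
              model = build_section(model, model_config, "model"),
              cdaa = build_section(cdaa, loss_weights, "cdaa"),
              optim = build_section(optim, optim_config, "optim"),
              seed = as.integer(seed), out = out)
  abort_if(cfg$model$image_size != cfg$phantom$image_size,
           "model.image_size must equal phantom.image_size")
  class(cfg) <- "run_config"
  cfg
}

#' Load a run configuration from YAML
#'
#' Strict parsing: unknown sections or keys are rejected with an error naming
#' them; omitted keys take their documented defaults. An empty file yields
#' the full-default configuration.
#'
#' @param path YAML file path.
#' @return a `run_config`.
#' @export
load_config <- function(path) {
  abort_if(!file.exists(path), "no config file at '%s'", path)
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  unknown <- setdiff(names(raw), .config_sections)
  abort_if(length(unknown) > 0L, "unknown config section '%s'", unknown[1L])
  run_config(phantom = raw$phantom %||% list(), model = raw$model %||% list(),
             cdaa = raw$cdaa %||% list(), optim = raw$optim %||% list(),
             seed = raw$seed %||% 1L, out = raw$out)
}

#' Write a resolved configuration back to YAML
#'
#' The frozen config written into every run directory; reloading it with
#' [load_config()] reproduces the same `run_config`.
#'
#' @param cfg a `run_config`.
#' @param path output YAML path.
#' @return `path`, invisibly.
#' @export
save_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "run_config"))
  strip <- function(x) {
    x <- unclass(x)
    x[!vapply(x, is.null, logical(1))]
  }
  payload <- list(phantom = strip(cfg$phantom), model = strip(cfg$model),
                  cdaa = strip(cfg$cdaa), optim = strip(cfg$optim),
                  seed = cfg$seed)
  if (!is.null(cfg$out)) payload$out <- cfg$out
  yaml::write_yaml(payload, path, precision = 15)
  invisible(path)
}
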