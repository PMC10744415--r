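#' Default run configuration
#'
#' The nested configuration consumed by the command-line entry point and
#' [load_run_config()]: blocks `synth`, `augment`, `gridmask`, `model` and
#' `train`, each mirroring the corresponding constructor's arguments, plus
#' top-level `seed` and `verbose`.
#'
#' @return A named list of defaults.
#' @export
default_run_config <- function() {
  list(
    seed = 1L,
    verbose = 0L,
    synth = list(height = 64L, width = 64L, n_tools = 2L,
                 tool_width = c(4, 8), tool_length = c(0.4, 0.9),
                 bg_texture_scale = 8, bg_contrast = 0.25,
                 specular_prob = 0.5, occluder_prob = 0.3,
                 occluder_size = c(3, 7), splash_prob = 0.3),
    augment = list(rotation_deg = 0, hflip_prob = 0, vflip_prob = 0,
                   scale_range = c(1, 1), translate_px = 0,
                   elastic_amplitude = 0, elastic_sigma = 8,
                   brightness_delta = 0, noise_sd = 0, crop_size = NULL),
    gridmask = list(r = 0.6, d_range = c(8L, 24L), apply_prob = 0.5,
                    rotate = TRUE, mask_labels = FALSE),
    model = list(variant = "enhanced", in_channels = 3L, num_classes = 2L,
                 depth = 4L, base_channels = 8L, dilation_rates = NULL,
                 use_residual_skips = NULL, use_adaptive_fusion = NULL,
                 use_depthwise_separable = NULL),
    train = list(epochs = 10L, batch_size = 4L, base_lr = 1e-4,
                 max_lr = 1e-2, cycle_steps = NULL,
                 weight_mode = "dataset", momentum = 0.9,
                 val_fraction = 0.2)
  )
}

# recursive merge of user values over defaults; unknown keys are an error so
# typos surface immediately
merge_config <- function(defaults, user, path = "") {
  if (is.null(user)) return(defaults)
  if (!is.list(user))
    stop_invalid("configuration block '", path, "' must be a mapping")
  extra <- setdiff(names(user), names(defaults))
  if (length(extra) > 0)
    stop_invalid("unknown configuration key: ",
                 paste0(sub("^\\.", "", paste0(path, ".", extra)),
                        collapse = ", "))
  for (nm in names(user)) {
    if (is.list(defaults[[nm]]) && !is.null(names(defaults[[nm]]))) {
      defaults[[nm]] <- merge_config(defaults[[nm]], user[[nm]],
                                     paste0(path, ".", nm))
    } else {
      v <- user[[nm]]
      if (is.list(v)) v <- unlist(v)
      defaults[[nm]] <- v
    }
  }
  defaults
}

# validate by constructing every sub-config; returns the realised objects
realise_config <- function(cfg) {
  sc <- do.call(scene_config, cfg$synth)
  au <- do.call(augment_config, cfg$augment)
  gm <- do.call(gridmask_policy, cfg$gridmask)
  mc <- do.call(model_config, cfg$model)
  tc <- do.call(train_config,
                c(cfg$train, list(seed = cfg$seed, gridmask = gm,
                                  augment = au)))
  list(raw = cfg, synth = sc, augment = au, gridmask = gm, model = mc,
       train = tc)
}

#' Load and validate a YAML run configuration
#'
#' Reads a YAML file, fills defaults for absent keys, rejects unknown keys
#' (naming the offending key path), and validates every block through its
#' constructor. An empty file yields the all-defaults configuration.
#'
#' @param path Path to a YAML file, or `NULL` for pure defaults.
#' @return An object of class `run_config`: the normalised raw list plus the
#'   realised `synth`, `augment`, `gridmask`, `model` and `train` objects.
#' @export
load_run_config <- function(path = NULL) {
  user <- if (is.null(path)) list() else {
    if (!file.exists(path)) stop_invalid("configuration file not found: ",
                                         path)
    y <- yaml::read_yaml(path)
    if (is.null(y)) list() else y
  }
  cfg <- merge_config(default_run_config(), user)
  structure(realise_config(cfg), class = "run_config")
}

#' Write a normalised configuration back to YAML
#'
#' `dump_run_config(load_run_config(x))` is idempotent: dumping and reloading
#' yields the same normalised configuration.
#'
#' @param config A `run_config`.
#' @param path Destination YAML path.
#' @return `path`, invisibly.
#' @export
dump_run_config <- function(config, path) {
  if (!inherits(config, "run_config"))
    stop_invalid("config must be a run_config")
  raw <- config$raw
  drop_null <- function(x) {
    if (!is.list(x)) return(x)
    x <- lapply(x, drop_null)
    x[!vapply(x, is.null, logical(1))]
  }
  yaml::write_yaml(drop_null(raw), path)
  invisible(path)
}
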