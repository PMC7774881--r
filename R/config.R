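# Run configuration: nested sections for io, augmentation, model, train,
# fusion and synth. The "paper" profile carries the published
# hyperparameters (300 epochs, batch 24, tile 256, lr 1e-3 -> 1e-4 at epoch
# 150); the "tiny" profile is the CPU-scale preset used throughout the test
# suite. Unknown keys are rejected on validation.

#' Default run configuration
#'
#' @param profile `"paper"` (published hyperparameters) or `"tiny"`
#'   (CPU-scale preset: tile 64, width 1/8, batch 4).
#' @return Nested `run_config` list.
#' @export
default_config <- function(profile = c("paper", "tiny")) {
  profile <- match.arg(profile)
  cfg <- list(
    profile = profile,
    io = list(normalize_low_pct = 1, normalize_high_pct = 99.9),
    augmentation = list(rotation = c(0, 360), translation = c(-0.1, 0.1),
                        zoom = c(0.8, 1.2), flip_h = 0.5, flip_v = 0.5,
                        jitter = c(-0.1, 0.1)),
    model = list(architecture = "linknet", encoder = "vgg16_style",
                 input_tile = 256L, width_multiplier = 1, out_channels = 7L),
    train = list(epochs = 300L, batch_size = 24L, lr_phase1 = 1e-3,
                 lr_phase2 = 1e-4, phase_split_epoch = 150L,
                 optimizer = "adam", rng_seed = 1L),
    fusion = list(threshold = 0.5, seed_binarize_level = 0.5,
                  weights = rep(1, 7), hmin = 0.05),
    synth = list(field = c(256L, 256L), density = 50,
                 boundary_intensity = 0.8, cytoplasm_intensity = 0.15,
                 staining = "continuous", psf_sigma = 1, noise_sd = 0.05,
                 gradient_amplitude = 0.1, lloyd_iters = 2L)
  )
  if (profile == "tiny") {
    cfg$model$encoder <- "tiny"
    cfg$model$input_tile <- 64L
    cfg$model$width_multiplier <- 0.125
    cfg$train$epochs <- 100L
    cfg$train$batch_size <- 4L
    cfg$train$phase_split_epoch <- 50L
  }
  structure(cfg, class = "run_config")
}

#' Validate a run configuration against the schema
#'
#' Checks the nesting against [default_config()]; unknown keys at any level
#' are an error.
#' @param cfg A nested list.
#' @return The validated `run_config` (invisibly on success).
#' @export
validate_config <- function(cfg) {
  ref <- unclass(default_config())
  check <- function(x, r, path) {
    extra <- setdiff(names(x), names(r))
    if (length(extra)) {
      stop("unknown config key(s): ",
           paste(paste0(path, extra), collapse = ", "))
    }
    for (nm in names(x)) {
      if (is.list(r[[nm]]) && !is.null(names(r[[nm]]))) {
        if (!is.list(x[[nm]])) stop("config section `", path, nm, "` must be a mapping")
        check(x[[nm]], r[[nm]], paste0(path, nm, "."))
      }
    }
  }
  check(unclass(cfg), ref, "")
  invisible(structure(cfg, class = "run_config"))
}

#' Read / write a run configuration as YAML
#'
#' Values found in the file override the profile defaults; the merged result
#' is schema-validated.
#' @param path YAML file path.
#' @export
read_config <- function(path) {
  y <- yaml::read_yaml(path)
  profile <- if (!is.null(y$profile)) y$profile else "paper"
  cfg <- unclass(default_config(profile))
  merge_in <- function(base, over) {
    for (nm in names(over)) {
      base[[nm]] <- if (is.list(base[[nm]]) && is.list(over[[nm]])) {
        merge_in(base[[nm]], over[[nm]])
      } else over[[nm]]
    }
    base
  }
  validate_config(merge_in(cfg, y))
}

#' @rdname read_config
#' @param cfg A `run_config`.
#' @export
write_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

# Stable short hash of a configuration (for output sidecars).
.config_hash <- function(cfg) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(unclass(cfg), auto_unbox = TRUE, digits = NA), tmp)
  unname(tools::md5sum(tmp))
}

.sidecar <- function(path, cfg, extra = list()) {
  meta <- c(list(package = "memseg",
                 version = as.character(utils::packageVersion("memseg")),
                 config_hash = .config_hash(cfg)), extra)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
}
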