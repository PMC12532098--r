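#' Default configuration
#'
#' The resolved configuration drives every pipeline stage; any YAML file
#' passed to [load_config()] is merged over these defaults. Keys:
#' `diffusion` (n_steps, gamma, growth_p, beta1, betaN), `model` (the
#' [denoiser_config()] fields), `train` (the [train_config()] fields plus
#' seed), `simulate` (severity, noise_sigma, spacing), `data`
#' (size, n, split).
#'
#' @return nested list.
#' @export
default_config <- function() {
  list(
    diffusion = list(n_steps = 4L, gamma = 2, growth_p = 0.3,
                     beta1 = NULL, betaN = 0.999),
    model = list(base_channels = 16L, channel_multipliers = c(1L, 2L),
                 swin_window = 4L, swin_heads = 2L, time_embed_dim = 32L,
                 levels_with_swin = NULL, image_size = 64L),
    train = list(iterations = 1000L, batch_size = 4L, lr_start = 2e-4,
                 lr_min = 2e-5, warmup_steps = 50L, loss_mode = "l1l2",
                 seed = 0L),
    simulate = list(severity = "heavy", noise_sigma = 0, spacing = 1),
    data = list(size = 64L, n = 50L, split = c(0.8, 0.1, 0.1))
  )
}

merge_config <- function(base, override) {
  for (nm in names(override)) {
    if (is.list(base[[nm]]) && is.list(override[[nm]])) {
      base[[nm]] <- merge_config(base[[nm]], override[[nm]])
    } else {
      base[[nm]] <- override[[nm]]
    }
  }
  base
}

#' Load a YAML configuration file merged over the defaults
#'
#' @param path YAML file, or `NULL` for pure defaults.
#' @return nested configuration list.
#' @export
load_config <- function(path = NULL) {
  cfg <- default_config()
  if (!is.null(path)) {
    if (!file.exists(path)) stop_io("config file not found: ", path)
    cfg <- merge_config(cfg, yaml::read_yaml(path))
  }
  cfg
}

schedule_from_config <- function(cfg) {
  d <- cfg$diffusion
  beta1 <- if (is.null(d$beta1)) (0.04 / d$gamma)^2 else d$beta1
  build_schedule(d$n_steps, d$gamma, d$growth_p, beta1, d$betaN)
}

denoiser_cfg_from_config <- function(cfg) {
  m <- cfg$model
  denoiser_config(m$base_channels, m$channel_multipliers, m$swin_window,
                  m$swin_heads, m$time_embed_dim, m$levels_with_swin,
                  m$image_size)
}
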