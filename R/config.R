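#' Study configuration (YAML round-trip)
#'
#' A study configuration bundles the generator and extraction settings that
#' define one robustness experiment. [write_study_config()] and
#' [read_study_config()] serialize it to YAML so a run can be frozen and
#' reproduced; [platforms_from_config()] materializes the platform models.
#'
#' @param n_platforms,platform_seed,spread_hu,vmi_factor,noise_sd,kernel_fwhm_px
#'   see [default_platform_models()]
#' @param n_repeats repeats per platform/image type
#' @param image_types image types to simulate
#' @param bin_width discretization bin width (HU)
#' @param repeat_policy repeat used by inter-platform analyses
#' @export
study_config <- function(n_platforms = 10L, platform_seed = 1L,
                         spread_hu = 15, vmi_factor = 0.5, noise_sd = 10,
                         kernel_fwhm_px = 2, n_repeats = 2L,
                         image_types = image_types_all(), bin_width = 25,
                         repeat_policy = "first") {
  list(n_platforms = as.integer(n_platforms),
       platform_seed = as.integer(platform_seed),
       spread_hu = spread_hu, vmi_factor = vmi_factor, noise_sd = noise_sd,
       kernel_fwhm_px = kernel_fwhm_px, n_repeats = as.integer(n_repeats),
       image_types = image_types, bin_width = bin_width,
       repeat_policy = repeat_policy)
}

#' @rdname study_config
#' @param config a configuration list
#' @param path YAML file path
#' @export
write_study_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

#' @rdname study_config
#' @export
read_study_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  defaults <- study_config()
  for (nm in names(defaults))
    if (is.null(cfg[[nm]])) cfg[[nm]] <- defaults[[nm]]
  cfg
}

#' @rdname study_config
#' @export
platforms_from_config <- function(config) {
  default_platform_models(
    n_platforms = config$n_platforms, seed = config$platform_seed,
    spread_hu = config$spread_hu, vmi_factor = config$vmi_factor,
    noise_sd = config$noise_sd, kernel_fwhm_px = config$kernel_fwhm_px)
}
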