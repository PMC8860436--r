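# YAML configuration: sections lifecycle, mating, tet, strategy, season map
# onto the parameter constructors, so any published vital-rate values are
# drop-in replacements for the calibrated defaults.

#' Read a season configuration from a YAML file
#'
#' Recognised sections (all optional; omitted fields keep constructor
#' defaults): \code{lifecycle}, \code{mating}, \code{tet}, \code{strategy}
#' (fields of [release_strategy()]), and \code{season} with \code{start},
#' \code{end}, \code{seed} and climatology fields (\code{annual_mean},
#' \code{amplitude}, \code{peak_doy}, \code{noise_sd}, \code{ar1}) or a
#' \code{temperature_csv} path.
#'
#' @param path path to the YAML file.
#' @return A list with \code{config} (a [season_config()]), \code{temps}
#'   (a \code{temperature_series} or NULL when the season section is
#'   absent), and \code{seed}.
#' @export
read_config <- function(path) {
  y <- yaml::read_yaml(path)
  build <- function(ctor, args) {
    args <- args %||% list()
    # YAML 1.1 reads a bare key `n` as the boolean FALSE (and `y` as TRUE)
    names(args)[names(args) == "FALSE"] <- "n"
    names(args)[names(args) == "TRUE"] <- "y"
    do.call(ctor, args)
  }
  cfg <- season_config(
    lifecycle = build(lifecycle_params, y$lifecycle),
    mating = build(mating_params, y$mating),
    tet = build(tet_params, y$tet),
    strategy = build(release_strategy, y$strategy),
    field_tet = y$field_tet %||% 0
  )
  temps <- NULL
  seed <- as.integer(y$season$seed %||% 1L)
  if (!is.null(y$season)) {
    if (!is.null(y$season$temperature_csv)) {
      temps <- read_temperature_csv(y$season$temperature_csv)
    } else {
      clim_fields <- intersect(names(y$season),
                               names(formals(climatology_params)))
      clim <- do.call(climatology_params, y$season[clim_fields])
      temps <- synthesize_season(
        clim,
        start = y$season$start %||% "2021-03-01",
        end = y$season$end %||% "2021-09-01",
        seed = seed)
    }
  }
  list(config = cfg, temps = temps, seed = seed)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a JSON run manifest next to an output file
#'
#' Records the seed, package version and the full configuration, so a run
#' can be reproduced bit-for-bit.
#'
#' @param out_path the output file the manifest describes; the manifest is
#'   written to \code{<out_path>.manifest.json}.
#' @param config the configuration object used.
#' @param seed the seed used.
#' @return The manifest path, invisibly.
#' @export
write_manifest <- function(out_path, config, seed) {
  man <- list(
    output = basename(out_path),
    seed = seed,
    package_version = as.character(utils::packageVersion("ssims")),
    config = config
  )
  mp <- paste0(out_path, ".manifest.json")
  jsonlite::write_json(man, mp, auto_unbox = TRUE, digits = NA,
                       force = TRUE)
  invisible(mp)
}
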