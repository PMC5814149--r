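#' Read and write radial profiles as CSV
#'
#' Profiles use the column convention `x_um`, `value`, and optionally `sd`,
#' `n`; units are micrometers and arbitrary fluorescence units.
#'
#' @param profile A [radial_profile()].
#' @param path File path.
#' @param kind Profile kind to assign on read.
#' @param overwrite Allow overwriting an existing file.
#' @return `read_profile()` returns a [radial_profile()];
#'   `write_profile()` returns `path` invisibly.
#' @export
write_profile <- function(profile, path, overwrite = FALSE) {
  stopifnot(inherits(profile, "radial_profile"))
  check_overwrite(path, overwrite)
  df <- data.frame(x_um = profile$x, value = profile$values)
  if (!is.null(profile$sd)) df$sd <- profile$sd
  if (!is.null(profile$n)) df$n <- profile$n
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_profile
#' @export
read_profile <- function(path, kind = "density") {
  df <- utils::read.csv(path)
  if (!all(c("x_um", "value") %in% names(df)))
    stop("profile CSV needs columns x_um, value")
  radial_profile(df$x_um, df$value, kind = kind, sd = df$sd, n = df$n)
}

#' Read and write model parameters (JSON or YAML)
#'
#' Flat key-value files with keys `ell_um`, `ell_u_um`, `alpha`, `rho0`,
#' `theta_per_s` (and `beta0_per_um` for uniform activation, where
#' `ell_u_um` may be the string `"infinite"`). Format is chosen by file
#' extension (`.json` vs `.yaml`/`.yml`).
#'
#' @param params A [model_params()] object.
#' @param path File path.
#' @param overwrite Allow overwriting an existing file.
#' @return `read_params()` returns a [model_params()] object.
#' @export
write_params <- function(params, path, overwrite = FALSE) {
  stopifnot(inherits(params, "model_params"))
  check_overwrite(path, overwrite)
  x <- list(ell_um = params$ell,
            ell_u_um = if (params$uniform) "infinite" else params$ell_u,
            alpha = if (params$uniform) NULL else params$alpha,
            rho0 = params$rho0,
            theta_per_s = if (is.na(params$theta)) NULL else params$theta,
            beta0_per_um = if (params$uniform) params$beta0 else NULL)
  x <- x[!vapply(x, is.null, logical(1))]
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE))
    yaml::write_yaml(x, path)
  else jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_params
#' @export
read_params <- function(path) {
  x <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE))
    yaml::read_yaml(path) else jsonlite::read_json(path, simplifyVector = TRUE)
  ell_u <- x$ell_u_um
  uniform <- identical(ell_u, "infinite") || is.infinite(as.numeric(ell_u))
  model_params(ell = as.numeric(x$ell_um),
               ell_u = if (uniform) Inf else as.numeric(ell_u),
               alpha = if (uniform) 0 else as.numeric(x$alpha),
               rho0 = if (is.null(x$rho0)) 1 else as.numeric(x$rho0),
               theta = if (is.null(x$theta_per_s)) NA_real_
                       else as.numeric(x$theta_per_s),
               beta0 = if (uniform) as.numeric(x$beta0_per_um) else NULL)
}

#' Read and write image stacks as multi-frame TIFF with a metadata sidecar
#'
#' Frames are stored as 32-bit float TIFF, normalized to `[0, 1]` by the
#' global maximum (TIFF convention); the scale and the acquisition metadata
#' (`pixel_size_um`, `frame_interval_s`, `center_row`, `center_col`,
#' `cut_frame`, `intensity_scale`) go to a JSON sidecar `<path>.json`, so
#' the round trip restores absolute intensities.
#'
#' @param stack An [image_stack()].
#' @param path TIFF file path.
#' @param overwrite Allow overwriting existing files.
#' @return `read_stack()` returns an [image_stack()].
#' @export
write_stack <- function(stack, path, overwrite = FALSE) {
  stopifnot(inherits(stack, "image_stack"))
  check_overwrite(path, overwrite)
  scale <- max(vapply(stack$frames, max, numeric(1)), 1e-300)
  frames <- lapply(stack$frames, function(f) {
    attributes(f) <- list(dim = dim(f))
    f / scale
  })
  tiff::writeTIFF(frames, path, bits.per.sample = 32L, reduce = FALSE)
  meta <- list(pixel_size_um = stack$pixel_size,
               frame_interval_s = stack$frame_interval,
               center_row = stack$center[1], center_col = stack$center[2],
               cut_frame = stack$cut_time_index,
               intensity_scale = scale)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_stack
#' @export
read_stack <- function(path) {
  frames <- tiff::readTIFF(path, all = TRUE)
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  scale <- if (is.null(meta$intensity_scale)) 1 else meta$intensity_scale
  frames <- lapply(frames, function(f) f * scale)
  image_stack(frames, pixel_size = meta$pixel_size_um,
              frame_interval = meta$frame_interval_s,
              center = c(meta$center_row, meta$center_col),
              cut_time_index = if (is.null(meta$cut_frame)) NA_integer_
                               else meta$cut_frame)
}

#' Write a wave track as CSV
#'
#' Columns: `t_s`, `center_um`, `sigma_um`, `area`, `accepted`, `flag`.
#'
#' @param track A `"wave_track"`.
#' @param path File path.
#' @param overwrite Allow overwriting an existing file.
#' @export
write_wave_track <- function(track, path, overwrite = FALSE) {
  stopifnot(inherits(track, "wave_track"))
  check_overwrite(path, overwrite)
  utils::write.csv(as.data.frame(track), path, row.names = FALSE)
  invisible(path)
}

#' Write a filament table as CSV
#'
#' Columns: `minus_pos_um`, `length_um`, `birth_s`.
#'
#' @param filaments A [filament_set()].
#' @param path File path.
#' @param overwrite Allow overwriting an existing file.
#' @export
write_filaments <- function(filaments, path, overwrite = FALSE) {
  stopifnot(inherits(filaments, "filament_set"))
  check_overwrite(path, overwrite)
  utils::write.csv(data.frame(minus_pos_um = filaments$minus_pos,
                              length_um = filaments$length,
                              birth_s = filaments$birth_time),
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_filaments
#' @export
read_filaments <- function(path) {
  df <- utils::read.csv(path)
  filament_set(df$minus_pos_um, df$length_um, df$birth_s)
}

#' Write a lifetime fit report as JSON
#'
#' Keys: `tau_s`, `mean_lifetime_s`, `theta_per_s`, `t_min_s`, `n_used`.
#'
#' @param fit A `"lifetime_fit"`.
#' @param path File path.
#' @param overwrite Allow overwriting an existing file.
#' @export
write_lifetime_report <- function(fit, path, overwrite = FALSE) {
  stopifnot(inherits(fit, "lifetime_fit"))
  check_overwrite(path, overwrite)
  jsonlite::write_json(list(tau_s = fit$tau,
                            mean_lifetime_s = fit$mean_lifetime,
                            theta_per_s = fit$theta, t_min_s = fit$t_min,
                            n_used = fit$n_used, ks_stat = fit$ks_stat,
                            ks_p = fit$ks_p, gof_flag = fit$gof_flag),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write a JSON run manifest
#'
#' Records inputs (with MD5 content hashes), parameters, and the RNG seed
#' of a run, so any output can be traced to exact inputs.
#'
#' @param path Manifest path.
#' @param inputs Character vector of input file paths.
#' @param parameters Named list of parameters.
#' @param seed Integer seed used for the run.
#' @param outputs Character vector of output file paths.
#' @param overwrite Allow overwriting an existing file.
#' @export
write_run_manifest <- function(path, inputs = character(0),
                               parameters = list(), seed = NA_integer_,
                               outputs = character(0), overwrite = FALSE) {
  check_overwrite(path, overwrite)
  hashes <- if (length(inputs)) as.list(tools::md5sum(inputs)) else list()
  jsonlite::write_json(list(inputs = as.list(inputs),
                            input_md5 = hashes,
                            parameters = parameters, seed = seed,
                            outputs = as.list(outputs),
                            timestamp = format(Sys.time(), tz = "UTC")),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

check_overwrite <- function(path, overwrite) {
  if (file.exists(path) && !isTRUE(overwrite))
    stop("refusing to overwrite existing file: ", path,
         " (pass overwrite = TRUE)")
  invisible(TRUE)
}
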