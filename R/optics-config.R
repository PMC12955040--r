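#' Optical system configuration
#'
#' Bundles the objective-side parameters of a (Fourier) light-field microscope:
#' numerical aperture, magnification, illumination wavelength, immersion
#' refractive index, the axial depth grid over which point-spread functions are
#' computed, and the lateral field grid on which wavefronts are sampled.
#'
#' @param numerical_aperture Objective NA (dimensionless, must be < `refractive_index`).
#' @param magnification Lateral magnification M (dimensionless, > 0).
#' @param wavelength Monochromatic wavelength in nm.
#' @param refractive_index Immersion refractive index n.
#' @param sensor_pixel_pitch Sensor pixel pitch in um.
#' @param depth_grid Uniformly spaced, strictly increasing axial positions in um.
#' @param lateral_grid_spacing Wavefront sampling pitch in um.
#' @param lateral_grid_extent Wavefront grid size in samples (positive even integer).
#'
#' @return An object of class `optical_config`.
#' @export
optical_config <- function(numerical_aperture, magnification, wavelength,
                           refractive_index, sensor_pixel_pitch,
                           depth_grid, lateral_grid_spacing,
                           lateral_grid_extent) {
  if (!is.numeric(numerical_aperture) || numerical_aperture <= 0)
    stop("invalid-config: numerical_aperture must be positive", call. = FALSE)
  if (numerical_aperture >= refractive_index)
    stop("invalid-config: NA must be smaller than the refractive index",
         call. = FALSE)
  if (wavelength <= 0) stop("invalid-config: wavelength must be > 0", call. = FALSE)
  if (length(depth_grid) < 1 || is.unsorted(depth_grid, strictly = TRUE))
    stop("invalid-config: depth_grid must be strictly increasing", call. = FALSE)
  if (length(depth_grid) > 2) {
    dz <- diff(depth_grid)
    if (max(abs(dz - dz[1])) > 1e-9 * max(abs(dz)))
      stop("invalid-config: depth_grid must be uniformly spaced", call. = FALSE)
  }
  if (lateral_grid_extent <= 0 || lateral_grid_extent %% 2 != 0)
    stop("invalid-config: lateral_grid_extent must be a positive even integer",
         call. = FALSE)
  structure(list(
    numerical_aperture = numerical_aperture,
    magnification = magnification,
    wavelength = wavelength,
    refractive_index = refractive_index,
    sensor_pixel_pitch = sensor_pixel_pitch,
    depth_grid = as.numeric(depth_grid),
    lateral_grid_spacing = lateral_grid_spacing,
    lateral_grid_extent = as.integer(lateral_grid_extent)
  ), class = "optical_config")
}

#' Microlens-array configuration
#'
#' @param pitch Lenslet pitch in um.
#' @param focal_length Lenslet focal length in um.
#' @param n_pix Pixels per lenslet along one axis (odd, so a central view exists).
#' @param f_number Lenslet f-number (dimensionless), optional.
#' @param relay_focal_lengths Length-2 numeric, relay focal lengths fR1 and fR2 in mm
#'   (used by the Fourier configuration); optional.
#'
#' @return An object of class `mla_config`.
#' @export
mla_config <- function(pitch, focal_length, n_pix,
                       f_number = NA_real_, relay_focal_lengths = c(NA_real_, NA_real_)) {
  if (pitch <= 0 || focal_length <= 0)
    stop("invalid-config: MLA lengths must be positive", call. = FALSE)
  if (n_pix < 1 || n_pix %% 2 != 1)
    stop("invalid-config: n_pix must be odd so a central view exists", call. = FALSE)
  structure(list(
    pitch = pitch,
    focal_length = focal_length,
    n_pix = as.integer(n_pix),
    f_number = f_number,
    relay_focal_lengths = relay_focal_lengths
  ), class = "mla_config")
}

#' Reference LFM optical preset
#'
#' 40x/0.8 NA water-immersion system at 580 nm with a depth range of -30 to
#' 30 um in 1 um steps (61 planes). The wavefront grid covers a 16x16-lenslet
#' sensor patch at one sample per sensor pixel.
#'
#' @param n_depth Number of depth planes (default 61).
#' @param depth_half_range Half depth range in um (default 30).
#' @return An `optical_config`.
#' @export
lfm_optics_preset <- function(n_depth = 61, depth_half_range = 30) {
  mla <- lfm_mla_preset()
  pixel <- mla$pitch / mla$n_pix           # 150/11 um sensor pixel
  extent <- 16L * mla$n_pix                # 16x16-lenslet sensor patch
  optical_config(
    numerical_aperture = 0.8, magnification = 40, wavelength = 580,
    refractive_index = 1.33, sensor_pixel_pitch = pixel,
    depth_grid = seq(-depth_half_range, depth_half_range, length.out = n_depth),
    lateral_grid_spacing = pixel, lateral_grid_extent = extent
  )
}

#' Reference LFM microlens-array preset
#'
#' 150 um pitch, 3500 um focal length, 11 sensor pixels per lenslet.
#' @return An `mla_config`.
#' @export
lfm_mla_preset <- function() {
  mla_config(pitch = 150, focal_length = 3500, n_pix = 11)
}

#' Reference FLFM optical preset
#'
#' 100x/1.4 NA system at 510 nm; depth grid matches the LFM preset so volumes
#' project through both systems.
#'
#' @param n_depth Number of depth planes (default 61).
#' @param depth_half_range Half depth range in um (default 30).
#' @param grid_extent Pupil-plane grid size in samples (default 128).
#' @return An `optical_config`.
#' @export
flfm_optics_preset <- function(n_depth = 61, depth_half_range = 30,
                               grid_extent = 128) {
  mla <- flfm_mla_preset()
  # pupil-plane grid spans the 2-3-2 lenslet footprint (~3 pitches across)
  spacing <- 3 * mla$pitch / grid_extent
  optical_config(
    numerical_aperture = 1.4, magnification = 100, wavelength = 510,
    refractive_index = 1.515, sensor_pixel_pitch = 6.5,
    depth_grid = seq(-depth_half_range, depth_half_range, length.out = n_depth),
    lateral_grid_spacing = spacing, lateral_grid_extent = as.integer(grid_extent)
  )
}

#' Reference Fourier microlens-array preset
#'
#' 3.25 mm pitch, 120 mm focal length, f/37, relay 180/300 mm. Lengths are
#' stored in um for consistency with the field grids.
#' @return An `mla_config`.
#' @export
flfm_mla_preset <- function() {
  mla_config(pitch = 3250, focal_length = 120e3, n_pix = 1,
             f_number = 37, relay_focal_lengths = c(180, 300))
}

#' Read or write configurations as YAML
#'
#' @param config An `optical_config` or `mla_config`.
#' @param path File path.
#' @return `write_config` returns `path` invisibly; `read_config` the object.
#' @export
write_config <- function(config, path) {
  obj <- unclass(config)
  obj$.class <- class(config)[1]
  yaml::write_yaml(obj, path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  obj <- yaml::read_yaml(path)
  cls <- obj$.class
  obj$.class <- NULL
  switch(cls,
    optical_config = do.call(optical_config, obj),
    mla_config = {
      obj$relay_focal_lengths <- as.numeric(unlist(obj$relay_focal_lengths))
      do.call(mla_config, obj)
    },
    stop("unknown config class: ", cls, call. = FALSE))
}

#' @export
print.optical_config <- function(x, ...) {
  cat(sprintf("<optical_config> NA=%.2f M=%gx lambda=%g nm n=%.3f\n",
              x$numerical_aperture, x$magnification, x$wavelength,
              x$refractive_index))
  cat(sprintf("  depth: %g..%g um (%d planes); grid %d px @ %.3f um\n",
              min(x$depth_grid), max(x$depth_grid), length(x$depth_grid),
              x$lateral_grid_extent, x$lateral_grid_spacing))
  invisible(x)
}

#' @export
print.mla_config <- function(x, ...) {
  cat(sprintf("<mla_config> pitch=%g um f=%g um n_pix=%d\n",
              x$pitch, x$focal_length, x$n_pix))
  invisible(x)
}
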