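#' Complex scalar wavefront on a square grid
#'
#' Container for a monochromatic complex amplitude sampled on a uniform,
#' FFT-centred square grid: sample `i` (0-based) sits at `(i - n/2) * spacing`,
#' so the origin is an actual sample and the grid is closed under the discrete
#' Fourier transform conventions used throughout.
#'
#' @param values Square complex (or numeric) matrix, rows = y, cols = x.
#' @param spacing Grid pitch in um.
#' @param wavelength Wavelength tag in nm.
#' @return An object of class `complex_field`.
#' @export
complex_field <- function(values, spacing, wavelength) {
  if (!is.matrix(values) || nrow(values) != ncol(values))
    stop("complex_field requires a square matrix", call. = FALSE)
  if (!all(is.finite(Re(values))) || !all(is.finite(Im(values))))
    stop("complex_field values must be finite", call. = FALSE)
  storage.mode(values) <- "complex"
  structure(list(values = values, spacing = spacing, wavelength = wavelength),
            class = "complex_field")
}

#' @export
print.complex_field <- function(x, ...) {
  cat(sprintf("<complex_field> %dx%d @ %.4g um, lambda=%g nm, energy=%.4g\n",
              nrow(x$values), ncol(x$values), x$spacing, x$wavelength,
              field_energy(x)))
  invisible(x)
}

#' Field energy
#'
#' Discrete energy \eqn{\sum |U|^2 \Delta^2} of a sampled wavefront.
#' @param field A `complex_field`.
#' @return Scalar energy.
#' @export
field_energy <- function(field) {
  sum(Mod(field$values)^2) * field$spacing^2
}

# centred grid coordinates in um for an n-sample axis
grid_coords <- function(n, spacing) (seq_len(n) - 1 - n %/% 2) * spacing

#' Radial Debye focal-field profile
#'
#' Evaluates the scalar Debye integral
#' \deqn{U_b(r) = \int_0^{\theta_{max}} U_o(\theta) J_0(2\pi r \sin\theta/\lambda)
#'   \sin\theta \, d\theta}
#' by Gauss-Legendre quadrature, with the defocus phase
#' \eqn{\exp(i 2\pi n z \cos\theta / \lambda)} of a source at axial position `z`
#' folded into \eqn{U_o}. The aperture half-angle is
#' \eqn{\theta_{max} = \arcsin(NA/n)}.
#'
#' @param config An `optical_config`.
#' @param source_depth Axial source position z in um.
#' @param radii Radial positions (um) at which to evaluate.
#' @param n_nodes Number of quadrature nodes (default 256).
#' @param apodization Optional function of theta giving the pupil apodization
#'   \eqn{U_o(\theta)} before the defocus term; default is the uniform pupil.
#' @return Complex vector of `length(radii)`.
#' @export
debye_radial <- function(config, source_depth, radii, n_nodes = 256,
                         apodization = NULL) {
  na <- config$numerical_aperture
  n <- config$refractive_index
  if (na >= n) stop("invalid-config: NA must be < refractive index", call. = FALSE)
  lambda <- config$wavelength / 1000  # nm -> um
  theta_max <- asin(na / n)
  if (theta_max >= pi / 2) stop("invalid-config: aperture half-angle >= pi/2",
                                call. = FALSE)
  if (theta_max <= 0) return(complex(length(radii)))
  gl <- pracma::gaussLegendre(n_nodes, 0, theta_max)
  theta <- gl$x
  apod <- if (is.null(apodization)) rep(1, n_nodes) else apodization(theta)
  uo <- apod * exp(2i * pi * n * source_depth * cos(theta) / lambda)
  wgt <- gl$w * uo * sin(theta)
  # J0(2 pi r sin(theta) / lambda) for all (r, theta) pairs
  arg <- outer(radii, 2 * pi * sin(theta) / lambda)
  out <- as.vector(besselJ(abs(arg), 0) %*% wgt)
  if (!all(is.finite(Re(out))) || !all(is.finite(Im(out))))
    stop("numerical error: Debye quadrature produced non-finite values",
         call. = FALSE)
  out
}

#' Debye wavefront of a point source
#'
#' Samples the radially symmetric Debye focal field of a point source at the
#' given depth onto the configured lateral grid.
#'
#' @inheritParams debye_radial
#' @param grid_extent Optional override of the grid size in samples.
#' @param grid_spacing Optional override of the grid pitch in um.
#' @return A `complex_field`.
#' @export
debye_wavefront <- function(config, source_depth, n_nodes = 256,
                            apodization = NULL, grid_extent = NULL,
                            grid_spacing = NULL) {
  zr <- range(config$depth_grid)
  if (source_depth < zr[1] - 1e-9 || source_depth > zr[2] + 1e-9)
    stop("source_depth outside the configured depth range", call. = FALSE)
  n_grid <- if (is.null(grid_extent)) config$lateral_grid_extent else grid_extent
  dx <- if (is.null(grid_spacing)) config$lateral_grid_spacing else grid_spacing
  xs <- grid_coords(n_grid, dx)
  r <- sqrt(outer(xs^2, xs^2, "+"))
  # evaluate once per distinct radius so radial symmetry is exact
  key <- signif(r, 12)
  ru <- sort(unique(as.vector(key)))
  prof <- debye_radial(config, source_depth, ru, n_nodes, apodization)
  vals <- matrix(prof[match(as.vector(key), ru)], n_grid, n_grid)
  complex_field(vals, dx, config$wavelength)
}

#' Super-Gaussian aperture transmission profile
#'
#' Transmission \eqn{P(\rho) = \exp(-(\rho/\lambda_c)^{2\alpha})}: a smooth
#' clipping window of radius `cutoff` whose edge sharpens as `order` grows
#' (large `order` approaches the indicator of the disk \eqn{\rho < \lambda_c}).
#'
#' @param rho_grid Non-negative radial coordinates (same units as `cutoff`).
#' @param cutoff Clipping radius \eqn{\lambda_c} (> 0).
#' @param order Super-Gaussian order \eqn{\alpha \ge 1}.
#' @return An object of class `aperture_profile` with fields `transmission`,
#'   `rho`, `cutoff`, `order`.
#' @export
aperture_profile <- function(rho_grid, cutoff, order = 1) {
  if (cutoff <= 0) stop("invalid-config: cutoff must be > 0", call. = FALSE)
  if (order < 1) stop("invalid-config: order must be >= 1", call. = FALSE)
  p <- exp(-(rho_grid / cutoff)^(2 * order))
  structure(list(transmission = p, rho = rho_grid, cutoff = cutoff,
                 order = order),
            class = "aperture_profile")
}

#' Apply an aperture transmission to a wavefront
#'
#' Pointwise product \eqn{U_{AS} = U_b \cdot P}; since \eqn{0 \le P \le 1} the
#' output energy never exceeds the input energy.
#'
#' @param field A `complex_field`.
#' @param profile An `aperture_profile` sampled on the field grid (its
#'   `transmission` must match the field dimensions), or a numeric matrix.
#' @return A `complex_field`.
#' @export
apply_aperture <- function(field, profile) {
  p <- if (inherits(profile, "aperture_profile")) profile$transmission else profile
  if (!all(dim(p) == dim(field$values)))
    stop("shape error: aperture grid does not match field grid", call. = FALSE)
  complex_field(field$values * p, field$spacing, field$wavelength)
}

#' Microlens-array transmission function
#'
#' Pure-phase mask, periodic with the lenslet pitch: each tile carries the
#' thin-lens phase \eqn{\exp(-i\pi (x'^2+y'^2)/(\lambda f_{ml}))} about its
#' lenslet centre, with lenslet centres on integer multiples of the pitch.
#'
#' @param mla An `mla_config`.
#' @param grid_extent Grid size in samples.
#' @param spacing Grid pitch in um; must divide the lenslet pitch to within 0.5%.
#' @param wavelength Wavelength in nm.
#' @return A `complex_field` with unit-magnitude values.
#' @export
mla_transmission <- function(mla, grid_extent, spacing, wavelength) {
  if (mla$pitch < 2 * spacing)
    stop("undersampling error: lenslet pitch smaller than 2 grid samples",
         call. = FALSE)
  ratio <- mla$pitch / spacing
  if (abs(ratio - round(ratio)) > 0.005 * ratio)
    stop("grid spacing must divide the lenslet pitch to within 0.5%",
         call. = FALSE)
  lambda <- wavelength / 1000
  xs <- grid_coords(grid_extent, spacing)
  xp <- xs - round(xs / mla$pitch) * mla$pitch   # lenslet-relative coordinate
  phase <- outer(xp^2, xp^2, "+") * (-pi / (lambda * mla$focal_length))
  complex_field(exp(1i * phase), spacing, wavelength)
}

#' Angular-spectrum free-space propagation
#'
#' Propagates a sampled wavefront over `distance` with the band-limited
#' angular-spectrum kernel
#' \eqn{H(f_x,f_y) = \exp(i 2\pi d \sqrt{1/\lambda^2 - f_x^2 - f_y^2})},
#' zeroing evanescent components. By default the field is zero-padded to twice
#' its extent before the transform to suppress wraparound, and cropped back.
#'
#' @param field A `complex_field`.
#' @param distance Propagation distance in um (may be negative).
#' @param pad Zero-pad to 2x extent before transforming (default TRUE).
#' @return A `complex_field` on the original grid.
#' @export
propagate_angular_spectrum <- function(field, distance, pad = TRUE) {
  n0 <- nrow(field$values)
  lambda <- field$wavelength / 1000
  v <- field$values
  if (pad) {
    n <- 2L * n0
    big <- matrix(0 + 0i, n, n)
    idx <- (n0 %/% 2 + 1):(n0 %/% 2 + n0)
    big[idx, idx] <- v
    v <- big
  } else n <- n0
  f1 <- c(0:(n %/% 2 - 1), -(n %/% 2):-1) / (n * field$spacing)
  fsq <- outer(f1^2, f1^2, "+")
  root <- 1 / lambda^2 - fsq
  h <- ifelse(root > 0, exp(2i * pi * distance * sqrt(pmax(root, 0))), 0 + 0i)
  out <- stats::fft(stats::fft(v) * h, inverse = TRUE) / length(v)
  if (pad) {
    idx <- (n0 %/% 2 + 1):(n0 %/% 2 + n0)
    out <- out[idx, idx]
  }
  complex_field(out, field$spacing, field$wavelength)
}

#' Band-limit a wavefront with the sinc anti-aliasing filter
#'
#' Multiplies the field spectrum by the transform of the radial kernel
#' \eqn{\mathrm{sinc}(2\rho/\lambda_c)}, which is band-limited to radial
#' frequency \eqn{1/\lambda_c}; the response is normalised to unit passband
#' gain (ideal radial low-pass), which makes the filter idempotent and
#' suppresses all content beyond the cutoff.
#'
#' @param field A `complex_field`.
#' @param cutoff Spatial cutoff parameter \eqn{\lambda_c} in um (> 0); the
#'   frequency cutoff is \eqn{1/\lambda_c} cycles/um.
#' @return A `complex_field`.
#' @export
flfm_bandlimit <- function(field, cutoff) {
  if (cutoff <= 0) stop("invalid-config: cutoff must be > 0", call. = FALSE)
  n <- nrow(field$values)
  f1 <- c(0:(n %/% 2 - 1), -(n %/% 2):-1) / (n * field$spacing)
  fr <- sqrt(outer(f1^2, f1^2, "+"))
  h <- ifelse(fr < 1 / cutoff, 1 + 0i, 0 + 0i)
  out <- stats::fft(stats::fft(field$values) * h, inverse = TRUE) / n^2
  complex_field(out, field$spacing, field$wavelength)
}
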