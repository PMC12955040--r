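#' Project a 3D volume to an LFM 4D light field
#'
#' Linear forward model: the sensor image is
#' \eqn{I_{LFM} = \sum_z I_z * PSF_z} (per-depth 2D FFT convolution with zero
#' padding, 'same' output with the PSF source pixel as the convolution
#' centre), then rearranged into the 4D light field `L(u, v, w, h)` with
#' angular axes of size `n_pix` and spatial axes at lenslet resolution.
#'
#' @param vol Non-negative array `(z, y, x)`; the lateral size must be
#'   divisible by the PSF's `n_pix`.
#' @param psf An `lfm_psf` whose depth axis matches `vol`.
#' @return 4D light field array `(u, v, w, h)` with
#'   `w = y / n_pix`, `h = x / n_pix` lenslet samples.
#' @export
project_lfm <- function(vol, psf) {
  if (dim(vol)[2] %% psf$n_pix != 0 || dim(vol)[3] %% psf$n_pix != 0)
    stop("shape error: lateral size must be divisible by n_pix", call. = FALSE)
  sensor <- project_lfm_sensor(vol, psf)
  lfm_sensor_to_views(sensor, psf$n_pix)
}

#' @rdname project_lfm
#' @export
project_lfm_sensor <- function(vol, psf) {
  dims <- dim(vol)
  if (length(dims) != 3) stop("shape error: vol must be (z,y,x)", call. = FALSE)
  imgs <- psf$images
  if (dims[1] != dim(imgs)[1])
    stop("shape error: volume depth count does not match PSF", call. = FALSE)
  nz <- dims[1]; ny <- dims[2]; nx <- dims[3]
  s <- dim(imgs)[2]
  ctr <- psf$center
  py <- ny + s; px <- nx + s
  acc <- matrix(0 + 0i, py, px)
  for (zi in seq_len(nz)) {
    m <- matrix(0, py, px)
    m[1:ny, 1:nx] <- vol[zi, , ]
    k <- matrix(0, py, px)
    k[1:s, 1:s] <- imgs[zi, , ]
    acc <- acc + stats::fft(m) * stats::fft(k)
  }
  full <- Re(stats::fft(acc, inverse = TRUE)) / (py * px)
  full[ctr:(ctr + ny - 1), ctr:(ctr + nx - 1)]
}

#' Project a 3D volume to an FLFM sensor image and view stack
#'
#' Frequency-domain forward model
#' \eqn{I = F^{-1}\{\sum_z w(z) F\{I_z\} H_z\}} on the `3V x 3V` sensor
#' mosaic, where `H_z` is the stored per-depth transfer function and `w(z)`
#' the complex depth weight. The imaginary residue of the inverse transform is
#' recorded (attribute `imag_residue`, warning above `residue_tol`) and
#' discarded; negative intensities are clipped with the clipped mass logged
#' (attribute `clipped_mass`).
#'
#' @param vol Non-negative array `(z, y, x)` with `y = x = view_size`.
#' @param psf An `flfm_psf`.
#' @param residue_tol Relative imaginary-residue warning threshold.
#' @return An object of class `flfm_view_stack`: array `(7, V, V)` in 2-3-2
#'   row order, with attributes `sensor` (the raw `3V x 3V` image),
#'   `view_corners`, `imag_residue`, `clipped_mass`.
#' @export
project_flfm <- function(vol, psf, residue_tol = 1e-8) {
  dims <- dim(vol)
  if (length(dims) != 3) stop("shape error: vol must be (z,y,x)", call. = FALSE)
  nz <- dim(psf$freq_response)[3]
  if (dims[1] != nz)
    stop("shape error: volume depth count does not match PSF", call. = FALSE)
  v <- psf$view_size
  if (dims[2] != v || dims[3] != v)
    stop("shape error: lateral size must equal the PSF view size", call. = FALSE)
  s <- 3L * v
  acc <- matrix(0 + 0i, s, s)
  for (zi in seq_len(nz)) {
    m <- matrix(0, s, s)
    m[1:v, 1:v] <- vol[zi, , ]
    acc <- acc + psf$weights[zi, 1, 1] * stats::fft(m) * psf$freq_response[, , zi]
  }
  img_c <- stats::fft(acc, inverse = TRUE) / (s * s)
  denom <- sqrt(sum(Mod(img_c)^2))
  residue <- if (denom > 0) sqrt(sum(Im(img_c)^2)) / denom else 0
  if (residue > residue_tol)
    warning(sprintf("FLFM image imaginary residue %.3g exceeds %.3g",
                    residue, residue_tol), call. = FALSE)
  raw <- Re(img_c)
  clipped <- -sum(raw[raw < 0])
  img <- pmax(raw, 0)
  out <- flfm_views(img, flfm_geometry(psf))
  attr(out, "sensor") <- img
  attr(out, "sensor_raw") <- raw       # pre-clip image: the linear model output
  attr(out, "imag_residue") <- residue
  attr(out, "clipped_mass") <- clipped
  out
}

#' View-window geometry of an FLFM point-spread function
#' @param psf An `flfm_psf`.
#' @return List with `view_corners` (0-based top-left corners, row-major
#'   2-3-2 order) and `view_size`.
#' @export
flfm_geometry <- function(psf) {
  list(view_corners = psf$view_corners, view_size = psf$view_size)
}

#' Crop an FLFM sensor image into its seven 2-3-2 sub-aperture views
#'
#' @param sensor_image Matrix, the raw sensor mosaic.
#' @param geometry List with `view_corners` (0-based) and `view_size`, e.g.
#'   from [flfm_geometry()].
#' @return An `flfm_view_stack`: array `(7, V, V)` in 2-3-2 row order
#'   (top-left to bottom-right).
#' @export
flfm_views <- function(sensor_image, geometry) {
  v <- geometry$view_size
  corners <- geometry$view_corners
  if (length(corners) != 7)
    stop("geometry error: expected seven 2-3-2 view corners", call. = FALSE)
  out <- array(0, dim = c(7, v, v))
  for (k in 1:7) {
    r0 <- corners[[k]][1]; c0 <- corners[[k]][2]
    if (r0 < 0 || c0 < 0 || r0 + v > nrow(sensor_image) ||
        c0 + v > ncol(sensor_image))
      stop("geometry error: view crop outside sensor bounds", call. = FALSE)
    out[k, , ] <- sensor_image[(r0 + 1):(r0 + v), (c0 + 1):(c0 + v)]
  }
  structure(out, class = "flfm_view_stack", view_corners = corners,
            view_size = v)
}

#' Reassemble an FLFM sensor mosaic from its view stack
#'
#' Places the seven view crops back into their (disjoint) windows on a zero
#' `3V x 3V` mosaic; the sensor area outside the view windows is lost.
#'
#' @param views An `flfm_view_stack`.
#' @return Matrix `(3V, 3V)`.
#' @export
flfm_views_to_sensor <- function(views) {
  v <- attr(views, "view_size")
  corners <- attr(views, "view_corners")
  out <- matrix(0, 3 * v, 3 * v)
  for (k in 1:7) {
    r0 <- corners[[k]][1]; c0 <- corners[[k]][2]
    out[(r0 + 1):(r0 + v), (c0 + 1):(c0 + v)] <- views[k, , ]
  }
  out
}

#' Stack light-field views as channels
#'
#' Rearranges a 4D light field `(u, v, w, h)` into the channel stack
#' `(u*v, w, h)` with row-major ordering (`u` outer, `v` inner), so channel 1
#' is view `(u=1, v=1)`. The rearrangement is lossless; [lfm_views_inverse()]
#' restores the 4D array bit-exactly.
#'
#' @param lf 4D array `(u, v, w, h)`.
#' @return 3D array `(u*v, w, h)`.
#' @export
lfm_views <- function(lf) {
  d <- dim(lf)
  stopifnot(length(d) == 4)
  out <- aperm(lf, c(2, 1, 3, 4))   # column-major: v fastest => c = (u-1)*V + v
  dim(out) <- c(d[1] * d[2], d[3], d[4])
  out
}

#' @rdname lfm_views
#' @param stack 3D array `(u*v, w, h)`.
#' @param n_u,n_v Angular dimensions of the original light field.
#' @export
lfm_views_inverse <- function(stack, n_u, n_v) {
  d <- dim(stack)
  stopifnot(length(d) == 3, d[1] == n_u * n_v)
  dim(stack) <- c(n_v, n_u, d[2], d[3])
  aperm(stack, c(2, 1, 3, 4))
}
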