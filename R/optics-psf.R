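#' Light-field microscope 5D point-spread function
#'
#' Computes the depth-indexed LFM response as a 5D tensor
#' `psf$values[z, w, h, u, v]`: the sensor-plane intensity patch of a point
#' source at the centre of the field, over a `n_lenslets x n_lenslets`
#' microlens patch with `n_pix x n_pix` sensor pixels per lenslet, rearranged
#' so `(w, h)` index the lenslet (spatial sample) and `(u, v)` the pixel
#' within the lenslet (angular sample, `u`/`h` along x, `v`/`w` along y). For
#' each depth the Debye focal field is relayed to the microlens plane,
#' modulated by the MLA phase, propagated one lenslet focal length, and
#' squared. The simulation runs on an odd, mirror-closed lenslet-aligned grid,
#' on which the optical point symmetry PSF(x,y,z) = PSF(-x,-y,z) holds
#' exactly, and is cropped to the stored patch. Each depth slice is
#' normalised to unit sum so forward projection conserves flux per plane.
#'
#' @param config An `optical_config` (see [lfm_optics_preset()]).
#' @param mla An `mla_config` (see [lfm_mla_preset()]).
#' @param n_lenslets Lenslets per axis of the stored patch (even, default 16).
#' @param n_nodes Quadrature nodes for the Debye integral.
#' @param apodization Optional pupil apodization function of theta.
#' @param oversample Odd sub-pixel sampling factor of the wavefront relative
#'   to the sensor pixel; intensities are integrated (binned) over each pixel.
#'   The default 3 resolves the lenslet focal spots, which are about one
#'   sensor pixel wide.
#' @return An object of class `lfm_psf`: list with the 5D non-negative array
#'   `values` of dimension `(n_z, n_lenslets, n_lenslets, n_pix, n_pix)`,
#'   the equivalent per-depth sensor `images` `(n_z, N, N)` with
#'   `N = n_lenslets * n_pix`, the source pixel index `center`
#'   (the central pixel of lenslet `n_lenslets/2 + 1`), `depth_grid`,
#'   `n_pix`, and the object-space pixel pitch `voxel_pitch` (um) at which
#'   projected volumes are sampled.
#' @export
compute_lfm_psf <- function(config, mla, n_lenslets = 16, n_nodes = 256,
                            apodization = NULL, oversample = 3) {
  if (n_lenslets %% 2 != 0) stop("n_lenslets must be even", call. = FALSE)
  os <- as.integer(oversample)
  if (os < 1 || os %% 2 != 1) stop("oversample must be a positive odd integer",
                                   call. = FALSE)
  np <- mla$n_pix
  dp <- mla$pitch / np / os                 # wavefront sampling pitch
  m <- config$magnification
  nz <- length(config$depth_grid)
  # odd lenslet-aligned computational grid, closed under negation, centred on
  # a lenslet centre
  ng <- (n_lenslets + 1L) * np * os         # e.g. 561 for the reference preset
  xs <- grid_coords(ng, dp)
  tmask <- mla_transmission(mla, ng, dp, config$wavelength)$values
  npad <- 2L * ng
  idx <- (ng %/% 2 + 1):(ng %/% 2 + ng)
  lambda <- config$wavelength / 1000
  f1 <- c(0:(npad %/% 2 - 1), -(npad %/% 2):-1) / (npad * dp)
  root <- 1 / lambda^2 - outer(f1^2, f1^2, "+")
  hker <- ifelse(root > 0, exp(2i * pi * mla$focal_length * sqrt(pmax(root, 0))),
                 0 + 0i)
  # bin samples into sensor pixels and keep the first n_lenslets complete
  # lenslet blocks (the grid holds n_lenslets + 1), so pixel rows align with
  # lenslet boundaries; the source then sits at the central pixel of lenslet
  # n_lenslets/2 + 1
  n_img <- n_lenslets * np
  ctr_odd <- ng %/% 2 + 1L
  pixel <- floor((seq_len(ng) - ctr_odd + os %/% 2) / os)
  half_pix <- ((n_lenslets + 1L) %/% 2L) * np + np %/% 2L   # e.g. 93
  keep <- pixel >= -half_pix & pixel <= n_img - half_pix - 1L
  grp <- factor(pixel[keep], levels = -half_pix:(n_img - half_pix - 1L))
  center <- (n_lenslets %/% 2L) * np + (np + 1L) %/% 2L     # e.g. 94
  rmax <- max(abs(xs)) * sqrt(2) / m
  # resolve the focal-field oscillation scale lambda/(2 NA) with ~8 samples
  dr <- lambda / (2 * config$numerical_aperture) / 8
  rgrid <- seq(0, rmax * 1.02, length.out = max(1024, ceiling(rmax / dr)))
  r <- sqrt(outer(xs^2, xs^2, "+")) / m
  psf <- array(0, dim = c(nz, n_lenslets, n_lenslets, np, np))
  imgs <- array(0, dim = c(nz, n_img, n_img))
  for (zi in seq_len(nz)) {
    prof <- debye_radial(config, config$depth_grid[zi], rgrid, n_nodes,
                         apodization)
    u <- matrix(interp_complex(rgrid, prof, r), ng, ng) * tmask
    big <- matrix(0 + 0i, npad, npad)
    big[idx, idx] <- u
    sens <- stats::fft(stats::fft(big) * hker, inverse = TRUE)[idx, idx]
    inten <- Mod(sens)^2
    binned <- t(rowsum(t(rowsum(inten[keep, keep], grp)), grp))
    tot <- sum(binned)
    if (tot > 0) binned <- binned / tot
    imgs[zi, , ] <- binned
    psf[zi, , , , ] <- lfm_sensor_to_views(binned, np, four_d = FALSE)
  }
  structure(list(values = psf, images = imgs, depth_grid = config$depth_grid,
                 n_pix = np, center = center, voxel_pitch = dp * os / m),
            class = "lfm_psf")
}

#' Rearrange an LFM sensor image into lenslet/pixel indices
#'
#' A sensor patch of `n_lenslets * n_pix` pixels per axis is split into the
#' 4D light field `L[u, v, w, h]` (`u, v` = pixel within lenslet along x and
#' y; `w, h` = lenslet index along y and x), or into the 5D PSF layout
#' `(w, h, u, v)` when `four_d = FALSE`. [lfm_views_to_sensor()] inverts the
#' 4D rearrangement bit-exactly.
#'
#' @param sensor Square matrix with side divisible by `n_pix`.
#' @param n_pix Pixels per lenslet.
#' @param four_d Return `(u, v, w, h)` (default) or `(w, h, u, v)`.
#' @return 4D array.
#' @export
lfm_sensor_to_views <- function(sensor, n_pix, four_d = TRUE) {
  n <- nrow(sensor)
  nl <- n %/% n_pix
  stopifnot(nl * n_pix == n, ncol(sensor) == n)
  a <- array(sensor, dim = c(n_pix, nl, n_pix, nl))   # (v, w, u, h) col-major
  if (four_d) aperm(a, c(3, 1, 2, 4)) else aperm(a, c(2, 4, 3, 1))
}

#' @rdname lfm_sensor_to_views
#' @param lf 4D light field `(u, v, w, h)`.
#' @export
lfm_views_to_sensor <- function(lf) {
  d <- dim(lf)
  a <- aperm(lf, c(2, 3, 1, 4))                       # (v, w, u, h)
  matrix(a, d[1] * d[3], d[2] * d[4])
}

# linear interpolation of a complex radial profile
interp_complex <- function(rgrid, prof, r) {
  i <- findInterval(r, rgrid, all.inside = TRUE)
  t <- (r - rgrid[i]) / (rgrid[i + 1] - rgrid[i])
  prof[i] * (1 - t) + prof[i + 1] * t
}

#' @export
print.lfm_psf <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<lfm_psf> dims (%s); depth %g..%g um\n",
              paste(d, collapse = ","), min(x$depth_grid), max(x$depth_grid)))
  invisible(x)
}

# top-left corners (0-based) of the seven 2-3-2 view windows on the 3V mosaic
flfm_view_corners <- function(view_size) {
  v <- view_size
  list(c(0, v %/% 2), c(0, v + v %/% 2),
       c(v, 0), c(v, v), c(v, 2 * v),
       c(2 * v, v %/% 2), c(2 * v, v + v %/% 2))
}

# pupil-offset layout of the 2-3-2 views in units of the lenslet pitch (x, y)
flfm_view_offsets <- function() {
  list(c(-0.5, 1), c(0.5, 1),
       c(-1, 0), c(0, 0), c(1, 0),
       c(-0.5, -1), c(0.5, -1))
}

#' Fourier light-field microscope frequency-domain point-spread function
#'
#' Builds, per depth, the sensor-plane response of the seven-view (2-3-2)
#' Fourier light-field system, stored as a frequency-domain transfer stack
#' plus complex depth weights `w(z)`. For each depth the Debye focal field is
#' computed on the reconstruction voxel grid (with the aperture half-angle
#' capped at the grid's representable band so the sampled field is alias-free),
#' windowed by the aperture transmission, band-limited with the sinc
#' anti-aliasing filter, and split into seven sub-aperture views by circular
#' frequency masks laid out in the 2-3-2 pattern scaled from the microlens
#' pitch and relay magnification fR2/fR1. View intensities are placed on a
#' `3V x 3V` sensor mosaic, normalised to unit sum, and transformed; the
#' complex weight `w(z)` is the normalised inner product between the processed
#' depth-z field and the in-focus field (so `w(0) = 1` and `w` acquires an
#' imaginary part off focus).
#'
#' @param config An `optical_config` (see [flfm_optics_preset()]).
#' @param mla An `mla_config` (see [flfm_mla_preset()]).
#' @param aperture Optional `aperture_profile`; its transmission is evaluated
#'   at the normalised focal-plane radius `rho = r / (V/2 voxels)`.
#' @param view_size V, the per-view image size in pixels (even).
#' @param voxel_pitch Lateral voxel pitch of the reconstruction grid in um.
#' @param n_nodes Quadrature nodes for the Debye integral.
#' @param band_fraction Fraction of the Nyquist band used (default 0.95).
#' @return An object of class `flfm_psf`: `freq_response` complex array
#'   `(3V, 3V, n_z)` whose per-depth inverse transform is real (Hermitian),
#'   `weights` complex array `(n_z, 1, 1)`, `view_corners`, `view_size`,
#'   `depth_grid`, `voxel_pitch`.
#' @export
compute_flfm_psf <- function(config, mla, aperture = NULL, view_size = 64,
                             voxel_pitch = 0.34, n_nodes = 256,
                             band_fraction = 0.95) {
  v <- as.integer(view_size)
  if (v %% 2 != 0) stop("view_size must be even", call. = FALSE)
  nz <- length(config$depth_grid)
  lambda <- config$wavelength / 1000
  n_ref <- config$refractive_index
  # cap the aperture half-angle at the representable band of the voxel grid
  f_max <- band_fraction / (2 * voxel_pitch)
  sin_cap <- min(config$numerical_aperture / n_ref, lambda * f_max / n_ref)
  theta_cap <- asin(sin_cap)
  apod <- function(theta) as.numeric(theta <= theta_cap)
  # aperture transmission on the focal grid, rho normalised to half-extent
  ap_mat <- NULL
  if (!is.null(aperture)) {
    xs <- grid_coords(v, voxel_pitch)
    rho <- sqrt(outer(xs^2, xs^2, "+")) / (v / 2 * voxel_pitch)
    ap_mat <- aperture_profile(rho, aperture$cutoff, aperture$order)$transmission
  }
  # sinc band limit: frequency cutoff at f_max  =>  spatial cutoff 1/f_max
  lc <- 1 / f_max
  # sub-aperture frequency layout: the 2-3-2 footprint (radius 1.5 pitches,
  # relayed by fR2/fR1) is mapped onto the representable band
  f_per_pitch <- f_max / 1.5
  f_sub <- 0.5 * f_per_pitch
  f1 <- c(0:(v %/% 2 - 1), -(v %/% 2):-1) / (v * voxel_pitch)
  fx <- matrix(f1, v, v, byrow = TRUE)
  fy <- matrix(f1, v, v)
  offs <- flfm_view_offsets()
  masks <- lapply(offs, function(o) {
    (fx - o[1] * f_per_pitch)^2 + (fy - o[2] * f_per_pitch)^2 < f_sub^2
  })
  corners <- flfm_view_corners(v)
  s <- 3L * v
  freq <- array(0 + 0i, dim = c(s, s, nz))
  fields <- vector("list", nz)
  for (zi in seq_len(nz)) {
    fld <- debye_wavefront(config, config$depth_grid[zi], n_nodes = n_nodes,
                           apodization = apod, grid_extent = v,
                           grid_spacing = voxel_pitch)
    if (!is.null(ap_mat)) fld <- apply_aperture(fld, ap_mat)
    fld <- flfm_bandlimit(fld, lc)
    fields[[zi]] <- fld$values
    g <- stats::fft(fld$values)
    comp <- matrix(0, s, s)
    for (k in seq_along(masks)) {
      a <- stats::fft(g * masks[[k]], inverse = TRUE) / v^2
      inten <- Mod(a)^2
      # paste so the view's point response is centred at corner + V/2
      ri <- ((corners[[k]][1] + 0:(v - 1)) %% s) + 1
      ci <- ((corners[[k]][2] + 0:(v - 1)) %% s) + 1
      comp[ri, ci] <- comp[ri, ci] + inten
    }
    tot <- sum(comp)
    if (tot > 0) comp <- comp / tot
    # shift so a source at slice index (1,1) responds at the view corners
    comp <- circ_shift2(comp, -(v %/% 2), -(v %/% 2))
    freq[, , zi] <- stats::fft(comp)
  }
  # complex depth weights: inner product with the field at the in-focus plane
  zi0 <- which.min(abs(config$depth_grid))
  norm0 <- sum(Mod(fields[[zi0]])^2)
  wts <- array(0 + 0i, dim = c(nz, 1, 1))
  for (zi in seq_len(nz))
    wts[zi, 1, 1] <- sum(Conj(fields[[zi0]]) * fields[[zi]]) / norm0
  structure(list(freq_response = freq, weights = wts, view_corners = corners,
                 view_size = v, depth_grid = config$depth_grid,
                 voxel_pitch = voxel_pitch),
            class = "flfm_psf")
}

# circular 2D shift by (dy, dx) grid samples
circ_shift2 <- function(m, dy, dx) {
  n1 <- nrow(m); n2 <- ncol(m)
  m[((seq_len(n1) - 1 - dy) %% n1) + 1, ((seq_len(n2) - 1 - dx) %% n2) + 1]
}

#' @export
print.flfm_psf <- function(x, ...) {
  cat(sprintf("<flfm_psf> %d depths, view %dx%d (2-3-2), weights (%s)\n",
              length(x$depth_grid), x$view_size, x$view_size,
              paste(dim(x$weights), collapse = ",")))
  invisible(x)
}
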