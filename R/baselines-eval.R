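# Richardson-Lucy baseline, PSNR/SSIM metrics and visual diagnostics.

# pad-and-fft helper
fft_pad <- function(m, py, px) {
  big <- matrix(0, py, px)
  big[seq_len(nrow(m)), seq_len(ncol(m))] <- m
  stats::fft(big)
}

# adjoint of project_lfm_sensor: per-depth correlation with the PSF image
lfm_adjoint <- function(sensor, psf) {
  imgs <- psf$images
  nz <- dim(imgs)[1]; s <- dim(imgs)[2]
  ny <- nrow(sensor); nx <- ncol(sensor)
  ctr <- psf$center
  py <- ny + s; px <- nx + s
  rows <- ((seq_len(ny) - ctr) %% py) + 1
  cols <- ((seq_len(nx) - ctr) %% px) + 1
  fs <- fft_pad(sensor, py, px)
  vol <- array(0, dim = c(nz, ny, nx))
  for (zi in seq_len(nz)) {
    kf <- fft_pad(imgs[zi, , ], py, px)
    corr <- Re(stats::fft(fs * Conj(kf), inverse = TRUE)) / (py * px)
    vol[zi, , ] <- corr[rows, cols]
  }
  vol
}

# linear FLFM forward (real sensor image, no clipping) and adjoint
flfm_forward_linear <- function(vol, psf) {
  nz <- dim(psf$freq_response)[3]
  v <- psf$view_size; s <- 3L * v
  acc <- matrix(0 + 0i, s, s)
  for (zi in seq_len(nz)) {
    m <- matrix(0, s, s)
    m[1:v, 1:v] <- vol[zi, , ]
    acc <- acc + psf$weights[zi, 1, 1] * stats::fft(m) * psf$freq_response[, , zi]
  }
  Re(stats::fft(acc, inverse = TRUE)) / (s * s)
}

flfm_adjoint <- function(sensor, psf) {
  nz <- dim(psf$freq_response)[3]
  v <- psf$view_size; s <- 3L * v
  fs <- stats::fft(sensor)
  vol <- array(0, dim = c(nz, v, v))
  for (zi in seq_len(nz)) {
    g <- Conj(psf$weights[zi, 1, 1] * psf$freq_response[, , zi]) * fs
    full <- Re(stats::fft(g, inverse = TRUE)) / (s * s)
    vol[zi, , ] <- full[1:v, 1:v]
  }
  vol
}

#' Richardson-Lucy deconvolution of a light-field measurement
#'
#' Multiplicative maximum-likelihood updates
#' \eqn{x \leftarrow x \cdot A^T(m / A x) / A^T 1} with the forward projector
#' `A` of the chosen modality and its exact (matched transpose) adjoint.
#' Iterates stay non-negative; on noiseless non-negative data the
#' I-divergence between the measurement and its reprojection is
#' non-increasing.
#'
#' @param measurement For `modality = "lfm"` a 4D light field `(u, v, w, h)`;
#'   for `"flfm"` the raw sensor image matrix (e.g. `attr(views, "sensor")`).
#' @param psf The matching `lfm_psf` or `flfm_psf`.
#' @param n_iter Number of RL iterations (>= 1).
#' @param modality `"lfm"` or `"flfm"`.
#' @param init Optional non-negative starting volume (default uniform).
#' @param eps Ratio-protection floor.
#' @return Non-negative volume `(z, y, x)`.
#' @export
rl_deconvolve <- function(measurement, psf, n_iter = 30,
                          modality = c("lfm", "flfm"), init = NULL,
                          eps = 1e-12) {
  modality <- match.arg(modality)
  if (n_iter < 1) stop("n_iter must be >= 1", call. = FALSE)
  if (min(measurement) < -1e-9)
    stop("invalid input: measurement must be non-negative", call. = FALSE)
  if (modality == "lfm") {
    if (sum(psf$values) <= 0) stop("invalid input: zero PSF", call. = FALSE)
    if (length(dim(measurement)) == 4)
      measurement <- lfm_views_to_sensor(measurement)
    nz <- dim(psf$values)[1]
    ny <- nrow(measurement); nx <- ncol(measurement)
    fwd <- function(x) project_lfm_sensor(x, psf)
    adj <- function(y) lfm_adjoint(y, psf)
    ones <- matrix(1, ny, nx)
  } else {
    if (sum(Mod(psf$freq_response)) <= 0)
      stop("invalid input: zero PSF", call. = FALSE)
    nz <- dim(psf$freq_response)[3]; ny <- nx <- psf$view_size
    fwd <- function(x) flfm_forward_linear(x, psf)
    adj <- function(y) flfm_adjoint(y, psf)
    ones <- matrix(1, 3 * psf$view_size, 3 * psf$view_size)
  }
  norm <- adj(ones)
  norm[norm < eps] <- eps
  x <- if (is.null(init)) array(mean(measurement) + eps, dim = c(nz, ny, nx))
  else init
  m <- pmax(measurement, 0)
  for (it in seq_len(n_iter)) {
    ax <- pmax(fwd(x), 0)
    ratio <- m / pmax(ax, eps)
    ratio[m == 0 & ax <= eps] <- 0
    x <- x * adj(ratio) / norm
    x <- pmax(x, 0)
  }
  x
}

#' I-divergence between a measurement and its reprojection
#'
#' \eqn{D(m \| p) = \sum m \log(m/p) - m + p}, the Csiszar divergence that
#' Richardson-Lucy descends on noiseless data.
#'
#' @param measurement,reprojection Non-negative arrays of equal shape.
#' @param eps Protection floor inside the logarithm.
#' @return Scalar divergence.
#' @export
i_divergence <- function(measurement, reprojection, eps = 1e-12) {
  m <- pmax(measurement, 0)
  p <- pmax(reprojection, eps)
  sum(ifelse(m > 0, m * log(m / p) - m + p, p))
}

#' Peak signal-to-noise ratio
#'
#' \eqn{10 \log_{10}(L^2 / MSE)} in dB; identical inputs give `Inf`.
#'
#' @param x,ref Arrays of equal shape.
#' @param data_range Dynamic range L (> 0); defaults to `max(ref)`.
#' @return PSNR in dB.
#' @export
psnr <- function(x, ref, data_range = max(ref)) {
  if (!all(dim(x) == dim(ref)))
    stop("shape error: inputs must have equal shapes", call. = FALSE)
  if (data_range <= 0) stop("data_range must be > 0", call. = FALSE)
  mse <- mean((x - ref)^2)
  if (mse == 0) return(Inf)
  10 * log10(data_range^2 / mse)
}

# separable valid-region Gaussian filtering matrices
gauss_band <- function(n, width, sigma) {
  g <- stats::dnorm(seq_len(width) - (width + 1) / 2, sd = sigma)
  g <- g / sum(g)
  m <- matrix(0, n - width + 1, n)
  for (i in seq_len(n - width + 1)) m[i, i:(i + width - 1)] <- g
  m
}

ssim_2d <- function(a, b, data_range, width = 7, sigma = 1.5) {
  k1 <- 0.01; k2 <- 0.03
  c1 <- (k1 * data_range)^2; c2 <- (k2 * data_range)^2
  gy <- gauss_band(nrow(a), width, sigma)
  gx <- gauss_band(ncol(a), width, sigma)
  f <- function(m) gy %*% m %*% t(gx)
  mu_a <- f(a); mu_b <- f(b)
  va <- f(a * a) - mu_a^2
  vb <- f(b * b) - mu_b^2
  cab <- f(a * b) - mu_a * mu_b
  num <- (2 * mu_a * mu_b + c1) * (2 * cab + c2)
  den <- (mu_a^2 + mu_b^2 + c1) * (va + vb + c2)
  mean(num / den)
}

#' Structural similarity index
#'
#' Standard SSIM with K1 = 0.01, K2 = 0.03 and a 7x7 Gaussian window
#' (sigma 1.5), computed per z-slice and averaged over depth. The default
#' dynamic range is the joint range of both inputs, making the measure
#' symmetric in its arguments; identical inputs give 1.
#'
#' @param x,ref Volumes `(z, y, x)` (or single matrices) of equal shape.
#' @param data_range Dynamic range; default `diff(range(c(x, ref)))`.
#' @return SSIM in `[-1, 1]`.
#' @export
ssim <- function(x, ref, data_range = NULL) {
  if (!all(dim(x) == dim(ref)))
    stop("shape error: inputs must have equal shapes", call. = FALSE)
  if (is.null(data_range)) data_range <- diff(range(c(x, ref)))
  if (data_range == 0) return(1)
  if (is.matrix(x)) return(ssim_2d(x, ref, data_range))
  mean(vapply(seq_len(dim(x)[1]),
              function(zi) ssim_2d(x[zi, , ], ref[zi, , ], data_range),
              numeric(1)))
}

#' Visual diagnostics of a reconstructed volume
#'
#' `depth_colormap` colours each lateral position by its argmax depth (hue)
#' with the maximum intensity as brightness; `projections` returns the three
#' maximum-intensity projections; `spectrum` the centred log-magnitude 2D
#' spectrum of one z-slice.
#'
#' @param vol Volume `(z, y, x)`.
#' @param mode One of `"depth_colormap"`, `"projections"`, `"spectrum"`.
#' @param slice_index Slice used by `"spectrum"` (default: middle).
#' @param file Optional PNG path (depth map only; requires the png package).
#' @return `depth_colormap`: `(y, x, 3)` RGB array; `projections`: list of
#'   matrices `xy`, `xz`, `yz`; `spectrum`: matrix.
#' @export
render_views <- function(vol, mode = c("depth_colormap", "projections",
                                       "spectrum"),
                         slice_index = NULL, file = NULL) {
  mode <- match.arg(mode)
  d <- dim(vol)
  if (any(d == 0)) stop("non-empty volume required", call. = FALSE)
  out <- switch(mode,
    depth_colormap = {
      amax <- apply(vol, c(2, 3), which.max)
      vmax <- apply(vol, c(2, 3), max)
      hue <- (amax - 1) / max(1, d[1] - 1) * 0.7     # blue..red span
      val <- if (max(vmax) > 0) vmax / max(vmax) else vmax
      cols <- grDevices::hsv(h = as.vector(hue), s = 1, v = as.vector(val))
      rgb <- grDevices::col2rgb(cols) / 255
      array(c(matrix(rgb[1, ], d[2], d[3]), matrix(rgb[2, ], d[2], d[3]),
              matrix(rgb[3, ], d[2], d[3])), dim = c(d[2], d[3], 3))
    },
    projections = list(xy = apply(vol, c(2, 3), max),
                       xz = apply(vol, c(1, 3), max),
                       yz = apply(vol, c(1, 2), max)),
    spectrum = {
      zi <- if (is.null(slice_index)) (d[1] + 1) %/% 2 else slice_index
      sl <- vol[zi, , ]
      sp <- Mod(stats::fft(sl))
      log1p(circ_shift2(sp, nrow(sp) %/% 2, ncol(sp) %/% 2))
    })
  if (!is.null(file) && mode == "depth_colormap" &&
      requireNamespace("png", quietly = TRUE))
    png::writePNG(out, file)
  out
}

#' Evaluate reconstructions on a test set
#'
#' Computes per-sample and mean PSNR/SSIM of a reconstruction method against
#' the ground truth. The method may be a trained `recon_model` (its fused
#' output is scored), a function `sample -> volume`, or a named list of
#' either (ablation mode: one summary row per entry).
#'
#' @param object `recon_model`, function, or named list of them.
#' @param test_set List of `sample_pair`s.
#' @param csv Optional path; per-sample metrics are written as CSV.
#' @return A `metric_report`: list with `per_sample` (data.frame of id, psnr,
#'   ssim, runtime_s), `mean_psnr`, `mean_ssim`; in ablation mode a
#'   data.frame with one row per method.
#' @export
evaluate_suite <- function(object, test_set, csv = NULL) {
  if (length(test_set) == 0) stop("non-empty test set required", call. = FALSE)
  if (is.list(object) && !inherits(object, "recon_model") &&
      !is.function(object)) {
    rows <- lapply(names(object), function(nm) {
      rep <- evaluate_suite(object[[nm]], test_set)
      data.frame(method = nm, mean_psnr = rep$mean_psnr,
                 mean_ssim = rep$mean_ssim)
    })
    out <- do.call(rbind, rows)
    if (!is.null(csv)) utils::write.csv(out, csv, row.names = FALSE)
    return(out)
  }
  predict_fun <- if (inherits(object, "recon_model"))
    function(s) reconstruct(object, s)$fused else object
  rows <- NULL
  for (s in test_set) {
    row <- tryCatch({
      t0 <- proc.time()[["elapsed"]]
      est <- predict_fun(s)
      dt <- proc.time()[["elapsed"]] - t0
      data.frame(id = s$id, psnr = psnr(est, s$gt),
                 ssim = ssim(est, s$gt), runtime_s = dt)
    }, error = function(e) {
      warning(sprintf("sample %s failed: %s", s$id, conditionMessage(e)),
              call. = FALSE)
      data.frame(id = s$id, psnr = NA_real_, ssim = NA_real_,
                 runtime_s = NA_real_)
    })
    rows <- rbind(rows, row)
  }
  if (all(is.na(rows$psnr))) stop("all samples failed evaluation", call. = FALSE)
  rep <- structure(list(per_sample = rows,
                        mean_psnr = mean(rows$psnr, na.rm = TRUE),
                        mean_ssim = mean(rows$ssim, na.rm = TRUE)),
                   class = "metric_report")
  if (!is.null(csv)) utils::write.csv(rows, csv, row.names = FALSE)
  rep
}

#' @export
print.metric_report <- function(x, ...) {
  cat(sprintf("<metric_report> %d samples; mean PSNR %.4f dB, mean SSIM %.4f\n",
              nrow(x$per_sample), x$mean_psnr, x$mean_ssim))
  invisible(x)
}
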