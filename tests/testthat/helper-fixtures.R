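# Shared micro-scale fixtures, built once per test run and memoised.
# Geometry: 5 px/lenslet, 4x4 lenslets (20x20 lateral), 5 depth planes.

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(name, builder) {
  if (is.null(.fixture_cache[[name]])) .fixture_cache[[name]] <- builder()
  .fixture_cache[[name]]
}

tiny_mla <- function() mla_config(pitch = 150, focal_length = 3500, n_pix = 5)

tiny_optics <- function(n_depth = 5, half = 2) {
  optical_config(numerical_aperture = 0.8, magnification = 40,
                 wavelength = 580, refractive_index = 1.33,
                 sensor_pixel_pitch = 30,
                 depth_grid = seq(-half, half, length.out = n_depth),
                 lateral_grid_spacing = 30, lateral_grid_extent = 20)
}

tiny_lfm_psf <- function() {
  memo("lfm_psf", function()
    compute_lfm_psf(tiny_optics(), tiny_mla(), n_lenslets = 4))
}

tiny_flfm_psf <- function() {
  memo("flfm_psf", function() {
    cfg <- flfm_optics_preset(n_depth = 5, depth_half_range = 2)
    compute_flfm_psf(cfg, flfm_mla_preset(),
                     aperture = aperture_profile(0, 0.9, 8),
                     view_size = 20, voxel_pitch = tiny_lfm_psf()$voxel_pitch)
  })
}

tiny_phantom_cfg <- function(seed = 7) {
  phantom_config(shape = c(5, 20, 20), kind = "tubulin", n_structures = 2,
                 radius = 1, seed = seed, n_control = 4)
}

tiny_dataset <- function() {
  memo("dataset", function()
    make_dataset(5, tiny_phantom_cfg(), tiny_lfm_psf(), tiny_flfm_psf(),
                 split_ratio = 0.8))
}

tiny_sample <- function() tiny_dataset()$train[[1]]

# brute-force 'same' 2D convolution oracle with explicit centre tap
conv2_same_brute <- function(img, ker, center) {
  ny <- nrow(img); nx <- ncol(img)
  s <- nrow(ker)
  out <- matrix(0, ny, nx)
  for (y in seq_len(ny)) for (x in seq_len(nx)) {
    acc <- 0
    for (a in seq_len(s)) for (b in seq_len(s)) {
      yy <- y - (a - center); xx <- x - (b - center)
      if (yy >= 1 && yy <= ny && xx >= 1 && xx <= nx)
        acc <- acc + img[yy, xx] * ker[a, b]
    }
    out[y, x] <- acc
  }
  out
}
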