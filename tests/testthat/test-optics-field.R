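test_that("Debye integral matches its closed form on axis", {
  cfg <- tiny_optics()
  # with Uo = 1 and z = 0, Ub(0) = integral of sin(theta) = 1 - cos(theta_max)
  theta_max <- asin(cfg$numerical_aperture / cfg$refractive_index)
  v0 <- debye_radial(cfg, 0, 0)
  expect_equal(Re(v0), 1 - cos(theta_max), tolerance = 1e-12)
  expect_equal(Im(v0), 0, tolerance = 1e-12)
})

test_that("Debye quadrature converges and the field is radially symmetric", {
  cfg <- tiny_optics()
  radii <- seq(0, 5, 0.05)
  f1 <- debye_radial(cfg, 1.5, radii, n_nodes = 256)
  f2 <- debye_radial(cfg, 1.5, radii, n_nodes = 512)
  expect_lt(max(Mod(f1 - f2)) / max(Mod(f2)), 1e-6)
  fld <- debye_wavefront(cfg, 1)
  v <- fld$values
  n <- nrow(v)
  # grid points at mirrored positions share a radius, hence a value
  expect_lt(max(Mod(v[2:n, 2:n] - v[n:2, n:2])), 1e-10)
})

test_that("degenerate apertures are rejected or give empty fields", {
  expect_error(optical_config(1.5, 40, 580, 1.33, 13.6, 0:5, 1, 64),
               "refractive index")
  cfg <- tiny_optics()
  cfg$numerical_aperture <- 1e-12   # theta_max -> 0: empty integration range
  expect_equal(max(Mod(debye_radial(cfg, 0, c(0, 1, 2)))), 0)
  expect_error(debye_wavefront(tiny_optics(), 100), "depth range")
})

test_that("super-Gaussian aperture profile behaves as a clipping window", {
  rho <- seq(0, 1, 1e-3)
  p <- aperture_profile(rho, cutoff = 0.5, order = 1)
  expect_equal(p$transmission[1], 1)
  expect_true(all(diff(p$transmission) < 0))
  expect_true(all(p$transmission >= 0 & p$transmission <= 1))
  # high order approaches the indicator of the disk rho < cutoff
  p64 <- aperture_profile(rho, cutoff = 0.5, order = 64)$transmission
  away <- abs(rho - 0.5) >= 0.05
  expect_lt(max(abs(p64[away] - as.numeric(rho[away] < 0.5))), 1e-3)
  expect_error(aperture_profile(rho, cutoff = -1), "cutoff")
})

test_that("applying an aperture is a pointwise contraction", {
  cfg <- tiny_optics()
  fld <- debye_wavefront(cfg, 0.5)
  n <- nrow(fld$values)
  ones <- matrix(1, n, n)
  expect_identical(apply_aperture(fld, ones)$values, fld$values)
  zero <- complex_field(matrix(0 + 0i, n, n), fld$spacing, fld$wavelength)
  expect_equal(max(Mod(apply_aperture(zero, ones)$values)), 0)
  set.seed(1)
  p <- matrix(runif(n * n), n, n)
  expect_lte(field_energy(apply_aperture(fld, p)), field_energy(fld))
  expect_error(apply_aperture(fld, matrix(1, 2, 2)), "shape")
})

test_that("MLA transmission is a periodic unit-modulus thin-lens phase mask", {
  mla <- tiny_mla()
  tm <- mla_transmission(mla, 40, mla$pitch / 5, 580)
  expect_lt(max(abs(Mod(tm$values) - 1)), 1e-12)
  xs <- (seq_len(40) - 1 - 20) * mla$pitch / 5
  centers <- which(abs(xs %% mla$pitch) < 1e-9)
  expect_lt(max(abs(Arg(tm$values[centers, centers]))), 1e-12)
  # periodicity across one pitch for interior tiles
  i <- 6:30
  expect_lt(max(Mod(tm$values[i, i] - tm$values[i + 5, i + 5])), 1e-10)
  expect_error(mla_transmission(mla_config(1, 3500, 1), 40, 30, 580),
               "undersampling")
})

test_that("angular-spectrum propagation is unitary on the band", {
  set.seed(42)
  n <- 32
  for (k in 1:20) {
    g <- matrix(complex(real = rnorm(n * n), imaginary = rnorm(n * n)), n)
    f0 <- propagate_angular_spectrum(complex_field(g, 0.3, 580), 0, pad = FALSE)
    d <- runif(1, 1, 10)
    fp <- propagate_angular_spectrum(f0, d, pad = FALSE)
    fb <- propagate_angular_spectrum(fp, -d, pad = FALSE)
    expect_lt(max(Mod(fb$values - f0$values)), 1e-8)
    expect_lt(abs(field_energy(fp) - field_energy(f0)) / field_energy(f0),
              1e-6)
  }
})

test_that("propagation at distance zero is the band-limited identity", {
  set.seed(5)
  n <- 32
  g <- matrix(complex(real = rnorm(n * n), imaginary = rnorm(n * n)), n)
  f <- complex_field(g, 0.3, 580)
  f0 <- propagate_angular_spectrum(f, 0, pad = FALSE)
  f00 <- propagate_angular_spectrum(f0, 0, pad = FALSE)
  expect_lt(max(Mod(f00$values - f0$values)), 1e-10)
})

test_that("padded propagation round-trips a compact beam and advances plane waves", {
  n <- 64
  xs <- (seq_len(n) - 1 - n %/% 2) * 0.2
  g <- exp(-outer(xs^2, xs^2, "+") / (2 * 0.8^2))
  f <- complex_field(g, 0.2, 580)
  fb <- propagate_angular_spectrum(propagate_angular_spectrum(f, 2), -2)
  expect_lt(max(Mod(fb$values - g)), 1e-8)
  pw <- complex_field(matrix(1 + 0i, n, n), 0.2, 580)
  out <- propagate_angular_spectrum(pw, 3, pad = FALSE)$values
  expect_lt(max(Mod(out - exp(2i * pi * 3 / 0.58))), 1e-10)
})

test_that("sinc band-limit filter suppresses content beyond the cutoff", {
  set.seed(9)
  n <- 64
  dc <- complex_field(matrix(1 + 0i, n, n), 0.2, 580)
  out <- flfm_bandlimit(dc, 0.8)
  expect_lt(max(Mod(out$values - 1)), 1e-10)     # unit DC gain
  wn <- complex_field(matrix(complex(real = rnorm(n^2),
                                     imaginary = rnorm(n^2)), n), 0.2, 580)
  bl <- flfm_bandlimit(wn, 0.8)
  sp <- Mod(stats::fft(bl$values))^2
  f1 <- c(0:(n / 2 - 1), -(n / 2):-1) / (n * 0.2)
  fr <- sqrt(outer(f1^2, f1^2, "+"))
  expect_lt(sum(sp[fr >= 1 / 0.8]) / sum(sp), 1e-4)
  bl2 <- flfm_bandlimit(bl, 0.8)
  expect_lt(max(Mod(bl2$values - bl$values)) / max(Mod(bl$values)), 1e-6)
  expect_error(flfm_bandlimit(wn, 0), "cutoff")
})
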