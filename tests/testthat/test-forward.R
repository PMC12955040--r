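test_that("LFM projection: zero volume, delta sifting, shape errors", {
  psf <- tiny_lfm_psf()
  vol <- array(0, dim = c(5, 20, 20))
  expect_equal(max(abs(project_lfm(vol, psf))), 0)
  ctr <- psf$center
  vol[3, ctr, ctr] <- 1
  sens <- project_lfm_sensor(vol, psf)
  expect_lt(max(abs(sens - psf$images[3, , ])), 1e-8)
  lf <- project_lfm(vol, psf)
  expect_equal(dim(lf), c(5, 5, 4, 4))
  expect_lt(max(abs(lf - lfm_sensor_to_views(psf$images[3, , ], 5))), 1e-8)
  expect_error(project_lfm(array(0, dim = c(4, 20, 20)), psf), "depth")
  expect_error(project_lfm(array(0, dim = c(5, 21, 21)), psf), "divisible")
})

test_that("FFT projection matches the brute-force convolution oracle", {
  psf <- tiny_lfm_psf()
  set.seed(21)
  vol <- array(stats::runif(3 * 10 * 10), dim = c(3, 10, 10))
  psf3 <- psf
  psf3$images <- psf$images[1:3, , , drop = FALSE]
  psf3$values <- psf$values[1:3, , , , , drop = FALSE]
  sens <- project_lfm_sensor(vol, psf3)
  brute <- matrix(0, 10, 10)
  for (zi in 1:3)
    brute <- brute + conv2_same_brute(vol[zi, , ], psf$images[zi, , ],
                                      psf$center)
  expect_lt(max(abs(sens - brute)), 1e-8)
})

test_that("both projectors are linear operators", {
  lpsf <- tiny_lfm_psf()
  fpsf <- tiny_flfm_psf()
  set.seed(4)
  a <- array(stats::runif(5 * 20 * 20), dim = c(5, 20, 20))
  b <- array(stats::runif(5 * 20 * 20), dim = c(5, 20, 20))
  expect_lt(max(abs(project_lfm(a + b, lpsf) -
                    project_lfm(a, lpsf) - project_lfm(b, lpsf))), 1e-8)
  pa <- suppressWarnings(attr(project_flfm(a, fpsf), "sensor_raw"))
  pb <- suppressWarnings(attr(project_flfm(b, fpsf), "sensor_raw"))
  pab <- suppressWarnings(attr(project_flfm(a + b, fpsf), "sensor_raw"))
  expect_lt(max(abs(pab - pa - pb)), 1e-8)
})

test_that("flux is conserved for interior sources with unit-sum PSF slices", {
  psf <- tiny_lfm_psf()
  set.seed(2)
  # 40 px volume leaves a >= 10 px margin so the 20 px PSF patch of every
  # source lies fully inside the sensor window
  vol <- array(0, dim = c(5, 40, 40))
  vol[, 18:22, 18:22] <- stats::runif(5 * 25)
  lf <- project_lfm(vol, psf)
  expect_lt(abs(sum(lf) - sum(vol)) / sum(vol), 1e-6)
})

test_that("FLFM projection: zero volume, delta sifting, residue bookkeeping", {
  psf <- tiny_flfm_psf()
  v <- psf$view_size
  vol <- array(0, dim = c(5, v, v))
  out0 <- project_flfm(vol, psf)
  expect_equal(max(abs(out0)), 0)
  zi0 <- which.min(abs(psf$depth_grid))
  vol[zi0, 1, 1] <- 1
  out <- project_flfm(vol, psf)
  s <- 3 * v
  href <- Re(stats::fft(psf$weights[zi0, 1, 1] * psf$freq_response[, , zi0],
                        inverse = TRUE)) / s^2
  expect_lt(max(abs(attr(out, "sensor") - pmax(href, 0))), 1e-8)
  expect_lt(attr(out, "imag_residue"), 1e-8)
  expect_true(attr(out, "clipped_mass") >= 0)
  expect_error(project_flfm(array(0, dim = c(4, v, v)), psf), "depth")
})

test_that("light-field view stacking is deterministic and invertible", {
  set.seed(8)
  lf <- array(stats::rnorm(11 * 11 * 16 * 16), dim = c(11, 11, 16, 16))
  st <- lfm_views(lf)
  expect_equal(dim(st), c(121, 16, 16))
  expect_identical(lfm_views_inverse(st, 11, 11), lf)
  # channel 1 is view (u = 1, v = 1): 0-based channel 0 <-> (u=0, v=0)
  expect_identical(st[1, , ], lf[1, 1, , ])
  expect_identical(st[12, , ], lf[2, 1, , ])   # u-major, v-minor ordering
})

test_that("FLFM view cropping follows the 2-3-2 layout", {
  psf <- tiny_flfm_psf()
  v <- psf$view_size
  geom <- flfm_geometry(psf)
  zero <- matrix(0, 3 * v, 3 * v)
  vs <- flfm_views(zero, geom)
  expect_equal(dim(vs), c(7, v, v))
  expect_equal(max(abs(vs)), 0)
  # paint each view window with its index and recover it at the view centre
  lab <- zero
  for (k in 1:7) {
    r0 <- geom$view_corners[[k]][1]; c0 <- geom$view_corners[[k]][2]
    lab[(r0 + 1):(r0 + v), (c0 + 1):(c0 + v)] <- k
  }
  vs2 <- flfm_views(lab, geom)
  for (k in 1:7) expect_equal(vs2[k, v / 2, v / 2], k)
  bad <- geom
  bad$view_corners[[1]] <- c(-3, 0)
  expect_error(flfm_views(zero, bad), "geometry")
})
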