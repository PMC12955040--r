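test_that("LFM EPI stacks have the published shapes and invert bit-exactly", {
  set.seed(31)
  lf <- array(stats::rnorm(11 * 11 * 16 * 16), dim = c(11, 11, 16, 16))
  ep <- lfm_epi(lf)
  expect_equal(dim(ep$uh), c(176, 11, 16))
  expect_equal(dim(ep$vw), c(176, 11, 16))
  expect_identical(lfm_epi_inverse(ep$uh, "uh", dim(lf)), lf)
  expect_identical(lfm_epi_inverse(ep$vw, "vw", dim(lf)), lf)
  # channel order of the u-h stack: v-major then w
  expect_identical(ep$uh[1, , ], lf[, 1, 1, ])
  expect_identical(ep$uh[2, , ], lf[, 1, 2, ])
  expect_identical(ep$uh[17, , ], lf[, 2, 1, ])
})

test_that("a light field constant across u gives constant EPI rows", {
  lf <- array(0, dim = c(5, 4, 6, 6))
  set.seed(3)
  base <- array(stats::rnorm(4 * 6 * 6), dim = c(4, 6, 6))
  for (u in 1:5) lf[u, , , ] <- base
  ep <- lfm_epi(lf)
  for (ch in c(1, 9, 24)) {
    sl <- ep$uh[ch, , ]
    expect_lt(max(abs(sweep(sl, 2, sl[1, ]))), 1e-14)
  }
})

test_that("FLFM EPI stacks use three collinear views and invert bit-exactly", {
  set.seed(12)
  views <- structure(array(stats::rnorm(7 * 8 * 8), dim = c(7, 8, 8)),
                     class = "flfm_view_stack")
  ep <- flfm_epi(views)
  expect_equal(dim(ep$cw), c(8, 3, 8))
  expect_equal(dim(ep$ch), c(8, 3, 8))
  inv <- flfm_epi_inverse(ep$cw, ep$ch)
  expect_identical(inv$row_views, unclass(views)[c(3, 4, 5), , ])
  expect_identical(inv$col_views, unclass(views)[c(1, 4, 7), , ])
  zeros <- structure(array(0, dim = c(7, 8, 8)), class = "flfm_view_stack")
  ez <- flfm_epi(zeros)
  expect_equal(max(abs(ez$cw)), 0)
  expect_error(flfm_epi(array(0, dim = c(6, 8, 8))), "geometry")
})

test_that("the structure-tensor slope recovers drawn lines within 5%", {
  for (s in c(-2, -0.8, 0.5, 1.5)) {
    epi <- matrix(0, 11, 64)
    for (u in 1:11) {
      x0 <- 32 + s * (u - 6)
      xs <- seq_len(64)
      epi[u, ] <- exp(-(xs - x0)^2 / 2)
    }
    est <- epi_dominant_slope(epi)
    expect_lt(abs(est - s) / abs(s), 0.05)
  }
})

test_that("degenerate EPI slices are flagged", {
  flat <- matrix(1, 5, 16)
  out <- epi_dominant_slope(flat)
  expect_true(is.na(out))
  expect_true(isTRUE(attr(out, "undefined")))
  expect_error(epi_dominant_slope(matrix(1, 1, 16)), "view rows")
})

test_that("point-source EPI slope is near zero at the focal plane", {
  psf <- tiny_lfm_psf()
  vol <- array(0, dim = c(5, 20, 20))
  vol[3, psf$center, psf$center] <- 1      # z = 0 plane
  lf <- project_lfm(vol, psf)
  ep <- lfm_epi(lf)
  # channel of (v = central view, w = lenslet containing the source)
  wc <- ceiling(psf$center / psf$n_pix)
  ch <- (3 - 1) * 4 + wc
  expect_lt(abs(epi_dominant_slope(ep$uh[ch, , ])), 0.1)
})

test_that("EPI slope magnitude grows monotonically with defocus", {
  psf <- tiny_lfm_psf()
  wc <- ceiling(psf$center / psf$n_pix)
  ch <- (3 - 1) * 4 + wc
  slopes <- vapply(seq_len(5), function(zi) {
    vol <- array(0, dim = c(5, 20, 20))
    vol[zi, psf$center, psf$center] <- 1
    ep <- lfm_epi(project_lfm(vol, psf))
    epi_dominant_slope(ep$uh[ch, , ])
  }, numeric(1))
  z <- tiny_optics()$depth_grid
  # the micro fixture (5 views, 4 lenslets) resolves disparity only coarsely;
  # the full-scale 11-depth monotonicity check lives in the acceptance suite
  expect_gte(stats::cor(abs(slopes), abs(z), method = "spearman"), 0.75)
})
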