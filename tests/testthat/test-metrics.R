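test_that("PSNR follows its closed form", {
  set.seed(1)
  x <- array(stats::runif(4 * 8 * 8), dim = c(4, 8, 8))
  expect_true(is.infinite(psnr(x, x)))
  ref <- array(0.5, dim = c(4, 8, 8))
  y <- ref + sqrt(0.01)            # MSE = 0.01 at data_range 1
  expect_equal(psnr(y, ref, data_range = 1), 20, tolerance = 1e-12)
  y2 <- ref + sqrt(0.005)          # halved MSE: +10 log10(2) dB
  expect_equal(psnr(y2, ref, data_range = 1) - psnr(y, ref, data_range = 1),
               10 * log10(2), tolerance = 1e-10)
  expect_error(psnr(x, x[1:2, , ]), "shape")
  expect_error(psnr(x, x, data_range = 0), "data_range")
})

test_that("SSIM is 1 for identical inputs, symmetric, low for noise pairs", {
  set.seed(6)
  x <- array(stats::runif(3 * 32 * 32), dim = c(3, 32, 32))
  expect_equal(ssim(x, x), 1)
  y <- x + array(stats::rnorm(length(x), 0, 0.2), dim = dim(x))
  expect_equal(ssim(x, y), ssim(y, x), tolerance = 1e-12)
  expect_true(ssim(x, y) < 1 && ssim(x, y) > 0)
  a <- matrix(stats::rnorm(64 * 64), 64)
  b <- matrix(stats::rnorm(64 * 64), 64)
  expect_lt(abs(ssim(a, b)), 0.1)
  expect_error(ssim(x, x[, 1:2, ]), "shape")
})

test_that("render_views produces the documented diagnostics", {
  vol <- array(0, dim = c(5, 12, 12))
  dm0 <- render_views(vol, "depth_colormap")
  expect_equal(dim(dm0), c(12, 12, 3))
  expect_equal(max(dm0), 0)                       # all-zero volume -> black
  vol[4, , ] <- 1                                 # one bright plane
  dm <- render_views(vol, "depth_colormap")
  expect_equal(max(abs(sweep(matrix(dm, 144, 3), 2,
                             matrix(dm, 144, 3)[1, ]))), 0)  # uniform hue
  pr <- render_views(vol, "projections")
  expect_named(pr, c("xy", "xz", "yz"))
  expect_equal(dim(pr$xy), c(12, 12))
  expect_equal(dim(pr$xz), c(5, 12))
  sp <- render_views(array(1, dim = c(3, 8, 8)), "spectrum")
  dc_only <- sp
  dc_only[5, 5] <- 0                              # centred DC bin
  expect_equal(max(abs(dc_only)), 0)
  expect_gt(sp[5, 5], 0)
  expect_error(render_views(vol, "unknown"))
})

test_that("evaluate_suite aggregates per-sample metrics and ablation rows", {
  ds <- tiny_dataset()
  idfun <- function(s) s$gt
  rep <- evaluate_suite(idfun, ds$train)
  expect_true(all(is.infinite(rep$per_sample$psnr)))
  expect_equal(rep$per_sample$ssim, rep(1, 4))
  blur <- function(s) s$gt * 0.9
  rep2 <- evaluate_suite(blur, ds$train)
  expect_equal(rep2$mean_psnr, mean(rep2$per_sample$psnr))
  expect_equal(rep2$mean_ssim, mean(rep2$per_sample$ssim))
  tab <- evaluate_suite(list(exact = idfun, blurred = blur), ds$train)
  expect_equal(nrow(tab), 2)
  expect_equal(tab$method, c("exact", "blurred"))
  csv <- tempfile(fileext = ".csv")
  evaluate_suite(blur, ds$train, csv = csv)
  expect_true(file.exists(csv))
  expect_error(evaluate_suite(blur, list()), "non-empty")
})
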