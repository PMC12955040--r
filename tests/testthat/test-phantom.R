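test_that("tubulin phantoms are reproducible, non-negative and sized", {
  cfg <- tubulin_preset(seed = 3)
  expect_equal(cfg$shape, c(61L, 176L, 176L))
  small <- tiny_phantom_cfg(seed = 5)
  v1 <- make_tubulin_volume(small)
  v2 <- make_tubulin_volume(small)
  expect_identical(v1, v2)
  expect_true(all(v1 >= 0))
  expect_equal(dim(v1), c(5L, 20L, 20L))
  expect_gt(max(v1), 0)
  empty_cfg <- tiny_phantom_cfg()
  empty_cfg$n_structures <- 0L
  expect_warning(v0 <- make_tubulin_volume(empty_cfg), "zero structures")
  expect_equal(max(v0), 0)
})

test_that("vessel trees taper: child radii are smaller than their parents", {
  cfg <- phantom_config(shape = c(9, 40, 40), kind = "vessel",
                        n_structures = 1, radius = 1.2, seed = 9,
                        branch_depth = 2, taper = 0.7)
  vol <- make_vessel_volume(cfg)
  expect_true(all(vol >= 0))
  tree <- attr(vol, "tree")
  expect_gt(length(tree), 1)
  lev <- vapply(tree, function(s) s$level, numeric(1))
  rad <- vapply(tree, function(s) s$radius, numeric(1))
  expect_lt(mean(rad[lev == 1]), mean(rad[lev == 0]))
  # measure rasterised radii: second moment of a straight single tube scales
  # with the nominal radius
  tube <- function(r) {
    c1 <- phantom_config(shape = c(5, 30, 30), kind = "vessel",
                         n_structures = 1, radius = r, seed = 4,
                         branch_depth = 0)
    v <- make_vessel_volume(c1)
    sl <- apply(v, c(2, 3), max)
    sum(sl > 0.5 * max(sl))    # cross-section area proxy
  }
  expect_gt(tube(2), tube(1))
  # depth 0 gives a single segment
  c0 <- phantom_config(shape = c(5, 30, 30), kind = "vessel",
                       n_structures = 1, radius = 1, seed = 4,
                       branch_depth = 0)
  expect_equal(length(attr(make_vessel_volume(c0), "tree")), 1)
})

test_that("datasets split 8:2, deterministically, and samples regenerate", {
  ds <- tiny_dataset()
  expect_equal(length(ds$train), 4)
  expect_equal(length(ds$test), 1)
  ids <- c(vapply(ds$train, function(s) s$id, character(1)),
           vapply(ds$test, function(s) s$id, character(1)))
  expect_equal(sort(ids), sprintf("sample_%03d", 1:5))
  ds2 <- make_dataset(5, tiny_phantom_cfg(), tiny_lfm_psf(), tiny_flfm_psf(),
                      split_ratio = 0.8)
  expect_identical(vapply(ds2$train, function(s) s$id, character(1)),
                   vapply(ds$train, function(s) s$id, character(1)))
  # stored light field regenerates bit-exactly from the ground truth
  s <- ds$train[[1]]
  expect_identical(project_lfm(s$gt, tiny_lfm_psf()), s$lfm)
  expect_error(make_dataset(1, tiny_phantom_cfg(), tiny_lfm_psf(),
                            tiny_flfm_psf()), "n_samples")
})

test_that("sample directories round-trip through TIFF + YAML", {
  s <- tiny_sample()
  dir <- file.path(tempdir(), "lffuse_sample")
  write_sample(s, dir)
  expect_true(file.exists(file.path(dir, "gt.tif")))
  s2 <- read_sample(dir)
  expect_equal(s2$gt, s$gt, tolerance = 1e-6)
  expect_equal(s2$lfm, s$lfm, tolerance = 1e-6)
  expect_equal(unclass(s2$flfm), unclass(s$flfm), tolerance = 1e-6,
               ignore_attr = TRUE)
  expect_equal(s2$epi_lfm_uh, s$epi_lfm_uh, tolerance = 1e-6)
  expect_equal(s2$id, s$id)
  unlink(dir, recursive = TRUE)
})
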