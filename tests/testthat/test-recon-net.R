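tiny_model <- function(branches = c("lfm", "flfm", "lfm_epi", "flfm_epi"),
                       seed = 5) {
  build_recon_model(tiny_sample(), branches = branches, unified_channels = 6,
                    unet_depth = 2, base_width = 6, fusion_width = 6,
                    seed = seed)
}

test_that("adapters align every modality to the target geometry", {
  m <- tiny_model()
  s <- tiny_sample()
  for (b in m$branches) {
    spec <- m$specs[[b]]
    stacks <- switch(b,
      lfm = lfm_views(s$lfm),
      flfm = unclass(s$flfm),
      lfm_epi = list(s$epi_lfm_uh, s$epi_lfm_vw),
      flfm_epi = list(s$epi_flfm_cw, s$epi_flfm_ch))
    out <- adapter(stacks, spec, m$params[[b]])
    expect_equal(dim(out$value), c(20, 20, 6))
  }
  expect_equal(m$specs$lfm$in_channels, 25)       # n_pix^2 view channels
  expect_error(adapter(array(0, dim = c(3, 4, 4)), m$specs$lfm,
                       m$params$lfm), "channel count")
})

test_that("branch reconstruction outputs ground-truth-shaped volumes", {
  m <- tiny_model()
  s <- tiny_sample()
  out <- branch_reconstruct(m, s, "flfm")
  expect_equal(dim(out$value), c(20, 20, 5))
  # spatial sizes not divisible by 2^depth are padded and cropped back
  m2 <- tiny_model(branches = "flfm")
  m2$specs$flfm$target_size <- c(19, 19)
  m2$target <- c(19, 19)
  s2 <- s
  s2$gt <- s$gt[, 1:19, 1:19]
  out2 <- branch_reconstruct(m2, s2, "flfm")
  expect_equal(dim(out2$value), c(19, 19, 5))
})

test_that("untrained fusion passes the input mean; gradients reach both inputs", {
  m <- tiny_model()
  set.seed(9)
  a <- lffuse:::tg_node(array(stats::rnorm(6 * 6 * 5), dim = c(6, 6, 5)))
  b <- lffuse:::tg_node(array(stats::rnorm(6 * 6 * 5), dim = c(6, 6, 5)))
  fused <- fuse_pair(a, b, m$fusion$pair_lfm)
  expect_equal(fused$value, (a$value + b$value) / 2, tolerance = 1e-12)
  # perturb the zero-initialised layer, then probe gradient flow
  m$fusion$pair_lfm$f2$w$value[] <- stats::rnorm(
    length(m$fusion$pair_lfm$f2$w$value), 0, 0.1)
  fused2 <- fuse_pair(a, b, m$fusion$pair_lfm)
  loss <- lffuse:::tg_mse(fused2, array(0, dim = c(6, 6, 5)))
  lffuse:::tg_backward(loss)
  expect_true(all(is.finite(a$grad)) && sqrt(sum(a$grad^2)) > 0)
  expect_true(all(is.finite(b$grad)) && sqrt(sum(b$grad^2)) > 0)
  expect_error(fuse_pair(a, lffuse:::tg_node(array(0, dim = c(5, 6, 5))),
                         m$fusion$pair_lfm), "shape")
})

test_that("the full cascade returns five ground-truth-shaped volumes", {
  m <- tiny_model()
  s <- tiny_sample()
  fw <- forward_full(m, s)
  expect_setequal(names(fw$volumes),
                  c("lfm", "flfm", "lfm_epi", "flfm_epi", "fuse"))
  for (v in fw$volumes) expect_equal(dim(v), dim(s$gt))
  # deterministic repeatability
  fw2 <- forward_full(m, s)
  expect_identical(fw$volumes$fuse, fw2$volumes$fuse)
  # ablating a branch (zero input) still yields finite outputs
  s0 <- s
  s0$flfm[] <- 0
  fw0 <- forward_full(m, s0)
  expect_true(all(vapply(fw0$volumes, function(v) all(is.finite(v)),
                         logical(1))))
})

test_that("every branch receives parameter gradient", {
  m <- tiny_model()
  s <- tiny_sample()
  fw <- forward_full(m, s)
  gt_hwc <- aperm(s$gt, c(2, 3, 1))
  losses <- lapply(fw$nodes, function(n) lffuse:::tg_mse(n, gt_hwc))
  lffuse:::tg_backward(lffuse:::tg_sum_scalars(losses))
  for (b in m$branches) {
    g <- m$params[[b]]$head$w$grad
    expect_false(is.null(g))
    expect_gt(sqrt(sum(g^2)), 0)
  }
})

test_that("the multilevel loss is additive, non-negative and zero iff exact", {
  s <- tiny_sample()
  outs <- list(lfm = s$gt, flfm = s$gt, lfm_epi = s$gt, flfm_epi = s$gt,
               fuse = s$gt)
  lb0 <- multilevel_loss(outs, s$gt)
  expect_equal(lb0$total, 0)
  outs$fuse <- s$gt + 1
  lb1 <- multilevel_loss(outs, s$gt)
  expect_equal(lb1$total, 1, tolerance = 1e-12)   # MSE of a constant-1 offset
  set.seed(10)
  outs_r <- lapply(outs, function(o) o + array(stats::rnorm(length(o)),
                                               dim = dim(o)))
  lb <- multilevel_loss(outs_r, s$gt)
  terms <- c(lb$loss_lfm, lb$loss_flfm, lb$loss_lfm_epi, lb$loss_flfm_epi,
             lb$loss_fuse)
  expect_true(all(terms >= 0))
  expect_equal(lb$total, sum(terms), tolerance = 1e-10)
  expect_equal(lb$loss_lfm, mean((outs_r$lfm - s$gt)^2), tolerance = 1e-12)
  expect_error(multilevel_loss(list(fuse = s$gt[, 1:10, ]), s$gt), "shape")
})

test_that("training reduces the loss, is seeded, and rejects empty data", {
  s <- tiny_sample()
  m <- tiny_model(seed = 21)
  w0 <- model_get_weights(m)
  r1 <- train_recon(m, list(s), train_config(epochs = 2, learning_rate = 1e-3,
                                             seed = 3))
  m2 <- tiny_model(seed = 21)
  r2 <- train_recon(m2, list(s), train_config(epochs = 2,
                                              learning_rate = 1e-3, seed = 3))
  expect_identical(r1$history$total[1], r2$history$total[1])
  m3 <- tiny_model(seed = 21)
  r3 <- train_recon(m3, list(s), train_config(epochs = 30,
                                              learning_rate = 2e-3, seed = 3))
  expect_lt(tail(r3$history$total, 1), r3$history$total[1])
  expect_error(train_recon(tiny_model(), list(), train_config()), "empty")
})

test_that("single-branch models fuse through pass-through stages", {
  m <- tiny_model(branches = "lfm")
  s <- tiny_sample()
  fw <- forward_full(m, s)
  expect_setequal(names(fw$volumes), c("lfm", "fuse"))
  expect_identical(fw$volumes$fuse, fw$volumes$lfm)
})
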