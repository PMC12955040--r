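# Four-branch multimodal reconstruction network with hierarchical cascade
# result-level fusion. Each branch adapts its modality stack to a common
# spatial size and channel width, reconstructs a volume (depth as output
# channels) with a small U-Net, and the per-pair / cross-modal fusion blocks
# merge the branch volumes.

MODALITIES <- c("lfm", "flfm", "lfm_epi", "flfm_epi")

# stack (C, H, W) -> internal (H, W, C)
stack_to_hwc <- function(s) aperm(s, c(2, 3, 1))

# zero-pad an (H, W, C) node up to (hp, wp); backward crops
tg_pad_to <- function(x, hp, wp) {
  d <- dim(x$value)
  if (d[1] == hp && d[2] == wp) return(x)
  v <- array(0, dim = c(hp, wp, d[3]))
  v[1:d[1], 1:d[2], ] <- x$value
  out <- tg_node(v, parents = list(x))
  out$backward <- function(node)
    tg_accum(x, node$grad[1:d[1], 1:d[2], , drop = FALSE])
  out
}

tg_crop_to <- function(x, h, w) {
  d <- dim(x$value)
  if (d[1] == h && d[2] == w) return(x)
  out <- tg_node(x$value[1:h, 1:w, , drop = FALSE], parents = list(x))
  out$backward <- function(node) {
    g <- array(0, dim = d)
    g[1:h, 1:w, ] <- node$grad
    tg_accum(x, g)
  }
  out
}

#' Branch specification
#'
#' @param modality One of `"lfm"`, `"flfm"`, `"lfm_epi"`, `"flfm_epi"`.
#' @param in_channels Channel count(s) of the modality stack(s); length 2 for
#'   the EPI branches (two stacks each).
#' @param target_size Spatial size `c(H, W)` the adapter interpolates to.
#' @param unified_channels Feature channels after the adapter.
#' @param unet_depth Encoder/decoder levels.
#' @param base_width Channel width of the first encoder level.
#' @return An object of class `branch_spec`.
#' @export
branch_spec <- function(modality, in_channels, target_size, unified_channels,
                        unet_depth = 2, base_width = 16) {
  modality <- match.arg(modality, MODALITIES)
  structure(list(modality = modality, in_channels = in_channels,
                 target_size = target_size,
                 unified_channels = unified_channels,
                 unet_depth = unet_depth, base_width = base_width),
            class = "branch_spec")
}

branch_params_new <- function(spec, n_z) {
  p <- list()
  for (i in seq_along(spec$in_channels))
    p[[paste0("adapt", i)]] <- tg_init_conv(spec$in_channels[i],
                                            spec$unified_channels, 3L)
  if (length(spec$in_channels) > 1)
    p$merge <- tg_init_conv(length(spec$in_channels) * spec$unified_channels,
                            spec$unified_channels, 3L)
  w <- spec$base_width
  for (lev in seq_len(spec$unet_depth)) {
    cin <- if (lev == 1) spec$unified_channels else w * 2^(lev - 2)
    cout <- w * 2^(lev - 1)
    p[[paste0("enc", lev, "a")]] <- tg_init_conv(cin, cout, 3L)
    p[[paste0("enc", lev, "b")]] <- tg_init_conv(cout, cout, 3L)
  }
  cb <- w * 2^(spec$unet_depth - 1)
  p$bottle_a <- tg_init_conv(cb, 2 * cb, 3L)
  p$bottle_b <- tg_init_conv(2 * cb, cb, 3L)
  for (lev in rev(seq_len(spec$unet_depth))) {
    cskip <- w * 2^(lev - 1)
    cup <- if (lev == spec$unet_depth) cb else w * 2^lev
    p[[paste0("dec", lev, "a")]] <- tg_init_conv(cup + cskip, cskip, 3L)
    p[[paste0("dec", lev, "b")]] <- tg_init_conv(cskip, cskip, 3L)
  }
  p$head <- tg_init_conv(w, n_z, 1L)
  p
}

fuse_params_new <- function(n_z, width) {
  list(f1 = tg_init_conv(2 * n_z, width, 3L),
       f2 = tg_init_conv(width, n_z, 3L, scale = 0))   # zero-init last layer
}

#' Build the multimodal reconstruction model
#'
#' Creates the adapter, U-Net and fusion parameters for the requested subset
#' of branches, sized from a representative sample.
#'
#' @param sample A `sample_pair` giving the input/output geometry.
#' @param branches Character subset of
#'   `c("lfm", "flfm", "lfm_epi", "flfm_epi")`.
#' @param unified_channels Adapter output channels.
#' @param unet_depth U-Net levels.
#' @param base_width First-level U-Net width.
#' @param fusion_width Hidden width of the fusion blocks.
#' @param seed Seed for weight initialisation.
#' @return An object of class `recon_model`.
#' @export
build_recon_model <- function(sample, branches = MODALITIES,
                              unified_channels = 16, unet_depth = 2,
                              base_width = 16, fusion_width = 16, seed = 1) {
  branches <- match.arg(branches, MODALITIES, several.ok = TRUE)
  n_z <- dim(sample$gt)[1]
  target <- dim(sample$gt)[2:3]
  set.seed(seed)
  in_ch <- list(
    lfm = dim(sample$lfm)[1] * dim(sample$lfm)[2],
    flfm = dim(sample$flfm)[1],
    lfm_epi = c(dim(sample$epi_lfm_uh)[1], dim(sample$epi_lfm_vw)[1]),
    flfm_epi = c(dim(sample$epi_flfm_cw)[1], dim(sample$epi_flfm_ch)[1]))
  specs <- list(); params <- list()
  for (b in branches) {
    specs[[b]] <- branch_spec(b, in_ch[[b]], target, unified_channels,
                              unet_depth, base_width)
    params[[b]] <- branch_params_new(specs[[b]], n_z)
  }
  fus <- list()
  if (all(c("lfm", "lfm_epi") %in% branches))
    fus$pair_lfm <- fuse_params_new(n_z, fusion_width)
  if (all(c("flfm", "flfm_epi") %in% branches))
    fus$pair_flfm <- fuse_params_new(n_z, fusion_width)
  has_a <- any(c("lfm", "lfm_epi") %in% branches)
  has_b <- any(c("flfm", "flfm_epi") %in% branches)
  if (has_a && has_b) fus$cross <- fuse_params_new(n_z, fusion_width)
  structure(list(branches = branches, specs = specs, params = params,
                 fusion = fus, n_z = n_z, target = target, seed = seed),
            class = "recon_model")
}

#' @export
print.recon_model <- function(x, ...) {
  cat(sprintf("<recon_model> branches: %s; output (%d, %d, %d); %d parameters\n",
              paste(x$branches, collapse = "+"), x$n_z, x$target[1],
              x$target[2],
              sum(vapply(model_params(x),
                         function(p) length(p$value), numeric(1)))))
  invisible(x)
}

# flat list of all tg_param nodes in the model
model_params <- function(model) {
  out <- list()
  grab <- function(l) {
    for (el in l) {
      if (inherits(el, "tg_node")) out[[length(out) + 1L]] <<- el
      else if (is.list(el)) grab(el)
    }
  }
  grab(model$params)
  grab(model$fusion)
  out
}

#' Get or set all model weights
#' @param model A `recon_model`.
#' @param values For `model_set_weights`, a list as returned by
#'   `model_get_weights`.
#' @return A list of numeric arrays, or (invisibly) the model.
#' @export
model_get_weights <- function(model) {
  lapply(model_params(model), function(p) p$value)
}

#' @rdname model_get_weights
#' @export
model_set_weights <- function(model, values) {
  ps <- model_params(model)
  stopifnot(length(ps) == length(values))
  for (i in seq_along(ps)) ps[[i]]$value <- values[[i]]
  invisible(model)
}

#' Adapter: align a modality stack to the network geometry
#'
#' Bilinear interpolation of the stack's spatial axes to the target size,
#' followed by a convolution to the unified channel count; two-stack (EPI)
#' branches adapt each stack separately and merge with a further convolution.
#'
#' @param stacks A single `(C, H, W)` array or list of them (EPI branches).
#' @param spec The `branch_spec`.
#' @param params The branch parameter list (from a built model).
#' @return A `tg_node` with value `(H_target, W_target, unified_channels)`.
#' @export
adapter <- function(stacks, spec, params) {
  if (!is.list(stacks)) stacks <- list(stacks)
  if (length(stacks) != length(spec$in_channels))
    stop("config error: stack count does not match branch spec", call. = FALSE)
  feats <- vector("list", length(stacks))
  for (i in seq_along(stacks)) {
    if (dim(stacks[[i]])[1] != spec$in_channels[i])
      stop("config error: channel count does not match branch spec",
           call. = FALSE)
    v <- stack_to_hwc(unclass(stacks[[i]]))
    mx <- max(abs(v))
    if (mx > 0) v <- v / mx            # per-sample input normalisation
    x <- tg_node(v)
    x <- tg_bilinear(x, spec$target_size[1], spec$target_size[2])
    pp <- params[[paste0("adapt", i)]]
    feats[[i]] <- tg_relu(tg_conv2d(x, pp$w, pp$b, 3L))
  }
  if (length(feats) == 1) return(feats[[1]])
  x <- Reduce(tg_cat, feats)
  tg_relu(tg_conv2d(x, params$merge$w, params$merge$b, 3L))
}

# U-Net encoder-decoder on a (H, W, C) node; returns (H, W, n_z)
unet_forward <- function(x, spec, params) {
  d0 <- dim(x$value)
  m <- 2^spec$unet_depth
  hp <- ceiling(d0[1] / m) * m; wp <- ceiling(d0[2] / m) * m
  x <- tg_pad_to(x, hp, wp)
  skips <- list()
  for (lev in seq_len(spec$unet_depth)) {
    pa <- params[[paste0("enc", lev, "a")]]
    pb <- params[[paste0("enc", lev, "b")]]
    x <- tg_relu(tg_conv2d(x, pa$w, pa$b, 3L))
    x <- tg_relu(tg_conv2d(x, pb$w, pb$b, 3L))
    skips[[lev]] <- x
    x <- tg_pool2(x)
  }
  x <- tg_relu(tg_conv2d(x, params$bottle_a$w, params$bottle_a$b, 3L))
  x <- tg_relu(tg_conv2d(x, params$bottle_b$w, params$bottle_b$b, 3L))
  for (lev in rev(seq_len(spec$unet_depth))) {
    x <- tg_up2(x)
    x <- tg_cat(x, skips[[lev]])
    pa <- params[[paste0("dec", lev, "a")]]
    pb <- params[[paste0("dec", lev, "b")]]
    x <- tg_relu(tg_conv2d(x, pa$w, pa$b, 3L))
    x <- tg_relu(tg_conv2d(x, pb$w, pb$b, 3L))
  }
  x <- tg_conv2d(x, params$head$w, params$head$b, 1L)
  tg_crop_to(x, d0[1], d0[2])
}

#' Single-branch volume reconstruction
#'
#' Runs one modality through its adapter and U-Net.
#'
#' @param model A `recon_model`.
#' @param sample A `sample_pair`.
#' @param branch Branch name.
#' @return A `tg_node` whose value is `(H, W, n_z)`.
#' @export
branch_reconstruct <- function(model, sample, branch) {
  spec <- model$specs[[branch]]
  if (is.null(spec)) stop("config error: model has no branch ", branch,
                          call. = FALSE)
  stacks <- switch(branch,
    lfm = lfm_views(sample$lfm),
    flfm = unclass(sample$flfm),
    lfm_epi = list(sample$epi_lfm_uh, sample$epi_lfm_vw),
    flfm_epi = list(sample$epi_flfm_cw, sample$epi_flfm_ch))
  x <- adapter(stacks, spec, model$params[[branch]])
  unet_forward(x, spec, model$params[[branch]])
}

#' Result-level fusion of two reconstructed volumes
#'
#' Channel-concatenates two `(H, W, n_z)` volumes, applies two convolutions,
#' and adds the result to the average of the inputs. The final convolution is
#' zero-initialised, so an untrained fusion block passes through the mean of
#' its inputs (warm start) while keeping a gradient path into and through the
#' block — a pure zero-initialised output would leave the whole fusion
#' cascade with exactly zero gradient.
#'
#' @param rec_a,rec_b `tg_node` volumes of equal shape.
#' @param params Fusion parameter pair from the model.
#' @return A `tg_node` volume of the same shape.
#' @export
fuse_pair <- function(rec_a, rec_b, params) {
  if (!all(dim(rec_a$value) == dim(rec_b$value)))
    stop("shape error: fusion inputs must have equal shapes", call. = FALSE)
  x <- tg_cat(rec_a, rec_b)
  x <- tg_relu(tg_conv2d(x, params$f1$w, params$f1$b, 3L))
  x <- tg_conv2d(x, params$f2$w, params$f2$b, 3L)
  tg_add(tg_scale(tg_add(rec_a, rec_b), 0.5), x)
}

# (H, W, n_z) value -> (z, y, x) volume
hwc_to_volume <- function(v) aperm(v, c(3, 1, 2))

#' Full forward pass: four branches and the hierarchical cascade
#'
#' Cascade order: A = fuse(LFM, LFM_EPI); B = fuse(FLFM, FLFM_EPI);
#' final = fuse(A, B). Branches absent from the model pass through their
#' cascade stage unfused. All available intermediate volumes and the final
#' fused volume are returned for multilevel supervision.
#'
#' @param model A `recon_model`.
#' @param sample A `sample_pair` matching the model geometry.
#' @return List with `nodes` (named `tg_node`s: per-branch and `fuse`) and
#'   `volumes` (the same as `(z, y, x)` arrays).
#' @export
forward_full <- function(model, sample) {
  if (!all(dim(sample$gt)[2:3] == model$target))
    stop("config error: sample geometry does not match the model", call. = FALSE)
  nodes <- list()
  for (b in model$branches) nodes[[b]] <- branch_reconstruct(model, sample, b)
  a <- if (!is.null(nodes$lfm) && !is.null(nodes$lfm_epi))
    fuse_pair(nodes$lfm, nodes$lfm_epi, model$fusion$pair_lfm)
  else nodes$lfm %||% nodes$lfm_epi
  b <- if (!is.null(nodes$flfm) && !is.null(nodes$flfm_epi))
    fuse_pair(nodes$flfm, nodes$flfm_epi, model$fusion$pair_flfm)
  else nodes$flfm %||% nodes$flfm_epi
  final <- if (!is.null(a) && !is.null(b)) fuse_pair(a, b, model$fusion$cross)
  else a %||% b
  nodes$fuse <- final
  vols <- lapply(nodes, function(n) hwc_to_volume(n$value))
  list(nodes = nodes, volumes = vols)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Multilevel supervision loss
#'
#' Mean squared error of each branch volume and the fused volume against the
#' ground truth; the total is the sum of the five terms (absent branches
#' contribute 0).
#'
#' @param outputs Named list of `(z, y, x)` arrays with any of the elements
#'   `lfm`, `flfm`, `lfm_epi`, `flfm_epi`, `fuse`.
#' @param gt Ground-truth volume `(z, y, x)`.
#' @return An object of class `loss_breakdown`: `loss_lfm`, `loss_flfm`,
#'   `loss_lfm_epi`, `loss_flfm_epi`, `loss_fuse`, `total`.
#' @export
multilevel_loss <- function(outputs, gt) {
  term <- function(name) {
    o <- outputs[[name]]
    if (is.null(o)) return(0)
    if (!all(dim(o) == dim(gt)))
      stop("shape error: output and ground truth differ", call. = FALSE)
    mean((o - gt)^2)
  }
  out <- list(loss_lfm = term("lfm"), loss_flfm = term("flfm"),
              loss_lfm_epi = term("lfm_epi"),
              loss_flfm_epi = term("flfm_epi"), loss_fuse = term("fuse"))
  out$total <- out$loss_lfm + out$loss_flfm + out$loss_lfm_epi +
    out$loss_flfm_epi + out$loss_fuse
  structure(out, class = "loss_breakdown")
}

#' @export
print.loss_breakdown <- function(x, ...) {
  cat(sprintf(
    "<loss_breakdown> total=%.4g (lfm=%.3g flfm=%.3g lfm_epi=%.3g flfm_epi=%.3g fuse=%.3g)\n",
    x$total, x$loss_lfm, x$loss_flfm, x$loss_lfm_epi, x$loss_flfm_epi,
    x$loss_fuse))
  invisible(x)
}

#' Training configuration
#'
#' @param epochs Training epochs.
#' @param batch_size Samples per gradient step (1 = per-sample updates).
#' @param learning_rate Adam learning rate.
#' @param optimizer Only `"adam"` is implemented.
#' @param seed Master seed for shuffling.
#' @param checkpoint_every Epoch cadence for weight snapshots (0 = none).
#' @return An object of class `train_config`.
#' @export
train_config <- function(epochs = 20, batch_size = 1, learning_rate = 1e-4,
                         optimizer = "adam", seed = 1, checkpoint_every = 0) {
  stopifnot(epochs >= 1, batch_size >= 1, learning_rate > 0,
            optimizer == "adam")
  structure(list(epochs = epochs, batch_size = batch_size,
                 learning_rate = learning_rate, optimizer = optimizer,
                 seed = seed, checkpoint_every = checkpoint_every),
            class = "train_config")
}

#' Train the reconstruction model
#'
#' Seeded Adam loop minimising the multilevel loss over the training samples.
#' If the loss becomes non-finite, training aborts with an error carrying the
#' last finite weights in the condition field `checkpoint`.
#'
#' @param model A `recon_model` (updated in place by reference).
#' @param dataset List of `sample_pair` training samples.
#' @param cfg A `train_config`.
#' @return List with `model` and `history` (one row per epoch with the mean
#'   loss terms).
#' @export
train_recon <- function(model, dataset, cfg = train_config()) {
  if (length(dataset) == 0) stop("empty training set", call. = FALSE)
  params <- model_params(model)
  opt <- adam_state_new(params)
  set.seed(cfg$seed)
  history <- NULL
  checkpoint <- model_get_weights(model)
  for (ep in seq_len(cfg$epochs)) {
    ord <- sample(seq_along(dataset))
    sums <- c(lfm = 0, flfm = 0, lfm_epi = 0, flfm_epi = 0, fuse = 0,
              total = 0)
    n_done <- 0
    for (start in seq(1, length(ord), by = cfg$batch_size)) {
      idx <- ord[start:min(start + cfg$batch_size - 1, length(ord))]
      losses <- list()
      for (si in idx) {
        s <- dataset[[si]]
        fw <- forward_full(model, s)
        gt_hwc <- aperm(s$gt, c(2, 3, 1))
        for (nm in names(fw$nodes))
          losses[[length(losses) + 1L]] <- tg_mse(fw$nodes[[nm]], gt_hwc)
        lb <- multilevel_loss(fw$volumes, s$gt)
        sums <- sums + c(lb$loss_lfm, lb$loss_flfm, lb$loss_lfm_epi,
                         lb$loss_flfm_epi, lb$loss_fuse, lb$total)
        n_done <- n_done + 1
      }
      total <- tg_sum_scalars(losses)
      if (!is.finite(total$value)) {
        cond <- simpleError("training aborted: non-finite loss")
        cond$checkpoint <- checkpoint
        stop(cond)
      }
      tg_backward(total)
      opt <- adam_step(params, opt, lr = cfg$learning_rate)
    }
    history <- rbind(history, data.frame(
      epoch = ep, loss_lfm = sums[["lfm"]] / n_done,
      loss_flfm = sums[["flfm"]] / n_done,
      loss_lfm_epi = sums[["lfm_epi"]] / n_done,
      loss_flfm_epi = sums[["flfm_epi"]] / n_done,
      loss_fuse = sums[["fuse"]] / n_done,
      total = sums[["total"]] / n_done))
    if (cfg$checkpoint_every > 0 && ep %% cfg$checkpoint_every == 0)
      checkpoint <- model_get_weights(model)
  }
  list(model = model, history = history)
}

#' Reconstruct a volume from a sample
#'
#' Forward pass without training; returns the final fused volume (and all
#' intermediate branch volumes).
#'
#' @param model A trained `recon_model`.
#' @param sample A `sample_pair`.
#' @return List with `fused` (`(z, y, x)` array) and `branches` (named list).
#' @export
reconstruct <- function(model, sample) {
  fw <- forward_full(model, sample)
  list(fused = fw$volumes$fuse,
       branches = fw$volumes[setdiff(names(fw$volumes), "fuse")])
}
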