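#' Phantom generator configuration
#'
#' Parameters of the synthetic ground-truth volumes: sparse curvilinear
#' filaments ("tubulin", smooth random spline curves with Gaussian
#' cross-section) or branching vascular trees ("vessel", recursive bifurcating
#' tubes with radius tapering).
#'
#' @param shape Volume shape `c(z, y, x)` in voxels.
#' @param voxel_size Voxel size `c(z, y, x)` in um.
#' @param kind `"tubulin"` or `"vessel"`.
#' @param n_structures Number of filaments (tubulin) or tree roots (vessel).
#' @param radius Structure radius in voxels (Gaussian sigma of the
#'   cross-section, >= 1 recommended).
#' @param intensity_range Length-2, output intensities are scaled so the
#'   maximum equals `intensity_range[2]`.
#' @param seed Integer seed; generation is reproducible given the seed.
#' @param n_control Control points per filament spline (tubulin).
#' @param branch_depth Bifurcation levels (vessel); 0 gives a single tube.
#' @param taper Child/parent radius ratio (vessel), in (0, 1].
#' @param branch_angle Mean bifurcation half-angle in radians (vessel).
#' @return An object of class `phantom_config`.
#' @export
phantom_config <- function(shape = c(31, 64, 64), voxel_size = c(1, 0.34, 0.34),
                           kind = c("tubulin", "vessel"), n_structures = 8,
                           radius = 1, intensity_range = c(0, 1), seed = 1,
                           n_control = 6, branch_depth = 3, taper = 0.75,
                           branch_angle = 0.5) {
  kind <- match.arg(kind)
  if (any(shape <= 0)) stop("invalid-config: shape must be positive", call. = FALSE)
  if (radius < 0.5) stop("invalid-config: radius must be >= 0.5 voxel", call. = FALSE)
  structure(list(shape = as.integer(shape), voxel_size = voxel_size,
                 kind = kind, n_structures = as.integer(n_structures),
                 radius = radius, intensity_range = intensity_range,
                 seed = as.integer(seed), n_control = as.integer(n_control),
                 branch_depth = as.integer(branch_depth), taper = taper,
                 branch_angle = branch_angle),
            class = "phantom_config")
}

#' Full-scale tubulin phantom preset
#'
#' 176 x 176 x 61 voxels at 0.34 / 0.34 / 1 um, sparse filaments.
#' @param seed Integer seed.
#' @return A `phantom_config`.
#' @export
tubulin_preset <- function(seed = 1) {
  phantom_config(shape = c(61, 176, 176), kind = "tubulin", n_structures = 10,
                 radius = 1.2, seed = seed)
}

#' Desk-scale phantom preset
#'
#' 60 x 60 x 31 voxels, for fast end-to-end runs (the lateral size is a
#' multiple of the desk microlens sampling of 5 pixels per lenslet).
#' @param seed Integer seed.
#' @param kind Phantom kind.
#' @return A `phantom_config`.
#' @export
desk_preset <- function(seed = 1, kind = "tubulin") {
  phantom_config(shape = c(31, 60, 60), kind = kind, n_structures = 6,
                 radius = 1, seed = seed)
}

# splat a Gaussian ball of the given sigma (voxels) at a (z,y,x) position
splat_ball <- function(vol, pos, sigma, intensity = 1) {
  d <- dim(vol)
  ext <- ceiling(3 * sigma)
  lo <- pmax(1, floor(pos) - ext)
  hi <- pmin(d, ceiling(pos) + ext)
  if (any(lo > hi)) return(vol)
  zi <- lo[1]:hi[1]; yi <- lo[2]:hi[2]; xi <- lo[3]:hi[3]
  wz <- exp(-((zi - pos[1])^2) / (2 * sigma^2))
  wy <- exp(-((yi - pos[2])^2) / (2 * sigma^2))
  wx <- exp(-((xi - pos[3])^2) / (2 * sigma^2))
  blob <- intensity * outer(wz, outer(wy, wx))
  vol[zi, yi, xi] <- pmax(vol[zi, yi, xi], blob)
  vol
}

# rasterize a polyline with per-point radii by dense ball splatting
splat_path <- function(vol, pts, radii, step = 0.5) {
  n <- nrow(pts)
  for (i in seq_len(n - 1)) {
    seg <- pts[i + 1, ] - pts[i, ]
    len <- sqrt(sum(seg^2))
    k <- max(2, ceiling(len / step))
    for (t in seq(0, 1, length.out = k)) {
      vol <- splat_ball(vol, pts[i, ] + t * seg,
                        radii[i] * (1 - t) + radii[i + 1] * t)
    }
  }
  vol
}

finalize_phantom <- function(vol, cfg) {
  mx <- max(vol)
  if (mx > 0) vol <- vol / mx * cfg$intensity_range[2]
  vol
}

#' Synthetic tubulin volume
#'
#' Rasterizes `n_structures` smooth random 3D curves (cubic-spline
#' interpolation of a random walk of control points) with a Gaussian
#' cross-section of sigma `radius` voxels. Emulates a sparsely labelled
#' filament sample. Reproducible given `cfg$seed`; zero structures yield an
#' all-zero volume with attribute `empty = TRUE`.
#'
#' @param cfg A `phantom_config` with `kind = "tubulin"`.
#' @return Non-negative array `(z, y, x)`.
#' @export
make_tubulin_volume <- function(cfg) {
  stopifnot(inherits(cfg, "phantom_config"))
  if (cfg$kind != "tubulin") stop("cfg$kind must be 'tubulin'", call. = FALSE)
  d <- cfg$shape
  vol <- array(0, dim = d)
  if (cfg$n_structures == 0) {
    warning("phantom has zero structures; returning an empty volume",
            call. = FALSE)
    return(structure(finalize_phantom(vol, cfg), empty = TRUE))
  }
  set.seed(cfg$seed)
  for (s in seq_len(cfg$n_structures)) {
    nc <- cfg$n_control
    # control-point random walk spanning the box
    ctrl <- cbind(stats::runif(1, 1, d[1]) + cumsum(stats::rnorm(nc, 0, d[1] / 6)),
                  stats::runif(1, 1, d[2]) + cumsum(stats::rnorm(nc, 0, d[2] / 4)),
                  stats::runif(1, 1, d[3]) + cumsum(stats::rnorm(nc, 0, d[3] / 4)))
    tt <- seq_len(nc)
    n_out <- 12L * nc
    to <- seq(1, nc, length.out = n_out)
    pts <- cbind(stats::spline(tt, ctrl[, 1], xout = to)$y,
                 stats::spline(tt, ctrl[, 2], xout = to)$y,
                 stats::spline(tt, ctrl[, 3], xout = to)$y)
    vol <- splat_path(vol, pts, rep(cfg$radius, n_out))
  }
  finalize_phantom(vol, cfg)
}

# unit vector orthogonal-ish rotation: rotate dir by angle about a random axis
rotate_dir <- function(dir, angle, axis) {
  axis <- axis / sqrt(sum(axis^2))
  dir * cos(angle) + pracma::cross(axis, dir) * sin(angle) +
    axis * sum(axis * dir) * (1 - cos(angle))
}

#' Synthetic vessel volume
#'
#' Rasterizes `n_structures` recursive bifurcating trees: each branch is a
#' straight tube splatted with a Gaussian cross-section; children leave the
#' parent tip at random angles around `branch_angle` with radius multiplied by
#' `taper`. `branch_depth = 0` gives single straight tubes. The branch
#' segments (positions and radii) are attached as attribute `tree`.
#'
#' @param cfg A `phantom_config` with `kind = "vessel"`.
#' @return Non-negative array `(z, y, x)` with attribute `tree`.
#' @export
make_vessel_volume <- function(cfg) {
  stopifnot(inherits(cfg, "phantom_config"))
  if (cfg$kind != "vessel") stop("cfg$kind must be 'vessel'", call. = FALSE)
  d <- cfg$shape
  vol <- array(0, dim = d)
  if (cfg$n_structures == 0) {
    warning("phantom has zero structures; returning an empty volume",
            call. = FALSE)
    return(structure(finalize_phantom(vol, cfg), empty = TRUE))
  }
  set.seed(cfg$seed)
  segments <- list()
  grow <- function(pos, dir, radius, level) {
    len <- stats::runif(1, 0.25, 0.45) * min(d[2], d[3])
    tip <- pos + dir * len
    segments[[length(segments) + 1]] <<-
      list(from = pos, to = tip, radius = radius, level = level)
    vol <<- splat_path(vol, rbind(pos, tip), c(radius, radius))
    if (level < cfg$branch_depth) {
      for (k in 1:2) {
        ang <- abs(stats::rnorm(1, cfg$branch_angle, cfg$branch_angle / 4))
        axis <- stats::rnorm(3)
        child_dir <- rotate_dir(dir, ifelse(k == 1, ang, -ang), axis)
        child_dir <- child_dir / sqrt(sum(child_dir^2))
        grow(tip, child_dir, radius * cfg$taper, level + 1)
      }
    }
  }
  for (s in seq_len(cfg$n_structures)) {
    pos <- c(stats::runif(1, d[1] * 0.3, d[1] * 0.7),
             stats::runif(1, d[2] * 0.15, d[2] * 0.85),
             stats::runif(1, d[3] * 0.15, d[3] * 0.85))
    dir <- stats::rnorm(3); dir[1] <- dir[1] * 0.3  # mostly lateral growth
    dir <- dir / sqrt(sum(dir^2))
    grow(pos, dir, cfg$radius * 2, 0)
  }
  structure(finalize_phantom(vol, cfg), tree = segments)
}

#' Generate a phantom ground-truth volume
#'
#' Dispatches on `cfg$kind`.
#' @param cfg A `phantom_config`.
#' @return Non-negative array `(z, y, x)`.
#' @export
make_phantom_volume <- function(cfg) {
  switch(cfg$kind,
         tubulin = make_tubulin_volume(cfg),
         vessel = make_vessel_volume(cfg))
}

#' Build a paired multimodal sample
#'
#' Projects a ground-truth volume through both simulated systems and extracts
#' all four EPI stacks.
#'
#' @param gt Ground-truth volume `(z, y, x)`.
#' @param lfm_psf An `lfm_psf`.
#' @param flfm_psf An `flfm_psf`.
#' @param id Sample identifier.
#' @param seed Seed recorded with the sample.
#' @return An object of class `sample_pair` with elements `gt`, `lfm`
#'   (4D light field), `flfm` (view stack), `epi_lfm_uh`, `epi_lfm_vw`,
#'   `epi_flfm_cw`, `epi_flfm_ch`, `id`, `seed`.
#' @export
make_sample_pair <- function(gt, lfm_psf, flfm_psf, id = "sample", seed = NA) {
  lf <- project_lfm(gt, lfm_psf)
  fv <- suppressWarnings(project_flfm(gt, flfm_psf))
  el <- lfm_epi(lf)
  ef <- flfm_epi(fv)
  structure(list(gt = gt, lfm = lf, flfm = fv,
                 epi_lfm_uh = el$uh, epi_lfm_vw = el$vw,
                 epi_flfm_cw = ef$cw, epi_flfm_ch = ef$ch,
                 id = id, seed = seed),
            class = "sample_pair")
}

#' Generate a paired multimodal dataset with a train/test split
#'
#' Generates `n_samples` phantom volumes (per-sample seeds derived from
#' `cfg$seed`), projects each through the LFM and FLFM systems, extracts the
#' four EPI stacks, and splits the samples into train and test subsets by a
#' seeded shuffle at `split_ratio` (default the 8:2 split).
#'
#' @param n_samples Number of samples (>= 2).
#' @param cfg A `phantom_config` (its `shape` must match the PSF geometry).
#' @param lfm_psf An `lfm_psf`.
#' @param flfm_psf An `flfm_psf`.
#' @param split_ratio Fraction of samples assigned to training (default 0.8).
#' @return List with elements `train` and `test`, each a list of
#'   `sample_pair` objects.
#' @export
make_dataset <- function(n_samples, cfg, lfm_psf, flfm_psf, split_ratio = 0.8) {
  if (n_samples < 2) stop("n_samples must be >= 2", call. = FALSE)
  samples <- vector("list", n_samples)
  for (i in seq_len(n_samples)) {
    ci <- cfg
    ci$seed <- cfg$seed + i
    gt <- make_phantom_volume(ci)
    samples[[i]] <- tryCatch(
      make_sample_pair(gt, lfm_psf, flfm_psf,
                       id = sprintf("sample_%03d", i), seed = ci$seed),
      error = function(e) stop(sprintf("projection failed for sample_%03d: %s",
                                       i, conditionMessage(e)), call. = FALSE))
  }
  set.seed(cfg$seed)
  ord <- sample.int(n_samples)
  n_train <- round(split_ratio * n_samples)
  list(train = samples[ord[seq_len(n_train)]],
       test = samples[ord[-seq_len(n_train)]])
}

#' Write or read a sample directory
#'
#' One directory per sample: `gt.tif`, `lfm.tif` (views as pages), `flfm.tif`,
#' `epi_*.tif`, plus `meta.yaml` with ids, seeds and array dimensions.
#'
#' @param sample A `sample_pair`.
#' @param dir Directory to create.
#' @return `write_sample` returns `dir` invisibly; `read_sample` a
#'   `sample_pair`.
#' @export
write_sample <- function(sample, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  d <- dim(sample$lfm)
  write_stack_tiff(sample$gt, file.path(dir, "gt.tif"))
  write_stack_tiff(lfm_views(sample$lfm), file.path(dir, "lfm.tif"))
  write_stack_tiff(unclass(sample$flfm), file.path(dir, "flfm.tif"))
  write_stack_tiff(sample$epi_lfm_uh, file.path(dir, "epi_lfm_uh.tif"))
  write_stack_tiff(sample$epi_lfm_vw, file.path(dir, "epi_lfm_vw.tif"))
  write_stack_tiff(sample$epi_flfm_cw, file.path(dir, "epi_flfm_cw.tif"))
  write_stack_tiff(sample$epi_flfm_ch, file.path(dir, "epi_flfm_ch.tif"))
  yaml::write_yaml(list(id = sample$id, seed = sample$seed,
                        lf_dims = d,
                        view_corners = attr(sample$flfm, "view_corners"),
                        view_size = attr(sample$flfm, "view_size")),
                   file.path(dir, "meta.yaml"))
  invisible(dir)
}

#' @rdname write_sample
#' @export
read_sample <- function(dir) {
  meta <- yaml::read_yaml(file.path(dir, "meta.yaml"))
  d <- unlist(meta$lf_dims)
  fl <- read_stack_tiff(file.path(dir, "flfm.tif"))
  structure(list(
    gt = read_stack_tiff(file.path(dir, "gt.tif")),
    lfm = lfm_views_inverse(read_stack_tiff(file.path(dir, "lfm.tif")),
                            d[1], d[2]),
    flfm = structure(fl, class = "flfm_view_stack",
                     view_corners = lapply(meta$view_corners, unlist),
                     view_size = meta$view_size),
    epi_lfm_uh = read_stack_tiff(file.path(dir, "epi_lfm_uh.tif")),
    epi_lfm_vw = read_stack_tiff(file.path(dir, "epi_lfm_vw.tif")),
    epi_flfm_cw = read_stack_tiff(file.path(dir, "epi_flfm_cw.tif")),
    epi_flfm_ch = read_stack_tiff(file.path(dir, "epi_flfm_ch.tif")),
    id = meta$id, seed = meta$seed), class = "sample_pair")
}
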