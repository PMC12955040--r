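#' Desk-scale dual-modality geometry
#'
#' Builds the matched LFM/FLFM point-spread-function pair used by the
#' desk-scale benchmark and the command-line tools: a 40x/0.8 NA LFM system
#' with 5 sensor pixels per lenslet over a 6x6-lenslet patch (30 x 30 voxel
#' lateral field at 0.75 um pitch) and the 100x/1.4 NA Fourier system with
#' seven 2-3-2 views at the same voxel pitch, both over 16 depth planes from
#' -7.5 to 7.5 um in 1 um steps.
#'
#' @return List with elements `lfm` (an `lfm_psf`) and `flfm` (an
#'   `flfm_psf`).
#' @export
desk_psf_pair <- function() {
  mla <- mla_config(pitch = 150, focal_length = 3500, n_pix = 5)
  cfg <- optical_config(0.8, 40, 580, 1.33, 30, seq(-7.5, 7.5, 1), 30, 30)
  lpsf <- compute_lfm_psf(cfg, mla, n_lenslets = 6)
  fcfg <- flfm_optics_preset(n_depth = 16, depth_half_range = 7.5)
  fpsf <- compute_flfm_psf(fcfg, flfm_mla_preset(),
                           aperture = aperture_profile(0, 0.9, 8),
                           view_size = 30, voxel_pitch = lpsf$voxel_pitch)
  list(lfm = lpsf, flfm = fpsf)
}

#' Desk-scale benchmark dataset
#'
#' Twenty seeded tubulin phantoms (30 x 30 x 16 voxels, four filaments each)
#' projected through the [desk_psf_pair()] geometry and split 8:2.
#'
#' @param psfs PSF pair from [desk_psf_pair()].
#' @param seed Master seed.
#' @param n_samples Number of samples (default 20).
#' @return List with `train` and `test` sample lists.
#' @export
desk_benchmark_dataset <- function(psfs, seed = 11, n_samples = 20) {
  pc <- phantom_config(shape = c(16, 30, 30), kind = "tubulin",
                       n_structures = 4, radius = 1, seed = seed)
  make_dataset(n_samples, pc, psfs$lfm, psfs$flfm)
}

#' Train one desk-scale reconstruction model
#'
#' The benchmark protocol: unified channel width 12, U-Net depth 2 / width
#' 12, fusion width 16, 28 epochs of Adam at learning rate 2e-3.
#'
#' @param dataset From [desk_benchmark_dataset()].
#' @param branches Branch subset to train.
#' @param seed Seed for initialisation and sample order.
#' @param epochs Training epochs.
#' @return The trained `recon_model`.
#' @export
desk_train <- function(dataset, branches = c("lfm", "flfm", "lfm_epi",
                                             "flfm_epi"),
                       seed = 1, epochs = 28) {
  model <- build_recon_model(dataset$train[[1]], branches = branches,
                             unified_channels = 12, unet_depth = 2,
                             base_width = 12, fusion_width = 16,
                             seed = seed)
  train_recon(model, dataset$train,
              train_config(epochs = epochs, learning_rate = 2e-3,
                           seed = seed + 1000))
  model
}
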