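#' Read and write 3D arrays as multi-page TIFF
#'
#' Volumes and stacks are stored one page per leading-axis slice as 32-bit
#' float TIFF. Values are scaled into `[0, 1]` on write; the scale factor is
#' stored in a small YAML sidecar (`<path>.yaml`) and undone on read.
#'
#' @param arr 3D numeric array `(slice, y, x)`.
#' @param path Output file path (`.tif`).
#' @return `write_stack_tiff` returns `path` invisibly; `read_stack_tiff`
#'   the array.
#' @export
write_stack_tiff <- function(arr, path) {
  stopifnot(length(dim(arr)) == 3)
  mn <- min(arr)
  mx <- max(arr)
  scale <- if (mx > mn) mx - mn else 1
  pages <- lapply(seq_len(dim(arr)[1]), function(i) (arr[i, , ] - mn) / scale)
  tiff::writeTIFF(pages, path, bits.per.sample = 32L, reduce = FALSE)
  yaml::write_yaml(list(offset = mn, scale = scale, dim = dim(arr)),
                   paste0(path, ".yaml"))
  invisible(path)
}

#' @rdname write_stack_tiff
#' @export
read_stack_tiff <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  meta <- yaml::read_yaml(paste0(path, ".yaml"))
  arr <- array(0, dim = c(length(pages), nrow(pages[[1]]), ncol(pages[[1]])))
  for (i in seq_along(pages)) arr[i, , ] <- pages[[i]]
  arr * meta$scale + meta$offset
}
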