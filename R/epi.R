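#' Epipolar-plane-image stacks from a 4D LFM light field
#'
#' Rearranges `L(u, v, w, h)` (with `u` the angular and `h` the spatial index
#' along x, `v`/`w` their y counterparts) into the two EPI channel stacks:
#' the u-h plane stack `(v*w, u, h)` (channels ordered v-major then w) and the
#' v-w plane stack `(u*h, v, w)` (channels ordered u-major then h). Both are
#' pure axis permutations and bit-exactly invertible.
#'
#' @param lf 4D array `(u, v, w, h)`.
#' @return List with elements `uh` (array `(v*w, u, h)`) and `vw`
#'   (array `(u*h, v, w)`).
#' @export
lfm_epi <- function(lf) {
  d <- dim(lf)
  stopifnot(length(d) == 4)
  uh <- aperm(lf, c(3, 2, 1, 4))          # (w, v, u, h); collapse -> v-major, w
  dim(uh) <- c(d[3] * d[2], d[1], d[4])
  vw <- aperm(lf, c(4, 1, 2, 3))          # (h, u, v, w); collapse -> u-major, h
  dim(vw) <- c(d[4] * d[1], d[2], d[3])
  list(uh = uh, vw = vw)
}

#' Invert [lfm_epi()]
#'
#' Reconstructs the 4D light field from either EPI stack.
#'
#' @param stack An EPI stack produced by [lfm_epi()].
#' @param which `"uh"` or `"vw"`, which layout `stack` holds.
#' @param dims The original light-field dimensions `c(u, v, w, h)`.
#' @return The 4D light field, bit-exact.
#' @export
lfm_epi_inverse <- function(stack, which = c("uh", "vw"), dims) {
  which <- match.arg(which)
  if (which == "uh") {
    dim(stack) <- c(dims[3], dims[2], dims[1], dims[4])
    aperm(stack, c(3, 2, 1, 4))
  } else {
    dim(stack) <- c(dims[4], dims[1], dims[2], dims[3])
    aperm(stack, c(2, 3, 4, 1))
  }
}

# view indices used for the FLFM EPI stacks: the central row of the 2-3-2
# layout, and the collinear near-vertical triple (top-left, centre,
# bottom-right) -- a 2-3-2 arrangement has no strictly vertical triple
flfm_epi_row_views <- function() c(3L, 4L, 5L)
flfm_epi_col_views <- function() c(1L, 4L, 7L)

#' Epipolar-plane-image stacks from an FLFM view stack
#'
#' Builds the c-w plane stack `(h, c, w)` from the central row of the 2-3-2
#' layout and the c-h plane stack `(w, c, h)` from the collinear
#' top-left/centre/bottom-right triple, `c = 3` views in both cases. Both are
#' bit-exactly invertible to the selected views.
#'
#' @param views An `flfm_view_stack` (array `(7, w, h)`).
#' @return List with elements `cw` (array `(h, 3, w)`) and `ch`
#'   (array `(w, 3, h)`).
#' @export
flfm_epi <- function(views) {
  d <- dim(views)
  if (length(d) != 3 || d[1] != 7)
    stop("geometry error: expected a (7, w, h) 2-3-2 view stack", call. = FALSE)
  va <- unclass(views)
  row_sub <- va[flfm_epi_row_views(), , , drop = FALSE]   # (3, w, h)
  col_sub <- va[flfm_epi_col_views(), , , drop = FALSE]
  cw <- aperm(row_sub, c(3, 1, 2))                        # (h, c, w)
  ch <- aperm(col_sub, c(2, 1, 3))                        # (w, c, h)
  list(cw = cw, ch = ch)
}

#' Invert [flfm_epi()]
#'
#' @param cw,ch The two stacks produced by [flfm_epi()].
#' @return List with `row_views` and `col_views`, each `(3, w, h)`, equal to
#'   the selected views bit-exactly.
#' @export
flfm_epi_inverse <- function(cw, ch) {
  list(row_views = aperm(cw, c(2, 3, 1)),
       col_views = aperm(ch, c(2, 1, 3)))
}

# separable Gaussian smoothing with edge replication
epi_smooth <- function(m, sigma) {
  r <- ceiling(3 * sigma)
  k <- stats::dnorm(-r:r, sd = sigma)
  k <- k / sum(k)
  h <- nrow(m); w <- ncol(m)
  ri <- pmin(pmax(outer(seq_len(h), -r:r, "+"), 1), h)
  out <- matrix(0, h, w)
  for (j in seq_along(k)) out <- out + k[j] * m[ri[, j], , drop = FALSE]
  ci <- pmin(pmax(outer(seq_len(w), -r:r, "+"), 1), w)
  out2 <- matrix(0, h, w)
  for (j in seq_along(k)) out2 <- out2 + k[j] * out[, ci[, j], drop = FALSE]
  out2
}

# plain structure-tensor orientation of a slice (slope, or NA flag)
epi_tensor_slope <- function(m, sigma) {
  m <- epi_smooth(m, sigma)
  nu <- nrow(m); nh <- ncol(m)
  gu <- (m[-(1:2), , drop = FALSE] - m[1:(nu - 2), , drop = FALSE]) / 2
  gu <- gu[, -c(1, nh), drop = FALSE]
  gh <- (m[, -(1:2), drop = FALSE] - m[, 1:(nh - 2), drop = FALSE]) / 2
  gh <- gh[-c(1, nu), , drop = FALSE]
  if (nrow(gu) < 1 || ncol(gh) < 1)
    return(structure(NA_real_, undefined = TRUE))
  juu <- sum(gu * gu); jhh <- sum(gh * gh); juh <- sum(gu * gh)
  if (juu + jhh <= 1e-20) return(structure(NA_real_, undefined = TRUE))
  e <- eigen(matrix(c(juu, juh, juh, jhh), 2, 2), symmetric = TRUE)
  # tie: no dominant orientation, break toward slope 0
  if (abs(e$values[1] - e$values[2]) <= 1e-12 * max(e$values)) return(0)
  v <- e$vectors[, 2]                      # smallest eigenvalue: line direction
  if (abs(v[1]) < 1e-12 * abs(v[2])) return(Inf)
  v[2] / v[1]
}

# shear the slice so lines of slope s become vertical (linear interpolation)
epi_shear <- function(m, s) {
  h <- nrow(m); w <- ncol(m)
  u0 <- (h + 1) / 2
  out <- matrix(0, h, w)
  for (u in seq_len(h)) {
    pos <- seq_len(w) + s * (u - u0)
    i <- floor(pos)
    t <- pos - i
    ok <- i >= 1 & i < w
    out[u, ok] <- m[u, i[ok]] * (1 - t[ok]) + m[u, i[ok] + 1] * t[ok]
  }
  out
}

#' Dominant line slope of an EPI slice
#'
#' Structure-tensor estimate of the dominant orientation of an EPI slice
#' (rows = view index, columns = spatial index), returned as spatial pixels
#' per view step. The slice is Gaussian pre-smoothed, and the tensor estimate
#' is refined by shearing the slice with the current estimate and measuring
#' the residual orientation, which removes the finite-difference bias for
#' steep lines. Ties in the tensor orientation are broken toward slope 0; a
#' (near-)constant slice yields `NA` with attribute `undefined = TRUE`.
#'
#' @param epi_slice Numeric matrix with at least 2 view rows.
#' @param sigma Pre-smoothing width in pixels (default 1).
#' @param refine Number of shear-refinement passes (default 2).
#' @return Scalar slope (possibly `Inf` for structure varying only along the
#'   view axis), or flagged `NA`.
#' @export
epi_dominant_slope <- function(epi_slice, sigma = 1, refine = 2) {
  if (!is.matrix(epi_slice) || nrow(epi_slice) < 2)
    stop("epi_slice must be a matrix with >= 2 view rows", call. = FALSE)
  rng <- max(epi_slice) - min(epi_slice)
  if (rng <= 1e-12 * max(abs(epi_slice), 1))
    return(structure(NA_real_, undefined = TRUE))
  m <- epi_slice / rng
  s <- epi_tensor_slope(m, sigma)
  if (is.na(s) || is.infinite(s)) return(s)
  for (k in seq_len(refine)) {
    ds <- epi_tensor_slope(epi_shear(m, s), sigma)
    if (is.na(ds) || is.infinite(ds)) break
    s <- s + ds
  }
  s
}
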