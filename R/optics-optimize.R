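#' Aperture-profile optimization state
#'
#' State for tailoring the Fourier-plane aperture transmission P so the
#' simulated point-spread function matches a target. The simulated PSF is the
#' intensity of a linear image of the windowed pupil field,
#' \eqn{PSF_{sim}(P) = |L(U_0 \odot P)|^2}, where `L` is band-limited
#' angular-spectrum propagation over `propagate_distance` (the identity when 0).
#' The objective is
#' \deqn{J(P) = \|PSF_{target} - PSF_{sim}(P)\|_2^2 + \lambda_1 \|\nabla P\|_1}
#' with forward-difference total variation.
#'
#' @param profile Real matrix, current transmission P in `[0,1]`.
#' @param target_psf Real matrix, target intensity PSF.
#' @param pupil_field A `complex_field` U0 on the same grid.
#' @param step_size Gradient step \eqn{\eta} (> 0).
#' @param lambda1 Total-variation weight \eqn{\lambda_1 \ge 0}.
#' @param propagate_distance Propagation distance of `L` in um (default 0).
#' @return An object of class `aperture_opt_state`.
#' @export
aperture_opt_state <- function(profile, target_psf, pupil_field,
                               step_size = 1e-3, lambda1 = 0,
                               propagate_distance = 0) {
  stopifnot(is.matrix(profile), all(dim(profile) == dim(target_psf)),
            all(dim(profile) == dim(pupil_field$values)))
  if (step_size <= 0) stop("step_size must be > 0", call. = FALSE)
  if (lambda1 < 0) stop("lambda1 must be >= 0", call. = FALSE)
  st <- structure(list(
    profile = profile, target_psf = target_psf, pupil_field = pupil_field,
    step_size = step_size, lambda1 = lambda1,
    propagate_distance = propagate_distance,
    simulated_psf = NULL, objective_history = numeric(0)
  ), class = "aperture_opt_state")
  st$simulated_psf <- aperture_simulate(st, profile)
  st
}

# linear imaging operator L and its adjoint (unitary band-limited propagation)
aperture_L <- function(state, v) {
  if (state$propagate_distance == 0) return(v)
  f <- complex_field(v, state$pupil_field$spacing, state$pupil_field$wavelength)
  propagate_angular_spectrum(f, state$propagate_distance, pad = FALSE)$values
}

aperture_Lt <- function(state, v) {
  if (state$propagate_distance == 0) return(v)
  f <- complex_field(v, state$pupil_field$spacing, state$pupil_field$wavelength)
  propagate_angular_spectrum(f, -state$propagate_distance, pad = FALSE)$values
}

# simulated intensity PSF for a given profile
aperture_simulate <- function(state, profile) {
  e <- aperture_L(state, state$pupil_field$values * profile)
  Mod(e)^2
}

# forward-difference anisotropic TV, |P[i+1,j]-P[i,j]| + |P[i,j+1]-P[i,j]|
tv_l1 <- function(p) {
  sum(abs(diff(p))) + sum(abs(t(diff(t(p)))))
}

# subgradient of tv_l1 (0 at ties)
tv_l1_grad <- function(p) {
  g <- matrix(0, nrow(p), ncol(p))
  dy <- sign(diff(p))                       # (n-1) x n
  g[-1, ] <- g[-1, ] + dy
  g[-nrow(p), ] <- g[-nrow(p), ] - dy
  dx <- sign(t(diff(t(p))))                 # n x (n-1)
  g[, -1] <- g[, -1] + dx
  g[, -ncol(p)] <- g[, -ncol(p)] - dx
  g
}

#' Objective and gradient of the aperture optimization
#'
#' @param state An `aperture_opt_state`.
#' @param profile Optional profile at which to evaluate (defaults to the
#'   state's current profile).
#' @return `aperture_objective` returns the scalar J; `aperture_gradient` the
#'   gradient matrix dJ/dP.
#' @export
aperture_objective <- function(state, profile = state$profile) {
  s <- aperture_simulate(state, profile)
  sum((state$target_psf - s)^2) + state$lambda1 * tv_l1(profile)
}

#' @rdname aperture_objective
#' @export
aperture_gradient <- function(state, profile = state$profile) {
  u0 <- state$pupil_field$values
  e <- aperture_L(state, u0 * profile)
  s <- Mod(e)^2
  resid <- s - state$target_psf
  # d/dP sum((s - T)^2) with s = |L(U0 P)|^2
  g_data <- 4 * Re(Conj(u0) * aperture_Lt(state, resid * e))
  g_data + state$lambda1 * tv_l1_grad(profile)
}

#' Gradient-descent refinement of the aperture profile
#'
#' Runs `n_iter` descent steps \eqn{P_{n+1} = P_n - \eta \nabla J(P_n)}
#' (projected back onto `[0,1]`). If a step would increase J, the step size is
#' halved, up to 20 times; if J still increases, a convergence-failure error
#' carrying the objective history is raised.
#'
#' @param state An `aperture_opt_state`.
#' @param n_iter Number of iterations.
#' @return The updated `aperture_opt_state` with appended `objective_history`.
#' @export
optimize_aperture <- function(state, n_iter) {
  p <- state$profile
  eta <- state$step_size
  hist <- state$objective_history
  j_cur <- aperture_objective(state, p)
  if (length(hist) == 0) hist <- j_cur
  for (it in seq_len(n_iter)) {
    g <- aperture_gradient(state, p)
    accepted <- FALSE
    for (halving in 0:20) {
      cand <- pmin(pmax(p - eta * g, 0), 1)
      j_new <- aperture_objective(state, cand)
      if (j_new <= j_cur + 1e-12 * max(1, abs(j_cur))) {
        accepted <- TRUE
        break
      }
      eta <- eta / 2
    }
    if (!accepted) {
      cond <- simpleError("convergence failure: objective increased after step-size exhaustion")
      cond$objective_history <- hist
      stop(cond)
    }
    p <- cand
    j_cur <- j_new
    hist <- c(hist, j_cur)
  }
  state$profile <- p
  state$step_size <- eta
  state$objective_history <- hist
  state$simulated_psf <- aperture_simulate(state, p)
  state
}
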