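#' System state of one epidemic episode
#'
#' Bundles the scaled state variables: susceptible density `s` (units
#' `K`), per-variant lysogen densities `l` (units `K`), per-variant
#' free-phage densities `p` (scaled as `p = bP/K`), arbitrium
#' concentration `A` (units `cK`), and the episode's carrying capacity
#' `k` (units `K`; 1 unless carrying-capacity noise is active).
#'
#' @param s Susceptible density (scalar, >= 0).
#' @param l,p Numeric vectors of lysogen and free-phage densities, one
#'   entry per variant, all >= 0.
#' @param A Arbitrium concentration (scalar, >= 0).
#' @param k Episode carrying capacity (scalar, > 0). Default 1.
#' @return An object of class `"system_state"`.
#' @export
system_state <- function(s, l, p, A = 0, k = 1) {
  if (length(l) != length(p))
    stop("'l' and 'p' must have the same length", call. = FALSE)
  st <- structure(list(s = as.numeric(s), l = as.numeric(l),
                       p = as.numeric(p), A = as.numeric(A),
                       k = as.numeric(k)),
                  class = "system_state")
  validate_system_state(st)
  st
}

validate_system_state <- function(st) {
  if (length(st$s) != 1L || length(st$A) != 1L || length(st$k) != 1L)
    stop("'s', 'A' and 'k' must be scalars", call. = FALSE)
  vals <- c(st$s, st$l, st$p, st$A)
  if (anyNA(vals) || any(vals < 0))
    stop("state components must be non-negative and finite", call. = FALSE)
  if (!is.finite(st$k) || st$k <= 0)
    stop("'k' must be positive", call. = FALSE)
  invisible(st)
}

#' @export
print.system_state <- function(x, ...) {
  cat(sprintf(
    "System state: s = %.4g, sum(l) = %.4g, sum(p) = %.4g, A = %.4g, k = %g (%d variants)\n",
    x$s, sum(x$l), sum(x$p), x$A, x$k, length(x$l)))
  invisible(x)
}

pack_state <- function(state) c(state$s, state$l, state$p, state$A)

unpack_state <- function(y, k) {
  n <- (length(y) - 2L) %/% 2L
  structure(list(s = y[1L], l = y[2L:(n + 1L)],
                 p = y[(n + 2L):(2L * n + 1L)], A = y[2L * n + 2L],
                 k = k),
            class = "system_state")
}

#' Arbitrium-dependent lysogeny propensity
#'
#' The lysis-lysogeny decision is modelled as a step response: a
#' communicating phage causes purely lytic infections while the
#' arbitrium concentration is below its response threshold, and switches
#' to lysogeny propensity `phi_max` once the concentration reaches the
#' threshold. The boundary is closed (`A >= theta` yields `phi_max`),
#' so `theta = 0` reproduces a constant, signal-independent propensity.
#'
#' @param phi_max Maximal lysogeny propensity in \[0, 1\].
#' @param theta Response threshold in units of `cK`, >= 0.
#' @param A Arbitrium concentration in units of `cK`, >= 0.
#' @return The realised lysogeny propensity, `phi_max` if `A >= theta`
#'   and 0 otherwise. All arguments recycle to a common length.
#' @examples
#' lysogeny_propensity(1, 0.65, 0)    # early epidemic: fully lytic
#' lysogeny_propensity(0.7, 0, 0)     # threshold 0: constant propensity
#' @export
lysogeny_propensity <- function(phi_max, theta, A) {
  if (any(phi_max < 0 | phi_max > 1))
    stop("'phi_max' must lie in [0, 1]", call. = FALSE)
  if (any(theta < 0)) stop("'theta' must be non-negative", call. = FALSE)
  if (any(A < 0)) stop("'A' must be non-negative", call. = FALSE)
  ifelse(A >= theta, phi_max, 0)
}

#' Nearest-neighbour mutation operator
#'
#' Redistributes phage burst mass between neighbouring variants on the
#' trait grid. Per trait axis, a fraction `mu` of each variant's mass
#' moves to its grid neighbours, split equally when both neighbours
#' exist; at the grid boundary the outward half-flux is retained by the
#' source variant, so total mass is conserved exactly. The two axes act
#' as sequential independent linear operators (propensity axis first).
#'
#' @param burst Non-negative numeric vector of per-variant burst terms.
#' @param grid A `"variant_grid"` describing neighbour structure.
#' @param mu_phi,mu_theta Mutation probabilities per axis, in \[0, 1).
#' @return Numeric vector of the same length with identical sum.
#' @examples
#' g <- constant_grid(seq(0, 0.1, by = 0.01))
#' w <- numeric(11); w[6] <- 1
#' mutation_operator(w, g, mu_phi = 0.01, mu_theta = 0)
#' @export
mutation_operator <- function(burst, grid, mu_phi, mu_theta) {
  if (length(burst) != grid$n_variants)
    stop("'burst' length does not match the grid", call. = FALSE)
  if (any(burst < 0)) stop("'burst' must be non-negative", call. = FALSE)
  m <- matrix(burst, nrow = grid$n_phi, ncol = grid$n_theta)
  m <- mutate_axis_rows(m, mu_phi)
  m <- t(mutate_axis_rows(t(m), mu_theta))
  as.vector(m)
}

# Apply the one-axis kernel along the rows of m (axis length nrow(m)).
mutate_axis_rows <- function(m, mu) {
  n <- nrow(m)
  if (n == 1L || mu == 0) return(m)
  out <- (1 - mu) * m
  half <- (mu / 2) * m
  # inward fluxes from neighbours
  out[1:(n - 1), ] <- out[1:(n - 1), ] + half[2:n, ]
  out[2:n, ] <- out[2:n, ] + half[1:(n - 1), ]
  # boundary variants retain the outward half-flux
  out[1, ] <- out[1, ] + half[1, ]
  out[n, ] <- out[n, ] + half[n, ]
  out
}

#' Scaled time derivatives of the epidemic model
#'
#' Right-hand side of the nondimensionalised ODE system for susceptible
#' cells, per-variant lysogens and free phages, and the arbitrium
#' concentration:
#' \deqn{ds/d\tau = g\,s(1 - n/k) - \hat a\, s \sum_i p_i}
#' \deqn{dl_i/d\tau = g\,l_i(1 - n/k) + \varphi_i(A)\,\hat a\,s\,p_i - \hat\alpha\,l_i}
#' \deqn{dp_i/d\tau = [M(\hat B \hat\alpha l + \hat B (1-\varphi(A))\,\hat a\,s\,p)]_i - \hat\delta p_i - \hat a\, n\, p_i}
#' \deqn{dA/d\tau = \hat a\, s \sum_i p_i - \hat u\, n\, A}
#' where `n = s + sum(l)` is the total bacterial density, `g` the
#' logistic growth switch and `M` the [mutation_operator()] applied to
#' the vector of burst terms.
#'
#' This is the reference R implementation; episode integration uses an
#' equivalent compiled version for speed (the two are required to agree
#' to near machine precision).
#'
#' @param state A [system_state()].
#' @param params A [scaled_params()] object.
#' @param grid A `"variant_grid"` consistent with the state.
#' @return A list with components `s`, `l`, `p`, `A` holding the time
#'   derivatives (the carrying capacity `k` has no dynamics).
#' @export
scaled_derivatives <- function(state, params, grid) {
  check_state_grid(state, grid)
  s <- state$s; l <- state$l; p <- state$p; A <- state$A; k <- state$k
  g <- params$growth_switch
  n_tot <- s + sum(l)
  growth <- g * (1 - n_tot / k)
  phi <- lysogeny_propensity(grid$phi_max, grid$theta, A)
  infect <- params$a_hat * s * p          # per-variant infection flux
  burst <- params$B_eff * (params$alpha_hat * l + (1 - phi) * infect)
  burst <- mutation_operator(burst, grid, params$mu_phi, params$mu_theta)
  list(
    s = growth * s - params$a_hat * s * sum(p),
    l = growth * l + phi * infect - params$alpha_hat * l,
    p = burst - params$delta_hat * p - params$a_hat * n_tot * p,
    A = params$a_hat * s * sum(p) - params$u_hat * n_tot * A
  )
}

# deSolve-compatible wrapper around the reference R derivatives
derivs_r <- function(t, y, parms) {
  state <- unpack_state(y, parms$k)
  d <- scaled_derivatives(state, parms$params, parms$grid)
  list(c(d$s, d$l, d$p, d$A))
}

# Pack parameters for the compiled right-hand side and install them in
# the DLL's static buffer. Must be called immediately before ode().
set_compiled_parms <- function(params, grid, k) {
  n <- grid$n_variants
  pv <- c(params$growth_switch, k, params$a_hat, params$B_eff,
          params$delta_hat, params$alpha_hat, params$u_hat,
          params$mu_phi, params$mu_theta, grid$n_phi, grid$n_theta,
          grid$phi_max, grid$theta)
  .C(C_set_phage_parms, as.double(pv), as.integer(length(pv)),
     status = integer(1))$status
}

#' Integrate one epidemic episode
#'
#' Deterministically integrates the scaled model over one passaging
#' episode of duration `params$T`, using an adaptive-step solver
#' (`deSolve::lsoda`) with compiled derivatives. Tiny negative solver
#' excursions (bounded by `clip_tol`) are clipped to zero in the stored
#' states; larger negative values raise an error.
#'
#' @param state0 Initial [system_state()].
#' @param params A [scaled_params()] object.
#' @param grid The `"variant_grid"`.
#' @param times Numeric vector of output times in `[0, T]`. Default
#'   `c(0, T)` (start and end only, the cheapest choice for passaging
#'   loops); supply a finer vector to record within-episode dynamics.
#' @param rtol,atol Relative and absolute integrator tolerances.
#' @param clip_tol Magnitude below which negative state components are
#'   clipped to zero (default `10 * atol` scaled up to 1e-9 for
#'   robustness against discontinuity-crossing excursions).
#' @return An object of class `"episode_trajectory"`: list with `times`,
#'   a numeric state matrix `states` (one row per time, columns
#'   `s`, `l` block, `p` block, `A`), the episode `k`, and the `grid`.
#' @export
integrate_episode <- function(state0, params, grid,
                              times = c(0, params$T),
                              rtol = 1e-8, atol = 1e-12,
                              clip_tol = 1e-9) {
  check_state_grid(state0, grid)
  validate_system_state(state0)
  if (times[1] != 0) stop("'times' must start at 0", call. = FALSE)
  if (grid$n_variants > 4096L)
    stop("variant grids beyond 4096 variants are not supported",
         call. = FALSE)
  set_compiled_parms(params, grid, state0$k)
  y0 <- pack_state(state0)
  sol <- deSolve::ode(y = y0, times = times, func = "phage_derivs",
                      parms = NULL, dllname = "arbitrium",
                      initfunc = NULL, nout = 0,
                      method = "lsoda", rtol = rtol, atol = atol,
                      maxsteps = 50000)
  if (attr(sol, "istate")[1] < 0)
    stop(sprintf("episode integration failed near t = %.6g",
                 attr(sol, "rstate")[1]), call. = FALSE)
  states <- unname(sol[, -1, drop = FALSE])
  neg <- states < 0
  if (any(neg)) {
    worst <- min(states[neg])
    if (worst < -clip_tol)
      stop(sprintf("integration produced a negative component (%.3g)",
                   worst), call. = FALSE)
    states[neg] <- 0
  }
  structure(list(times = as.numeric(sol[, 1]), states = states,
                 k = state0$k, grid = grid),
            class = "episode_trajectory")
}

#' Extract the state at a trajectory time point
#'
#' @param traj An `"episode_trajectory"`.
#' @param i Row index (default: final time point).
#' @return A [system_state()].
#' @export
episode_state <- function(traj, i = nrow(traj$states)) {
  unpack_state(traj$states[i, ], traj$k)
}

#' @export
print.episode_trajectory <- function(x, ...) {
  fin <- episode_state(x)
  cat(sprintf("Episode trajectory: %d time points over [0, %g]\n",
              length(x$times), max(x$times)))
  cat(sprintf("  final: s = %.4g, sum(l) = %.4g, sum(p) = %.4g, A = %.4g\n",
              fin$s, sum(fin$l), sum(fin$p), fin$A))
  invisible(x)
}

#' @export
as.data.frame.episode_trajectory <- function(x, ...) {
  n <- x$grid$n_variants
  labs <- variant_labels(x$grid)
  df <- data.frame(time = x$times, s = x$states[, 1],
                   A = x$states[, 2 * n + 2], k = x$k)
  lmat <- x$states[, 2:(n + 1), drop = FALSE]
  pmat <- x$states[, (n + 2):(2 * n + 1), drop = FALSE]
  colnames(lmat) <- paste0("l.", labs)
  colnames(pmat) <- paste0("p.", labs)
  cbind(df, lmat, pmat)
}
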