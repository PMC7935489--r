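#' Closed-form ESS lysogeny propensity
#'
#' Analytic approximation for the evolutionarily stable constant
#' lysogeny propensity under long serial-passaging intervals:
#' \deqn{\phi^* = 1 - (bB)^{-1} \log(BK / P_0)}
#' where `P0` is the free-phage density at the start of a passaging
#' episode. The raw expression can leave \[0, 1\] for weakly infective
#' phages or tiny inocula; the returned value is clamped, with the
#' attribute `"clamped"` flagging when that happened.
#'
#' `phi_star_scaled()` is the same formula in dimensionless variables:
#' with `p0 = b P0 / K` the argument of the logarithm is `B_eff / p0`.
#'
#' @param b Infection success probability (0, 1].
#' @param B Burst size, > 0.
#' @param K Carrying capacity, > 0.
#' @param P0 Episode-start phage density, > 0.
#' @return The clamped ESS propensity with attribute `clamped`.
#' @seealso [theta_star_closed_form()]
#' @export
phi_star_closed_form <- function(b, B, K, P0) {
  if (any(c(b, B, K, P0) <= 0))
    stop("all arguments must be strictly positive", call. = FALSE)
  raw <- 1 - log(B * K / P0) / (b * B)
  out <- min(max(raw, 0), 1)
  attr(out, "clamped") <- (raw != out)
  out
}

#' @rdname phi_star_closed_form
#' @param B_eff Effective burst size `bB`.
#' @param p0 Scaled episode-start phage density `b P0 / K`.
#' @export
phi_star_scaled <- function(B_eff, p0) {
  if (any(c(B_eff, p0) <= 0))
    stop("all arguments must be strictly positive", call. = FALSE)
  raw <- 1 - log(B_eff / p0) / B_eff
  out <- min(max(raw, 0), 1)
  attr(out, "clamped") <- (raw != out)
  out
}

#' Closed-form ESS response threshold
#'
#' Analytic approximation for the evolutionarily stable arbitrium
#' response threshold of a fully switching communicator
#' (`phi_max = 1`), in units of `cK`:
#' \deqn{\theta^*/(cK) = \frac{1}{2 - (bB)^{-1}}}
#' It decreases with the effective burst size and converges to 1/2 for
#' highly infective phages: such phages are predicted to switch from
#' lytic to lysogenic infections when about half of the susceptible
#' cells have been infected. The expression is valid for
#' `B_eff > 1/2` only.
#'
#' @param B_eff Effective burst size `bB`, > 1/2.
#' @return `theta*` in units of `cK`.
#' @export
theta_star_closed_form <- function(B_eff) {
  if (any(B_eff <= 0.5))
    stop("'B_eff' must exceed 1/2 for the closed form to apply",
         call. = FALSE)
  1 / (2 - 1 / B_eff)
}

#' Duration of a monomorphic epidemic
#'
#' Time at which the susceptible population of a single-resident
#' episode collapses below a fraction `collapse_eps` of the episode
#' carrying capacity, located by root-finding on the integrated
#' trajectory. The collapse time is the window length available to
#' phages for lysogen production and is the quantity through which the
#' resident strategy feeds back on invader fitness.
#'
#' @param resident Length-2 numeric `c(phi_max, theta)`.
#' @param params A [scaled_params()].
#' @param p0 Scaled free-phage inoculum. Default `1e-5 * B_eff`.
#' @param collapse_eps Collapse threshold as a fraction of the carrying
#'   capacity. Default 1e-3.
#' @param t_max Time cap; if the susceptibles never fall below the
#'   threshold before `t_max`, `NA` is returned (no collapse).
#'   Default `10 * params$T`.
#' @return Collapse time `T_E` (scaled time units), or `NA_real_`.
#' @export
epidemic_duration <- function(resident, params, p0 = 1e-5 * params$B_eff,
                              collapse_eps = 1e-3,
                              t_max = 10 * params$T) {
  bg <- resident_background(resident, params, p0, t_max)
  collapse_time(bg, collapse_eps)
}

# First time the background susceptible density crosses eps, located by
# root-finding on the interpolated trajectory; NA if it never does.
collapse_time <- function(bg, eps) {
  below <- which(bg$s_vals < eps)
  if (length(below) == 0) return(NA_real_)
  i <- below[1]
  if (i == 1) return(bg$times[1])
  stats::uniroot(function(t) bg$s(t) - eps,
                 lower = bg$times[i - 1], upper = bg$times[i],
                 tol = 1e-12)$root
}

# Dense resident background (s, n, A as functions of scaled time) for
# the rare-invader linearisation.
resident_background <- function(resident, params, p0, t_end,
                                n_points = 4001) {
  grid1 <- trait_pairs_grid(resident[1], resident[2])
  pp <- params; pp$mu_phi <- 0; pp$mu_theta <- 0
  st <- system_state(s = 1, l = 0, p = p0, A = 0, k = 1)
  traj <- integrate_episode(st, pp, grid1,
                            times = seq(0, t_end, length.out = n_points),
                            rtol = 1e-10, atol = 1e-14)
  s <- traj$states[, 1]
  l <- traj$states[, 2]
  A <- traj$states[, 4]
  list(times = traj$times, s_vals = s, A_vals = A,
       s = approxfun(traj$times, s, rule = 2),
       n = approxfun(traj$times, s + l, rule = 2),
       A = approxfun(traj$times, A, rule = 2))
}

# Times in (0, t_end) at which the background signal crosses theta,
# from linear interpolation of the dense grid. Used to split the
# invader integration into pieces with a smooth right-hand side.
signal_crossings <- function(bg, theta, t_end) {
  keep <- bg$times <= t_end
  tt <- bg$times[keep]; aa <- bg$A_vals[keep]
  above <- aa >= theta
  flips <- which(diff(above) != 0)
  if (length(flips) == 0) return(numeric(0))
  vapply(flips, function(i) {
    t1 <- tt[i]; t2 <- tt[i + 1]; a1 <- aa[i]; a2 <- aa[i + 1]
    t1 + (theta - a1) / (a2 - a1) * (t2 - t1)
  }, numeric(1))
}

#' Per-capita lysogen yield of a rare invader
#'
#' Integrates the linearised (rare-invader) lysogen and free-phage
#' equations on a frozen resident background from time 0 to the
#' collapse time `T_E`, starting from one unit of invader phage and no
#' invader lysogens, and returns the invader lysogen density at `T_E`.
#' The linearisation is exact in the rare-invader limit; yields are
#' proportional to the initial invader phage density, so the returned
#' value is a per-capita quantity.
#'
#' @param invader Length-2 numeric `c(phi_max, theta)`.
#' @param background A list of functions `s(t)`, `n(t)`, `A(t)` as
#'   returned by the internal resident-background constructor, spanning
#'   at least `[0, T_E]`.
#' @param params A [scaled_params()].
#' @param T_E Epidemic duration over which to integrate.
#' @return Invader lysogen density at `T_E` per unit of initial invader
#'   phage (>= 0).
#' @export
invader_lysogen_yield <- function(invader, background, params, T_E) {
  if (max(background$times) < T_E - 1e-9)
    stop("resident background does not span the requested window",
         call. = FALSE)
  phi_max <- invader[1]; theta <- invader[2]
  g <- params$growth_switch
  f_piece <- function(t, y, parms) {
    s <- background$s(t); n <- background$n(t)
    growth <- g * (1 - n)
    infect <- params$a_hat * s * y[2]
    dl <- growth * y[1] + parms$phi * infect - params$alpha_hat * y[1]
    dp <- params$B_eff * (params$alpha_hat * y[1] +
                          (1 - parms$phi) * infect) -
      params$delta_hat * y[2] - params$a_hat * n * y[2]
    list(c(dl, dp))
  }
  # split at signal-threshold crossings so each piece is smooth
  cuts <- signal_crossings(background, theta, T_E)
  bounds <- unique(pmin(pmax(c(0, cuts, T_E), 0), T_E))
  bounds <- sort(bounds)
  y <- c(l = 0, p = 1)
  for (j in seq_len(length(bounds) - 1)) {
    t1 <- bounds[j]; t2 <- bounds[j + 1]
    if (t2 - t1 < 1e-12) next
    tm <- (t1 + t2) / 2
    phi <- if (background$A(tm) >= theta) phi_max else 0
    sol <- deSolve::ode(y = y, times = c(t1, t2), func = f_piece,
                        parms = list(phi = phi), method = "lsoda",
                        rtol = 1e-10, atol = 1e-14, maxsteps = 20000)
    y <- c(l = unname(sol[nrow(sol), "l"]),
           p = unname(sol[nrow(sol), "p"]))
  }
  max(unname(y["l"]), 0)
}

#' Best invading trait on a fixed resident background
#'
#' Finds the trait value that maximises the per-capita lysogen yield of
#' a rare invader over the epidemic generated by a given resident:
#' grid search over the trait interval followed by local refinement.
#' For the `"phi"` axis the invader is a constant-propensity variant
#' (`theta = 0`); for the `"theta"` axis the invader is a full switcher
#' (`phi_max = 1`) and the trait is the response threshold in `cK`
#' units.
#'
#' @param resident Length-2 numeric `c(phi_max, theta)` of the resident
#'   shaping the epidemic.
#' @param params A [scaled_params()].
#' @param axis `"phi"` or `"theta"`.
#' @param p0 Scaled phage inoculum of the resident episode.
#' @param collapse_eps Collapse threshold, see [epidemic_duration()].
#' @param n_grid Coarse grid size. Default 51.
#' @return The maximising trait value in \[0, 1\], with attributes
#'   `yield` (the maximal yield) and `T_E`.
#' @export
optimal_invader_trait <- function(resident, params,
                                  axis = c("phi", "theta"),
                                  p0 = 1e-5 * params$B_eff,
                                  collapse_eps = 1e-3, n_grid = 51) {
  axis <- match.arg(axis)
  bg <- resident_background(resident, params, p0, params$T)
  T_E <- collapse_time(bg, collapse_eps)
  # A switching resident can end its epidemic with susceptibles left
  # over (all infections turn lysogenic once the signal passes the
  # threshold); the invasion window is then the full episode.
  if (is.na(T_E)) T_E <- params$T
  else bg <- resident_background(resident, params, p0, T_E)
  obj <- function(x) {
    inv <- if (axis == "phi") c(x, 0) else c(1, x)
    invader_lysogen_yield(inv, bg, params, T_E)
  }
  xs <- seq(0, 1, length.out = n_grid)
  ys <- vapply(xs, obj, numeric(1))
  if (max(ys) <= 0 || diff(range(ys)) <= 1e-300 * max(abs(ys))) {
    best <- xs[1]   # flat objective: tie broken toward the lower trait
    attr(best, "yield") <- ys[1]
    attr(best, "T_E") <- T_E
    return(best)
  }
  i <- which.max(ys)
  lo <- xs[max(i - 1, 1)]; hi <- xs[min(i + 1, n_grid)]
  opt <- optimize(obj, interval = c(lo, hi), maximum = TRUE,
                  tol = 1e-6)
  best <- opt$maximum
  if (obj(xs[i]) > opt$objective) best <- xs[i]
  attr(best, "yield") <- obj(best)
  attr(best, "T_E") <- T_E
  best
}

#' Numerical ESS by fixed-point iteration
#'
#' Solves `trait = optimal_invader_trait(resident = trait)`: the ESS is
#' the strategy that is the best response to the epidemic it itself
#' generates. Damped fixed-point iteration with a bisection fallback on
#' the displacement function when the iteration cycles.
#'
#' @param params A [scaled_params()].
#' @param axis `"phi"` or `"theta"`.
#' @param p0 Scaled phage inoculum per episode.
#' @param tol Convergence tolerance in trait units. Default 1e-3.
#' @param max_iter Iteration cap. Default 40.
#' @param damping Damping factor in (0, 1]. Default 0.5.
#' @param collapse_eps Collapse threshold, see [epidemic_duration()].
#' @param n_grid Coarse-grid size of the inner best-response search,
#'   see [optimal_invader_trait()]. Default 51.
#' @return An object of class `"ess_result"`: list with `axis`,
#'   `value`, `method`, `T_E`, `residual`, `iterations`, `converged`.
#' @export
ess_fixed_point <- function(params, axis = c("phi", "theta"),
                            p0 = 1e-5 * params$B_eff, tol = 1e-3,
                            max_iter = 40, damping = 0.5,
                            collapse_eps = 1e-3, n_grid = 51) {
  axis <- match.arg(axis)
  best_response <- function(x) {
    res <- if (axis == "phi") c(x, 0) else c(1, x)
    optimal_invader_trait(res, params, axis = axis, p0 = p0,
                          collapse_eps = collapse_eps, n_grid = n_grid)
  }
  x <- if (axis == "phi") 0.1 else theta_star_closed_form(max(params$B_eff, 0.6))
  x <- min(max(x, 0), 1)
  resid <- Inf
  it <- 0
  while (it < max_iter) {
    it <- it + 1
    bx <- best_response(x)
    resid <- abs(bx - x)
    if (resid < tol) {
      x <- as.numeric(bx)
      break
    }
    x <- (1 - damping) * x + damping * as.numeric(bx)
  }
  converged <- resid < tol
  if (!converged) {
    # bisection fallback on h(x) = best_response(x) - x
    h <- function(x) as.numeric(best_response(x)) - x
    lo <- 0; hi <- 1
    hlo <- h(lo); hhi <- h(hi)
    if (sign(hlo) != sign(hhi)) {
      for (j in 1:30) {
        mid <- (lo + hi) / 2
        hm <- h(mid)
        if (sign(hm) == sign(hlo)) { lo <- mid; hlo <- hm } else hi <- mid
        if (hi - lo < tol) break
      }
      x <- (lo + hi) / 2
      resid <- abs(h(x))
      converged <- resid < tol
    }
  }
  if (!converged)
    stop(sprintf(
      "ESS fixed-point iteration did not converge (residual %.3g after %d iterations)",
      resid, it), call. = FALSE)
  res_traits <- if (axis == "phi") c(x, 0) else c(1, x)
  structure(list(axis = axis, value = x, method = "fixed_point",
                 T_E = epidemic_duration(res_traits, params, p0 = p0,
                                         collapse_eps = collapse_eps),
                 residual = resid, iterations = it,
                 converged = converged, p0 = p0),
            class = "ess_result")
}

#' @export
print.ess_result <- function(x, ...) {
  cat(sprintf("ESS (%s axis, %s): %.5f\n", x$axis, x$method, x$value))
  if (!is.null(x$T_E)) cat(sprintf("  epidemic duration T_E = %.4f\n", x$T_E))
  cat(sprintf("  residual %.2g after %d iteration(s)\n",
              x$residual, x$iterations))
  invisible(x)
}

#' Locate and classify equilibria of the single-variant model
#'
#' Finds equilibria of the scaled ODE system (no passaging) for one
#' constant-propensity variant by multi-start damped-Newton root
#' finding, classifies each as phage-free, coexistence (susceptibles,
#' lysogens and phages all positive) or lysogen-only (susceptibles
#' depleted), and assesses local stability from the numerically
#' evaluated Jacobian. Viable parameter sets typically lead to a stable
#' lysogen-only state: the epidemic consumes every susceptible cell and
#' leaves a population of immune lysogens.
#'
#' @param params A [scaled_params()].
#' @param constant_phi Constant lysogeny propensity of the single
#'   variant, in \[0, 1\].
#' @param k Carrying capacity (default 1).
#' @param n_starts Number of random starting points in addition to the
#'   structured seeds. Default 40.
#' @param seed RNG seed for the random starts. Default 1.
#' @param residual_tol Maximum derivative norm accepted for a candidate
#'   equilibrium. Default 1e-10.
#' @return An object of class `"equilibrium_report"`: data frame
#'   `equilibria` with state components, classification, leading
#'   eigenvalue real part and stability flag.
#' @export
find_equilibria <- function(params, constant_phi, k = 1, n_starts = 40,
                            seed = 1, residual_tol = 1e-10) {
  if (constant_phi < 0 || constant_phi > 1)
    stop("'constant_phi' must lie in [0, 1]", call. = FALSE)
  phi <- constant_phi
  g <- params$growth_switch
  # plain algebraic right-hand side: the numerical Jacobian probes
  # states slightly outside the physical domain, so no state validation
  f <- function(y) {
    s <- y[1]; l <- y[2]; p <- y[3]; A <- y[4]
    n <- s + l
    growth <- g * (1 - n / k)
    infect <- params$a_hat * s * p
    c(growth * s - infect,
      growth * l + phi * infect - params$alpha_hat * l,
      params$B_eff * (params$alpha_hat * l + (1 - phi) * infect) -
        params$delta_hat * p - params$a_hat * n * p,
      infect - params$u_hat * n * A)
  }
  newton <- function(y0) {
    y <- y0
    for (i in 1:200) {
      fy <- f(y)
      if (max(abs(fy)) < residual_tol / 10) break
      J <- pracma::jacobian(f, y)
      step <- tryCatch(solve(J, fy), error = function(e) NULL)
      if (is.null(step)) return(NULL)
      lambda <- 1
      repeat {
        y_new <- y - lambda * step
        if (max(abs(f(y_new))) < max(abs(fy)) || lambda < 1e-6) break
        lambda <- lambda / 2
      }
      y <- y_new
    }
    y
  }
  starts <- list(c(k, 0, 0, 0),
                 c(0, k * (1 - params$alpha_hat), 1e-3, 0),
                 c(k / 2, k / 4, 0.1, 0.1))
  old_seed <- if (exists(".Random.seed", .GlobalEnv))
    get(".Random.seed", .GlobalEnv) else NULL
  set.seed(seed)
  for (i in seq_len(n_starts))
    starts[[length(starts) + 1]] <- runif(4) * c(k, k, 1, 1)
  if (!is.null(old_seed)) assign(".Random.seed", old_seed, .GlobalEnv)

  found <- list()
  for (y0 in starts) {
    y <- newton(y0)
    if (is.null(y)) next
    if (any(y < -1e-8)) next
    y <- pmax(y, 0)
    if (max(abs(f(y))) > residual_tol) next
    dup <- any(vapply(found, function(z) max(abs(z - y)) < 1e-6,
                      logical(1)))
    if (!dup) found[[length(found) + 1]] <- y
  }
  if (length(found) == 0)
    stop("no equilibria located at the requested residual tolerance",
         call. = FALSE)
  rows <- lapply(found, function(y) {
    J <- pracma::jacobian(f, y)
    lead <- max(Re(eigen(J, only.values = TRUE)$values))
    type <- if (y[3] < 1e-9 && y[2] < 1e-9) "phage_free"
            else if (y[1] < 1e-8) "lysogen_only_type_ii"
            else "coexistence_type_i"
    data.frame(s = y[1], l = y[2], p = y[3], A = y[4],
               classification = type, leading_eigenvalue = lead,
               stable = lead < 0,
               residual = max(abs(f(y))))
  })
  eq <- do.call(rbind, rows)
  eq <- eq[order(eq$s, decreasing = TRUE), , drop = FALSE]
  rownames(eq) <- NULL
  structure(list(equilibria = eq, params = params,
                 constant_phi = constant_phi, k = k),
            class = "equilibrium_report")
}

#' @export
print.equilibrium_report <- function(x, ...) {
  cat(sprintf("Equilibria of the single-variant model (phi = %g):\n",
              x$constant_phi))
  print(x$equilibria, row.names = FALSE, digits = 4)
  invisible(x)
}
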