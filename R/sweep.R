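#' Specification of a randomized parameter sweep
#'
#' Parameter uncertainty is explored by sampling each scaled parameter
#' log-uniformly and independently from a broad range and running one
#' steady-state serial-passaging simulation per sampled set. The
#' default ranges span the literature-derived uncertainty of each
#' parameter.
#'
#' @param ranges Named list of `c(low, high)` ranges for any subset of
#'   `B_eff`, `a_hat`, `delta_hat`, `alpha_hat`, `u_hat`, `D`;
#'   omitted entries use the defaults
#'   `B_eff` 1--1e3, `a_hat` 1--100, `delta_hat` 1e-3--0.1,
#'   `alpha_hat` 1e-4--1e-2, `u_hat` 1e-3--1, `D` 1e-3--0.1.
#' @param n_sets Number of parameter sets. Default 500.
#' @param seed RNG seed.
#' @param T Passage interval used for every run (long by default so
#'   that the post-epidemic pools equilibrate). Default 24.
#' @return An object of class `"sweep_spec"`.
#' @export
sweep_spec <- function(ranges = list(), n_sets = 500, seed = 1, T = 24) {
  defaults <- list(B_eff = c(1, 1e3), a_hat = c(1, 100),
                   delta_hat = c(1e-3, 0.1), alpha_hat = c(1e-4, 1e-2),
                   u_hat = c(1e-3, 1), D = c(1e-3, 0.1))
  unknown <- setdiff(names(ranges), names(defaults))
  if (length(unknown))
    stop("unknown sweep parameter(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  rg <- modifyList(defaults, ranges)
  for (nm in names(rg)) {
    r <- rg[[nm]]
    if (length(r) != 2 || any(r <= 0) || r[1] > r[2])
      stop("invalid range for '", nm, "'", call. = FALSE)
  }
  structure(list(ranges = rg, n_sets = as.integer(n_sets),
                 seed = seed, T = T),
            class = "sweep_spec")
}

#' Sample scaled parameter sets log-uniformly
#'
#' @param spec A [sweep_spec()].
#' @return List of [scaled_params()] objects of length `spec$n_sets`,
#'   reproducible from `spec$seed`.
#' @export
sample_parameter_sets <- function(spec) {
  stopifnot(inherits(spec, "sweep_spec"))
  set.seed(spec$seed)
  n <- spec$n_sets
  draws <- lapply(spec$ranges, function(r)
    exp(runif(n, log(r[1]), log(r[2]))))
  lapply(seq_len(n), function(i)
    scaled_params(B_eff = draws$B_eff[i], a_hat = draws$a_hat[i],
                  delta_hat = draws$delta_hat[i],
                  alpha_hat = draws$alpha_hat[i],
                  u_hat = draws$u_hat[i], D = draws$D[i],
                  T = spec$T))
}

sweep_row <- function(params) {
  data.frame(B_eff = params$B_eff, a_hat = params$a_hat,
             delta_hat = params$delta_hat, alpha_hat = params$alpha_hat,
             u_hat = params$u_hat, D = params$D, T = params$T)
}

#' Parameter sweep without communication
#'
#' For each sampled parameter set, runs phage-only serial passaging on
#' a constant-propensity grid to evolutionary steady state and records
#' the dominant lysogeny propensity next to the closed-form ESS
#' prediction. The prediction is evaluated in two modes, differing in
#' the phage density entering the formula: the episode-1 inoculum
#' (`phi_star_inoculum`), and the realized post-dilution density at
#' steady passaging (`phi_star_realized`).
#'
#' @param spec A [sweep_spec()].
#' @param grid Constant-propensity grid. Default 101 variants,
#'   propensities 0 to 0.5 step 0.005.
#' @param config A [passaging_config()].
#' @return Data frame with one row per parameter set: the full set,
#'   `dominant_phi`, both predictions, convergence and extinction
#'   flags.
#' @export
run_sweep_no_communication <- function(spec,
                                       grid = constant_grid(),
                                       config = passaging_config()) {
  sets <- sample_parameter_sets(spec)
  rows <- lapply(sets, function(pars) {
    run <- run_serial_passaging(pars, grid, config)
    out <- sweep_row(pars)
    p0_inoc <- 1e-5 * pars$B_eff
    if (run$extinct) {
      out$dominant_phi <- NA_real_
      out$phi_star_inoculum <- as.numeric(phi_star_scaled(pars$B_eff, p0_inoc))
      out$phi_star_realized <- NA_real_
    } else {
      out$dominant_phi <- run$dominant$phi_max
      out$phi_star_inoculum <- as.numeric(phi_star_scaled(pars$B_eff, p0_inoc))
      p0_real <- pars$D * sum(run$final_state$p)
      out$phi_star_realized <- if (p0_real > 0)
        as.numeric(phi_star_scaled(pars$B_eff, p0_real)) else NA_real_
    }
    out$converged <- !is.na(run$converged_at)
    out$extinct <- run$extinct
    out
  })
  do.call(rbind, rows)
}

#' Parameter sweep with communication
#'
#' As [run_sweep_no_communication()], but on a communication grid;
#' records the dominant `phi_max` and `theta` per parameter set.
#'
#' @param spec A [sweep_spec()].
#' @param grid Communication grid. Default 121 variants (trait steps
#'   0.1 on both axes).
#' @param config A [passaging_config()].
#' @return Data frame with one row per parameter set.
#' @export
run_sweep_with_communication <- function(spec,
                                         grid = communication_grid(
                                           phi_max = seq(0, 1, by = 0.1),
                                           theta = seq(0, 1, by = 0.1)),
                                         config = passaging_config()) {
  sets <- sample_parameter_sets(spec)
  rows <- lapply(sets, function(pars) {
    run <- run_serial_passaging(pars, grid, config)
    out <- sweep_row(pars)
    if (run$extinct) {
      out$dominant_phi_max <- NA_real_
      out$dominant_theta <- NA_real_
    } else {
      out$dominant_phi_max <- run$dominant$phi_max
      out$dominant_theta <- run$dominant$theta
    }
    out$converged <- !is.na(run$converged_at)
    out$extinct <- run$extinct
    out
  })
  do.call(rbind, rows)
}

#' Scan of the selected response threshold against burst size
#'
#' Runs steady-state simulations restricted to fully switching
#' communicators (`phi_max = 1`) over a fine threshold grid, for a
#' series of effective burst sizes, and reports the selected threshold
#' next to the closed-form prediction. The prediction is accurate for
#' highly infective phages and overestimates the threshold at small
#' burst sizes, where peptide uptake during the slow epidemic lowers
#' the realized signal concentration.
#'
#' @param B_eff_values Positive numeric vector of effective burst
#'   sizes.
#' @param params A [scaled_params()] supplying all other parameters.
#' @param config A [passaging_config()].
#' @param theta_step Threshold grid step in `cK` units. Default 0.02.
#' @return Data frame with columns `B_eff`, `selected_theta`,
#'   `theta_star`, `converged`, `extinct`.
#' @export
burst_size_scan <- function(B_eff_values, params,
                            config = passaging_config(),
                            theta_step = 0.02) {
  grid <- communication_grid(phi_max = 1,
                             theta = seq(0, 1, by = theta_step))
  rows <- lapply(B_eff_values, function(Bv) {
    pars <- params; pars$B_eff <- Bv
    run <- run_serial_passaging(pars, grid, config)
    data.frame(B_eff = Bv,
               selected_theta = if (run$extinct) NA_real_
                                else run$dominant$theta,
               theta_star = theta_star_closed_form(Bv),
               converged = !is.na(run$converged_at),
               extinct = run$extinct)
  })
  do.call(rbind, rows)
}
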