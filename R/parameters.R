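#' Scaled (dimensionless) model parameters
#'
#' Constructs the set of dimensionless parameters governing the phage
#' epidemic model and the serial-passaging protocol. The scaling measures
#' bacterial densities in units of the carrying capacity `K`, free-phage
#' density as `p = bP/K`, the arbitrium concentration in units of `cK`
#' (the concentration reached when all `K` initial cells have been
#' infected once), and time in units of the inverse bacterial growth rate
#' `1/r`. With the literature value `r = 1` per hour, scaled time equals
#' hours.
#'
#' @param B_eff Effective burst size `bB`: expected progeny phages per
#'   adsorption to a susceptible cell. Default 2.
#' @param a_hat Scaled adsorption rate `aK/r`. Default 10.
#' @param delta_hat Scaled free-phage decay rate `delta/r`. Default 0.01.
#' @param alpha_hat Scaled spontaneous induction rate `alpha/r`.
#'   Default 1e-3.
#' @param u_hat Scaled arbitrium uptake/degradation rate `uK/r`.
#'   Default 0.1.
#' @param D Dilution factor applied to the passaged material at each
#'   serial transfer, in (0, 1]. Default 0.01.
#' @param T Duration of one passaging episode, in units of `1/r`
#'   (hours at the default growth rate). Default 12.
#' @param mu_phi,mu_theta Per-replication mutation probabilities along
#'   the lysogeny-propensity and response-threshold trait axes.
#'   Default 0.01 each.
#' @param growth_switch 0/1 flag multiplying the logistic growth terms.
#'   Setting it to 0 freezes bacterial growth, which is useful for
#'   conservation-law checks; the biological model always uses 1.
#'
#' @return An object of class `"scaled_params"` (a named list).
#' @seealso [dimensional_params()], [scale_parameters()]
#' @examples
#' pars <- scaled_params()
#' pars$B_eff
#' @export
scaled_params <- function(B_eff = 2, a_hat = 10, delta_hat = 0.01,
                          alpha_hat = 1e-3, u_hat = 0.1, D = 0.01,
                          T = 12, mu_phi = 0.01, mu_theta = 0.01,
                          growth_switch = 1) {
  p <- list(B_eff = B_eff, a_hat = a_hat, delta_hat = delta_hat,
            alpha_hat = alpha_hat, u_hat = u_hat, D = D, T = T,
            mu_phi = mu_phi, mu_theta = mu_theta,
            growth_switch = growth_switch)
  validate_scaled_params(p)
  structure(p, class = "scaled_params")
}

validate_scaled_params <- function(p) {
  num1 <- function(x, nm) {
    if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
      stop("parameter '", nm, "' must be a single finite number",
           call. = FALSE)
  }
  for (nm in c("B_eff", "a_hat", "delta_hat", "alpha_hat", "u_hat",
               "D", "T", "mu_phi", "mu_theta", "growth_switch"))
    num1(p[[nm]], nm)
  for (nm in c("B_eff", "a_hat", "delta_hat", "alpha_hat", "T"))
    if (p[[nm]] <= 0)
      stop("parameter '", nm, "' must be strictly positive", call. = FALSE)
  # u_hat = 0 (no signal uptake) is a meaningful limit of the model
  if (p$u_hat < 0)
    stop("parameter 'u_hat' must be non-negative", call. = FALSE)
  if (p$D <= 0 || p$D > 1)
    stop("parameter 'D' must lie in (0, 1]", call. = FALSE)
  for (nm in c("mu_phi", "mu_theta"))
    if (p[[nm]] < 0 || p[[nm]] >= 1)
      stop("parameter '", nm, "' must lie in [0, 1)", call. = FALSE)
  if (!p$growth_switch %in% c(0, 1))
    stop("parameter 'growth_switch' must be 0 or 1", call. = FALSE)
  invisible(p)
}

#' @export
print.scaled_params <- function(x, ...) {
  cat("Scaled phage-communication model parameters\n")
  cat(sprintf("  B_eff = %g, a_hat = %g, delta_hat = %g, alpha_hat = %g, u_hat = %g\n",
              x$B_eff, x$a_hat, x$delta_hat, x$alpha_hat, x$u_hat))
  cat(sprintf("  passaging: D = %g, T = %g\n", x$D, x$T))
  cat(sprintf("  mutation: mu_phi = %g, mu_theta = %g\n",
              x$mu_phi, x$mu_theta))
  if (x$growth_switch == 0) cat("  [bacterial growth switched off]\n")
  invisible(x)
}

#' Dimensional model parameters
#'
#' Original (dimensional) parameters of the phage epidemic model. They
#' are only needed when working in physical units; all simulation code
#' runs on the scaled parameters, obtained via [scale_parameters()].
#'
#' @param r Net bacterial replication rate (per hour).
#' @param K Bacterial carrying capacity (cells per mL).
#' @param a Phage adsorption rate (per hour per (cells/mL)).
#' @param b Probability that an adsorption to a susceptible cell leads to
#'   infection, in (0, 1].
#' @param B Burst size (phages released per lysis).
#' @param alpha Spontaneous lysogen induction rate (per hour).
#' @param delta Free-phage decay rate (per hour).
#' @param u Arbitrium uptake rate (per hour per (cells/mL)).
#' @param c Arbitrium concentration increment per infection.
#'
#' @return An object of class `"dimensional_params"`.
#' @export
dimensional_params <- function(r = 1, K = 1e9, a = 1e-8, b = 1e-2,
                               B = 200, alpha = 1e-3, delta = 1e-2,
                               u = 1e-10, c = 1) {
  p <- list(r = r, K = K, a = a, b = b, B = B, alpha = alpha,
            delta = delta, u = u, c = c)
  for (nm in names(p)) {
    v <- p[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0)
      stop("parameter '", nm, "' must be a single positive number",
           call. = FALSE)
  }
  if (b > 1) stop("parameter 'b' must lie in (0, 1]", call. = FALSE)
  structure(p, class = "dimensional_params")
}

#' Nondimensionalise a dimensional parameter set
#'
#' Applies the scaling `s = S/K`, `l = L/K`, `p = bP/K`, `A -> A/(cK)`,
#' `tau = r t`, under which the model closes over exactly five
#' dimensionless parameters.
#'
#' @param dp A [dimensional_params()] object.
#' @param D,T,mu_phi,mu_theta,growth_switch Passaging and mutation
#'   settings, passed through to [scaled_params()].
#' @return A [scaled_params()] object.
#' @export
scale_parameters <- function(dp, D = 0.01, T = 12, mu_phi = 0.01,
                             mu_theta = 0.01, growth_switch = 1) {
  stopifnot(inherits(dp, "dimensional_params"))
  scaled_params(B_eff = dp$b * dp$B,
                a_hat = dp$a * dp$K / dp$r,
                delta_hat = dp$delta / dp$r,
                alpha_hat = dp$alpha / dp$r,
                u_hat = dp$u * dp$K / dp$r,
                D = D, T = T, mu_phi = mu_phi, mu_theta = mu_theta,
                growth_switch = growth_switch)
}
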