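#' Phage variant grids
#'
#' A variant grid is the discrete set of phage strategies competing in a
#' simulation. Each variant is characterised by a maximal lysogeny
#' propensity `phi_max` in \[0, 1\] and an arbitrium response threshold
#' `theta` (in units of `cK`, the peptide concentration reached when the
#' whole initial host population has been infected). Two scenarios are
#' supported:
#'
#' * `constant_grid()` builds a one-dimensional grid of non-communicating
#'   bet-hedging variants: each has a constant lysogeny propensity `phi`
#'   (internally `theta = 0`, so the propensity never depends on the
#'   signal).
#' * `communication_grid()` builds the full factorial grid over
#'   `phi_max` and `theta` levels; variants with `theta = 0` reduce to
#'   the constant-propensity strategies, so the communication scenario
#'   strictly contains the baseline one.
#'
#' Mutation moves burst mass between nearest neighbours along each trait
#' axis (see [mutation_operator()]), so both constructors require
#' regularly spaced levels.
#'
#' @param phi Numeric vector of constant lysogeny propensities
#'   (regularly spaced, within \[0, 1\]).
#' @param phi_max,theta Numeric vectors of grid levels for the two trait
#'   axes (regularly spaced; `phi_max` within \[0, 1\], `theta >= 0`).
#' @return An object of class `"variant_grid"` with per-variant trait
#'   vectors `phi_max` and `theta` (variants ordered with `phi_max`
#'   varying fastest), level vectors, axis sizes `n_phi`/`n_theta`, and
#'   the scenario label.
#' @examples
#' g <- constant_grid(seq(0, 0.5, by = 0.005))
#' g$n_variants
#' gc <- communication_grid()
#' gc$n_variants
#' @name variant_grid
NULL

new_variant_grid <- function(phi_levels, theta_levels, scenario) {
  check_levels <- function(x, nm, upper = Inf) {
    if (length(x) < 1L || anyNA(x) || !is.numeric(x))
      stop("'", nm, "' must be a non-empty numeric vector", call. = FALSE)
    if (any(x < 0) || any(x > upper))
      stop("'", nm, "' levels out of range", call. = FALSE)
    if (is.unsorted(x, strictly = TRUE) && length(x) > 1L)
      stop("'", nm, "' levels must be strictly increasing", call. = FALSE)
    if (length(x) > 2L) {
      d <- diff(x)
      if (max(abs(d - d[1])) > 1e-9 * max(abs(d)))
        stop("'", nm, "' levels must be regularly spaced", call. = FALSE)
    }
  }
  check_levels(phi_levels, "phi_max", upper = 1)
  check_levels(theta_levels, "theta")
  n_phi <- length(phi_levels)
  n_theta <- length(theta_levels)
  structure(list(
    n_variants = n_phi * n_theta,
    n_phi = n_phi,
    n_theta = n_theta,
    phi_levels = phi_levels,
    theta_levels = theta_levels,
    phi_max = rep(phi_levels, times = n_theta),
    theta = rep(theta_levels, each = n_phi),
    scenario = scenario
  ), class = "variant_grid")
}

#' @rdname variant_grid
#' @export
constant_grid <- function(phi = seq(0, 0.5, by = 0.005)) {
  new_variant_grid(phi, 0, scenario = "constant-propensity")
}

#' @rdname variant_grid
#' @export
communication_grid <- function(phi_max = seq(0, 1, by = 0.05),
                               theta = seq(0, 1, by = 0.05)) {
  new_variant_grid(phi_max, theta, scenario = "communication")
}

#' Single- or few-variant grids from explicit trait pairs
#'
#' Convenience constructor used by competition experiments and ESS
#' machinery, where a small number of arbitrary variants compete without
#' mutation. No neighbour structure is implied: mutation must be
#' disabled (`mu_phi = mu_theta = 0`) when integrating such a grid with
#' more than one variant per axis level.
#'
#' @param phi_max,theta Equal-length numeric vectors of trait values.
#' @return A `"variant_grid"` with one axis per variant
#'   (`n_theta = 1`), suitable only for mutation-free dynamics.
#' @export
trait_pairs_grid <- function(phi_max, theta = rep(0, length(phi_max))) {
  if (length(phi_max) != length(theta))
    stop("'phi_max' and 'theta' must have equal length", call. = FALSE)
  if (any(phi_max < 0 | phi_max > 1))
    stop("'phi_max' must lie in [0, 1]", call. = FALSE)
  if (any(theta < 0)) stop("'theta' must be non-negative", call. = FALSE)
  structure(list(
    n_variants = length(phi_max),
    n_phi = length(phi_max),
    n_theta = 1L,
    phi_levels = phi_max,
    theta_levels = NA_real_,
    phi_max = as.numeric(phi_max),
    theta = as.numeric(theta),
    scenario = "explicit"
  ), class = "variant_grid")
}

#' @export
print.variant_grid <- function(x, ...) {
  cat(sprintf("Variant grid (%s): %d variants\n", x$scenario, x$n_variants))
  cat(sprintf("  phi_max: %d level(s) in [%g, %g]\n", x$n_phi,
              min(x$phi_max), max(x$phi_max)))
  cat(sprintf("  theta:   %d level(s) in [%g, %g] (units cK)\n",
              x$n_theta, min(x$theta), max(x$theta)))
  invisible(x)
}

#' Variant labels of a grid
#'
#' @param grid A `"variant_grid"`.
#' @return Character vector, one label per variant, encoding the trait
#'   values (used as column headers in written tables).
#' @export
variant_labels <- function(grid) {
  if (grid$scenario == "constant-propensity")
    sprintf("phi=%g", grid$phi_max)
  else
    sprintf("phimax=%g,theta=%g", grid$phi_max, grid$theta)
}

check_state_grid <- function(state, grid) {
  if (length(state$l) != grid$n_variants ||
      length(state$p) != grid$n_variants)
    stop("state dimension does not match the variant grid", call. = FALSE)
}
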