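#' Variant frequencies in a pool
#'
#' Normalised distribution of variants in the free-phage or lysogen pool
#' of a system state. Late in a long episode the free-phage distribution
#' comes to reflect the lysogen distribution, because after the collapse
#' of the susceptible population new phages arise only by induction.
#'
#' @param state A [system_state()].
#' @param pool `"phage"` or `"lysogen"`.
#' @return Non-negative frequency vector summing to 1.
#' @export
variant_frequencies <- function(state, pool = c("phage", "lysogen")) {
  pool <- match.arg(pool)
  x <- if (pool == "phage") state$p else state$l
  tot <- sum(x)
  if (tot <= 0)
    stop(structure(class = c("empty_pool_error", "error", "condition"),
                   list(message = paste0("the ", pool,
                                         " pool has zero total mass"),
                        call = sys.call(-1))))
  x / tot
}

#' Most abundant variant
#'
#' @param freq Normalised frequency vector over the grid's variants.
#' @param grid A `"variant_grid"`.
#' @return A list with `index`, `phi_max`, `theta` and `freq` of the
#'   most abundant variant. Ties are broken towards lower `phi_max`,
#'   then lower `theta`.
#' @export
dominant_variant <- function(freq, grid) {
  if (length(freq) != grid$n_variants)
    stop("'freq' length does not match the grid", call. = FALSE)
  cand <- which(freq == max(freq))
  pick <- cand[order(grid$phi_max[cand], grid$theta[cand])][1]
  list(index = pick, phi_max = grid$phi_max[pick],
       theta = grid$theta[pick], freq = freq[pick])
}

new_regime_scan <- function(variable, values, runs, grid) {
  freq <- do.call(rbind, lapply(runs, steady_state_frequencies))
  dom <- do.call(rbind, lapply(seq_along(runs), function(i) {
    if (runs[[i]]$extinct)
      return(data.frame(phi_max = NA_real_, theta = NA_real_,
                        freq = NA_real_))
    d <- dominant_variant(freq[i, ], grid)
    data.frame(phi_max = d$phi_max, theta = d$theta, freq = d$freq)
  }))
  dom <- cbind(data.frame(value = values), dom,
               converged_at = vapply(runs, function(r)
                 as.integer(r$converged_at), integer(1)),
               extinct = vapply(runs, function(r) r$extinct, logical(1)))
  names(dom)[1] <- variable
  structure(list(variable = variable, values = values,
                 frequencies = freq, dominant = dom, grid = grid,
                 runs = runs),
            class = "regime_scan")
}

#' Steady-state scan over the passage interval
#'
#' Runs one serial-passaging simulation per passage interval `T` and
#' records the steady-state variant distribution. The scan exposes the
#' two selection regimes: for short intervals a fully lytic strategy
#' dominates, for long intervals a fixed non-trivial strategy is
#' selected independently of `T`.
#'
#' @param T_values Positive numeric vector of episode durations.
#' @param params A [scaled_params()] (its `T` is overridden per run).
#' @param grid A `"variant_grid"`.
#' @param config A [passaging_config()].
#' @return A `"regime_scan"` object: scanned values, per-value final
#'   frequency matrix and dominant-variant table.
#' @export
regime_scan_T <- function(T_values, params, grid,
                          config = passaging_config()) {
  if (any(T_values <= 0)) stop("'T_values' must be positive", call. = FALSE)
  runs <- lapply(T_values, function(Tv) {
    p <- params; p$T <- Tv
    run_serial_passaging(p, grid, config)
  })
  new_regime_scan("T", T_values, runs, grid)
}

#' Steady-state scan over carrying-capacity noise
#'
#' Runs one serial-passaging simulation per coefficient of variation of
#' the episode carrying capacity. Each run draws the capacity of every
#' episode from a gamma distribution with mean 1 and the scanned CV and
#' simulates a fixed number of episodes (noisy runs do not satisfy an
#' episode-to-episode convergence criterion).
#'
#' @param cv_values Non-negative numeric vector of CVs.
#' @param params A [scaled_params()].
#' @param grid A `"variant_grid"`.
#' @param config A [passaging_config()]; its `n_episodes_max` is the
#'   per-run episode count (default here 1000) and convergence stopping
#'   is disabled for `cv > 0`.
#' @param seed Base RNG seed; run `i` uses `seed + i - 1` so that
#'   adding scan values does not change earlier runs.
#' @return A `"regime_scan"` object.
#' @export
regime_scan_cv <- function(cv_values, params, grid,
                           config = passaging_config(n_episodes_max = 1000),
                           seed = 1) {
  if (any(cv_values < 0))
    stop("'cv_values' must be non-negative", call. = FALSE)
  runs <- lapply(seq_along(cv_values), function(i) {
    cfg <- config
    cfg$cv_K <- cv_values[i]
    cfg$seed <- seed + i - 1
    if (cv_values[i] > 0) cfg$stop_at_steady_state <- FALSE
    run_serial_passaging(params, grid, cfg)
  })
  new_regime_scan("cv", cv_values, runs, grid)
}

#' @export
print.regime_scan <- function(x, ...) {
  cat(sprintf("Regime scan over %s (%d value(s))\n", x$variable,
              length(x$values)))
  print(x$dominant, row.names = FALSE)
  invisible(x)
}

#' @export
as.data.frame.regime_scan <- function(x, ...) {
  labs <- variant_labels(x$grid)
  long <- expand.grid(variant = seq_len(x$grid$n_variants),
                      value = x$values)
  data.frame(setNames(list(rep(x$values, each = x$grid$n_variants)),
                      x$variable),
             variant = labs[long$variant],
             phi_max = x$grid$phi_max[long$variant],
             theta = x$grid$theta[long$variant],
             frequency = as.vector(t(x$frequencies)))
}

#' Head-to-head competition between two strategies
#'
#' Serial-passaging competition between exactly two phage variants with
#' mutation disabled, reporting the frequency of the second variant in
#' the free-phage pool at the end of every episode. Used for direct
#' invasion experiments (e.g. a communicating strategy invading a
#' resident bet-hedging population).
#'
#' @param variant_a,variant_b Length-2 numeric vectors
#'   `c(phi_max, theta)`.
#' @param init_freq_b Initial frequency of variant b, in (0, 1).
#' @param params A [scaled_params()]; mutation rates are forced to 0.
#' @param config A [passaging_config()].
#' @return An object of class `"competition"`: data frame `trajectory`
#'   with columns `episode` and `freq_b`, plus the underlying
#'   `"passaging_run"`.
#' @export
competition_experiment <- function(variant_a, variant_b, init_freq_b,
                                   params,
                                   config = passaging_config(
                                     n_episodes_max = 200)) {
  if (init_freq_b <= 0 || init_freq_b >= 1)
    stop("'init_freq_b' must lie in (0, 1)", call. = FALSE)
  grid <- trait_pairs_grid(phi_max = c(variant_a[1], variant_b[1]),
                           theta = c(variant_a[2], variant_b[2]))
  p <- params
  p$mu_phi <- 0
  p$mu_theta <- 0
  cfg <- config
  cfg$init_freq <- c(1 - init_freq_b, init_freq_b)
  run <- run_serial_passaging(p, grid, cfg)
  structure(list(trajectory = data.frame(
                   episode = seq_len(run$episodes_run),
                   freq_b = run$freq_phage[, 2]),
                 variant_a = variant_a, variant_b = variant_b,
                 run = run),
            class = "competition")
}

#' @export
print.competition <- function(x, ...) {
  tr <- x$trajectory
  cat(sprintf("Competition: a = (%g, %g) vs b = (%g, %g)\n",
              x$variant_a[1], x$variant_a[2],
              x$variant_b[1], x$variant_b[2]))
  cat(sprintf("  freq(b): %.4g (episode 1) -> %.4g (episode %d)\n",
              tr$freq_b[1], tr$freq_b[nrow(tr)], nrow(tr)))
  invisible(x)
}

#' @export
plot.competition <- function(x, ...) {
  plot(x$trajectory$episode, x$trajectory$freq_b, type = "l",
       xlab = "episode", ylab = "frequency of variant b",
       ylim = c(0, 1), ...)
  invisible(x)
}
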