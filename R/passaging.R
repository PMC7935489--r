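#' Serial-passaging protocol settings
#'
#' Configuration of the multi-episode driver that exposes the phage
#' population to a long series of epidemics. Two transfer protocols are
#' supported: `"phage_only"` (only free phages are diluted into the next
#' episode, the standard protocol) and `"full_sample"` (susceptible
#' cells, lysogens, phages and arbitrium are all carried over).
#'
#' @param n_episodes_max Maximum number of passaging episodes.
#'   Default 2000.
#' @param protocol `"phage_only"` or `"full_sample"`.
#' @param p_total_init Total scaled free-phage density inoculated in
#'   episode 1. `NULL` (default) uses `1e-5 * B_eff`, the scaled image
#'   of a total phage density `1e-5 * K * B`.
#' @param init_freq Per-variant initial frequency vector (sums to 1).
#'   `NULL` (default) starts uniform across the grid.
#' @param cv_K Coefficient of variation of the episode carrying
#'   capacity; 0 (default) keeps it constant at 1. Positive values draw
#'   each episode's capacity from a gamma distribution with mean 1.
#' @param seed RNG seed for the carrying-capacity draws (`NULL` leaves
#'   the RNG state untouched).
#' @param ss_tol,ss_window Evolutionary steady state is declared when
#'   the L1 distance between consecutive end-of-episode phage frequency
#'   vectors stays below `ss_tol` for `ss_window` consecutive episodes.
#'   Defaults 1e-6 and 10.
#' @param stop_at_steady_state If `FALSE`, always run `n_episodes_max`
#'   episodes (used for noisy-capacity experiments, which do not settle
#'   to a fixed distribution episode-by-episode).
#' @param full_sample_cap If `TRUE`, the full-sample protocol caps the
#'   total bacterial inoculum at the new carrying capacity instead of
#'   adding fresh susceptibles on top of the carried-over cells.
#' @param extinction_floor Total scaled phage density below which the
#'   population is reported extinct. Default 1e-30.
#' @return An object of class `"passaging_config"`.
#' @export
passaging_config <- function(n_episodes_max = 2000,
                             protocol = c("phage_only", "full_sample"),
                             p_total_init = NULL, init_freq = NULL,
                             cv_K = 0, seed = NULL,
                             ss_tol = 1e-6, ss_window = 10,
                             stop_at_steady_state = TRUE,
                             full_sample_cap = FALSE,
                             extinction_floor = 1e-30) {
  protocol <- match.arg(protocol)
  if (n_episodes_max < 1) stop("'n_episodes_max' must be >= 1", call. = FALSE)
  if (!is.null(p_total_init) && p_total_init <= 0)
    stop("'p_total_init' must be positive", call. = FALSE)
  if (cv_K < 0) stop("'cv_K' must be non-negative", call. = FALSE)
  if (!is.null(init_freq)) {
    if (any(init_freq < 0) || abs(sum(init_freq) - 1) > 1e-8)
      stop("'init_freq' must be non-negative and sum to 1", call. = FALSE)
  }
  structure(list(n_episodes_max = as.integer(n_episodes_max),
                 protocol = protocol, p_total_init = p_total_init,
                 init_freq = init_freq, cv_K = cv_K, seed = seed,
                 ss_tol = ss_tol, ss_window = as.integer(ss_window),
                 stop_at_steady_state = stop_at_steady_state,
                 full_sample_cap = full_sample_cap,
                 extinction_floor = extinction_floor),
            class = "passaging_config")
}

#' Initial state of a passaging episode
#'
#' A fresh episode starts with a susceptible population at the episode's
#' carrying capacity, no lysogens, no arbitrium, and a small free-phage
#' inoculum distributed across variants.
#'
#' @param grid A `"variant_grid"`.
#' @param k Episode carrying capacity (units `K`).
#' @param p_total Total scaled free-phage density at episode start.
#' @param freq Per-variant frequency vector (non-negative, sums to 1).
#' @return A [system_state()] with `s = k`, `l = 0`, `A = 0`,
#'   `p = p_total * freq`.
#' @export
initialize_episode <- function(grid, k = 1,
                               p_total = NULL, freq = NULL) {
  if (is.null(freq)) freq <- rep(1 / grid$n_variants, grid$n_variants)
  if (length(freq) != grid$n_variants)
    stop("'freq' length does not match the grid", call. = FALSE)
  if (any(freq < 0) || abs(sum(freq) - 1) > 1e-8)
    stop("'freq' must be non-negative and sum to 1", call. = FALSE)
  if (is.null(p_total)) stop("'p_total' must be supplied", call. = FALSE)
  if (p_total <= 0) stop("'p_total' must be positive", call. = FALSE)
  system_state(s = k, l = rep(0, grid$n_variants),
               p = p_total * freq, A = 0, k = k)
}

#' Phage-only serial transfer
#'
#' Dilutes the free phages of an episode's end state by the factor `D`
#' into a fresh susceptible population at the next episode's carrying
#' capacity. Lysogens and arbitrium are discarded; relative variant
#' frequencies among the phages are preserved exactly.
#'
#' @param end_state End-of-episode [system_state()].
#' @param params A [scaled_params()] (supplies the dilution factor `D`).
#' @param k_next Carrying capacity of the next episode.
#' @return The next episode's initial [system_state()].
#' @export
passage_phage_only <- function(end_state, params, k_next = 1) {
  validate_system_state(end_state)
  system_state(s = k_next, l = rep(0, length(end_state$l)),
               p = params$D * end_state$p, A = 0, k = k_next)
}

#' Full-sample serial transfer
#'
#' Dilutes the complete end-of-episode sample -- susceptible cells,
#' lysogens, free phages and arbitrium -- by the factor `D` and adds it
#' to a fresh susceptible population. By default the fresh susceptibles
#' are at the new carrying capacity and the carried-over cells come on
#' top; with `cap = TRUE` the total bacterial inoculum is instead capped
#' at `k_next` (fresh cells fill up to capacity only).
#'
#' @inheritParams passage_phage_only
#' @param cap Logical; see Details.
#' @return The next episode's initial [system_state()].
#' @export
passage_full_sample <- function(end_state, params, k_next = 1,
                                cap = FALSE) {
  validate_system_state(end_state)
  D <- params$D
  l_new <- D * end_state$l
  s_fresh <- if (cap) max(k_next - D * end_state$s - sum(l_new), 0)
             else k_next
  system_state(s = s_fresh + D * end_state$s, l = l_new,
               p = D * end_state$p, A = D * end_state$A, k = k_next)
}

#' Draw an episode carrying capacity
#'
#' Episode-to-episode variability in host availability is modelled by a
#' gamma-distributed carrying capacity with mean 1 (units `K`). The
#' coefficient of variation controls the noise level: shape `1/cv^2`,
#' scale `cv^2`. `cv = 1` is the exponential distribution; `cv = 0`
#' returns exactly 1 without consuming random numbers.
#'
#' @param cv Coefficient of variation, >= 0.
#' @param n Number of draws.
#' @return Numeric vector of capacities.
#' @export
draw_carrying_capacity <- function(cv, n = 1) {
  if (cv < 0) stop("'cv' must be non-negative", call. = FALSE)
  if (cv == 0) return(rep(1, n))
  rgamma(n, shape = 1 / cv^2, scale = cv^2)
}

#' Detect an evolutionary steady state
#'
#' Scans a per-episode history of phage variant frequencies for the
#' first episode after which the L1 distance between consecutive
#' end-of-episode frequency vectors stays below `tol` for `window`
#' consecutive episodes.
#'
#' @param freq_history Numeric matrix, one row per episode, one column
#'   per variant.
#' @param tol L1 tolerance.
#' @param window Number of consecutive sub-tolerance steps required.
#' @return The 1-based episode index at which convergence is declared,
#'   or `NA_integer_` if the history never settles.
#' @export
detect_evolutionary_steady_state <- function(freq_history, tol = 1e-6,
                                             window = 10) {
  n_ep <- nrow(freq_history)
  if (n_ep < window + 1) return(NA_integer_)
  d <- rowSums(abs(freq_history[-1, , drop = FALSE] -
                   freq_history[-n_ep, , drop = FALSE]))
  ok <- d < tol
  run <- 0L
  for (i in seq_along(ok)) {
    run <- if (ok[i]) run + 1L else 0L
    # d[i] compares episodes i and i+1; a constant history converges
    # after `window` consecutive sub-tolerance steps, i.e. at index
    # `window`
    if (run >= window) return(i)
  }
  NA_integer_
}

#' Run a serial-passaging simulation
#'
#' The multi-episode driver: initialise a susceptible population with a
#' small phage inoculum, integrate one epidemic episode of duration
#' `T`, transfer a diluted sample into fresh susceptibles, and repeat
#' until the distribution of phage variants settles (or an episode cap
#' is reached). Mutation continuously regenerates neighbouring variants,
#' so the long-run outcome is a mutation-selection balance centred on
#' the selected strategy.
#'
#' @param params A [scaled_params()] object.
#' @param grid A `"variant_grid"`.
#' @param config A [passaging_config()].
#' @return An object of class `"passaging_run"`: per-episode matrices of
#'   end-of-episode phage-pool and lysogen-pool variant frequencies,
#'   the carrying-capacity history, the convergence episode (`NA` if
#'   none), extinction flag, dominant-variant traits, the final state
#'   and the inputs.
#' @examples
#' \donttest{
#' pars <- scaled_params(T = 12)
#' g <- constant_grid(seq(0, 0.5, by = 0.05))
#' run <- run_serial_passaging(pars, g, passaging_config(n_episodes_max = 50))
#' dominant_variant(final_frequencies(run), g)
#' }
#' @export
run_serial_passaging <- function(params, grid,
                                 config = passaging_config()) {
  stopifnot(inherits(params, "scaled_params"),
            inherits(grid, "variant_grid"),
            inherits(config, "passaging_config"))
  n <- grid$n_variants
  n_max <- config$n_episodes_max
  p_total <- config$p_total_init
  if (is.null(p_total)) p_total <- 1e-5 * params$B_eff

  if (!is.null(config$seed)) set.seed(config$seed)
  k_vec <- draw_carrying_capacity(config$cv_K, n_max)

  freq_p <- matrix(NA_real_, n_max, n)
  freq_l <- matrix(NA_real_, n_max, n)
  state <- initialize_episode(grid, k_vec[1], p_total, config$init_freq)

  converged_at <- NA_integer_
  extinct <- FALSE
  run_len <- 0L
  prev_freq <- NULL
  ep_done <- 0L
  final_state <- state

  for (ep in seq_len(n_max)) {
    traj <- integrate_episode(state, params, grid)
    end_state <- episode_state(traj)
    ep_done <- ep
    final_state <- end_state

    tot_p <- sum(end_state$p)
    if (tot_p < config$extinction_floor) {
      extinct <- TRUE
      break
    }
    freq_p[ep, ] <- end_state$p / tot_p
    tot_l <- sum(end_state$l)
    freq_l[ep, ] <- if (tot_l > 0) end_state$l / tot_l else NA_real_

    if (!is.null(prev_freq)) {
      if (sum(abs(freq_p[ep, ] - prev_freq)) < config$ss_tol)
        run_len <- run_len + 1L
      else run_len <- 0L
      if (run_len >= config$ss_window && is.na(converged_at)) {
        converged_at <- ep
        if (config$stop_at_steady_state) break
      }
    }
    prev_freq <- freq_p[ep, ]

    if (ep < n_max) {
      state <- switch(config$protocol,
        phage_only = passage_phage_only(end_state, params, k_vec[ep + 1]),
        full_sample = passage_full_sample(end_state, params, k_vec[ep + 1],
                                          cap = config$full_sample_cap))
    }
  }

  freq_p <- freq_p[seq_len(ep_done), , drop = FALSE]
  freq_l <- freq_l[seq_len(ep_done), , drop = FALSE]
  dom <- if (extinct) NULL
         else dominant_variant(freq_p[nrow(freq_p), ], grid)

  structure(list(freq_phage = freq_p, freq_lysogen = freq_l,
                 k_history = k_vec[seq_len(ep_done)],
                 episodes_run = ep_done, converged_at = converged_at,
                 extinct = extinct, dominant = dom,
                 final_state = final_state, params = params,
                 grid = grid, config = config),
            class = "passaging_run")
}

#' End-of-run variant frequencies
#'
#' @param run A `"passaging_run"`.
#' @param pool `"phage"` (free phages, the passaged pool) or
#'   `"lysogen"`.
#' @return Frequency vector at the final recorded episode.
#' @export
final_frequencies <- function(run, pool = c("phage", "lysogen")) {
  pool <- match.arg(pool)
  m <- if (pool == "phage") run$freq_phage else run$freq_lysogen
  m[nrow(m), ]
}

#' Steady-state variant distribution of a run
#'
#' For deterministic runs (constant carrying capacity) the steady-state
#' distribution is the final episode's end-of-episode phage-pool
#' frequency vector. Under carrying-capacity noise the distribution
#' fluctuates from episode to episode around its stationary value, so
#' the estimator is the mean of the end-of-episode frequency vectors
#' over the final quarter of the episodes (renormalised).
#'
#' @param run A `"passaging_run"`.
#' @param pool `"phage"` or `"lysogen"`.
#' @param tail_frac Fraction of trailing episodes averaged for noisy
#'   runs. Default 0.25.
#' @return Frequency vector over the grid's variants.
#' @export
steady_state_frequencies <- function(run, pool = c("phage", "lysogen"),
                                     tail_frac = 0.25) {
  pool <- match.arg(pool)
  m <- if (pool == "phage") run$freq_phage else run$freq_lysogen
  if (run$config$cv_K == 0) return(m[nrow(m), ])
  n_tail <- max(1L, floor(tail_frac * nrow(m)))
  f <- colMeans(m[(nrow(m) - n_tail + 1L):nrow(m), , drop = FALSE],
                na.rm = TRUE)
  f / sum(f)
}

#' @export
print.passaging_run <- function(x, ...) {
  cat(sprintf("Serial-passaging run: %d episode(s), protocol %s, T = %g\n",
              x$episodes_run, x$config$protocol, x$params$T))
  if (x$extinct) {
    cat("  phage population went extinct\n")
  } else {
    if (!is.na(x$converged_at))
      cat(sprintf("  evolutionary steady state at episode %d\n",
                  x$converged_at))
    else cat("  no evolutionary steady state detected\n")
    cat(sprintf("  dominant variant: phi_max = %g, theta = %g (freq %.3f)\n",
                x$dominant$phi_max, x$dominant$theta, x$dominant$freq))
  }
  invisible(x)
}

#' @export
summary.passaging_run <- function(object, ...) {
  f <- final_frequencies(object)
  ord <- order(f, decreasing = TRUE)
  top <- ord[seq_len(min(5, length(ord)))]
  out <- list(episodes_run = object$episodes_run,
              converged_at = object$converged_at,
              extinct = object$extinct,
              dominant = object$dominant,
              top_variants = data.frame(
                phi_max = object$grid$phi_max[top],
                theta = object$grid$theta[top],
                frequency = f[top]))
  class(out) <- "summary.passaging_run"
  out
}

#' @export
print.summary.passaging_run <- function(x, ...) {
  cat(sprintf("Serial-passaging run: %d episodes, converged at %s\n",
              x$episodes_run,
              ifelse(is.na(x$converged_at), "none", x$converged_at)))
  cat("Top variants at final episode (phage pool):\n")
  print(x$top_variants, row.names = FALSE)
  invisible(x)
}

#' @export
plot.passaging_run <- function(x, pool = c("phage", "lysogen"),
                               n_top = 8, ...) {
  pool <- match.arg(pool)
  m <- if (pool == "phage") x$freq_phage else x$freq_lysogen
  keep <- order(m[nrow(m), ], decreasing = TRUE)[seq_len(min(n_top, ncol(m)))]
  graphics::matplot(seq_len(nrow(m)), m[, keep, drop = FALSE], type = "l",
                    lty = 1, xlab = "episode",
                    ylab = paste(pool, "variant frequency"), ...)
  graphics::legend("topright", legend = variant_labels(x$grid)[keep],
                   col = seq_along(keep), lty = 1, cex = 0.7, bty = "n")
  invisible(x)
}

#' @export
as.data.frame.passaging_run <- function(x, ...) {
  labs <- variant_labels(x$grid)
  df <- data.frame(episode = seq_len(x$episodes_run),
                   k = x$k_history)
  fp <- x$freq_phage
  colnames(fp) <- paste0("freq.", labs)
  cbind(df, fp)
}
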