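#' Load a run configuration file
#'
#' Reads a YAML configuration describing a complete simulation run:
#' scaled parameters, variant grid, passaging protocol, seed and output
#' paths. Omitted keys fall back to the package defaults; unknown keys
#' are rejected with the offending key named, so typos never silently
#' fall back to defaults.
#'
#' The recognised structure is:
#' ```yaml
#' parameters:            # any field of scaled_params()
#'   B_eff: 2
#'   T: 12
#' grid:
#'   scenario: communication        # or constant
#'   phi_max: {from: 0, to: 1, by: 0.05}
#'   theta:   {from: 0, to: 1, by: 0.05}
#' passaging:             # any field of passaging_config()
#'   n_episodes_max: 2000
#'   protocol: phage_only
#' seed: 1
#' output:
#'   table: results.tsv
#'   metadata: run.yml
#' ```
#'
#' @param path Path to a YAML file.
#' @return An object of class `"run_config"`: list with elements
#'   `params` ([scaled_params()]), `grid` (`"variant_grid"`), `config`
#'   ([passaging_config()]), `seed` and `output`.
#' @export
load_config <- function(path) {
  if (!file.exists(path))
    stop("config file not found: ", path, call. = FALSE)
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  known <- c("parameters", "grid", "passaging", "seed", "output")
  unknown <- setdiff(names(raw), known)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)

  check_sub <- function(block, allowed, label) {
    bad <- setdiff(names(block), allowed)
    if (length(bad))
      stop("unknown key(s) in '", label, "': ",
           paste(bad, collapse = ", "), call. = FALSE)
  }

  par_block <- raw$parameters
  check_sub(par_block, names(formals(scaled_params)), "parameters")
  params <- do.call(scaled_params, as.list(par_block))

  axis_seq <- function(x, default) {
    if (is.null(x)) return(default)
    if (is.list(x)) {
      check_sub(x, c("from", "to", "by"), "grid axis")
      return(seq(x$from, x$to, by = x$by))
    }
    as.numeric(x)
  }
  grid_block <- raw$grid
  check_sub(grid_block, c("scenario", "phi_max", "phi", "theta"), "grid")
  scenario <- if (is.null(grid_block$scenario)) "communication"
              else grid_block$scenario
  grid <- switch(scenario,
    constant = constant_grid(axis_seq(
      if (!is.null(grid_block$phi)) grid_block$phi else grid_block$phi_max,
      seq(0, 0.5, by = 0.005))),
    communication = communication_grid(
      axis_seq(grid_block$phi_max, seq(0, 1, by = 0.05)),
      axis_seq(grid_block$theta, seq(0, 1, by = 0.05))),
    stop("unknown grid scenario: ", scenario, call. = FALSE))

  pas_block <- raw$passaging
  check_sub(pas_block, names(formals(passaging_config)), "passaging")
  config <- do.call(passaging_config, as.list(pas_block))
  if (!is.null(raw$seed)) config$seed <- raw$seed

  structure(list(params = params, grid = grid, config = config,
                 seed = raw$seed, output = raw$output),
            class = "run_config")
}

#' Write simulation results to disk
#'
#' `format = "table"` writes a tab-delimited table with a header row,
#' numbers carrying 17 significant digits so that re-reading reproduces
#' the values bit-for-bit. `format = "metadata"` writes a structured
#' YAML record carrying the package version, the full configuration,
#' the seed and convergence diagnostics, from which the run can be
#' reconstructed exactly.
#'
#' @param result A result object (`"passaging_run"`, `"regime_scan"`,
#'   `"episode_trajectory"`, or a data frame) for tables; a
#'   `"passaging_run"` or arbitrary named list for metadata.
#' @param path Output file path.
#' @param format `"table"` or `"metadata"`.
#' @return Invisibly, `path`.
#' @export
write_results <- function(result, path, format = c("table", "metadata")) {
  format <- match.arg(format)
  if (format == "table") {
    df <- if (is.data.frame(result)) result else as.data.frame(result)
    num <- vapply(df, is.numeric, logical(1))
    df[num] <- lapply(df[num], function(x) sprintf("%.17g", x))
    ok <- tryCatch({
      write.table(df, path, sep = "\t", quote = FALSE,
                  row.names = FALSE)
      TRUE
    }, error = function(e) e)
    if (!isTRUE(ok))
      stop("failed to write table to '", path, "': ",
           conditionMessage(ok), call. = FALSE)
  } else {
    meta <- if (inherits(result, "passaging_run")) {
      list(package = "arbitrium",
           version = as.character(packageVersion("arbitrium")),
           parameters = unclass(result$params),
           grid = list(scenario = result$grid$scenario,
                       n_variants = result$grid$n_variants,
                       phi_levels = result$grid$phi_levels,
                       theta_levels = result$grid$theta_levels),
           passaging = unclass(result$config),
           episodes_run = result$episodes_run,
           converged_at = result$converged_at,
           extinct = result$extinct,
           dominant = result$dominant)
    } else {
      c(list(package = "arbitrium",
             version = as.character(packageVersion("arbitrium"))),
        result)
    }
    drop_null <- function(x) {
      if (!is.list(x)) return(x)
      x <- x[!vapply(x, is.null, logical(1))]
      lapply(x, drop_null)
    }
    ok <- tryCatch({
      yaml::write_yaml(drop_null(meta), path)
      TRUE
    }, error = function(e) e)
    if (!isTRUE(ok))
      stop("failed to write metadata to '", path, "': ",
           conditionMessage(ok), call. = FALSE)
  }
  invisible(path)
}

#' Read back a written results table
#'
#' @param path Path written by [write_results()] with
#'   `format = "table"`.
#' @return A data frame.
#' @export
read_results <- function(path) {
  read.table(path, header = TRUE, sep = "\t", check.names = FALSE)
}
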