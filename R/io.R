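#' Gaussian initial-profile specification
#'
#' The case studies start both compartments from the same Gaussian age
#' profile `k0 / sqrt(2 pi sigma2) * exp(-(a - mu)^2 / (2 sigma2))`.
#'
#' @param k0 amplitude scale (cells).
#' @param mu center age (h).
#' @param sigma2 variance (h^2).
#' @return A `gaussian_profile_spec`.
#' @export
gaussian_profile_spec <- function(k0 = 1e6, mu = 2, sigma2 = 200) {
  stopifnot(k0 > 0, sigma2 > 0)
  structure(list(k0 = k0, mu = mu, sigma2 = sigma2),
            class = "gaussian_profile_spec")
}

#' Evaluate a Gaussian age profile on a grid
#'
#' @param spec a [gaussian_profile_spec()].
#' @param grid an [age_grid()].
#' @return strictly positive density vector on the grid nodes, peaked at
#'   the node nearest `mu`.
#' @examples
#' make_gaussian_profile(gaussian_profile_spec(1e6, 2, 200),
#'                       age_grid(50, 0.5))[5]  # value at a = 2
#' @export
make_gaussian_profile <- function(spec, grid) {
  stopifnot(inherits(spec, "gaussian_profile_spec"),
            inherits(grid, "age_grid"))
  a <- grid$nodes
  spec$k0 / sqrt(2 * pi * spec$sigma2) *
    exp(-(a - spec$mu)^2 / (2 * spec$sigma2))
}

# numeric-only representation of a config (for YAML serialization and
# round-trip comparison); requires constant mu_p, mu_q, g
config_to_list <- function(cfg) {
  stopifnot(inherits(cfg, "simulation_config"))
  mp <- cfg$macro
  if (is.na(mp$mu_p_const) || is.na(mp$mu_q_const) || is.na(mp$g_const))
    stop("configs with functional mu_p/mu_q/g cannot be serialized")
  list(
    preset = cfg$preset,
    macro = list(nu = mp$nu, theta = mp$theta, kappa = mp$kappa,
                 rho1 = mp$rho1, rho2 = mp$rho2, gamma1 = mp$gamma1,
                 sigma1 = mp$sigma1, sigma2 = mp$sigma2,
                 sigma3 = mp$sigma3, gamma2 = mp$gamma2,
                 gamma3 = mp$gamma3, k_t = mp$k_t,
                 mu_p = mp$mu_p_const, mu_q = mp$mu_q_const,
                 g = mp$g_const, a_star = mp$a_star),
    cycle = unclass(cfg$cycle),
    grid = list(a_star = cfg$grid$a_star, da = cfg$grid$da),
    dt = cfg$dt, t_end = cfg$t_end,
    initial = cfg$initial,
    record_every = cfg$record_every,
    snapshot_every = cfg$snapshot_every,
    refresh = cfg$refresh,
    seed = cfg$seed,
    units = "per-day rate constants used as-is on the hour-based grid")
}

check_num <- function(x, path) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop("config field '", path, "' must be a finite number", call. = FALSE)
  x
}

#' Load a simulation configuration from YAML
#'
#' The file may name a `preset` (one of the case studies), in which case
#' its remaining fields override the preset's values; otherwise defaults
#' are used for anything unspecified. Malformed fields are reported with
#' their path.
#'
#' @param path YAML file path.
#' @return A [simulation_config()].
#' @seealso [save_config()] for the inverse; `load_config(save_config(cfg))`
#'   reproduces `cfg` exactly.
#' @export
load_config <- function(path) {
  raw <- yaml::read_yaml(path)
  base <- if (!is.null(raw$preset)) scenario_preset(raw$preset)
          else simulation_config()
  mac <- config_to_list(base)$macro
  if (!is.null(raw$macro)) {
    bad <- setdiff(names(raw$macro), names(mac))
    if (length(bad)) stop("unknown config field 'macro.", bad[1], "'")
    for (nm in names(raw$macro))
      mac[[nm]] <- check_num(raw$macro[[nm]], paste0("macro.", nm))
  }
  cyc <- unclass(base$cycle)
  if (!is.null(raw$cycle)) {
    bad <- setdiff(names(raw$cycle), names(cyc))
    if (length(bad)) stop("unknown config field 'cycle.", bad[1], "'")
    for (nm in names(raw$cycle))
      cyc[[nm]] <- check_num(raw$cycle[[nm]], paste0("cycle.", nm))
  }
  grd <- list(a_star = base$grid$a_star, da = base$grid$da)
  if (!is.null(raw$grid))
    for (nm in names(raw$grid))
      grd[[nm]] <- check_num(raw$grid[[nm]], paste0("grid.", nm))
  mac$a_star <- grd$a_star

  init <- base$initial
  if (!is.null(raw$initial)) {
    init <- raw$initial
    if (is.null(init$type)) stop("config field 'initial.type' is missing")
    if (init$type == "gaussian")
      for (nm in c("k0", "mu", "sigma2"))
        init[[nm]] <- check_num(init[[nm]], paste0("initial.", nm))
  }
  refresh <- if (!is.null(raw$refresh)) raw$refresh else base$refresh

  simulation_config(
    macro = do.call(macro_params, mac),
    cycle = do.call(cycle_params, cyc),
    grid = age_grid(grd$a_star, grd$da),
    dt = if (!is.null(raw$dt)) check_num(raw$dt, "dt") else base$dt,
    t_end = if (!is.null(raw$t_end)) check_num(raw$t_end, "t_end")
            else base$t_end,
    initial = init,
    record_every = if (!is.null(raw$record_every))
      check_num(raw$record_every, "record_every") else base$record_every,
    snapshot_every = if (!is.null(raw$snapshot_every))
      check_num(raw$snapshot_every, "snapshot_every")
      else base$snapshot_every,
    refresh = refresh, seed = raw$seed, preset = raw$preset)
}

#' Save a simulation configuration to YAML
#'
#' @param cfg a [simulation_config()] with constant `mu_p`, `mu_q`, `g`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
save_config <- function(cfg, path) {
  lst <- config_to_list(cfg)
  lst$preset <- NULL   # write fully resolved values, not the preset name
  yaml::write_yaml(lst, path, precision = 17)
  invisible(path)
}

fmt_num_df <- function(df) {
  df[] <- lapply(df, function(col)
    if (is.numeric(col)) sprintf("%.17g", col) else col)
  df
}

#' Write simulation results to a directory
#'
#' Writes `timeseries.csv` (`t`, `N`, `g_f`, `gamma_N`, `p_boundary`),
#' `final_profile.csv` (`age`, `q`, `p`), `cycle_trajectory.csv` (`age`,
#' `x1..x4`, `gf`), one `snapshot_NNN.csv` per stored snapshot,
#' `config.yaml` (the resolved configuration) and `metadata.json` (resolved
#' parameters, package version, blow-up time if any). Numeric values are
#' written with 17 significant digits so files parse back to the in-memory
#' doubles exactly.
#'
#' @param result a [run_simulation()] result.
#' @param dir output directory (created if needed).
#' @return character vector of the files written, invisibly.
#' @export
write_results <- function(result, dir) {
  stopifnot(inherits(result, "simulation_result"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  wr <- function(df, name) {
    f <- file.path(dir, name)
    write.csv(fmt_num_df(df), f, row.names = FALSE, quote = FALSE)
    files <<- c(files, f)
  }
  wr(data.frame(t = result$times, N = result$N, g_f = result$g_f,
                gamma_N = result$gamma_N, p_boundary = result$p_boundary),
     "timeseries.csv")
  fs <- result$final_state
  wr(data.frame(age = fs$grid$nodes, q = fs$q, p = fs$p),
     "final_profile.csv")
  wr(as.data.frame(result$final_cycle), "cycle_trajectory.csv")
  sn <- result$snapshots
  for (k in seq_along(sn$t))
    wr(data.frame(age = fs$grid$nodes, q = sn$q[, k], p = sn$p[, k]),
       sprintf("snapshot_%03d.csv", k))
  save_config(result$config, file.path(dir, "config.yaml"))
  files <- c(files, file.path(dir, "config.yaml"))
  meta <- list(
    package = "qpcycle",
    version = as.character(utils::packageVersion("qpcycle")),
    config = config_to_list(result$config),
    n_recorded = length(result$times),
    blowup_time = if (is.na(result$blowup_time)) NULL
                  else result$blowup_time)
  mf <- file.path(dir, "metadata.json")
  jsonlite::write_json(meta, mf, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(c(files, mf))
}
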