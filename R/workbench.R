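# Orchestration: experiment configuration, replicate management, sweeps and
# provenance.  Configurations are plain lists (YAML on disk); seeds for the
# replicates derive deterministically from the base seed.

#' Total subunit concentration
#'
#' @param N subunit count.
#' @param L box edge length.
#' @return `rho_T = N / L^3`.
#' @export
subunit_concentration <- function(N, L) N / L^3

#' Box edge length for a target concentration
#' @param rho_T target concentration.
#' @param N subunit count.
#' @export
box_length_for <- function(rho_T, N) (N / rho_T)^(1 / 3)

#' Experiment configuration
#'
#' Exactly one of `rho_T` (with `N`) or (`N`, `L`) fixes the box, and
#' exactly one of `V_r` or `R_c` fixes the condensate geometry.  Replicate
#' seeds are `base_seed + replicate - 1`.
#'
#' @param model `"dodecahedron"` or `"icosahedron"`.
#' @param eps_ss subunit-subunit well depth.
#' @param eps_c condensate well depth.
#' @param N subunit count.
#' @param rho_T total concentration (alternative to `L`).
#' @param L box edge length (alternative to `rho_T`).
#' @param V_r condensate volume ratio (alternative to `R_c`).
#' @param R_c condensate radius (alternative to `V_r`).
#' @param dt,gamma,T,t_F,snapshot_every engine parameters (see
#'   [run_config()]).
#' @param n_replicates independent trajectories (>= 1).
#' @param base_seed integer; replicate r uses `base_seed + r - 1`.
#' @return an object of class `experiment_config`.
#' @export
experiment_config <- function(model = "dodecahedron", eps_ss, eps_c, N,
                              rho_T = NULL, L = NULL, V_r = NULL, R_c = NULL,
                              dt = 5e-3, gamma = 1, T = 1, t_F,
                              snapshot_every = 500, n_replicates = 1,
                              base_seed = 1) {
  if (is.null(rho_T) == is.null(L)) {
    stop("give exactly one of 'rho_T' or 'L'", call. = FALSE)
  }
  if (is.null(V_r) == is.null(R_c)) {
    stop("give exactly one of 'V_r' or 'R_c'", call. = FALSE)
  }
  if (n_replicates < 1) stop("'n_replicates' must be >= 1", call. = FALSE)
  if (is.null(L)) L <- box_length_for(rho_T, N)
  if (is.null(rho_T)) rho_T <- subunit_concentration(N, L)
  structure(list(model = model, eps_ss = eps_ss, eps_c = eps_c, N = N,
                 rho_T = rho_T, L = L, V_r = V_r, R_c = R_c, dt = dt,
                 gamma = gamma, T = T, t_F = t_F,
                 snapshot_every = snapshot_every,
                 n_replicates = as.integer(n_replicates),
                 base_seed = as.integer(base_seed)),
            class = "experiment_config")
}

#' Read an experiment configuration from YAML
#'
#' Files written by [write_experiment_config()] store both `rho_T` and the
#' derived `L`; consistent pairs are accepted as-is, anything else goes
#' through [experiment_config()] validation.
#' @param path YAML file with the fields of [experiment_config()].
#' @export
read_experiment_config <- function(path) {
  x <- yaml::read_yaml(path)
  # YAML 1.1 reads a bare `N:` key as a boolean; map it back
  names(x)[names(x) %in% c("FALSE", "no")] <- "N"
  if (!is.null(x$rho_T) && !is.null(x$L)) {
    if (abs(x$rho_T - x$N / x$L^3) > 1e-8 * x$rho_T) {
      stop("inconsistent 'rho_T' and 'L' in config file", call. = FALSE)
    }
    x$rho_T <- NULL
  }
  cfg <- do.call(experiment_config, x)
  cfg
}

#' Write an experiment configuration to YAML
#' @param config an `experiment_config`.
#' @param path output path.
#' @export
write_experiment_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @keywords internal
config_hash <- function(config) {
  tf <- tempfile()
  on.exit(unlink(tf))
  writeLines(paste(deparse(unclass(config)), collapse = ""), tf)
  unname(tools::md5sum(tf))
}

#' Run a replicated assembly experiment
#'
#' Runs `n_replicates` seeded trajectories from random initial states,
#' analyzes each, and aggregates final observables as mean +/- twice the
#' standard error of the mean.  The summary embeds a provenance block
#' (config hash, seeds, package version).
#'
#' @param config an [experiment_config()].
#' @param analyze_every analyze every n-th snapshot (default 1).
#' @param keep_series keep per-replicate time series (default TRUE).
#' @return an object of class `experiment_summary`: `observables`
#'   (data.frame of mean / sem2 per observable), `series` (list), `final`
#'   (per-replicate final-frame values), `provenance`.
#' @export
run_experiment <- function(config, analyze_every = 1L, keep_series = TRUE) {
  tpl <- switch(config$model,
                dodecahedron = build_dodecahedron_subunit(),
                icosahedron = build_icosahedron_subunit())
  table <- build_interaction_table(config$model, eps_ss = config$eps_ss,
                                   template = tpl)
  spec <- if (!is.null(config$R_c)) {
    condensate_spec(R_c = config$R_c, eps_c = config$eps_c,
                    alpha_C = 10 / tpl$length_scale)
  } else {
    condensate_spec(V_r = config$V_r, L = config$L, eps_c = config$eps_c,
                    alpha_C = 10 / tpl$length_scale)
  }
  seeds <- config$base_seed + seq_len(config$n_replicates) - 1L
  series <- vector("list", config$n_replicates)
  finals <- NULL
  for (r in seq_len(config$n_replicates)) {
    st <- initialize_random(config$N, config$L, tpl, seed = seeds[r],
                            T = config$T)
    rc <- run_config(dt = config$dt, gamma = config$gamma, T = config$T,
                     t_F = config$t_F,
                     snapshot_every = config$snapshot_every,
                     seed = seeds[r])
    traj <- run_dynamics(st, rc, table, spec)
    ts <- analyze_trajectory(traj, R_c = spec$R_c, every = analyze_every)
    series[[r]] <- ts
    last <- ts[nrow(ts), ]
    finals <- rbind(finals, data.frame(
      replicate = r, seed = seeds[r], f_c = last$f_c, f_c_c = last$f_c_c,
      f_c_bg = last$f_c_bg, K_c_meas = last$K_c_meas,
      off_target_fraction = last$off_target_fraction,
      n_complete = last$n_complete))
  }
  obs_names <- c("f_c", "f_c_c", "f_c_bg", "K_c_meas",
                 "off_target_fraction", "n_complete")
  observables <- do.call(rbind, lapply(obs_names, function(nm) {
    stt <- replicate_stats(finals[[nm]])
    data.frame(observable = nm, mean = stt$mean, sem2 = stt$sem2,
               n = stt$n)
  }))
  structure(list(
    observables = observables,
    final = finals,
    series = if (keep_series) series else NULL,
    provenance = list(config = config, config_hash = config_hash(config),
                      seeds = seeds,
                      package_version =
                        as.character(utils::packageVersion("condcap")))
  ), class = "experiment_summary")
}

#' @export
print.experiment_summary <- function(x, ...) {
  cat(sprintf("<experiment_summary: %d replicates, config %s>\n",
              length(x$provenance$seeds), x$provenance$config_hash))
  print(x$observables)
  invisible(x)
}

#' Parameter sweep over replicated experiments
#'
#' @param config template [experiment_config()].
#' @param parameter name of the config field to vary.
#' @param values values to scan (may be empty: returns an empty table).
#' @param ... passed to [run_experiment()].
#' @return tidy long-format data.frame: `parameter`, `value`, `observable`,
#'   `mean`, `sem2`, `n`.
#' @export
sweep_experiment <- function(config, parameter, values, ...) {
  if (!parameter %in% names(config)) {
    stop("unknown config field: ", parameter, call. = FALSE)
  }
  out <- data.frame(parameter = character(0), value = numeric(0),
                    observable = character(0), mean = numeric(0),
                    sem2 = numeric(0), n = integer(0))
  for (v in values) {
    cfg <- config
    cfg[[parameter]] <- v
    # re-resolve derived geometry when the density or count changes
    if (parameter %in% c("rho_T", "N")) cfg$L <- box_length_for(cfg$rho_T, cfg$N)
    summ <- run_experiment(cfg, ...)
    rows <- summ$observables
    rows <- cbind(data.frame(parameter = parameter, value = v), rows)
    out <- rbind(out, rows)
  }
  out
}
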