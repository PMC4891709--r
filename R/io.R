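#' Load and validate an experiment configuration
#'
#' Experiments are described by a flat YAML file with sections `params`,
#' `noise`, `init` and `sweep` plus top-level scalars. Unknown keys are
#' errors, not warnings, so configs stay diffable experiment records.
#' Defaults fill any omitted field: the reference parametrisation
#' (`s = 3.2`, `b0 = 15 c0`, `c2 = 1.6 c0`, `c0_base = 10`) at `h = 1`
#' for the slow-switching regimes (1, 3) and `h = 100` as the
#' operational stand-in for fast switching (regimes 2, 4); horizon
#' `t_end = 1e4` with 20% burn-in; 100 runs.
#'
#' @param path Path to a YAML config file.
#' @return A validated `experiment_config` list.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) abort(paste0("config file not found: ", path),
                                class = "bnmotif_config_error")
  raw <- yaml::read_yaml(path)
  validate_config(raw)
}

#' @rdname load_config
#' @param config A named list (as read from YAML) to validate and fill
#'   with defaults.
#' @export
validate_config <- function(config) {
  cfg_err <- function(msg) abort(msg, class = "bnmotif_config_error")
  known_top <- c("regime", "seed", "t_end", "burn_in", "n_runs",
                 "outdir", "params", "sbb", "noise", "init", "sweep")
  unknown <- setdiff(names(config), known_top)
  if (length(unknown) > 0) {
    cfg_err(paste0("unknown config key(s): ",
                   paste(unknown, collapse = ", ")))
  }
  regime <- config$regime %||% 4L
  if (!regime %in% 1:4) cfg_err("`regime` must be 1, 2, 3 or 4.")
  h_default <- if (regime %in% c(2L, 4L)) 100 else 1

  p_known <- c("h", "c0_base", "n", "s", "d", "omega", "c0", "c2", "b0")
  p <- config$params %||% list()
  unknown <- setdiff(names(p), p_known)
  if (length(unknown) > 0) {
    cfg_err(paste0("unknown params key(s): ",
                   paste(unknown, collapse = ", ")))
  }
  params <- tryCatch({
    if (!is.null(config$sbb)) {
      sbb_known <- c("d", "R_b", "K_d", "K_f")
      unknown <- setdiff(names(config$sbb), sbb_known)
      if (length(unknown) > 0) {
        cfg_err(paste0("unknown sbb key(s): ",
                       paste(unknown, collapse = ", ")))
      }
      do.call(convert_sbb_parameters,
              c(config$sbb,
                list(n = p$n %||% 2, c0_base = p$c0_base %||% 10,
                     h = p$h %||% h_default,
                     omega = p$omega %||% 6.022)))
    } else {
      do.call(network_params, modifyList(list(h = h_default), p))
    }
  }, error = function(e) cfg_err(conditionMessage(e)))

  n_known <- c("kind", "B", "tau", "z")
  nz <- config$noise %||% list(kind = "sine_wiener", B = 0)
  unknown <- setdiff(names(nz), n_known)
  if (length(unknown) > 0) {
    cfg_err(paste0("unknown noise key(s): ",
                   paste(unknown, collapse = ", ")))
  }
  noise <- tryCatch(do.call(noise_spec, nz),
                    error = function(e) cfg_err(conditionMessage(e)))

  init_known <- c("type", "lo", "hi", "value", "G", "G_mean")
  init <- config$init %||% list(type = "empty")
  unknown <- setdiff(names(init), init_known)
  if (length(unknown) > 0) {
    cfg_err(paste0("unknown init key(s): ",
                   paste(unknown, collapse = ", ")))
  }
  if (!(init$type %||% "empty") %in%
        c("empty", "fixed", "uniform_y", "uniform_count")) {
    cfg_err("init `type` must be empty, fixed, uniform_y or uniform_count.")
  }

  sweep_known <- c("B", "tau", "omega")
  sweep <- config$sweep %||% list()
  unknown <- setdiff(names(sweep), sweep_known)
  if (length(unknown) > 0) {
    cfg_err(paste0("unknown sweep key(s): ",
                   paste(unknown, collapse = ", ")))
  }

  t_end <- config$t_end %||% 1e4
  out <- list(
    regime = as.integer(regime),
    seed = as.integer(config$seed %||% 1L),
    t_end = t_end,
    burn_in = config$burn_in %||% (0.2 * t_end),
    n_runs = as.integer(config$n_runs %||% 100L),
    outdir = config$outdir %||% ".",
    params = params, noise = noise, init = init, sweep = sweep
  )
  class(out) <- "experiment_config"
  out
}

#' Save an experiment configuration
#'
#' Round-trips losslessly through [load_config()].
#' @param config An `experiment_config`.
#' @param path Output YAML path.
#' @return `path`, invisibly.
#' @export
save_config <- function(config, path) {
  p <- config$params
  out <- list(
    regime = config$regime, seed = config$seed, t_end = config$t_end,
    burn_in = config$burn_in, n_runs = config$n_runs,
    outdir = config$outdir,
    params = list(h = p$h, c0_base = p$c0_base, n = p$n, s = p$s,
                  d = p$d, omega = p$omega, c0 = p$c0, c2 = p$c2,
                  b0 = p$b0),
    noise = list(kind = config$noise$kind, B = config$noise$B,
                 tau = config$noise$tau, z = config$noise$z),
    init = config$init, sweep = config$sweep
  )
  if (config$noise$kind != "cai_lin") out$noise$z <- NULL
  yaml::write_yaml(out, path)
  invisible(path)
}

#' Stable hash of an experiment configuration
#'
#' FNV-1a over the canonical JSON serialisation; embedded in every output
#' manifest so artifacts are regenerable from their manifest alone.
#' @param config An `experiment_config` (or any list).
#' @return A hex string.
#' @export
config_hash <- function(config) {
  s <- jsonlite::toJSON(unclass(config), auto_unbox = TRUE, digits = NA,
                        force = TRUE)
  bytes <- utf8ToInt(as.character(s))
  # FNV-1a in plain doubles: R's bitwXor is limited to signed 32-bit
  # inputs, so the XOR with the low byte is done by arithmetic on the
  # lowest 8 bits, and the 32-bit multiply by the FNV prime in two
  # 16-bit halves
  h <- 2166136261
  for (b in bytes) {
    low <- h %% 256
    h <- h - low + bitwXor(low, b %% 256)
    lo <- h %% 65536; hi <- h %/% 65536
    h <- (lo * 16777619 + (hi * 16777619 %% 65536) * 65536) %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

build_ic_sampler <- function(init, regime, params) {
  type <- init$type %||% "empty"
  switch(type,
    empty = NULL,
    fixed = ic_fixed(init$value),
    uniform_y = {
      lo <- init$lo %||% 0; hi <- init$hi %||% 1
      G <- init$G %||% 0
      if (regime == 3) {
        function() list(G = G, y = runif(1, lo, hi))
      } else {
        ic_uniform_y(lo, hi)
      }
    },
    uniform_count = ic_uniform_count(init$lo %||% 0, init$hi %||% 100,
                                     G = init$G %||% 0,
                                     G_mean = init$G_mean %||% 0)
  )
}

write_manifest <- function(config, outdir, artifacts, extra = list()) {
  manifest <- c(list(
    config = unclass(save_config_list(config)),
    config_hash = config_hash(config),
    seed = config$seed,
    package_version = as.character(utils::packageVersion("bnmotif")),
    wall_clock = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    artifacts = artifacts
  ), extra)
  path <- file.path(outdir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  path
}

save_config_list <- function(config) {
  tmp <- tempfile(fileext = ".yml")
  on.exit(unlink(tmp))
  save_config(config, tmp)
  yaml::read_yaml(tmp)
}

#' Run a single simulation from a config and write its artifacts
#'
#' Writes `trajectory.csv` (time, gene, protein, xi) and `manifest.json`
#' into the config's output directory.
#' @param config An `experiment_config` (or a path to one).
#' @param outdir Overrides the config's output directory.
#' @return Exit status 0, invisibly.
#' @export
cmd_simulate <- function(config, outdir = NULL) {
  config <- as_config(config)
  outdir <- outdir %||% config$outdir
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  set.seed(derive_seed(config$seed, 1L))
  ic <- build_ic_sampler(config$init, config$regime, config$params)
  init <- if (is.null(ic)) NULL else ic()
  traj <- simulate_motif(config$regime, config$params, config$noise,
                         init = init, t_end = config$t_end,
                         burn_in = config$burn_in)
  f <- file.path(outdir, "trajectory.csv")
  write_trajectory_csv(traj, f)
  write_manifest(config, outdir, artifacts = list(trajectory = basename(f)),
                 extra = list(stats = trajectory_stats(traj)[
                   c("mean", "sd")]))
  invisible(0L)
}

#' Run a phase-diagram sweep from a config and write its artifacts
#'
#' Writes `phase_diagram.csv`, a per-cell density directory,
#' `transitions.json` and `manifest.json`. Per-cell failures are
#' aggregated in the manifest and make the command fail.
#' @inheritParams cmd_simulate
#' @return Exit status 0, invisibly; errors on any cell failure.
#' @export
cmd_sweep <- function(config, outdir = NULL) {
  config <- as_config(config)
  outdir <- outdir %||% config$outdir
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  sweep <- config$sweep
  if (is.null(sweep$B)) {
    abort("sweep config must provide a `B` grid.",
          class = "bnmotif_config_error")
  }
  facet <- if (!is.null(sweep$omega)) {
    list(omega = unlist(sweep$omega))
  } else if (!is.null(sweep$tau)) {
    list(tau = unlist(sweep$tau))
  } else NULL
  ic <- build_ic_sampler(config$init, config$regime, config$params)
  diagram <- sweep_phase_diagram(
    config$regime, config$params, noise_kind = config$noise$kind,
    B_grid = unlist(sweep$B), facet = facet, tau = config$noise$tau,
    z = if (is.na(config$noise$z)) 0.5 else config$noise$z,
    ic_sampler = ic, n_runs = config$n_runs, t_end = config$t_end,
    burn_in = config$burn_in, seed = config$seed)
  f <- file.path(outdir, "phase_diagram.csv")
  write_phase_diagram_csv(diagram, f)
  trans <- detect_transitions(diagram)
  tf <- file.path(outdir, "transitions.json")
  jsonlite::write_json(trans, tf, auto_unbox = TRUE, digits = NA)
  write_manifest(config, outdir,
                 artifacts = list(phase_diagram = basename(f),
                                  transitions = basename(tf)),
                 extra = list(n_cells = nrow(diagram),
                              all_succeeded = TRUE))
  invisible(0L)
}

#' Write the deterministic fixed points from a config
#'
#' Writes `fixed_points.csv` (y, stability) and `manifest.json`.
#' @inheritParams cmd_simulate
#' @return Exit status 0, invisibly.
#' @export
cmd_fixed_points <- function(config, outdir = NULL) {
  config <- as_config(config)
  outdir <- outdir %||% config$outdir
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  fp <- fixed_points(config$params)
  f <- file.path(outdir, "fixed_points.csv")
  readr::write_csv(tibble::as_tibble(fp), f)
  write_manifest(config, outdir,
                 artifacts = list(fixed_points = basename(f)))
  invisible(0L)
}

#' Export bounded-noise stationary-density diagnostics from a config
#'
#' Samples an ensemble of noise paths, writes the pooled histogram with
#' the closed-form stationary density (`noise_density.csv`) and the
#' first path (`noise_path.csv`), plus `manifest.json`.
#' @inheritParams cmd_simulate
#' @param n_paths Number of paths pooled.
#' @return Exit status 0, invisibly.
#' @export
cmd_noise_check <- function(config, outdir = NULL, n_paths = 50) {
  config <- as_config(config)
  outdir <- outdir %||% config$outdir
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  spec <- config$noise
  paths <- purrr::map(seq_len(n_paths), function(i) {
    sample_noise(spec, t_end = config$t_end,
                 seed = derive_seed(config$seed, i))
  })
  st <- empirical_noise_stats(paths)
  h <- st$histogram
  h$theory <- noise_stationary_cdf(h$bin_right, spec) -
    noise_stationary_cdf(h$bin_left, spec)
  f <- file.path(outdir, "noise_density.csv")
  readr::write_csv(h, f)
  pf <- file.path(outdir, "noise_path.csv")
  write_noise_csv(paths[[1L]], pf)
  write_manifest(config, outdir,
                 artifacts = list(noise_density = basename(f),
                                  noise_path = basename(pf)),
                 extra = list(noise_mean = st$mean))
  invisible(0L)
}

as_config <- function(config) {
  if (inherits(config, "experiment_config")) return(config)
  if (is.character(config)) return(load_config(config))
  if (is.list(config)) return(validate_config(config))
  abort("`config` must be an experiment_config, list or file path.",
        class = "bnmotif_config_error")
}
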