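## Experiment orchestration: named, config-driven experiments over the
## other modules, tidy CSV outputs and a JSON manifest, plus canonical
## small fixtures for property tests. Every stochastic step derives its
## seed from the master seed through named substreams; rerunning a config
## with the same seed reproduces the output files byte for byte.

experiment_registry <- function() {
  list(
    "simulate" = function(params, seed) {
      kin <- do.call(or_kinetics, params$kinetics)
      tp <- do.call(transduction_params,
                    if (is.null(params$transduction)) list() else
                      params$transduction)
      prot <- do.call(stimulus_protocol, params$protocol)
      ts <- simulate_orn(kin, tp, prot,
                         dt = if (is.null(params$dt)) 0.001 else params$dt)
      as.data.frame(ts)
    },
    "mixture-error" = function(params, seed) {
      do.call(approximation_error_experiment,
              c(params[names(params) %in%
                         c("nmix_values", "n_receptors", "sigma_kappa",
                           "conc_mode", "decades", "trials")],
                list(seed = seed)))
    },
    "masking-curve" = function(params, seed) {
      exc <- do.call(masked_odorant, params$excitant)
      msk <- do.call(masking_profile, params$masker)
      masking_dose_response(exc, msk, M_grid = params$M_grid)
    },
    "normalize-scan" = function(params, seed) {
      cfg <- do.call(ensemble_config, params$config)
      fraction_active_vs_complexity(
        cfg, nmix_values = params$nmix_values,
        rho_values = if (is.null(params$rho_values)) cfg$rho else
          params$rho_values,
        trials = if (is.null(params$trials)) 20 else params$trials,
        seed = seed)
    },
    "etamix-dist" = function(params, seed) {
      cfg <- do.call(ensemble_config, params$config)
      eta_mix_distribution(cfg, nmix_values = params$nmix_values,
                           samples = if (is.null(params$samples)) 10000 else
                             params$samples,
                           seed = seed)
    },
    "mi-scan" = function(params, seed) {
      cfg0 <- do.call(ensemble_config, params$config)
      bg <- do.call(background_model,
                    if (is.null(params$background)) list() else
                      params$background)
      rows <- list()
      for (rho in params$rho_values) {
        cfg <- ensemble_config(cfg0$n_receptors, cfg0$sigma_kappa, rho,
                               cfg0$p, cfg0$hill, cfg0$efficacy)
        task <- segregation_task(
          cfg, bg,
          q_draws = if (is.null(params$q_draws)) 800 else params$q_draws,
          z_draws = if (is.null(params$z_draws)) 4000 else params$z_draws,
          seed = substream_seed(seed, round(1e4 * rho)))
        est <- mutual_information(task,
                                  seed = substream_seed(seed,
                                                        round(1e4 * rho) + 1))
        rows[[length(rows) + 1L]] <-
          data.frame(rho = rho, p = cfg$p, mi = est$mi, se = est$se)
      }
      do.call(rbind, rows)
    },
    "optimal-rho" = function(params, seed) {
      cfg <- do.call(ensemble_config,
                     if (is.null(params$config)) list() else params$config)
      bg <- do.call(background_model,
                    if (is.null(params$background)) list() else
                      params$background)
      optimal_rho(p_values = params$p_values,
                  rho_grid = if (is.null(params$rho_grid))
                    seq(0, 1, by = 0.25) else params$rho_grid,
                  config = cfg, background = bg,
                  q_draws = if (is.null(params$q_draws)) 600 else
                    params$q_draws,
                  z_draws = if (is.null(params$z_draws)) 3000 else
                    params$z_draws,
                  seed = seed)
    },
    "train-panel" = function(params, seed) {
      cfg <- do.call(ensemble_config, params$config)
      panel <- sample_odorants(cfg, params$panel_size,
                               seed = substream_seed(seed, 1))
      clfs <- train_panel(panel,
                          n_trials = if (is.null(params$n_trials)) 400 else
                            params$n_trials,
                          seed = seed)
      do.call(rbind, lapply(seq_along(clfs), function(i)
        data.frame(target = i, b = clfs[[i]]$b,
                   glomerulus = seq_along(clfs[[i]]$theta),
                   theta = clfs[[i]]$theta)))
    },
    "roc" = function(params, seed) {
      cfg <- do.call(ensemble_config, params$config)
      panel <- sample_odorants(cfg, params$panel_size,
                               seed = substream_seed(seed, 1))
      clfs <- train_panel(panel,
                          n_trials = if (is.null(params$n_trials)) 400 else
                            params$n_trials,
                          seed = seed)
      component_separation_roc(
        panel, clfs,
        mix_range = if (is.null(params$mix_range)) 1:20 else
          params$mix_range,
        test_trials = if (is.null(params$test_trials)) 200 else
          params$test_trials,
        seed = substream_seed(seed, 2))
    },
    "noisy-fg" = function(params, seed) {
      cfg <- do.call(ensemble_config, params$config)
      noisy_figure_ground(
        cfg,
        epsilon0 = if (is.null(params$epsilon0)) 0 else params$epsilon0,
        bg_sizes = params$bg_sizes,
        train_trials = if (is.null(params$train_trials)) 400 else
          params$train_trials,
        test_trials = if (is.null(params$test_trials)) 200 else
          params$test_trials,
        seed = seed)
    },
    "psychophysics" = function(params, seed) {
      cfg <- do.call(ensemble_config,
                     if (is.null(params$config)) list(p = 0.5) else
                       params$config)
      mode <- if (is.null(params$mode)) "binary" else params$mode
      mixture_intensity_experiment(
        cfg, mode = mode,
        trials = if (is.null(params$trials)) 20 else params$trials,
        seed = seed)
    }
  )
}

#' Run a named experiment from a configuration
#'
#' Dispatches to one of the registered experiments, writes its tidy-CSV
#' result and a JSON manifest (configuration echo, seed, runtime, output
#' checksum-friendly file list) into `out_dir`.
#'
#' @param config Either a path to a JSON configuration file or a list with
#'   elements `experiment` (name), `params` (experiment parameters),
#'   `seed` (integer) and optionally `out_dir`.
#' @param out_dir Output directory (overrides the config; default
#'   `"."`).
#' @return Invisibly, the result data frame; files `<experiment>.csv` and
#'   `manifest.json` are written to `out_dir`.
#' @export
run_experiment <- function(config, out_dir = NULL) {
  if (is.character(config)) config <- jsonlite::read_json(config,
                                                          simplifyVector = TRUE)
  reg <- experiment_registry()
  name <- config$experiment
  if (is.null(name) || !name %in% names(reg))
    stop("unknown experiment `", name, "`; valid names: ",
         paste(names(reg), collapse = ", "))
  seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)
  if (is.null(out_dir)) out_dir <- if (is.null(config$out_dir)) "." else
    config$out_dir
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  t0 <- Sys.time()
  params <- if (is.null(config$params)) list() else config$params
  res <- reg[[name]](params, seed)
  csv <- file.path(out_dir, paste0(gsub("[^a-z0-9-]", "-", name), ".csv"))
  utils::write.csv(res, csv, row.names = FALSE)
  manifest <- list(experiment = name, seed = seed, params = params,
                   runtime_s = as.numeric(difftime(Sys.time(), t0,
                                                   units = "secs")),
                   output = basename(csv),
                   package_version = as.character(utils::packageVersion("ornmix")))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(res)
}

#' Canonical small fixtures
#'
#' Deterministic small instances used by the property-test suite: an
#' 8-receptor ensemble with a 4-odorant background pool (small enough for
#' exhaustive 2^8 pattern enumeration in the mutual-information oracle),
#' and the reference synergy/inhibition masked-odorant pairs
#' (`kappa_A = kappa_B = 1`, `eta_A = 1`, `eta_B = 5`; the strong
#' activator B carries the masking coefficient `mu_B = 0.7`, the synergy
#' pair gives B a weak site affinity with A blocking the sites, the
#' inhibition pair gives B a strong site affinity).
#'
#' @param seed Integer seed (default 1).
#' @return List with `small_config`, `pool` (odorant panel), `target`
#'   (one-column panel), `synergy_pair`, `inhibition_pair`.
#' @export
generate_fixtures <- function(seed = 1) {
  small_config <- ensemble_config(n_receptors = 8, rho = 0, p = 0.5)
  pool <- sample_odorants(small_config, 4, seed = substream_seed(seed, 1))
  target <- sample_odorants(small_config, 1, seed = substream_seed(seed, 2))
  synergy_pair <- list(
    A = masked_odorant(kappa = 1, eta = 1, KM = 1e-1, mu = 0),
    B = masked_odorant(kappa = 1, eta = 5, KM = 1e-5, mu = 0.7))
  inhibition_pair <- list(
    A = masked_odorant(kappa = 1, eta = 1, KM = 1e-5, mu = 0),
    B = masked_odorant(kappa = 1, eta = 5, KM = 1, mu = 0.7))
  list(small_config = small_config, pool = pool, target = target,
       synergy_pair = synergy_pair, inhibition_pair = inhibition_pair)
}
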