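## Simulated psychophysics. Perceived intensity of an odorant is read out
## from how many of "its" glomeruli are active: as concentration rises,
## glomeruli are recruited in order of sensitivity, so the active set
## encodes log-concentration with a concentration-invariant Weber ratio
## ~ log(cmax/c1) / (p N). Mixing a second odorant (or a masking agent)
## perturbs the active set and shifts the inferred concentration,
## reproducing inhibition, synergy, masking, suppression and overshadowing.

#' Recruitment table of an odorant
#'
#' For each glomerulus, the smallest grid concentration at which the
#' single-odorant response `y_i(c)` exceeds the activation threshold
#' `tau`. Glomeruli never recruited below `cmax` are excluded. In
#' expectation the table holds about `p * N` glomeruli.
#'
#' @param odorant A one-column odorant panel ([sample_odorant()]).
#' @param grid Log-spaced concentration grid (default 61 points over six
#'   decades centered on 1; the 0.1-decade step matches the mean
#'   recruitment spacing log10(cmax/c1)/(p N) of the reference ensemble,
#'   which keeps the increment estimator unbiased).
#' @param cmax Saturating concentration bound (default: top of the grid).
#' @return Object of class `"recruitment_table"`: data frame with columns
#'   `glomerulus` and `c_recruit`, sorted by `c_recruit`; the grid, `cmax`
#'   and the generating config are attached as attributes.
#' @export
recruitment_table <- function(odorant, grid = 10^seq(-3, 3, length.out = 61),
                              cmax = max(grid)) {
  cfg <- odorant$config
  if (any(diff(grid) <= 0)) stop("`grid` must be increasing")
  kinv <- exp(odorant$log_kappa_inv[, 1L])
  eta <- exp(odorant$log_eta[, 1L])
  # y is monotone in c, so the first grid crossing is well-defined.
  c_rec <- vapply(seq_along(kinv), function(i) {
    y <- rate_from_params(grid * kinv[i], eta[i], n = cfg$hill)
    j <- which(y > cfg$tau)[1L]
    if (is.na(j) || grid[j] > cmax) NA_real_ else grid[j]
  }, 0)
  keep <- !is.na(c_rec)
  out <- data.frame(glomerulus = which(keep), c_recruit = c_rec[keep])
  out <- out[order(out$c_recruit, out$glomerulus), ]
  rownames(out) <- NULL
  structure(out, class = c("recruitment_table", "data.frame"),
            grid = grid, cmax = cmax, config = cfg)
}

#' Infer log-concentration from an active glomerular set
#'
#' Each glomerulus in the table contributes its log-increment
#' `log10(c_i) - log10(c_{i-1})` (and `log10(c_1)` for the most sensitive
#' one) whenever it is active, independently of the other glomeruli;
#' for a contiguous active prefix the sum telescopes to `log10(c_k)` of
#' the last recruited glomerulus. Active glomeruli absent from the table
#' are ignored.
#'
#' @param active Logical vector over all `N` glomeruli, or integer indices
#'   of the active ones.
#' @param table A [recruitment_table()].
#' @return Inferred log10 concentration; `-Inf` when no table glomerulus
#'   is active.
#' @export
infer_concentration <- function(active, table) {
  stopifnot(inherits(table, "recruitment_table"))
  if (nrow(table) == 0L) stop("empty recruitment table")
  if (is.logical(active)) active <- which(active)
  lc <- log10(table$c_recruit)
  inc <- diff(c(0, lc))
  inc[1L] <- lc[1L]
  on <- table$glomerulus %in% active
  if (!any(on)) return(-Inf)
  sum(inc[on])
}

#' Inferred versus true concentration for mixtures
#'
#' Delivers odorant A alone, with a companion odorant B at equal
#' concentration, or with a pure masking agent B at fixed concentration
#' ratio, and infers A's concentration from A's recruitment table at each
#' true concentration. Averages over freshly sampled odorant pairs.
#'
#' @param config An [ensemble_config()] (the reference experiments use
#'   `p = 0.5`).
#' @param mode `"alone"`, `"binary"` (A + B at equal concentration) or
#'   `"masking"` (A at a fixed concentration, a non-receptor-binding
#'   masker B swept over `conc_grid`).
#' @param conc_grid In `"alone"`/`"binary"` modes the true concentrations
#'   of A; in `"masking"` mode the masker concentrations (default: the
#'   recruitment grid thinned to every 3rd point).
#' @param mu_B,KM_B Masking parameters of B in `"masking"` mode.
#' @param cA_fixed Fixed concentration of A in `"masking"` mode
#'   (default 100).
#' @param trials Number of odorant-pair draws (default 20).
#' @param seed Integer seed.
#' @return Data frame with columns `true_log_c` (log10 of A's
#'   concentration, or of the masker's in `"masking"` mode),
#'   `inferred_log_c` (mean over trials; `-Inf` contributions are
#'   evaluated as the bottom of the grid) and `mode`.
#' @export
mixture_intensity_experiment <- function(config,
                                         mode = c("alone", "binary",
                                                  "masking"),
                                         conc_grid = NULL, mu_B = 1,
                                         KM_B = 0.01, cA_fixed = 100,
                                         trials = 20, seed = 1) {
  mode <- match.arg(mode)
  grid <- 10^seq(-3, 3, length.out = 61)
  if (is.null(conc_grid)) conc_grid <- grid[seq(1, 61, by = 3)]
  floor_lc <- log10(min(grid))
  acc <- matrix(0, trials, length(conc_grid))
  for (tr in seq_len(trials)) {
    set.seed(substream_seed(seed, tr))
    A <- sample_odorants(config, 1)
    tab <- recruitment_table(A, grid = grid)
    if (nrow(tab) == 0L) { acc[tr, ] <- NA; next }
    B <- if (mode == "binary") sample_odorants(config, 1) else NULL
    for (j in seq_along(conc_grid)) {
      cj <- conc_grid[j]
      resp <- switch(
        mode,
        alone = finite_response(A, cj),
        binary = finite_response(
          structure(list(
            log_kappa_inv = cbind(A$log_kappa_inv, B$log_kappa_inv),
            log_eta = cbind(A$log_eta, B$log_eta),
            config = config), class = "odorant_panel"),
          c(cj, cj)),
        masking = {
          occ <- masking_occupancy(cj, KM_B)
          chi <- suppression_factor(occ, mu_B)
          finite_response(A, cA_fixed, chi = chi)
        })
      lc <- infer_concentration(resp$z, tab)
      acc[tr, j] <- max(lc, floor_lc)
    }
  }
  data.frame(true_log_c = log10(conc_grid),
             inferred_log_c = colMeans(acc, na.rm = TRUE),
             mode = mode)
}

#' Reciprocal and asymmetric suppression
#'
#' A is delivered at a fixed saturating concentration, B at concentration
#' `cA / ratio`. A glomerulus is "suppressed for A" when it is active
#' under A alone, inactive under B alone, and inactive in the mixture
#' (and symmetrically for B). Reported per concentration ratio as the
#' conditional fraction (normalized by the size of the conditioning set)
#' and, alongside, the unconditional per-N fraction; both are per-trial
#' fractions averaged over odorant-pair samples.
#'
#' @param config An [ensemble_config()].
#' @param ratio_grid Concentration ratios `cA / cB`.
#' @param cA Fixed concentration of A (default `1e3`, saturating for the
#'   central sensitivity range).
#' @param masking_B Optional [masking_profile()] giving B a masking
#'   propensity.
#' @param trials Odorant-pair draws per ratio (default 40).
#' @param seed Integer seed.
#' @return Data frame with columns `ratio`, `suppressed_A`,
#'   `suppressed_B` (conditional fractions), `suppressed_A_perN`,
#'   `suppressed_B_perN`, and `skipped` (trials with an empty
#'   conditioning set).
#' @details Both concentrations are large, so the receptor-level response
#'   is evaluated in the saturating limit (activation is governed by the
#'   effective mixture efficacy at fractions set by the ratio). Masking-
#'   site occupancy, which depends on the absolute masker concentration,
#'   uses `cB = cA / ratio`.
#' @export
suppression_fraction <- function(config, ratio_grid = 1, cA = 1e3,
                                 masking_B = NULL, trials = 40, seed = 1) {
  es <- config$eta_star
  rows <- list()
  for (r in seq_along(ratio_grid)) {
    ratio <- ratio_grid[r]
    cB <- cA / ratio
    beta <- c(ratio, 1) / (ratio + 1)
    sA <- sB <- sAn <- sBn <- numeric(0)
    skipped <- 0L
    for (tr in seq_len(trials)) {
      set.seed(substream_seed(seed, 1000 * r + tr))
      A <- sample_odorants(config, 1)
      B <- sample_odorants(config, 1)
      chiB <- 1
      if (!is.null(masking_B))
        chiB <- suppression_factor(
          masking_occupancy(cB, masking_B$KM), masking_B$mu, masking_B$m)
      zA <- exp(A$log_eta[, 1L]) > es
      zB <- chiB * exp(B$log_eta[, 1L]) > es
      AB <- structure(list(
        log_kappa_inv = cbind(A$log_kappa_inv, B$log_kappa_inv),
        log_eta = cbind(A$log_eta, B$log_eta),
        config = config), class = "odorant_panel")
      zM <- chiB * mixture_efficacy(AB, beta) > es
      condA <- zA & !zB
      condB <- zB & !zA
      if (!any(condA) || !any(condB)) { skipped <- skipped + 1L; next }
      sA <- c(sA, mean(!zM[condA]))
      sB <- c(sB, mean(!zM[condB]))
      sAn <- c(sAn, sum(condA & !zM) / config$n_receptors)
      sBn <- c(sBn, sum(condB & !zM) / config$n_receptors)
    }
    rows[[r]] <- data.frame(ratio = ratio,
                            suppressed_A = mean(sA), suppressed_B = mean(sB),
                            suppressed_A_perN = mean(sAn),
                            suppressed_B_perN = mean(sBn),
                            skipped = skipped)
  }
  do.call(rbind, rows)
}

#' Overshadowing of a weak component by a strong one
#'
#' Logistic regressors for two odorants A and B are trained to detect
#' their target delivered alone at varying concentrations. Negative
#' trials are an even mixture of stimulus-absent blanks (which calibrate
#' presence versus absence of the target's glomerular signature) and
#' single distractor odorants (which discount the chance coverage of the
#' target's glomeruli by unrelated stimuli); both ingredients are needed
#' for the detector to track the target rather than overall pattern
#' statistics. The pair is then delivered with A fixed at `cA` and B
#' diluted to `cA / ratio`, and the mean regressor output (probability of
#' presence) is reported for both odorants. B is overshadowed once its
#' probability falls below the detection threshold (0.5); antagonism
#' (`rho = 0`) suppresses B's glomeruli at smaller ratios than the
#' non-antagonistic code.
#'
#' @param config An [ensemble_config()].
#' @param ratio_grid Concentration ratios `cA / cB` (>= 1).
#' @param cA Fixed concentration of the strong odorant A (default 100).
#' @param trials Odorant-pair draws (each with freshly trained
#'   regressors; default 12).
#' @param train_trials Training trials per regressor (default 300).
#' @param conc_decades Training concentrations are log-uniform over this
#'   many decades below `cA` (default 3, covering the delivery range of
#'   the diluted component).
#' @param blank_frac Fraction of negative trials that are blanks
#'   (default 0.5).
#' @param lambda Ridge penalty.
#' @param seed Integer seed.
#' @return Data frame with columns `ratio`, `p_A`, `p_B` (mean regressor
#'   probabilities).
#' @export
overshadowing_curve <- function(config, ratio_grid = 10^seq(0, 3, by = 0.5),
                                cA = 100, trials = 12, train_trials = 300,
                                conc_decades = 3, blank_frac = 0.5,
                                lambda = 1e-3, seed = 1) {
  train_regressor <- function(target) {
    y <- rep(c(1, 0), length.out = train_trials)
    Z <- matrix(0, train_trials, config$n_receptors)
    for (i in seq_len(train_trials)) {
      if (y[i] == 1) {
        conc <- cA * 10^stats::runif(1, -conc_decades, 0)
        Z[i, ] <- finite_response(target, conc)$z * 1
      } else if (stats::runif(1) > blank_frac) {
        conc <- cA * 10^stats::runif(1, -conc_decades, 0)
        Z[i, ] <- finite_response(sample_odorants(config, 1), conc)$z * 1
      }
    }
    fit_logistic_ridge(Z, y, lambda = lambda)
  }
  pA <- pB <- matrix(NA_real_, trials, length(ratio_grid))
  for (tr in seq_len(trials)) {
    set.seed(substream_seed(seed, tr))
    A <- sample_odorants(config, 1)
    B <- sample_odorants(config, 1)
    clfA <- train_regressor(A)
    clfB <- train_regressor(B)
    AB <- structure(list(
      log_kappa_inv = cbind(A$log_kappa_inv, B$log_kappa_inv),
      log_eta = cbind(A$log_eta, B$log_eta),
      config = config), class = "odorant_panel")
    for (j in seq_along(ratio_grid)) {
      z <- finite_response(AB, c(cA, cA / ratio_grid[j]))$z * 1
      pA[tr, j] <- classifier_prob(clfA, z)
      pB[tr, j] <- classifier_prob(clfB, z)
    }
  }
  data.frame(ratio = ratio_grid, p_A = colMeans(pA), p_B = colMeans(pB))
}
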