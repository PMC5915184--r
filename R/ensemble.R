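## Population encoding model. An odorant is a pair of N-vectors over
## receptor types: log-sensitivities log kappa^-1 and log-efficacies
## log eta. The antagonism factor rho is the correlation between the two
## (rho = 1: the strongest binders are the strongest activators, no
## antagonism; rho = 0: binding and activation decorrelated, maximal
## statistical antagonism). Saturating responses y = 1/(1 + eta_mix^-n) are
## binarized by a threshold tau chosen so a single odorant activates a
## fraction p of the glomeruli.

#' Receptor-ensemble configuration
#'
#' @param n_receptors Number of receptor types `N` (default 250).
#' @param sigma_kappa Standard deviation of `log kappa^-1` in natural-log
#'   units (default 4).
#' @param rho Antagonism factor in `[0, 1]`: correlation between
#'   `log kappa^-1` and the latent efficacy variable.
#' @param p Target sparsity in `(0, 1)`: fraction of glomeruli a saturating
#'   single odorant activates.
#' @param hill Hill coefficient `n` (default 4).
#' @param efficacy Efficacy distribution: `"lognormal"` (`log eta ~ N(0,1)`)
#'   or `"exponential"` (`eta ~ Exp(1)`, coupled to the sensitivity through
#'   a Gaussian copula so `rho` keeps its meaning).
#' @return An object of class `"ensemble_config"`, with the derived
#'   activation threshold `tau` and the equivalent efficacy threshold
#'   `eta_star` (`y > tau` iff `eta_mix > eta_star`).
#' @examples
#' cfg <- ensemble_config(rho = 0, p = 0.3)
#' cfg$tau
#' @export
ensemble_config <- function(n_receptors = 250, sigma_kappa = 4, rho = 0,
                            p = 0.3, hill = 4,
                            efficacy = c("lognormal", "exponential")) {
  efficacy <- match.arg(efficacy)
  stopifnot_scalar(n_receptors, "n_receptors", positive = TRUE)
  stopifnot_scalar(sigma_kappa, "sigma_kappa", positive = TRUE)
  if (rho < 0 || rho > 1) stop("`rho` must lie in [0, 1]")
  if (p <= 0 || p >= 1) stop("`p` must lie in (0, 1)")
  eta_star <- if (efficacy == "lognormal") {
    exp(stats::qnorm(1 - p))
  } else {
    stats::qexp(1 - p)
  }
  tau <- 1 / (1 + eta_star^-hill)
  structure(list(n_receptors = as.integer(n_receptors),
                 sigma_kappa = sigma_kappa, rho = rho, p = p, hill = hill,
                 efficacy = efficacy, tau = tau, eta_star = eta_star),
            class = "ensemble_config")
}

#' @export
print.ensemble_config <- function(x, ...) {
  cat(sprintf(paste0("<ensemble_config> N = %d, sigma_kappa = %g, rho = %g, ",
                     "p = %g, n = %g, efficacy = %s (tau = %.4g)\n"),
              x$n_receptors, x$sigma_kappa, x$rho, x$p, x$hill,
              x$efficacy, x$tau))
  invisible(x)
}

#' Sample odorants from a receptor ensemble
#'
#' Draws `k` odorants. Per receptor, a latent standard normal `u` generates
#' the efficacy (`log eta = u` for log-normal ensembles, `eta = qexp(pnorm(u))`
#' for exponential ones) and the sensitivity is
#' `log kappa^-1 = sigma_kappa * (rho * u + sqrt(1 - rho^2) * omega)` with
#' independent standard-normal `omega`.
#'
#' @param config An [ensemble_config()].
#' @param k Number of odorants to draw.
#' @param seed Optional integer seed.
#' @return An object of class `"odorant_panel"`: list with `N x k` matrices
#'   `log_kappa_inv` and `log_eta`, and the generating `config`.
#' @export
sample_odorants <- function(config, k = 1, seed = NULL) {
  stopifnot(inherits(config, "ensemble_config"))
  if (!is.null(seed)) set.seed(seed)
  N <- config$n_receptors
  u <- matrix(stats::rnorm(N * k), N, k)
  omega <- matrix(stats::rnorm(N * k), N, k)
  log_eta <- if (config$efficacy == "lognormal") {
    u
  } else {
    log(stats::qexp(stats::pnorm(u)))
  }
  lki <- config$sigma_kappa *
    (config$rho * u + sqrt(1 - config$rho^2) * omega)
  structure(list(log_kappa_inv = lki, log_eta = log_eta, config = config),
            class = "odorant_panel")
}

#' @rdname sample_odorants
#' @export
sample_odorant <- function(config, seed = NULL) sample_odorants(config, 1, seed)

# Subset a panel's columns (odorants), keeping the class.
panel_subset <- function(panel, idx) {
  structure(list(log_kappa_inv = panel$log_kappa_inv[, idx, drop = FALSE],
                 log_eta = panel$log_eta[, idx, drop = FALSE],
                 config = panel$config),
            class = "odorant_panel")
}

#' Per-receptor effective mixture efficacy
#'
#' Exact effective efficacy `eta_mix` of a mixture of the panel's odorants
#' at fractions `beta`, per receptor; optionally the dominant-component
#' approximation (`eta_mix ~ eta_M`, `M = argmax beta_i kappa_i^-1`).
#'
#' @param panel An [sample_odorants()] panel (columns = mixture components).
#' @param beta Mixture fractions (default equiproportionate).
#' @param method `"exact"` (effective-parameter algebra) or `"dominant"`.
#' @return Numeric vector of length `N` of `eta_mix` values.
#' @export
mixture_efficacy <- function(panel, beta = NULL,
                             method = c("exact", "dominant")) {
  method <- match.arg(method)
  kinv <- exp(panel$log_kappa_inv)
  eta <- exp(panel$log_eta)
  K <- ncol(kinv)
  if (is.null(beta)) beta <- rep(1 / K, K)
  stopifnot(length(beta) == K, all(beta >= 0))
  bw <- sweep(kinv, 2L, beta, `*`)
  if (method == "exact") {
    rowSums(eta * bw) / rowSums(bw)
  } else {
    idx <- cbind(seq_len(nrow(bw)), max.col(bw, ties.method = "first"))
    eta[idx]
  }
}

#' Saturating population response to a mixture
#'
#' Glomerular activation at saturating total concentration: per receptor,
#' `y = 1 / (1 + eta_mix^-n)` with the exact (or dominant-approximate)
#' effective efficacy, thresholded to the binary pattern `z = (y > tau)`.
#'
#' @inheritParams mixture_efficacy
#' @return A list of class `"glomerular_response"` with the continuous
#'   vector `y`, the binary vector `z` and the threshold `tau` used.
#' @export
saturating_response <- function(panel, beta = NULL,
                                method = c("exact", "dominant")) {
  cfg <- panel$config
  eta_mix <- mixture_efficacy(panel, beta, method)
  y <- 1 / (1 + eta_mix^-cfg$hill)
  structure(list(y = y, z = y > cfg$tau, tau = cfg$tau),
            class = "glomerular_response")
}

#' Finite-concentration population response
#'
#' Full mixture dose-response per receptor at the given component
#' concentrations (arbitrary units; the sensitivity scale of each
#' receptor-odorant pair is `exp(-log_kappa_inv)`).
#'
#' @param panel An odorant panel whose columns are the mixture components.
#' @param conc Non-negative concentration per component.
#' @param chi Optional suppression factor (scalar or length-`N`) from
#'   masking, applied to `eta_mix`.
#' @return A `"glomerular_response"` as in [saturating_response()].
#' @export
finite_response <- function(panel, conc, chi = 1) {
  cfg <- panel$config
  kinv <- exp(panel$log_kappa_inv)
  eta <- exp(panel$log_eta)
  stopifnot(length(conc) == ncol(kinv), all(conc >= 0))
  C <- sum(conc)
  if (C <= 0) {
    y <- numeric(cfg$n_receptors)
  } else {
    beta <- conc / C
    bw <- sweep(kinv, 2L, beta, `*`)
    kinv_mix <- rowSums(bw)
    eta_mix <- rowSums(eta * bw) / kinv_mix
    y <- rate_from_params(C * kinv_mix, eta_mix, n = cfg$hill, chi = chi)
  }
  structure(list(y = y, z = y > cfg$tau, tau = cfg$tau),
            class = "glomerular_response")
}

#' Active fraction versus mixture complexity
#'
#' Fraction of active glomeruli for saturating equiproportionate mixtures of
#' `nmix` freshly sampled odorants, as a function of `nmix` and the
#' antagonism factor `rho`. With no antagonism (`rho = 1`) the population
#' approaches an OR gate (`1 - (1-p)^K`); with full antagonism (`rho = 0`)
#' the fraction stays near the single-odorant sparsity `p` (normalization).
#'
#' @param config An [ensemble_config()]; its `rho` is overridden by
#'   `rho_values`.
#' @param nmix_values Mixture sizes.
#' @param rho_values Antagonism factors to scan.
#' @param trials Monte-Carlo repetitions (fresh odorants each).
#' @param seed Integer seed.
#' @param method Passed to [saturating_response()].
#' @return Data frame with columns `rho`, `nmix`, `fraction_active` (mean
#'   over trials and receptors) and `se` (MC standard error over
#'   trial-receptor activations).
#' @export
fraction_active_vs_complexity <- function(config, nmix_values,
                                          rho_values = config$rho,
                                          trials = 20, seed = 1,
                                          method = c("exact", "dominant")) {
  method <- match.arg(method)
  rows <- list(); r <- 0L
  for (rho in rho_values) {
    cfg <- ensemble_config(config$n_receptors, config$sigma_kappa, rho,
                           config$p, config$hill, config$efficacy)
    for (K in nmix_values) {
      set.seed(substream_seed(seed, r))
      zs <- replicate(trials, {
        panel <- sample_odorants(cfg, K)
        saturating_response(panel, method = method)$z
      })
      f <- mean(zs)
      r <- r + 1L
      rows[[r]] <- data.frame(rho = rho, nmix = K, fraction_active = f,
                              se = stats::sd(zs) / sqrt(length(zs)))
    }
  }
  do.call(rbind, rows)
}

#' Distribution of the effective mixture efficacy
#'
#' Samples of `eta_mix` across receptors and trials for saturating
#' equiproportionate mixtures of increasing complexity. At `rho = 0` the
#' distribution is invariant to `nmix` (normalization); at `rho = 1` it is
#' increasingly biased toward large efficacies.
#'
#' @inheritParams fraction_active_vs_complexity
#' @param samples Target number of `eta_mix` samples per `nmix` (rounded up
#'   to whole trials of `N` receptors).
#' @param method `"exact"` or `"dominant"`, as in [mixture_efficacy()].
#' @return Data frame with columns `nmix` and `eta_mix`.
#' @export
eta_mix_distribution <- function(config, nmix_values, samples = 10000,
                                 seed = 1, method = c("exact", "dominant")) {
  method <- match.arg(method)
  rows <- list(); r <- 0L
  N <- config$n_receptors
  trials <- ceiling(samples / N)
  for (K in nmix_values) {
    set.seed(substream_seed(seed, K))
    em <- unlist(lapply(seq_len(trials), function(i) {
      mixture_efficacy(sample_odorants(config, K), method = method)
    }))
    em <- em[seq_len(min(samples, length(em)))]
    r <- r + 1L
    rows[[r]] <- data.frame(nmix = K, eta_mix = em)
  }
  do.call(rbind, rows)
}

#' Serialize an odorant panel to a tidy data frame
#'
#' Long-format representation with one row per (receptor, odorant) pair
#' and columns `receptor_id`, `odorant_id`, `log_kappa_inv`, `log_eta`;
#' `panel_from_df()` inverts it given the generating config.
#'
#' @param panel An [sample_odorants()] panel.
#' @param df A data frame in the same long format.
#' @param config The [ensemble_config()] the panel belongs to.
#' @return A data frame, or an `odorant_panel`.
#' @export
panel_to_df <- function(panel) {
  N <- nrow(panel$log_eta); K <- ncol(panel$log_eta)
  data.frame(receptor_id = rep(seq_len(N), K),
             odorant_id = rep(seq_len(K), each = N),
             log_kappa_inv = as.numeric(panel$log_kappa_inv),
             log_eta = as.numeric(panel$log_eta))
}

#' @rdname panel_to_df
#' @export
panel_from_df <- function(df, config) {
  req <- c("receptor_id", "odorant_id", "log_kappa_inv", "log_eta")
  if (!all(req %in% names(df))) stop("panel table needs columns: ",
                                     paste(req, collapse = ", "))
  df <- df[order(df$odorant_id, df$receptor_id), ]
  N <- length(unique(df$receptor_id)); K <- length(unique(df$odorant_id))
  if (nrow(df) != N * K) stop("panel table is not a complete grid")
  structure(list(log_kappa_inv = matrix(df$log_kappa_inv, N, K),
                 log_eta = matrix(df$log_eta, N, K),
                 config = config),
            class = "odorant_panel")
}
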