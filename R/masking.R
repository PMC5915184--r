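## Non-competitive masking. Masking agents bind a limited pool of sites on
## the ciliary membrane near the CNG channels and lower the effective
## affinity of cAMP for the channel. At the level of the peak-response
## algebra the whole effect condenses into a multiplicative suppression
## factor chi_M applied to the (mixture) activation efficacy:
##   eta_mix -> chi_M * eta_mix,   chi_M = (1 - sum_k mu_k Mtilde_k)^m
## with Mtilde_k the occupancy fraction of agent k on the shared sites.

#' Masking profile of an agent
#'
#' @param KM Binding affinity for the masking sites (1/concentration),
#'   `>= 0`; 0 means the agent never occupies masking sites.
#' @param mu Masking coefficient in `[0, 1]`: suppression exerted once bound.
#' @param m Subunit exponent (default 1); equals `j/n` when the agent
#'   affects `j` of the `n` channel subunits.
#' @return An object of class `"masking_profile"`.
#' @export
masking_profile <- function(KM = 0, mu = 0, m = 1) {
  if (!is.numeric(KM) || KM < 0) stop("`KM` must be >= 0")
  if (!is.numeric(mu) || mu < 0 || mu > 1) stop("`mu` must lie in [0, 1]")
  stopifnot_scalar(m, "m", positive = TRUE)
  structure(list(KM = as.double(KM), mu = as.double(mu), m = as.double(m)),
            class = "masking_profile")
}

#' Odorant with both receptor-binding and masking properties
#'
#' Many masking agents are themselves odorants: they bind receptors (an
#' [ss_profile()]) and in addition occupy masking sites (a
#' [masking_profile()]). Pure maskers take `kappa = Inf` (no receptor
#' binding); pure excitants take `KM = 0` or `mu = 0`.
#'
#' @param kappa,eta Receptor-level parameters, see [ss_profile()].
#' @param KM,mu,m Masking parameters, see [masking_profile()].
#' @return An object of class `"masked_odorant"`.
#' @export
masked_odorant <- function(kappa = Inf, eta = 1, KM = 0, mu = 0, m = 1) {
  structure(list(profile = ss_profile(kappa, eta),
                 masking = masking_profile(KM, mu, m)),
            class = "masked_odorant")
}

#' Masking-site occupancy fractions
#'
#' Steady-state occupancy of the shared masking sites by competing agents:
#' `Mtilde_i = KM_i M_i / (1 + sum_j KM_j M_j)`.
#'
#' @param M Agent concentrations (non-negative vector).
#' @param KM Agent site affinities (non-negative vector, same length).
#' @return Vector of occupancy fractions; their sum is `< 1`.
#' @export
masking_occupancy <- function(M, KM) {
  if (length(M) != length(KM)) stop("`M` and `KM` must have equal length")
  if (any(M < 0) || any(KM < 0)) stop("inputs must be non-negative")
  KM * M / (1 + sum(KM * M))
}

#' Suppression factor of the CNG channel
#'
#' `chi_M = (1 - sum_i mu_i Mtilde_i)^m`, clipped at 0. The base cannot go
#' negative for valid occupancies and `mu <= 1`, but is clipped defensively.
#'
#' @param occupancy Occupancy fractions from [masking_occupancy()].
#' @param mu Masking coefficients in `[0, 1]`, same length.
#' @param m Subunit exponent (default 1).
#' @return Scalar `chi_M` in `[0, 1]`.
#' @export
suppression_factor <- function(occupancy, mu, m = 1) {
  if (length(occupancy) != length(mu))
    stop("`occupancy` and `mu` must have equal length")
  base <- 1 - sum(mu * occupancy)
  max(0, base)^m
}

#' Saturating rate under masking
#'
#' The saturating firing rate with the efficacy scaled by `chi`:
#' `Fmax / (1 + (chi * eta)^-n)`; 0 when `chi = 0`.
#'
#' @param eta Activation efficacy (vectorized).
#' @param chi Suppression factor in `[0, 1]`.
#' @param n Hill coefficient.
#' @param fmax Maximal rate.
#' @return Numeric vector of rates.
#' @export
masked_saturating_rate <- function(eta, chi, n = 4, fmax = 1) {
  if (any(chi < 0 | chi > 1)) stop("`chi` must lie in [0, 1]")
  e <- chi * eta
  out <- fmax / (1 + e^-n)
  out[e == 0] <- 0
  out
}

#' Mixture response with masking
#'
#' Full peak response of a mixture of [masked_odorant()]s delivered at given
#' concentrations: receptor competition determines `(kappa_mix, eta_mix)`
#' from the receptor-binding components, masking-site competition determines
#' `chi_M` from all components, and the response is the mixture
#' dose-response with effective efficacy `chi_M * eta_mix`, evaluated at the
#' total concentration of the binding components.
#'
#' All components are assumed to share the subunit exponent of the first
#' component with `mu > 0` (default 1 when none masks).
#'
#' @param components List of [masked_odorant()]s.
#' @param conc Vector of concentrations, one per component.
#' @param n Hill coefficient.
#' @param fmax Maximal rate.
#' @return The scalar peak firing rate.
#' @export
mixture_rate_with_masking <- function(components, conc, n = 4, fmax = 1) {
  stopifnot(length(components) == length(conc))
  if (any(conc < 0)) stop("concentrations must be non-negative")
  kappa <- vapply(components, function(o) o$profile$kappa, 0)
  eta <- vapply(components, function(o) o$profile$eta, 0)
  KM <- vapply(components, function(o) o$masking$KM, 0)
  mu <- vapply(components, function(o) o$masking$mu, 0)
  mexp <- vapply(components, function(o) o$masking$m, 0)
  m <- if (any(mu > 0)) mexp[which(mu > 0)[1L]] else 1

  occ <- masking_occupancy(conc, KM)
  chi <- suppression_factor(occ, mu, m = m)

  bind <- is.finite(kappa) & conc > 0
  if (!any(bind)) return(0)
  Cb <- sum(conc[bind])
  beta <- conc[bind] / Cb
  kinv_mix <- sum(beta / kappa[bind])
  eta_mix <- sum(eta[bind] * beta / kappa[bind]) / kinv_mix
  rate_from_params(Cb * kinv_mix, eta_mix, n = n, fmax = fmax, chi = chi)
}

#' Dose-response curves of components and their mixture
#'
#' Convenience wrapper evaluating, on a shared total-concentration axis,
#' each component alone (including its self-masking) and the mixture at
#' fixed fractions `weights`. Used to exhibit synergy (mixture above every
#' component curve) and inhibition (below every curve), which are impossible
#' under pure receptor competition.
#'
#' @param components List of [masked_odorant()]s.
#' @param C_grid Total-concentration grid (positive, sorted).
#' @param weights Mixture fractions (default equiproportionate).
#' @param n,fmax As elsewhere.
#' @return Data frame with columns `C`, `component` (factor; `"mixture"` for
#'   the mixture curve) and `rate`.
#' @export
masked_mixture_curves <- function(components, C_grid,
                                  weights = NULL, n = 4, fmax = 1) {
  K <- length(components)
  if (is.null(weights)) weights <- rep(1 / K, K)
  stopifnot(length(weights) == K, all(weights >= 0), abs(sum(weights) - 1) < 1e-12)
  out <- list()
  for (i in seq_len(K)) {
    ri <- vapply(C_grid, function(ct) {
      conc <- numeric(K); conc[i] <- ct
      mixture_rate_with_masking(components, conc, n = n, fmax = fmax)
    }, 0)
    out[[i]] <- data.frame(C = C_grid, component = paste0("component_", i),
                           rate = ri)
  }
  rm_ <- vapply(C_grid, function(ct)
    mixture_rate_with_masking(components, weights * ct, n = n, fmax = fmax), 0)
  out[[K + 1L]] <- data.frame(C = C_grid, component = "mixture", rate = rm_)
  do.call(rbind, out)
}

#' Masking dose-response (suppression ratio) curve
#'
#' Fractional suppression `1 - F_M(inf) / F(inf)` of a saturating excitant as
#' a function of the masker concentration. The excitant is taken at
#' saturating concentration; the masker occupies masking sites only.
#'
#' @param excitant A [masked_odorant()] (its `eta` sets the unmasked
#'   saturating rate; its own masking parameters are ignored at the
#'   saturating limit unless it also occupies sites, controlled by
#'   `excitant_conc`).
#' @param masker A [masking_profile()].
#' @param M_grid Positive, sorted masker concentrations.
#' @param excitant_conc Optional finite excitant concentration competing for
#'   masking sites (default 0: the excitant does not occupy sites).
#' @param n,fmax As elsewhere.
#' @return Data frame with columns `M` and `ratio` (in `[0, 1]`, monotone
#'   non-decreasing).
#' @export
masking_dose_response <- function(excitant, masker, M_grid,
                                  excitant_conc = 0, n = 4, fmax = 1) {
  if (any(diff(M_grid) < 0) || any(M_grid < 0))
    stop("`M_grid` must be sorted and non-negative")
  eta <- excitant$profile$eta
  f0 <- masked_saturating_rate(eta, 1, n = n, fmax = fmax)
  ratio <- vapply(M_grid, function(M) {
    occ <- masking_occupancy(c(M, excitant_conc),
                             c(masker$KM, excitant$masking$KM))
    chi <- suppression_factor(occ, c(masker$mu, excitant$masking$mu),
                              m = masker$m)
    1 - masked_saturating_rate(eta, chi, n = n, fmax = fmax) / f0
  }, 0)
  data.frame(M = M_grid, ratio = ratio)
}

#' Least-squares fit of a masking profile
#'
#' Utility fitting `(KM, mu, m)` to user-supplied (concentration,
#' suppression-ratio) pairs by deterministic Nelder-Mead least squares on
#' `(log KM, logit mu, log m)`.
#'
#' @param M Masker concentrations.
#' @param ratio Observed suppression ratios `1 - F_M/F` in `[0, 1]`.
#' @param eta Efficacy of the probe excitant (default 100: strong excitant,
#'   ratio driven by masking alone).
#' @param n Hill coefficient.
#' @param fit_m Fit the subunit exponent as well (default `FALSE`, `m = 1`).
#' @param start Optional named list of starting values (`KM`, `mu`, `m`).
#' @return A [masking_profile()] with the fitted parameters; the achieved
#'   residual sum of squares is attached as attribute `"rss"`.
#' @export
fit_masking_profile <- function(M, ratio, eta = 100, n = 4,
                                fit_m = FALSE, start = NULL) {
  stopifnot(length(M) == length(ratio), all(M >= 0),
            all(ratio >= 0), all(ratio <= 1))
  s <- list(KM = if (is.null(start$KM)) 1 / stats::median(M[M > 0]) else start$KM,
            mu = if (is.null(start$mu)) 0.5 else start$mu,
            m = if (is.null(start$m)) 1 else start$m)
  probe <- masked_odorant(kappa = 1, eta = eta)
  obj <- function(par) {
    KM <- exp(par[1L]); mu <- stats::plogis(par[2L])
    m <- if (fit_m) exp(par[3L]) else s$m
    pred <- masking_dose_response(probe, masking_profile(KM, mu, m), M,
                                  n = n)$ratio
    sum((pred - ratio)^2)
  }
  par0 <- c(log(s$KM), stats::qlogis(min(max(s$mu, 1e-3), 1 - 1e-3)))
  if (fit_m) par0 <- c(par0, log(s$m))
  fit <- stats::optim(par0, obj, method = "Nelder-Mead",
                      control = list(maxit = 2000, reltol = 1e-10))
  out <- masking_profile(KM = exp(fit$par[1L]),
                         mu = stats::plogis(fit$par[2L]),
                         m = if (fit_m) exp(fit$par[3L]) else s$m)
  attr(out, "rss") <- fit$value
  out
}
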