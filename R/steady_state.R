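## Closed-form peak-response algebra for single odorants and competitive
## mixtures. An odorant-receptor pair is reduced to two numbers: the
## sensitivity scale kappa (response builds up around C ~ kappa; the
## *sensitivity* is kappa^-1) and the activation efficacy eta, which sets the
## saturating rate Fmax / (1 + eta^-n). A mixture of K odorants competing for
## the same receptor behaves like a single odorant with effective parameters
##   kappa_mix^-1 = sum_i beta_i kappa_i^-1
##   eta_mix      = kappa_mix * sum_i eta_i beta_i kappa_i^-1
## where beta_i are the concentration fractions.

#' Steady-state odorant-receptor profile
#'
#' Bundles the two parameters that fully determine the peak (steady-state)
#' firing-rate response of one receptor type to one odorant: the sensitivity
#' scale `kappa` (concentration units; the sensitivity proper is `1/kappa`)
#' and the dimensionless activation efficacy `eta`.
#'
#' @param kappa Sensitivity scale, strictly positive. `Inf` is allowed and
#'   denotes an agent that does not bind the receptor (zero sensitivity).
#' @param eta Activation efficacy, strictly positive.
#' @return An object of class `"ss_profile"`.
#' @examples
#' ss_profile(kappa = 1, eta = 5)
#' @export
ss_profile <- function(kappa, eta) {
  if (!is.numeric(kappa) || length(kappa) != 1L || is.na(kappa) || kappa <= 0)
    stop("`kappa` must be a positive scalar (Inf allowed for non-binders)")
  stopifnot_scalar(eta, "eta", positive = TRUE)
  structure(list(kappa = as.double(kappa), eta = as.double(eta)),
            class = "ss_profile")
}

#' @export
print.ss_profile <- function(x, ...) {
  cat(sprintf("<ss_profile> kappa = %g (sensitivity %g), eta = %g\n",
              x$kappa, 1 / x$kappa, x$eta))
  invisible(x)
}

#' Peak firing rate of a single odorant
#'
#' Hill-type dose-response of one receptor type to a monomolecular odorant at
#' concentration `C`:
#' \deqn{F(C) = F_{max} / (1 + ((1 + C/\kappa) / (\eta C/\kappa))^n)}
#' with `F(0) = 0`. The saturating limit is `Fmax / (1 + eta^-n)`.
#'
#' @param C Concentration(s), non-negative. Vectorized.
#' @param profile An [ss_profile()]; alternatively give `kappa` and `eta`.
#' @param kappa,eta Parameters used when `profile` is `NULL`.
#' @param n Hill coefficient (default 4, the four cAMP binding sites of the
#'   CNG channel).
#' @param fmax Maximal firing rate (default 1; rates are reported as a
#'   fraction of it).
#' @return Numeric vector of rates, same length as `C`.
#' @examples
#' single_odorant_rate(1, kappa = 1, eta = 1)   # 1/17
#' single_odorant_rate(Inf, kappa = 1, eta = 1) # 1/2
#' @export
single_odorant_rate <- function(C, profile = NULL, kappa = NULL, eta = NULL,
                                n = 4, fmax = 1) {
  if (!is.null(profile)) {
    kappa <- profile$kappa
    eta <- profile$eta
  }
  if (any(C < 0)) stop("concentrations must be non-negative")
  rate_from_params(C / kappa, eta, n = n, fmax = fmax)
}

# Core dose-response in terms of x = C / kappa. Vectorized over everything;
# handles x = 0 (rate 0) and x = Inf (saturation) exactly. `chi` is the
# masking suppression factor (1 = unmasked).
rate_from_params <- function(x, eta, n = 4, fmax = 1, chi = 1) {
  len <- max(length(x), length(eta), length(chi))
  x <- rep_len(x, len); eeff <- rep_len(chi * eta, len)
  out <- fmax / (1 + ((1 + x) / (eeff * x))^n)
  out[x == 0] <- 0
  sat <- is.infinite(x)
  out[sat] <- fmax / (1 + eeff[sat]^-n)
  out[eeff == 0] <- 0
  out
}

#' Competitive mixture specification
#'
#' A set of odorants, characterized per-receptor by their [ss_profile()]
#' parameters, delivered simultaneously at given concentrations to one
#' receptor type. Components with zero concentration are dropped; components
#' with `kappa = Inf` (non-binders) contribute nothing to receptor occupancy
#' but are retained for bookkeeping by callers.
#'
#' @param kappa,eta Numeric vectors of per-component parameters.
#' @param conc Numeric vector of non-negative concentrations.
#' @return An object of class `"mixture_spec"` with fields `kappa`, `eta`,
#'   `conc`, the total concentration `C` and fractions `beta`.
#' @export
mixture_spec <- function(kappa, eta, conc) {
  if (length(kappa) != length(eta) || length(eta) != length(conc))
    stop("`kappa`, `eta` and `conc` must have equal length")
  if (any(conc < 0)) stop("concentrations must be non-negative")
  if (any(kappa <= 0) || any(eta <= 0)) stop("kappa and eta must be positive")
  keep <- conc > 0
  kappa <- kappa[keep]; eta <- eta[keep]; conc <- conc[keep]
  C <- sum(conc)
  structure(list(kappa = kappa, eta = eta, conc = conc,
                 C = C, beta = if (C > 0) conc / C else conc),
            class = "mixture_spec")
}

#' Effective mixture parameters
#'
#' Collapses a competitive mixture into the single effective profile
#' `(kappa_mix, eta_mix)` that reproduces its dose-response:
#' `kappa_mix^-1 = sum(beta * kappa^-1)` and
#' `eta_mix = kappa_mix * sum(eta * beta * kappa^-1)`.
#'
#' @param mix A [mixture_spec()] with positive total concentration.
#' @return An [ss_profile()].
#' @export
effective_mixture_params <- function(mix) {
  stopifnot(inherits(mix, "mixture_spec"))
  if (mix$C <= 0) stop("empty mixture: total concentration is zero")
  kinv <- sum(mix$beta / mix$kappa)
  if (kinv <= 0) stop("mixture contains no receptor-binding component")
  eta <- sum(mix$eta * mix$beta / mix$kappa) / kinv
  ss_profile(kappa = 1 / kinv, eta = eta)
}

#' Peak response of a competitive mixture
#'
#' Evaluates the mixture dose-response at total concentration `C`
#' (by default the mixture's own total): identical to [single_odorant_rate()]
#' with the [effective_mixture_params()] profile.
#'
#' @inheritParams single_odorant_rate
#' @param mix A [mixture_spec()].
#' @param C Total concentration(s) at which to evaluate; defaults to
#'   `mix$C`. The component fractions `beta` are held fixed.
#' @return Numeric vector of rates.
#' @export
mixture_rate <- function(mix, n = 4, fmax = 1, C = NULL) {
  prof <- effective_mixture_params(mix)
  if (is.null(C)) C <- mix$C
  single_odorant_rate(C, profile = prof, n = n, fmax = fmax)
}

#' Dominant-component approximation of mixture parameters
#'
#' Broadly distributed sensitivities make the sum `sum(beta_i kappa_i^-1)`
#' typically dominated by a single term `M = argmax beta_i kappa_i^-1`.
#' Keeping only that term gives `kappa_mix^-1 ~ beta_M kappa_M^-1` and
#' `eta_mix ~ eta_M`. Ties are broken toward the lowest component index.
#'
#' @param mix A [mixture_spec()].
#' @return An [ss_profile()] with the approximate parameters.
#' @export
dominant_approximation <- function(mix) {
  stopifnot(inherits(mix, "mixture_spec"))
  if (mix$C <= 0) stop("empty mixture: total concentration is zero")
  w <- mix$beta / mix$kappa
  M <- which.max(w)   # which.max takes the first maximum: lowest index on ties
  ss_profile(kappa = 1 / w[M], eta = mix$eta[M])
}

#' Accuracy of the dominant-component approximation
#'
#' Monte-Carlo experiment quantifying the relative error of
#' [dominant_approximation()] against [effective_mixture_params()] for random
#' mixtures. Per receptor and trial, `nmix` component sensitivities are drawn
#' log-normal (`log kappa^-1 ~ N(0, sigma_kappa^2)`, natural log) and
#' efficacies log-normal (`log eta ~ N(0, 1)`), independently (no
#' antagonism). Concentrations are either equiproportionate or drawn
#' log-uniform over `decades` orders of magnitude.
#'
#' @param nmix_values Integer vector of mixture sizes.
#' @param n_receptors Number of receptor types per trial (default 250).
#' @param sigma_kappa Standard deviation of `log kappa^-1` in natural-log
#'   units (default 4, about six decades between the most and least
#'   sensitive receptors).
#' @param conc_mode `"equiproportionate"` or `"loguniform"`.
#' @param decades Width of the log-uniform concentration distribution
#'   (default 6).
#' @param trials Monte-Carlo repetitions per mixture size.
#' @param seed Integer seed.
#' @return A data frame in long format with one row per (nmix, trial):
#'   per-trial means over receptors of the relative errors `err_kappa`
#'   and `err_eta`, plus per-trial medians.
#' @export
approximation_error_experiment <- function(nmix_values, n_receptors = 250,
                                           sigma_kappa = 4,
                                           conc_mode = c("equiproportionate",
                                                         "loguniform"),
                                           decades = 6, trials = 100,
                                           seed = 1) {
  conc_mode <- match.arg(conc_mode)
  set.seed(seed)
  res <- vector("list", length(nmix_values) * trials)
  row <- 0L
  for (K in nmix_values) {
    for (tr in seq_len(trials)) {
      kinv <- matrix(exp(rnorm(n_receptors * K, 0, sigma_kappa)),
                     n_receptors, K)
      eta <- matrix(exp(rnorm(n_receptors * K, 0, 1)), n_receptors, K)
      beta <- if (conc_mode == "equiproportionate") {
        rep(1 / K, K)
      } else {
        c0 <- 10^runif(K, 0, decades)
        c0 / sum(c0)
      }
      bw <- sweep(kinv, 2L, beta, `*`)          # beta_i * kappa_i^-1
      exact_kinv <- rowSums(bw)
      exact_eta <- rowSums(eta * bw) / exact_kinv
      M <- max.col(bw, ties.method = "first")
      idx <- cbind(seq_len(n_receptors), M)
      appr_kinv <- bw[idx]
      appr_eta <- eta[idx]
      ek <- abs(appr_kinv - exact_kinv) / exact_kinv
      ee <- abs(appr_eta - exact_eta) / exact_eta
      row <- row + 1L
      res[[row]] <- data.frame(nmix = K, trial = tr,
                               err_kappa = mean(ek), err_eta = mean(ee),
                               err_kappa_median = stats::median(ek),
                               err_eta_median = stats::median(ee))
    }
  }
  do.call(rbind, res)
}

#' Read and write steady-state profile tables
#'
#' Profiles are exchanged as plain CSV with columns `odorant_id`,
#' `receptor_id`, `kappa`, `eta`; extra columns (e.g. masking parameters
#' `KM`, `mu`, `m`) are passed through untouched.
#'
#' @param df Data frame with at least the four required columns.
#' @param path File path.
#' @return `read_profiles()` returns the validated data frame;
#'   `write_profiles()` returns `path` invisibly.
#' @export
write_profiles <- function(df, path) {
  req <- c("odorant_id", "receptor_id", "kappa", "eta")
  if (!all(req %in% names(df)))
    stop("profile table needs columns: ", paste(req, collapse = ", "))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_profiles
#' @export
read_profiles <- function(path) {
  df <- utils::read.csv(path)
  req <- c("odorant_id", "receptor_id", "kappa", "eta")
  if (!all(req %in% names(df)))
    stop("profile table needs columns: ", paste(req, collapse = ", "))
  if (any(df$kappa <= 0) || any(df$eta <= 0))
    stop("kappa and eta must be positive")
  df
}
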