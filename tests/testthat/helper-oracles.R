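# Independent oracles used by the test suite. These re-derive expected
# values from the underlying formulas with deliberately different code
# paths than the package internals (scalar loops, explicit sums), so that
# agreement is informative.

# Single-odorant dose-response, written directly from the Hill form.
oracle_rate <- function(C, kappa, eta, n = 4, fmax = 1) {
  if (C == 0) return(0)
  if (is.infinite(C)) return(fmax / (1 + eta^-n))
  x <- C / kappa
  fmax / (1 + ((1 + x) / (eta * x))^n)
}

# Two-component competitive mixture response, explicit binary form.
oracle_binary_mixture_rate <- function(cA, cB, kA, kB, eA, eB, n = 4,
                                       fmax = 1) {
  num <- 1 + cA / kA + cB / kB
  den <- eA * cA / kA + eB * cB / kB
  fmax / (1 + (num / den)^n)
}

# Effective mixture parameters by explicit scalar summation.
oracle_mixture_params <- function(kappa, eta, conc) {
  C <- sum(conc)
  beta <- conc / C
  kinv <- 0
  s <- 0
  for (i in seq_along(kappa)) {
    kinv <- kinv + beta[i] / kappa[i]
    s <- s + eta[i] * beta[i] / kappa[i]
  }
  list(kappa = 1 / kinv, eta = s / kinv)
}

# Brute-force saturating conditional suppression fractions for a pair of
# odorants at equal concentrations, by direct per-receptor simulation.
oracle_suppression <- function(rho, p, sigma = 4, n = 4, draws = 200000,
                               seed = 1) {
  set.seed(seed)
  eta_star <- exp(qnorm(1 - p))
  uA <- rnorm(draws); uB <- rnorm(draws)
  eA <- exp(uA); eB <- exp(uB)
  kA <- exp(sigma * (rho * uA + sqrt(1 - rho^2) * rnorm(draws)))
  kB <- exp(sigma * (rho * uB + sqrt(1 - rho^2) * rnorm(draws)))
  emix <- (eA * kA + eB * kB) / (kA + kB)
  condA <- (eA > eta_star) & !(eB > eta_star)
  condB <- (eB > eta_star) & !(eA > eta_star)
  list(suppressed_A = mean(emix[condA] <= eta_star),
       suppressed_B = mean(emix[condB] <= eta_star))
}

# Exact per-receptor activation probabilities for the small enumerable
# figure-ground fixture: backgrounds are unordered draws (without
# replacement) from a fixed pool, and every combination is enumerated.
oracle_pool_probs <- function(target, pool, support) {
  cfg <- pool$config
  eta_star <- cfg$eta_star
  N <- cfg$n_receptors
  kP <- exp(pool$log_kappa_inv); eP <- exp(pool$log_eta)
  kT <- exp(target$log_kappa_inv[, 1]); eT <- exp(target$log_eta[, 1])
  npool <- ncol(kP)
  eps <- 1e-12
  q1 <- matrix(NA_real_, N, length(support))
  q0 <- numeric(length(support))
  for (j in seq_along(support)) {
    nb <- support[j]
    combos <- if (nb == 0) list(integer(0)) else
      asplit(utils::combn(npool, nb), 2)
    a1 <- matrix(0, N, length(combos)); a0 <- a1
    for (ci in seq_along(combos)) {
      idx <- combos[[ci]]
      Sb <- if (nb == 0) rep(0, N) else rowSums(kP[, idx, drop = FALSE])
      Se <- if (nb == 0) rep(0, N) else
        rowSums((eP * kP)[, idx, drop = FALSE])
      a1[, ci] <- (eT * kT + Se) / (kT + Sb) > eta_star
      a0[, ci] <- if (nb == 0) 0 else (Se / Sb) > eta_star
    }
    q1[, j] <- rowMeans(a1)
    q0[j] <- mean(a0)
  }
  list(q1 = pmin(pmax(q1, eps), 1 - eps),
       q0 = pmin(pmax(q0, eps), 1 - eps),
       support = support, pmf = rep(1 / length(support), length(support)))
}

# Column-subset of an odorant panel (test-local copy of an internal
# convenience).
panel_subset_for_test <- function(panel, idx) {
  structure(list(log_kappa_inv = panel$log_kappa_inv[, idx, drop = FALSE],
                 log_eta = panel$log_eta[, idx, drop = FALSE],
                 config = panel$config),
            class = "odorant_panel")
}

# Concentration ratio at which the weak component's probability of
# presence crosses the 0.5 detection threshold, by log-linear
# interpolation of the overshadowing curve.
overshadow_threshold <- function(curve) {
  lr <- log10(curve$ratio)
  p <- curve$p_B
  below <- which(p < 0.5)
  if (length(below) == 0) return(Inf)
  j <- below[1]
  if (j == 1) return(curve$ratio[1])
  10^stats::approx(p[c(j - 1, j)], lr[c(j - 1, j)], xout = 0.5)$y
}
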