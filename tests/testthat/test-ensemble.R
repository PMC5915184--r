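test_that("the activation threshold reproduces the target sparsity", {
  # tau construction: P(y > tau) = p for a saturating single odorant
  for (p in c(0.1, 0.3, 0.5)) {
    cfg <- ensemble_config(n_receptors = 100000, p = p, rho = 0)
    pan <- sample_odorants(cfg, 1, seed = 17)
    resp <- saturating_response(pan)
    se <- sqrt(p * (1 - p) / cfg$n_receptors)
    expect_lt(abs(mean(resp$z) - p), 2 * se)
    # strict-threshold definition
    expect_identical(resp$z, resp$y > cfg$tau)
  }
  # same construction for exponential efficacies
  cfge <- ensemble_config(n_receptors = 100000, p = 0.3, rho = 0,
                          efficacy = "exponential")
  pane <- sample_odorants(cfge, 1, seed = 19)
  expect_lt(abs(mean(saturating_response(pane)$z) - 0.3),
            2 * sqrt(0.3 * 0.7 / 1e5))
})

test_that("odorant sampling has the configured marginals and correlation", {
  cfg <- ensemble_config(n_receptors = 250, sigma_kappa = 4, rho = 0)
  pan <- sample_odorants(cfg, 400, seed = 23)
  lk <- as.numeric(pan$log_kappa_inv); le <- as.numeric(pan$log_eta)
  expect_lt(abs(sd(lk) - 4) / 4, 0.05)
  expect_lt(abs(sd(le) - 1), 0.05)
  expect_lt(abs(cor(lk, le)), 0.02)
  # rho = 1 is the deterministic coupling log kappa^-1 = sigma * log eta
  cfg1 <- ensemble_config(rho = 1)
  pan1 <- sample_odorants(cfg1, 3, seed = 29)
  expect_equal(pan1$log_kappa_inv, 4 * pan1$log_eta)
  expect_equal(cor(as.numeric(pan1$log_kappa_inv),
                   as.numeric(pan1$log_eta)), 1)
  # intermediate rho reproduces the Pearson correlation
  cfg5 <- ensemble_config(rho = 0.5)
  pan5 <- sample_odorants(cfg5, 400, seed = 31)
  expect_lt(abs(cor(as.numeric(pan5$log_kappa_inv),
                    as.numeric(pan5$log_eta)) - 0.5), 0.02)
})

test_that("self-mixtures and unit efficacies give the expected responses", {
  cfg <- ensemble_config(p = 0.3)
  pan <- sample_odorants(cfg, 1, seed = 37)
  both <- structure(list(
    log_kappa_inv = cbind(pan$log_kappa_inv, pan$log_kappa_inv),
    log_eta = cbind(pan$log_eta, pan$log_eta),
    config = cfg), class = "odorant_panel")
  expect_equal(saturating_response(both)$y, saturating_response(pan)$y)
  # eta_mix = 1, n = 4 gives y = 0.5
  one <- structure(list(log_kappa_inv = matrix(0, 5, 1),
                        log_eta = matrix(0, 5, 1), config = cfg),
                   class = "odorant_panel")
  expect_equal(saturating_response(one)$y, rep(0.5, 5))
})

test_that("the exact active fraction sits slightly below the OR-gate
           closed form at rho = 1", {
  # The OR formula 1 - (1-p)^K is exact for the dominant-component
  # encoding; the exact mixture algebra smooths eta_mix and lands a few
  # percent below it (measured bias up to ~0.07 at p = 0.1).
  cfg <- ensemble_config(p = 0.1, rho = 1)
  fa <- fraction_active_vs_complexity(cfg, c(5, 10, 20), trials = 12,
                                      seed = 41)
  or_gate <- 1 - (1 - 0.1)^c(5, 10, 20)
  expect_true(all(fa$fraction_active < or_gate))
  expect_true(all(or_gate - fa$fraction_active < 0.12))
})

test_that("normalization: the active fraction is flat in mixture size at
           rho = 0 and rises with rho", {
  cfg <- ensemble_config(p = 0.3, rho = 0)
  fa <- fraction_active_vs_complexity(cfg, c(1, 100), trials = 12, seed = 43)
  expect_lt(abs(fa$fraction_active[fa$nmix == 100] -
                  fa$fraction_active[fa$nmix == 1]), 0.1)
  # monotone in rho at fixed nmix = 50
  fr <- fraction_active_vs_complexity(cfg, 50,
                                      rho_values = c(0, 0.1, 0.2, 0.5, 1),
                                      trials = 8, seed = 47)
  expect_true(all(diff(fr$fraction_active) >= -2 * 0.012))
  expect_gt(fr$fraction_active[fr$rho == 1] -
              fr$fraction_active[fr$rho == 0], 0.4)
})

test_that("eta_mix distributions: invariant at rho = 0, biased upward at
           rho = 1", {
  cfg0 <- ensemble_config(p = 0.3, rho = 0)
  d <- eta_mix_distribution(cfg0, c(1, 100), samples = 10000, seed = 53)
  # single-component distribution is the plain efficacy distribution
  ks1 <- suppressWarnings(stats::ks.test(d$eta_mix[d$nmix == 1],
                                         function(q) stats::plnorm(q)))
  expect_gt(ks1$p.value, 0.01)
  # exact mixing smooths the distribution: KS ~ 0.2 at nmix = 100 ...
  ks_exact <- suppressWarnings(
    stats::ks.test(d$eta_mix[d$nmix == 1], d$eta_mix[d$nmix == 100]))
  expect_lt(unname(ks_exact$statistic), 0.3)
  # ... while the dominant-component encoding is strictly invariant
  dd <- eta_mix_distribution(cfg0, c(1, 100), samples = 10000, seed = 53,
                             method = "dominant")
  ks_dom <- suppressWarnings(
    stats::ks.test(dd$eta_mix[dd$nmix == 1], dd$eta_mix[dd$nmix == 100]))
  expect_lt(unname(ks_dom$statistic), 0.08)
  # rho = 1: median eta_mix strictly increases with mixture size
  cfg1 <- ensemble_config(p = 0.3, rho = 1)
  d1 <- eta_mix_distribution(cfg1, c(1, 10, 100), samples = 5000, seed = 59)
  med <- tapply(d1$eta_mix, d1$nmix, stats::median)
  expect_true(all(diff(med[order(as.numeric(names(med)))]) > 0))
})
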