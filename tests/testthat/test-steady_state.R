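test_that("single-odorant dose-response matches hand-computed values", {
  # C = kappa, eta = 1, n = 4: F = 1 / (1 + 2^4) = 1/17
  expect_equal(single_odorant_rate(1, kappa = 1, eta = 1), 1 / 17)
  # no stimulus, no response
  expect_identical(single_odorant_rate(0, kappa = 3, eta = 2), 0)
  # saturating limit Fmax / (1 + eta^-n)
  expect_equal(single_odorant_rate(Inf, kappa = 1, eta = 1), 0.5)
  expect_equal(single_odorant_rate(Inf, kappa = 7, eta = 3, n = 4, fmax = 2),
               2 / (1 + 3^-4))
  # random spot-checks against the independent scalar oracle
  set.seed(42)
  for (i in 1:20) {
    C <- 10^runif(1, -3, 3); k <- 10^runif(1, -2, 2); e <- 10^runif(1, -1, 1)
    expect_equal(single_odorant_rate(C, kappa = k, eta = e),
                 oracle_rate(C, k, e))
  }
})

test_that("effective mixture parameters obey the closed-form algebra", {
  # a single component is returned unchanged
  m1 <- mixture_spec(kappa = 2, eta = 3, conc = 5)
  p1 <- effective_mixture_params(m1)
  expect_equal(p1$kappa, 2)
  expect_equal(p1$eta, 3)
  # equal kappa, equal fractions: eta_mix is the plain mean
  m2 <- mixture_spec(kappa = c(1, 1), eta = c(1, 5), conc = c(2, 2))
  expect_equal(effective_mixture_params(m2)$eta, 3)
  # beta = (1, 0) reduces to component 1 (zero-concentration drop)
  m3 <- mixture_spec(kappa = c(2, 9), eta = c(3, 7), conc = c(1, 0))
  expect_equal(effective_mixture_params(m3)$kappa, 2)
  expect_equal(effective_mixture_params(m3)$eta, 3)
  # empty mixture errors
  expect_error(effective_mixture_params(
    mixture_spec(kappa = 1, eta = 1, conc = 0)), "empty")
  # random mixtures against the scalar-summation oracle
  set.seed(7)
  for (i in 1:20) {
    K <- sample(2:6, 1)
    k <- 10^runif(K, -2, 2); e <- 10^runif(K, -1, 1); cc <- runif(K)
    got <- effective_mixture_params(mixture_spec(k, e, cc))
    want <- oracle_mixture_params(k, e, cc)
    expect_equal(got$kappa, want$kappa)
    expect_equal(got$eta, want$eta)
  }
})

test_that("mixture response reduces to the binary closed form and is
           invariant to self-mixing and duplicate merging", {
  set.seed(11)
  for (i in 1:20) {
    kA <- 10^runif(1, -1, 1); kB <- 10^runif(1, -1, 1)
    eA <- 10^runif(1, -1, 1); eB <- 10^runif(1, -1, 1)
    cA <- 10^runif(1, -1, 2); cB <- 10^runif(1, -1, 2)
    expect_equal(mixture_rate(mixture_spec(c(kA, kB), c(eA, eB), c(cA, cB))),
                 oracle_binary_mixture_rate(cA, cB, kA, kB, eA, eB))
  }
  # a component mixed with itself at C/2 + C/2 equals the single odorant at C
  expect_equal(mixture_rate(mixture_spec(c(2, 2), c(3, 3), c(5, 5))),
               single_odorant_rate(10, kappa = 2, eta = 3))
  # merging duplicate components leaves the effective parameters unchanged
  m_dup <- mixture_spec(kappa = c(1, 4, 4), eta = c(2, 5, 5),
                        conc = c(1, 2, 3))
  m_merged <- mixture_spec(kappa = c(1, 4), eta = c(2, 5), conc = c(1, 5))
  expect_equal(effective_mixture_params(m_dup)$kappa,
               effective_mixture_params(m_merged)$kappa)
  expect_equal(effective_mixture_params(m_dup)$eta,
               effective_mixture_params(m_merged)$eta)
})

test_that("competitive mixtures stay within the component response envelope", {
  set.seed(5)
  for (i in 1:1000) {
    kA <- 10^runif(1, -2, 2); kB <- 10^runif(1, -2, 2)
    eA <- 10^runif(1, -1, 1); eB <- 10^runif(1, -1, 1)
    C <- 10^runif(1, -2, 3)
    w <- runif(1)
    fm <- mixture_rate(mixture_spec(c(kA, kB), c(eA, eB),
                                    C * c(w, 1 - w)))
    fA <- single_odorant_rate(C, kappa = kA, eta = eA)
    fB <- single_odorant_rate(C, kappa = kB, eta = eB)
    expect_gte(fm, min(fA, fB) - 1e-12)
    expect_lte(fm, max(fA, fB) + 1e-12)
  }
})

test_that("mixture response is monotone in the strongest component's
           concentration", {
  set.seed(13)
  for (i in 1:50) {
    k <- 10^runif(3, -1, 1); e <- sort(10^runif(3, -1, 1))
    cc <- 10^runif(3, -1, 1)
    grid <- cc[3] * 10^seq(0, 2, by = 0.25)
    f <- vapply(grid, function(c3)
      mixture_rate(mixture_spec(k, e, c(cc[1], cc[2], c3))), 0)
    expect_true(all(diff(f) >= -1e-12))
  }
})

test_that("dominant-component approximation is exact for K = 1 and for an
           overwhelming component, with lowest-index tie-breaking", {
  m1 <- mixture_spec(kappa = 2, eta = 3, conc = 1)
  expect_equal(dominant_approximation(m1)$kappa,
               effective_mixture_params(m1)$kappa)
  # one component with beta * kappa^-1 1e6 times all others
  m2 <- mixture_spec(kappa = c(1e-6, 1, 2), eta = c(2, 3, 4),
                     conc = c(1, 1, 1))
  ex <- effective_mixture_params(m2); ap <- dominant_approximation(m2)
  expect_lt(abs(1 / ap$kappa - 1 / ex$kappa) * ex$kappa, 1e-4)
  expect_lt(abs(ap$eta - ex$eta) / ex$eta, 1e-4)
  # tie: equal beta * kappa^-1 picks the first component's eta
  m3 <- mixture_spec(kappa = c(1, 1), eta = c(9, 2), conc = c(1, 1))
  expect_equal(dominant_approximation(m3)$eta, 9)
})

test_that("approximation error is zero for K = 1, grows with mixture size,
           and shrinks for variable concentrations", {
  res <- approximation_error_experiment(c(1, 8, 64), n_receptors = 100,
                                        trials = 12, seed = 3)
  agg <- aggregate(cbind(err_kappa, err_eta) ~ nmix, res, mean)
  expect_equal(agg$err_kappa[1], 0)
  expect_equal(agg$err_eta[1], 0)
  expect_true(all(diff(agg$err_kappa) > 0))
  expect_true(all(diff(agg$err_eta) > 0))
  res_lu <- approximation_error_experiment(c(64), n_receptors = 100,
                                           conc_mode = "loguniform",
                                           trials = 12, seed = 3)
  expect_lt(mean(res_lu$err_kappa), agg$err_kappa[3])
  expect_lt(mean(res_lu$err_eta), agg$err_eta[3])
})
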