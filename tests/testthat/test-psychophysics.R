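test_that("recruitment tables order glomeruli by sensitivity and hold
           about p * N glomeruli", {
  cfg <- ensemble_config(p = 0.5)
  # hand-built two-receptor odorant: equal efficacy above threshold,
  # the more sensitive receptor must be recruited first
  pan <- structure(list(
    log_kappa_inv = matrix(c(2, -2), 2, 1),
    log_eta = matrix(c(1, 1), 2, 1), config = cfg),
    class = "odorant_panel")
  tab <- recruitment_table(pan)
  expect_equal(tab$glomerulus, c(1, 2))
  expect_lt(tab$c_recruit[1], tab$c_recruit[2])
  expect_true(all(diff(tab$c_recruit) >= 0))
  # expected table size ~ p * N over many draws
  sizes <- vapply(1:30, function(i)
    nrow(recruitment_table(sample_odorants(cfg, 1, seed = 200 + i))), 0)
  expect_lt(abs(mean(sizes) - 0.5 * 250) / (0.5 * 250), 0.1)
})

test_that("inference telescopes over contiguous prefixes and flags empty
           active sets", {
  cfg <- ensemble_config(p = 0.5)
  pan <- sample_odorants(cfg, 1, seed = 301)
  tab <- recruitment_table(pan)
  k <- min(10, nrow(tab))
  # contiguous prefix g_1..g_k: inferred log c = log c_k exactly
  active <- tab$glomerulus[1:k]
  expect_equal(infer_concentration(active, tab), log10(tab$c_recruit[k]))
  # empty active set: sentinel
  expect_identical(infer_concentration(integer(0), tab), -Inf)
  # glomeruli outside the table are ignored
  outside <- setdiff(seq_len(250), tab$glomerulus)[1:3]
  expect_equal(infer_concentration(c(active, outside), tab),
               log10(tab$c_recruit[k]))
})

test_that("single-odorant concentration inference is unbiased at
           recruitment resolution, with the expected Weber ratio scale", {
  cfg <- ensemble_config(p = 0.5)
  r <- mixture_intensity_experiment(cfg, "alone", trials = 30, seed = 5)
  mid <- r$true_log_c >= -2 & r$true_log_c <= 2
  bias <- mean(r$inferred_log_c[mid] - r$true_log_c[mid])
  # half a grid step of the 61-point/6-decade recruitment grid
  expect_lt(abs(bias), 0.1 / 2)
  # Weber ratio ~ log10(cmax/c1) / (p N): inferred resolution per
  # glomerulus, here 6 decades / 125 recruited glomeruli
  expect_lt(max(abs(r$inferred_log_c[mid] - r$true_log_c[mid])), 5 * 6 / 125)
})

test_that("a companion odorant inhibits at high concentration and can
           synergize near threshold; maskers depress inferred intensity
           monotonically and faster for larger mu", {
  cfg <- ensemble_config(p = 0.5, rho = 0)
  rb <- mixture_intensity_experiment(cfg, "binary", trials = 25, seed = 7)
  ra <- mixture_intensity_experiment(cfg, "alone", trials = 25, seed = 7)
  diffc <- rb$inferred_log_c - ra$inferred_log_c
  hi <- rb$true_log_c >= 1.5
  lo <- rb$true_log_c <= -1 & rb$true_log_c >= -2.5
  expect_lt(mean(diffc[hi]), -0.1)     # inhibition at high concentration
  expect_gt(max(diffc[lo]), 0)         # hyper-additive synergy near threshold
  # masking sweep: A fixed, masker concentration rising
  curves <- lapply(c(0.4, 0.7, 1), function(mu)
    mixture_intensity_experiment(cfg, "masking", mu_B = mu, trials = 25,
                                 seed = 7))
  for (cv in curves) {
    drop_total <- cv$inferred_log_c[1] - cv$inferred_log_c[nrow(cv)]
    expect_gt(drop_total, 1)
    # monotone decline above the near-total-suppression floor, where the
    # few surviving glomeruli make the trial average noisy
    j <- which(cv$inferred_log_c < 0)[1]
    if (is.na(j)) j <- nrow(cv)
    expect_true(all(diff(cv$inferred_log_c[1:j]) <= 0.05))
  }
  final <- vapply(curves, function(cv) cv$inferred_log_c[nrow(cv)], 0)
  expect_true(all(diff(final) < 0))    # larger mu suppresses further
})

test_that("reciprocal suppression: near-oracle symmetric halving at
           rho = 0, absent at rho = 1, asymmetric under masking", {
  s0 <- suppression_fraction(ensemble_config(p = 0.5, rho = 0),
                             trials = 60, seed = 2)
  s1 <- suppression_fraction(ensemble_config(p = 0.5, rho = 1),
                             trials = 60, seed = 2)
  orc <- oracle_suppression(rho = 0, p = 0.5, seed = 77)
  expect_lt(abs(s0$suppressed_A - orc$suppressed_A), 0.03)
  expect_lt(abs(s0$suppressed_B - orc$suppressed_B), 0.03)
  expect_lt(abs(s0$suppressed_A - s0$suppressed_B), 0.05)  # symmetry
  expect_lt(s1$suppressed_A, 0.05)
  expect_lt(s1$suppressed_B, 0.05)
  # relabeling invariance for statistically identical pure excitants:
  # same seed, swapped roles
  expect_lt(abs(s0$suppressed_A - s0$suppressed_B), 0.05)
  # B with masking propensity suppresses A far more than it is suppressed
  sm <- suppression_fraction(ensemble_config(p = 0.5, rho = 0),
                             masking_B = masking_profile(KM = 0.01, mu = 1),
                             trials = 60, seed = 2)
  expect_gt(sm$suppressed_A - sm$suppressed_B, 0.15)
})

test_that("suppression orderings persist across sparsity levels", {
  for (p in c(0.3, 0.7)) {
    s0 <- suppression_fraction(ensemble_config(p = p, rho = 0),
                               trials = 30, seed = 3)
    s1 <- suppression_fraction(ensemble_config(p = p, rho = 1),
                               trials = 30, seed = 3)
    expect_gt(s0$suppressed_A, s1$suppressed_A + 0.2)
  }
})

test_that("overshadowing: the weak component is lost at a smaller
           concentration ratio under antagonism", {
  o0 <- overshadowing_curve(ensemble_config(p = 0.5, rho = 0), trials = 10,
                            seed = 4)
  o1 <- overshadowing_curve(ensemble_config(p = 0.5, rho = 1), trials = 10,
                            seed = 4)
  # both detectable at ratio 1
  expect_gt(o0$p_B[1], 0.5)
  expect_gt(o1$p_B[1], 0.5)
  expect_gt(o0$p_A[1], 0.5)
  expect_lt(overshadow_threshold(o0), overshadow_threshold(o1))
})
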