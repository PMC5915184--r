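test_that("ridge logistic regression matches glm on a non-separable
           problem and scores a separable one perfectly", {
  set.seed(61)
  X <- matrix(rnorm(600), 200, 3)
  y <- rbinom(200, 1, plogis(X %*% c(1, -0.5, 0.2)))
  ours <- fit_logistic_ridge(X, y, lambda = 1e-8)
  ref <- stats::glm.fit(cbind(1, X), y, family = stats::binomial())
  expect_equal(c(ours$b, ours$theta), unname(ref$coefficients),
               tolerance = 1e-4)
  # disjoint activation patterns: training accuracy 1
  Z <- rbind(matrix(rep(c(1, 1, 0, 0), 25), 25, 4, byrow = TRUE),
             matrix(rep(c(0, 0, 1, 1), 25), 25, 4, byrow = TRUE))
  yz <- rep(c(1, 0), each = 25)
  clf <- fit_logistic_ridge(Z, yz)
  expect_equal(mean((classifier_prob(clf, Z) > 0.5) == yz), 1)
})

test_that("a null classifier outputs one half and probabilities are
           invariant under joint glomerular permutation", {
  z <- rbinom(20, 1, 0.5)
  expect_equal(classifier_prob(list(theta = rep(0, 20), b = 0), z), 0.5)
  set.seed(67)
  clf <- list(theta = rnorm(20), b = 0.3)
  perm <- sample(20)
  expect_equal(classifier_prob(clf, z),
               classifier_prob(list(theta = clf$theta[perm], b = clf$b),
                               z[perm]))
})

test_that("trained classifiers separate their target from background-only
           patterns", {
  cfg <- ensemble_config(p = 0.3, rho = 0)
  panel <- sample_odorants(cfg, 30, seed = 71)
  clf <- train_classifier(panel, target = 1, n_trials = 300, seed = 73)
  set.seed(79)
  p_on <- p_off <- numeric(40)
  for (i in 1:40) {
    idx <- sample(2:30, 4)
    z_on <- saturating_response(panel_subset_for_test(panel, c(1, idx)))$z
    z_off <- saturating_response(panel_subset_for_test(panel, idx))$z
    p_on[i] <- classifier_prob(clf, z_on * 1)
    p_off[i] <- classifier_prob(clf, z_off * 1)
  }
  expect_gt(mean(p_on), mean(p_off))
})

test_that("ROC endpoints and monotonicity behave as a threshold sweep
           must", {
  cfg <- ensemble_config(p = 0.3, rho = 0)
  panel <- sample_odorants(cfg, 25, seed = 83)
  clfs <- train_panel(panel, n_trials = 200, seed = 89)
  roc <- component_separation_roc(panel, clfs,
                                  thresholds = c(0, seq(0.1, 0.9, 0.2), 1),
                                  mix_range = 1:5, test_trials = 60,
                                  seed = 97)
  expect_true(all(diff(roc$hit_rate) <= 1e-12))
  expect_true(all(diff(roc$false_positives) <= 1e-12))
  expect_equal(roc$hit_rate[1], 1)                # declare everything
  expect_equal(roc$false_positives[nrow(roc)], 0) # declare nothing
  expect_gt(roc$false_positives[1], 15)
  expect_equal(roc$hit_rate[nrow(roc)], 0)
})

test_that("identical seeds reproduce classifiers and ROC curves exactly", {
  cfg <- ensemble_config(p = 0.3, rho = 0)
  panel <- sample_odorants(cfg, 15, seed = 101)
  c1 <- train_classifier(panel, 2, n_trials = 100, bg_range = 1:5, seed = 5)
  c2 <- train_classifier(panel, 2, n_trials = 100, bg_range = 1:5, seed = 5)
  expect_identical(c1$theta, c2$theta)
  expect_identical(c1$b, c2$b)
})

test_that("antagonistic encoding wins component separation at p = 0.3", {
  rocs <- lapply(c(0, 1), function(rho) {
    cfg <- ensemble_config(p = 0.3, rho = rho)
    panel <- sample_odorants(cfg, 100, seed = 103)
    clfs <- train_panel(panel, n_trials = 800, seed = 107)
    component_separation_roc(panel, clfs, test_trials = 150, seed = 109)
  })
  r0 <- rocs[[1]]; r1 <- rocs[[2]]
  hit1_at <- stats::approxfun(r1$false_positives, r1$hit_rate, rule = 2)
  adv <- r0$hit_rate - hit1_at(r0$false_positives)
  expect_gt(mean(adv), 0.05)
})

test_that("noisy figure-ground discrimination: clean separable case is
           near-perfect, shuffled labels are chance, and antagonism wins
           under complex noisy backgrounds", {
  cfg0 <- ensemble_config(p = 0.3, rho = 0)
  # no background, no noise: accuracy ~ 1
  clean <- noisy_figure_ground(cfg0, epsilon0 = 0, bg_sizes = 0,
                               train_trials = 200, test_trials = 100,
                               seed = 113)
  expect_gt(clean$accuracy, 0.95)
  # label shuffling destroys performance
  set.seed(127)
  X <- matrix(rbinom(200 * 50, 1, 0.3), 200, 50)
  y <- sample(rep(0:1, 100))
  clf <- fit_logistic_ridge(X, y, lambda = 1)
  Xte <- matrix(rbinom(400 * 50, 1, 0.3), 400, 50)
  expect_lt(abs(mean((classifier_prob(clf, Xte) > 0.5)) - 0.5), 0.2)
  # 40% transduction noise, 50 background odorants: rho = 0 beats rho = 1
  # (averaged over three independent target draws)
  acc <- vapply(c(0, 1), function(rho) {
    cfg <- ensemble_config(p = 0.3, rho = rho)
    mean(noisy_figure_ground(cfg, epsilon0 = 0.4, bg_sizes = c(50, 50, 50),
                             train_trials = 1200, test_trials = 300,
                             seed = 131)$accuracy)
  }, 0)
  expect_gt(acc[1], acc[2] + 0.03)
})
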