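## Linear readouts of the glomerular code. A classifier computes the
## probability of presence of its target odorant as
## sigmoid(theta . z + b). Training is ridge-penalized maximum-likelihood
## logistic regression by iteratively reweighted least squares (IRLS):
## deterministic, fixed iteration budget, convergence tolerance 1e-6 on the
## penalized deviance. The small ridge keeps the fit finite under the
## perfect separation that saturating binary codes routinely produce.

#' Ridge-penalized logistic regression (IRLS)
#'
#' @param X Design matrix (no intercept column; one is added internally).
#' @param y Binary response vector.
#' @param lambda Ridge penalty on the weights (the intercept is not
#'   penalized); default 1e-3.
#' @param max_iter Iteration budget (default 50).
#' @param tol Convergence tolerance on the penalized deviance
#'   (default 1e-6).
#' @return List with `theta` (weights), `b` (bias), `converged`,
#'   `iterations` and the final gradient norm `grad_norm`.
#' @export
fit_logistic_ridge <- function(X, y, lambda = 1e-3, max_iter = 50,
                               tol = 1e-6) {
  X <- as.matrix(X)
  stopifnot(nrow(X) == length(y), all(y %in% c(0, 1)))
  d <- ncol(X)
  Xa <- cbind(1, X)
  pen <- diag(c(0, rep(lambda, d)))
  beta <- numeric(d + 1L)
  dev_old <- Inf
  converged <- FALSE
  it <- 0L
  for (it in seq_len(max_iter)) {
    eta <- drop(Xa %*% beta)
    p <- stats::plogis(eta)
    w <- pmax(p * (1 - p), 1e-10)
    grad <- drop(crossprod(Xa, y - p)) - drop(pen %*% beta)
    H <- crossprod(Xa * w, Xa) + pen
    beta <- beta + solve(H, grad)
    eta <- drop(Xa %*% beta)
    dev <- -2 * sum(y * stats::plogis(eta, log.p = TRUE) +
                      (1 - y) * stats::plogis(-eta, log.p = TRUE)) +
      sum(pen %*% beta^2)
    if (abs(dev_old - dev) < tol * (abs(dev) + 1)) {
      converged <- TRUE
      break
    }
    dev_old <- dev
  }
  p <- stats::plogis(drop(Xa %*% beta))
  gn <- sqrt(sum((drop(crossprod(Xa, y - p)) - drop(pen %*% beta))^2))
  if (!converged)
    warning(sprintf("IRLS did not converge; final gradient norm %.3g", gn))
  list(theta = beta[-1L], b = beta[1L], converged = converged,
       iterations = it, grad_norm = gn)
}

#' Classifier output probability
#'
#' @param clf A classifier (list with `theta`, `b`).
#' @param Z Pattern matrix (rows = trials) or a single pattern vector.
#' @return Probability of presence per row.
#' @export
classifier_prob <- function(clf, Z) {
  if (is.null(dim(Z))) Z <- matrix(Z, nrow = 1L)
  stats::plogis(drop(Z %*% clf$theta) + clf$b)
}

# Saturating equiproportionate z-pattern for a mixture given by column
# indices into a panel.
panel_pattern <- function(panel, idx, method = "exact") {
  saturating_response(panel_subset(panel, idx), method = method)$z * 1
}

# Build a balanced training/test set of patterns for target detection:
# half the trials contain the target plus nb backgrounds (nb uniform on
# bg_range, backgrounds drawn from the panel excluding the target), half
# contain backgrounds only.
detection_trials <- function(panel, target, n_trials, bg_range = 1:10) {
  S <- ncol(panel$log_eta)
  N <- nrow(panel$log_eta)
  pool <- setdiff(seq_len(S), target)
  y <- rep(c(1, 0), length.out = n_trials)
  Z <- matrix(0, n_trials, N)
  for (i in seq_len(n_trials)) {
    nb <- if (length(bg_range) == 1L) bg_range else
      sample(bg_range, 1L)
    idx <- sample(pool, nb)
    if (y[i] == 1) idx <- c(target, idx)
    Z[i, ] <- panel_pattern(panel, idx)
  }
  list(Z = Z, y = y)
}

#' Train a target-detection classifier
#'
#' Trains one ridge-logistic classifier to report the presence of a target
#' odorant from the binary glomerular pattern, against backgrounds of
#' `bg_range` other odorants from the same panel (balanced
#' present/absent trials, saturating equiproportionate mixtures).
#'
#' @param panel An odorant panel ([sample_odorants()]), the known set `S`.
#' @param target Column index of the target in the panel.
#' @param n_trials Number of training trials (default 400).
#' @param bg_range Background sizes sampled uniformly (default `1:10`).
#' @param lambda Ridge penalty (default 1e-3).
#' @param seed Integer seed.
#' @return The fitted classifier (list with `theta`, `b`, ...).
#' @export
train_classifier <- function(panel, target, n_trials = 400, bg_range = 1:10,
                             lambda = 1e-3, seed = 1) {
  set.seed(substream_seed(seed, target))
  tr <- detection_trials(panel, target, n_trials, bg_range)
  fit_logistic_ridge(tr$Z, tr$y, lambda = lambda)
}

#' Train classifiers for a whole panel
#'
#' @inheritParams train_classifier
#' @param targets Which panel columns to train (default all).
#' @return List of classifiers, one per target.
#' @export
train_panel <- function(panel, targets = seq_len(ncol(panel$log_eta)),
                        n_trials = 400, bg_range = 1:10, lambda = 1e-3,
                        seed = 1) {
  lapply(targets, function(tg)
    train_classifier(panel, tg, n_trials, bg_range, lambda, seed))
}

#' Generalized ROC for component separation
#'
#' Test mixtures of `mix_range` odorants are drawn from the panel; every
#' panel classifier is applied to each mixture pattern and an odorant is
#' declared present when its classifier probability exceeds a shared
#' detection threshold. Sweeping the threshold yields hit rate (fraction
#' of true components declared) versus the mean number of false positives.
#'
#' @param panel The odorant panel.
#' @param classifiers Output of [train_panel()].
#' @param thresholds Detection-threshold grid (default
#'   `seq(0.02, 0.98, by = 0.04)`).
#' @param mix_range Test mixture sizes, uniformly sampled (default `1:20`).
#' @param test_trials Number of test mixtures (default 200).
#' @param seed Integer seed.
#' @return Data frame with columns `threshold`, `hit_rate`,
#'   `false_positives` (mean count per mixture).
#' @export
component_separation_roc <- function(panel, classifiers,
                                     thresholds = seq(0.02, 0.98, by = 0.04),
                                     mix_range = 1:20, test_trials = 200,
                                     seed = 1) {
  S <- length(classifiers)
  set.seed(substream_seed(seed, 104729))
  Theta <- t(vapply(classifiers, function(c_) c(c_$b, c_$theta),
                    numeric(length(classifiers[[1L]]$theta) + 1L)))
  hits <- fps <- matrix(0, test_trials, length(thresholds))
  n_true <- numeric(test_trials)
  for (i in seq_len(test_trials)) {
    k <- if (length(mix_range) == 1L) mix_range else sample(mix_range, 1L)
    idx <- sample(S, k)
    z <- panel_pattern(panel, idx)
    pr <- stats::plogis(drop(Theta %*% c(1, z)))
    for (j in seq_along(thresholds)) {
      dec <- pr > thresholds[j]
      hits[i, j] <- sum(dec[idx]) / k
      fps[i, j] <- sum(dec[-idx])
    }
    n_true[i] <- k
  }
  data.frame(threshold = thresholds, hit_rate = colMeans(hits),
             false_positives = colMeans(fps))
}

#' Noisy figure-ground discrimination accuracy
#'
#' A single linear classifier discriminates the presence of a fixed target
#' against `nb` background odorants at finite concentrations drawn
#' log-uniform over `conc_decades` orders of magnitude. Transduction noise
#' scales the per-receptor effective efficacy as
#' `eta_mix -> (1 + eps) * eta_mix`, with `eps ~ N(0, epsilon0^2)`
#' truncated below at -0.99.
#'
#' @param config An [ensemble_config()].
#' @param epsilon0 Noise level (standard deviation of `eps`; default 0).
#' @param bg_sizes Background sizes to evaluate.
#' @param train_trials,test_trials Balanced trials per background size.
#' @param conc_decades Width of the log-uniform concentration distribution
#'   (default 3).
#' @param conc_scale Center of the concentration distribution (default 1).
#' @param lambda Ridge penalty.
#' @param seed Integer seed.
#' @return Data frame with columns `nb` and `accuracy` (balanced test
#'   accuracy).
#' @export
noisy_figure_ground <- function(config, epsilon0 = 0, bg_sizes = c(4, 32),
                                train_trials = 400, test_trials = 200,
                                conc_decades = 3, conc_scale = 1,
                                lambda = 1e-3, seed = 1) {
  draw_set <- function(target, nb, n_trials) {
    y <- rep(c(1, 0), length.out = n_trials)
    Z <- matrix(0, n_trials, config$n_receptors)
    for (i in seq_len(n_trials)) {
      k <- nb + y[i]
      if (k == 0L) next
      bgp <- sample_odorants(config, nb)
      pan <- if (y[i] == 1) {
        structure(list(
          log_kappa_inv = cbind(target$log_kappa_inv, bgp$log_kappa_inv),
          log_eta = cbind(target$log_eta, bgp$log_eta),
          config = config), class = "odorant_panel")
      } else bgp
      conc <- conc_scale * 10^stats::runif(k, -conc_decades / 2,
                                           conc_decades / 2)
      eps <- pmax(stats::rnorm(config$n_receptors, 0, epsilon0), -0.99)
      Z[i, ] <- finite_response(pan, conc, chi = 1 + eps)$z * 1
    }
    list(Z = Z, y = y)
  }
  rows <- list()
  for (j in seq_along(bg_sizes)) {
    nb <- bg_sizes[j]
    set.seed(substream_seed(seed, 31 * nb + 7 * j))
    target <- sample_odorants(config, 1)
    tr <- draw_set(target, nb, train_trials)
    clf <- fit_logistic_ridge(tr$Z, tr$y, lambda = lambda)
    te <- draw_set(target, nb, test_trials)
    pred <- classifier_prob(clf, te$Z) > 0.5
    acc <- (mean(pred[te$y == 1]) + mean(!pred[te$y == 0])) / 2
    rows[[j]] <- data.frame(nb = nb, accuracy = acc)
  }
  do.call(rbind, rows)
}
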