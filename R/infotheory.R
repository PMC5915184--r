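## Figure-ground segregation: how much information the binarized glomerular
## pattern z carries about the presence (T = 1) or absence (T = 0) of a
## known target odorant delivered on top of nb unknown background odorants.
## Receptor types are statistically independent, so Pr(z | T, nb)
## factorizes into per-receptor activation probabilities q_i(T, nb) that
## are pre-computed by Monte Carlo; the conditional entropy H(T | z) is
## then estimated by sampling patterns and averaging the binary entropy of
## the Bayes posterior. I(T; z) = H(T) - H(T | z) with H(T) = 1 bit.

#' Background-complexity model
#'
#' Distribution of the number of background odorants `nb`. Either a point
#' mass (`fixed`) or a discrete truncated exponential on `support_min..
#' support_max` with pmf proportional to `exp(-nb / lambda)`, with `lambda`
#' solved numerically so the distribution mean equals `mean` (default 32,
#' truncated at 128).
#'
#' @param mean Target mean number of background odorants.
#' @param support_max Upper truncation (default 128).
#' @param support_min Lower end of the support (default 1).
#' @param fixed If given, a point mass at this value (other arguments
#'   ignored).
#' @return An object of class `"background_model"` with fields `support`
#'   and `pmf`.
#' @examples
#' bg <- background_model(mean = 32)
#' sum(bg$pmf * bg$support)  # 32
#' @export
background_model <- function(mean = 32, support_max = 128, support_min = 1,
                             fixed = NULL) {
  if (!is.null(fixed)) {
    stopifnot(fixed >= 0, fixed == round(fixed))
    return(structure(list(support = as.integer(fixed), pmf = 1,
                          mean = as.double(fixed), lambda = NA_real_),
                     class = "background_model"))
  }
  support <- support_min:support_max
  if (mean <= support_min || mean >= support_max)
    stop("`mean` must lie strictly inside the support")
  pmf_of <- function(lambda) {
    w <- exp(-(support - support_min) / lambda)
    w / sum(w)
  }
  f <- function(lambda) sum(pmf_of(lambda) * support) - mean
  lambda <- stats::uniroot(f, c(1e-3, 1e6), tol = 1e-12)$root
  structure(list(support = support, pmf = pmf_of(lambda), mean = mean,
                 lambda = lambda),
            class = "background_model")
}

#' Sample background sizes
#'
#' @param model A [background_model()].
#' @param n Number of draws.
#' @param seed Optional integer seed.
#' @return Integer vector of background sizes.
#' @export
sample_background_sizes <- function(model, n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (length(model$support) == 1L) return(rep(model$support, n))
  sample(model$support, n, replace = TRUE, prob = model$pmf)
}

#' Figure-ground segregation task
#'
#' Bundles a known target odorant, the receptor ensemble it lives in, and
#' the background-complexity model. The presence prior is fixed at 1/2, so
#' the prior entropy `H(T)` is exactly 1 bit.
#'
#' @param config An [ensemble_config()].
#' @param background A [background_model()].
#' @param target Optional fixed target (an `odorant_panel` with one
#'   column); freshly sampled from `config` when `NULL`.
#' @param q_draws Monte-Carlo background draws per background size used to
#'   estimate the per-receptor activation probabilities (default 800).
#' @param z_draws Monte-Carlo pattern samples for the conditional entropy
#'   (default 4000).
#' @param seed Integer seed used when sampling the target.
#' @return An object of class `"segregation_task"`.
#' @export
segregation_task <- function(config, background = background_model(),
                             target = NULL, q_draws = 800, z_draws = 4000,
                             seed = 1) {
  stopifnot(inherits(config, "ensemble_config"),
            inherits(background, "background_model"))
  if (is.null(target)) target <- sample_odorants(config, 1, seed = seed)
  structure(list(config = config, background = background, target = target,
                 prior = 0.5, q_draws = q_draws, z_draws = z_draws),
            class = "segregation_task")
}

#' Prior entropy of target presence
#'
#' @param task A [segregation_task()].
#' @return Entropy of the presence prior in bits (1 for the 50/50 prior).
#' @export
prior_entropy <- function(task) {
  binary_entropy(task$prior)
}

#' Per-receptor activation probabilities
#'
#' Estimates `q_i(T, nb) = Pr(z_i = 1 | T, nb)` for every background size
#' in the model's support: the probability that receptor `i` is active for
#' a saturating equiproportionate mixture of `nb` random background
#' odorants, plus the target when `T = 1`. Background draws are shared
#' across receptors through the sufficient background sums, which leaves
#' each estimate unbiased. Probabilities are clipped to
#' `[1e-12, 1 - 1e-12]`.
#'
#' @param task A [segregation_task()].
#' @param seed Integer seed.
#' @return List with `q1` (`N x` support matrix), `q0` (vector over the
#'   support; background-only activation is receptor-exchangeable),
#'   `support` and `pmf`.
#' @export
receptor_activation_prob <- function(task, seed = 1) {
  cfg <- task$config
  N <- cfg$n_receptors
  eta_star <- cfg$eta_star
  a <- exp(task$target$log_kappa_inv[, 1L])   # target sensitivities
  h <- exp(task$target$log_eta[, 1L])         # target efficacies
  support <- task$background$support
  S <- task$q_draws
  eps <- 1e-12
  q1 <- matrix(NA_real_, N, length(support))
  q0 <- numeric(length(support))
  for (j in seq_along(support)) {
    nb <- support[j]
    if (nb == 0L) {
      q0[j] <- eps
      q1[, j] <- ifelse(h > eta_star, 1 - eps, eps)
      next
    }
    set.seed(substream_seed(seed, nb))
    # Sufficient statistics of the background mixture for one receptor:
    # Sb = sum of sensitivities, Se = sum of efficacy-weighted sensitivities.
    u <- matrix(stats::rnorm(nb * S), nb, S)
    omega <- matrix(stats::rnorm(nb * S), nb, S)
    eta_b <- if (cfg$efficacy == "lognormal") exp(u) else
      stats::qexp(stats::pnorm(u))
    kinv_b <- exp(cfg$sigma_kappa *
                    (cfg$rho * u + sqrt(1 - cfg$rho^2) * omega))
    Sb <- colSums(kinv_b)
    Se <- colSums(eta_b * kinv_b)
    q0[j] <- mean(Se / Sb > eta_star)
    # eta_mix with target: (h_i a_i + Se) / (a_i + Sb), per receptor x draw
    act <- (outer(h * a, Se, `+`) / outer(a, Sb, `+`)) > eta_star
    q1[, j] <- rowMeans(act)
  }
  list(q1 = pmin(pmax(q1, eps), 1 - eps),
       q0 = pmin(pmax(q0, eps), 1 - eps),
       support = support, pmf = task$background$pmf)
}

# Log-likelihood log Pr(z | T) for a matrix of patterns Z (M x N), given
# per-receptor probability tables, marginalizing over the background size.
loglik_given_T <- function(Z, q, pmf, exchangeable = FALSE) {
  if (exchangeable) {
    # q is a vector over the support; only the active count matters.
    s <- rowSums(Z)
    N <- ncol(Z)
    ll <- outer(s, log(q)) + outer(N - s, log1p(-q))
  } else {
    ll <- Z %*% log(q) + (1 - Z) %*% log1p(-q)
  }
  row_logsumexp(sweep(ll, 2L, log(pmf), `+`))
}

#' Mutual information between target presence and the glomerular code
#'
#' Monte-Carlo estimate of `I(T; z) = H(T) - H(T | z)`. Patterns are
#' sampled from the factorized model defined by the activation-probability
#' tables; for each pattern the Bayes posterior `Pr(T = 1 | z)` is computed
#' with all sums in the log domain, and `H(T | z)` is the average binary
#' entropy of the posterior.
#'
#' @param task A [segregation_task()].
#' @param seed Integer seed.
#' @param probs Optional precomputed [receptor_activation_prob()] tables.
#' @return List of class `"mi_estimate"` with `mi` (bits), `se` (MC
#'   standard error), `h_prior` and the sample count.
#' @export
mutual_information <- function(task, seed = 1, probs = NULL) {
  if (is.null(probs)) probs <- receptor_activation_prob(task, seed = seed)
  M <- task$z_draws
  N <- task$config$n_receptors
  set.seed(substream_seed(seed, 999983))
  Tval <- stats::runif(M) < task$prior
  nb_idx <- if (length(probs$support) == 1L) rep(1L, M) else
    sample(seq_along(probs$support), M, replace = TRUE, prob = probs$pmf)
  P <- matrix(probs$q0[nb_idx], M, N)
  if (any(Tval))
    P[Tval, ] <- t(probs$q1[, nb_idx[Tval], drop = FALSE])
  Z <- (matrix(stats::runif(M * N), M, N) < P) * 1
  ll1 <- loglik_given_T(Z, probs$q1, probs$pmf)
  ll0 <- loglik_given_T(Z, probs$q0, probs$pmf, exchangeable = TRUE)
  post <- 1 / (1 + exp(ll0 - ll1))
  h <- binary_entropy(post)
  mi <- binary_entropy(task$prior) - mean(h)
  structure(list(mi = mi, se = stats::sd(h) / sqrt(M),
                 h_prior = binary_entropy(task$prior), n = M),
            class = "mi_estimate")
}

#' Exact mutual information by pattern enumeration
#'
#' For small ensembles (N <= 20), computes `I(T; z)` exactly from the
#' activation-probability tables by enumerating all `2^N` binary patterns.
#' Serves as the independent oracle for the Monte-Carlo estimator.
#'
#' @param q1 `N x` support matrix of activation probabilities given
#'   presence.
#' @param q0 Vector over the support, given absence.
#' @param pmf Background-size probabilities.
#' @param prior Presence prior (default 0.5).
#' @return Mutual information in bits.
#' @export
exact_mutual_information <- function(q1, q0, pmf, prior = 0.5) {
  N <- nrow(q1)
  if (N > 20) stop("exhaustive enumeration limited to N <= 20")
  Z <- as.matrix(expand.grid(rep(list(0:1), N)))[, N:1, drop = FALSE]
  ll1 <- loglik_given_T(Z, q1, pmf)
  ll0 <- loglik_given_T(Z, q0, pmf, exchangeable = TRUE)
  pz1 <- exp(ll1); pz0 <- exp(ll0)
  pz <- prior * pz1 + (1 - prior) * pz0
  post <- prior * pz1 / pz
  h_cond <- sum(pz * binary_entropy(post))
  binary_entropy(prior) - h_cond
}

#' Optimal antagonism factor
#'
#' Scans the antagonism factor `rho` for each sparsity `p` and reports the
#' mutual information of the figure-ground task under the fluctuating
#' background model, together with the maximizing `rho*` (ties broken
#' toward the smallest `rho`).
#'
#' @param p_values Sparsity levels to scan.
#' @param rho_grid Antagonism factors to scan (subset of `[0, 1]`).
#' @param config Template [ensemble_config()] (its `rho` and `p` are
#'   overridden).
#' @param background A [background_model()].
#' @param q_draws,z_draws Monte-Carlo sizes per MI evaluation.
#' @param seed Integer seed.
#' @return Data frame with columns `p`, `rho`, `mi`, `se`; the per-`p`
#'   optimum is attached as attribute `"rho_star"` (data frame `p`,
#'   `rho_star`).
#' @export
optimal_rho <- function(p_values, rho_grid = seq(0, 1, by = 0.25),
                        config = ensemble_config(),
                        background = background_model(),
                        q_draws = 600, z_draws = 3000, seed = 1) {
  if (any(rho_grid < 0 | rho_grid > 1)) stop("`rho_grid` must lie in [0, 1]")
  rows <- list(); r <- 0L
  for (p in p_values) {
    for (rho in rho_grid) {
      cfg <- ensemble_config(config$n_receptors, config$sigma_kappa, rho,
                             p, config$hill, config$efficacy)
      task <- segregation_task(cfg, background, q_draws = q_draws,
                               z_draws = z_draws,
                               seed = substream_seed(seed, round(1000 * p)))
      est <- mutual_information(task, seed = substream_seed(seed,
                                                            round(1e4 * rho + 100 * p)))
      r <- r + 1L
      rows[[r]] <- data.frame(p = p, rho = rho, mi = est$mi, se = est$se)
    }
  }
  out <- do.call(rbind, rows)
  stars <- do.call(rbind, lapply(split(out, out$p), function(d) {
    data.frame(p = d$p[1L], rho_star = d$rho[which.max(d$mi)])
  }))
  rownames(stars) <- NULL
  attr(out, "rho_star") <- stars
  out
}
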