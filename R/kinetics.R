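## Full ORN signal-transduction kinetics. State variables: per-odorant bound
## (B_i) and activated (A_i) receptor pools, intracellular cAMP (C),
## calcium (Ca) and the Ca-calmodulin complex (CaCaM) that feeds back on
## the CNG channels. The CNG open fraction is treated as quasi-steady
## (instantaneous Hill function of cAMP, the strong-cooperativity limit),
## and the Cl- current / firing-rate map is linear, so the firing rate is
## proportional to Ca relative to its fully-open-channel steady state.

#' Odorant-receptor kinetic constants
#'
#' Rate constants of the two-step binding/activation scheme
#' `R + X <-> RX <-> RX*` for one odorant-receptor pair.
#'
#' @param k1 Binding forward rate (1/(concentration * s)).
#' @param k_neg1 Unbinding rate (1/s).
#' @param k2 Activation forward rate (1/s).
#' @param k_neg2 Deactivation rate (1/s).
#' @return An object of class `"or_kinetics"`, carrying the derived
#'   equilibrium ratios `kappa1 = k_neg1/k1`, `kappa2 = k_neg2/k2`, the
#'   sensitivity scale `kappa = kappa1 * kappa2 / (1 + kappa2)` and the
#'   receptor-level efficiency factor `alpha_frac = 1 / (1 + kappa2)`
#'   (fraction of occupied receptors that are activated at equilibrium).
#' @examples
#' or_kinetics(k1 = 100, k_neg1 = 100, k2 = 2, k_neg2 = 2)
#' @export
or_kinetics <- function(k1, k_neg1, k2, k_neg2) {
  for (nm in c("k1", "k_neg1", "k2", "k_neg2"))
    stopifnot_scalar(get(nm), nm, positive = TRUE)
  kappa1 <- k_neg1 / k1
  kappa2 <- k_neg2 / k2
  structure(list(k1 = k1, k_neg1 = k_neg1, k2 = k2, k_neg2 = k_neg2,
                 kappa1 = kappa1, kappa2 = kappa2,
                 kappa = kappa1 * kappa2 / (1 + kappa2),
                 alpha_frac = 1 / (1 + kappa2)),
            class = "or_kinetics")
}

#' Steady-state profile implied by kinetic constants
#'
#' Maps the full rate constants of an odorant-receptor pair to the
#' `(kappa, eta)` pair of the peak-response algebra, given the transduction
#' parameters: `eta = kC * kG * Rtot / (dC * (1 + kappa2))`.
#'
#' @param kin An [or_kinetics()].
#' @param params A [transduction_params()].
#' @return An [ss_profile()].
#' @export
kinetics_to_profile <- function(kin, params) {
  eta <- params$kC * params$kG * params$Rtot * kin$alpha_frac / params$dC
  ss_profile(kappa = kin$kappa, eta = eta)
}

#' Transduction-cascade parameters
#'
#' Parameters of the pathway downstream of the receptors. Defaults are the
#' reference parameter set used throughout: `kC = 2/s` (cAMP production per
#' activated receptor), `dC = 1/s` (cAMP degradation), `kG = 10` (lumped CNG
#' half-activation constant, 1/cAMP-concentration), `n = 4` cAMP sites,
#' `kCa = 20/s` (Ca influx per open channel), `dCa = 0.5/s` (extrusion),
#' `kCaCaM = 1/s` (Ca-CaM formation) and `CaCaM0 = 0.05` (feedback
#' half-suppression scale). `kCaCaM_back` (first-order Ca-CaM dissociation,
#' default 0.05/s) sets the recovery-from-adaptation timescale of a few tens
#' of seconds. Receptor count, channel count and maximal firing rate are
#' rescaled to 1.
#'
#' @param kC,dC,kG,CNGtot,n,kCa,dCa,kCaCaM,kCaCaM_back,CaCaM0,Rtot,Fmax
#'   See description; all strictly positive, `n >= 1`.
#' @return An object of class `"transduction_params"`.
#' @export
transduction_params <- function(kC = 2, dC = 1, kG = 10, CNGtot = 1, n = 4,
                                kCa = 20, dCa = 0.5, kCaCaM = 1,
                                kCaCaM_back = 0.05, CaCaM0 = 0.05,
                                Rtot = 1, Fmax = 1) {
  vals <- list(kC = kC, dC = dC, kG = kG, CNGtot = CNGtot, n = n, kCa = kCa,
               dCa = dCa, kCaCaM = kCaCaM, kCaCaM_back = kCaCaM_back,
               CaCaM0 = CaCaM0, Rtot = Rtot, Fmax = Fmax)
  for (nm in setdiff(names(vals), "CaCaM0"))
    stopifnot_scalar(vals[[nm]], nm, positive = TRUE)
  if (!(is.numeric(CaCaM0) && length(CaCaM0) == 1L && CaCaM0 > 0))
    stop("`CaCaM0` must be positive (Inf disables feedback)")
  if (n < 1) stop("`n` must be >= 1")
  structure(vals, class = "transduction_params")
}

#' Square-pulse stimulus protocol
#'
#' @param odorant Integer/character id per event, indexing the kinetics set.
#' @param conc Concentration per event (>= 0, arbitrary units; assumed in
#'   excess of the receptors).
#' @param onset,offset Event start/end times in seconds (`offset > onset`).
#'   Events may overlap (mixtures).
#' @param duration Total simulated duration (s); defaults to the last
#'   offset plus one second.
#' @return An object of class `"stimulus_protocol"`.
#' @export
stimulus_protocol <- function(odorant, conc, onset, offset,
                              duration = NULL) {
  stopifnot(length(odorant) == length(conc),
            length(conc) == length(onset),
            length(onset) == length(offset))
  if (any(conc < 0)) stop("concentrations must be non-negative")
  if (any(offset <= onset)) stop("each event must have offset > onset")
  if (is.null(duration)) duration <- max(offset) + 1
  if (duration < max(offset)) stop("duration must cover all events")
  structure(list(events = data.frame(odorant = odorant, conc = conc,
                                     onset = onset, offset = offset),
                 duration = duration),
            class = "stimulus_protocol")
}

# Concentration of each odorant at time t (vector over the kinetics set).
protocol_conc <- function(protocol, ids, t) {
  ev <- protocol$events
  vapply(ids, function(id) {
    on <- ev$odorant == id & ev$onset <= t & t < ev$offset
    sum(ev$conc[on])
  }, 0)
}

#' Simulate the ORN transduction cascade
#'
#' Numerically integrates the full cascade for an arbitrary square-pulse
#' protocol of one or more odorants. Per odorant `i`:
#' `dB_i/dt = k1_i C_i R - (k_neg1_i + k2_i) B_i + k_neg2_i A_i`,
#' `dA_i/dt = k2_i B_i - k_neg2_i A_i`, with `R = Rtot - sum(B + A)`;
#' downstream `dC/dt = kC sum(A) - dC C`, the CNG open fraction is the
#' quasi-steady Hill form `1 / (1 + (kG_eff C)^-n)` with
#' `kG_eff = kG / (1 + (CaCaM/CaCaM0)^2)`,
#' `dCa/dt = kCa CNGtot open - dCa Ca`, and
#' `dCaCaM/dt = kCaCaM Ca - kCaCaM_back CaCaM`. The firing rate is the
#' linear readout `F = Fmax * Ca * dCa / (kCa * CNGtot)`, normalized so the
#' feedback-free steady state of a saturating stimulus is
#' `Fmax / (1 + eta^-n)`.
#'
#' Integration uses a stiff-capable solver (`deSolve::lsoda`), piecewise
#' over the stimulus discontinuities, with relative tolerance 1e-6 and
#' absolute tolerance 1e-9 on a fixed output grid.
#'
#' @param kinetics A single [or_kinetics()] or a list of them (one per
#'   odorant id used in the protocol, in order).
#' @param params A [transduction_params()].
#' @param protocol A [stimulus_protocol()].
#' @param dt Output grid step in seconds (default 0.001).
#' @return An object of class `"orn_response"`: a data frame with columns
#'   `time`, `F`, per-odorant `B_i`/`A_i`, `C`, `Ca`, `CaCaM`, plus the
#'   inputs as attributes.
#' @export
simulate_orn <- function(kinetics, params, protocol, dt = 0.001) {
  if (inherits(kinetics, "or_kinetics")) kinetics <- list(kinetics)
  stopifnot(length(kinetics) >= 1L, inherits(params, "transduction_params"),
            inherits(protocol, "stimulus_protocol"))
  if (!is.numeric(protocol$events$odorant) ||
      any(!protocol$events$odorant %in% seq_along(kinetics)))
    stop("protocol odorant ids must index the kinetics list (1..",
         length(kinetics), ")")
  ids <- seq_along(kinetics)   # odorant ids index the kinetics list
  K <- length(kinetics)
  k1 <- vapply(kinetics, `[[`, 0, "k1")
  kn1 <- vapply(kinetics, `[[`, 0, "k_neg1")
  k2 <- vapply(kinetics, `[[`, 0, "k2")
  kn2 <- vapply(kinetics, `[[`, 0, "k_neg2")

  deriv <- function(t, y, parms, conc) {
    B <- y[1:K]; A <- y[(K + 1):(2 * K)]
    Cc <- y[2 * K + 1]; Ca <- y[2 * K + 2]; CaCaM <- y[2 * K + 3]
    Rfree <- params$Rtot - sum(B) - sum(A)
    dB <- k1 * conc * Rfree - (kn1 + k2) * B + kn2 * A
    dA <- k2 * B - kn2 * A
    dC <- params$kC * sum(A) - params$dC * Cc
    kG_eff <- params$kG / (1 + (CaCaM / params$CaCaM0)^2)
    open <- if (Cc <= 0) 0 else 1 / (1 + (kG_eff * Cc)^-params$n)
    dCa <- params$kCa * params$CNGtot * open - params$dCa * Ca
    dCaCaM <- params$kCaCaM * Ca - params$kCaCaM_back * CaCaM
    list(c(dB, dA, dC, dCa, dCaCaM))
  }

  ev <- protocol$events
  breaks <- sort(unique(c(0, ev$onset, ev$offset, protocol$duration)))
  breaks <- breaks[breaks >= 0 & breaks <= protocol$duration]
  y <- c(rep(0, 2 * K), 0, 0, 0)
  out <- NULL
  for (s in seq_len(length(breaks) - 1L)) {
    t0 <- breaks[s]; t1 <- breaks[s + 1L]
    conc <- protocol_conc(protocol, ids, (t0 + t1) / 2)
    times <- unique(c(seq(t0, t1, by = dt), t1))
    seg <- deSolve::lsoda(y, times, deriv, parms = NULL, conc = conc,
                          rtol = 1e-6, atol = 1e-9)
    if (attr(seg, "istate")[1L] < 0)
      stop("ODE integration failed in segment starting at t = ", t0)
    y <- as.numeric(seg[nrow(seg), -1L])
    seg <- seg[if (s == 1L) TRUE else -1L, , drop = FALSE]
    out <- rbind(out, seg)
  }
  bad <- !is.finite(out[, -1L, drop = FALSE])
  if (any(bad)) {
    vars <- c(paste0("B_", 1:K), paste0("A_", 1:K), "C", "Ca", "CaCaM")
    stop("non-finite state variable: ", vars[which(colSums(bad) > 0)[1L]])
  }
  df <- as.data.frame(out)
  names(df) <- c("time", paste0("B_", 1:K), paste0("A_", 1:K),
                 "C", "Ca", "CaCaM")
  df$F <- params$Fmax * df$Ca * params$dCa / (params$kCa * params$CNGtot)
  df <- df[!duplicated(df$time), c("time", "F",
                                   setdiff(names(df), c("time", "F")))]
  rownames(df) <- NULL
  structure(df, class = c("orn_response", "data.frame"),
            params = params, protocol = protocol, kinetics = kinetics)
}

#' Peak and latency of a simulated response
#'
#' Latency is the first time after stimulus onset at which the firing rate
#' crosses `latency_fraction` of a reference level. With Ca-CaM feedback at
#' its reference strength the transient is truncated well below `Fmax`
#' (peaks reach only ~2% of `Fmax` even at saturating concentration), so the
#' default reference is the trial's own peak; `"fmax"` selects an absolute
#' criterion instead.
#'
#' @param ts An `"orn_response"` from [simulate_orn()].
#' @param latency_fraction Crossing level as a fraction of the reference
#'   (default 0.05).
#' @param latency_reference `"peak"` (default) or `"fmax"`.
#' @param onset Stimulus onset to measure latency from (default: first
#'   event onset of the protocol).
#' @return A list with `peak` (max rate) and `latency` (s; `NA` if the
#'   response never crosses the criterion).
#' @export
response_summary <- function(ts, latency_fraction = 0.05,
                             latency_reference = c("peak", "fmax"),
                             onset = NULL) {
  stopifnot(inherits(ts, "orn_response"))
  latency_reference <- match.arg(latency_reference)
  if (nrow(ts) == 0L) stop("empty time series")
  if (latency_fraction <= 0 || latency_fraction >= 1)
    stop("`latency_fraction` must lie in (0, 1)")
  params <- attr(ts, "params")
  if (is.null(onset)) onset <- min(attr(ts, "protocol")$events$onset)
  peak <- max(ts$F)
  ref <- if (latency_reference == "fmax") params$Fmax else peak
  lev <- latency_fraction * ref
  cross <- which(ts$time >= onset & ts$F >= lev & ts$F > 0)
  latency <- if (length(cross) == 0L || peak <= 0) NA_real_ else
    ts$time[cross[1L]] - onset
  list(peak = peak, latency = latency)
}

#' Adaptation and recovery with paired pulses
#'
#' Delivers two identical pulses separated by each interpulse interval and
#' reports the recovery fraction (second-pulse peak / first-pulse peak).
#' Ca-CaM feedback built up during the first pulse suppresses the second;
#' recovery follows the slow Ca-CaM dissociation over tens of seconds.
#'
#' @param kin An [or_kinetics()].
#' @param params A [transduction_params()].
#' @param intervals Interpulse intervals in seconds (offset of pulse 1 to
#'   onset of pulse 2).
#' @param pulse_duration Pulse duration in seconds (default 1).
#' @param conc Pulse concentration (default 1).
#' @param dt Output grid step (default 0.005; latency precision is not
#'   needed here).
#' @return Data frame with columns `interval` and `recovery`.
#' @details The second-pulse peak is baseline-corrected by subtracting the
#'   simulated single-pulse response, so the decaying tail of the first
#'   pulse cannot masquerade as recovery at short intervals.
#' @export
adaptation_protocol <- function(kin, params, intervals, pulse_duration = 1,
                                conc = 1, dt = 0.005) {
  if (any(intervals <= 0)) stop("intervals must be positive")
  rec <- vapply(intervals, function(gap) {
    t2 <- pulse_duration + gap
    dur <- t2 + pulse_duration + 2
    prot2 <- stimulus_protocol(odorant = c(1, 1), conc = c(conc, conc),
                               onset = c(0, t2),
                               offset = c(pulse_duration, t2 + pulse_duration),
                               duration = dur)
    prot1 <- stimulus_protocol(odorant = 1, conc = conc, onset = 0,
                               offset = pulse_duration, duration = dur)
    ts2 <- simulate_orn(kin, params, prot2, dt = dt)
    ts1 <- simulate_orn(kin, params, prot1, dt = dt)
    p1 <- max(ts1$F)
    win <- ts2$time >= t2
    base <- stats::approx(ts1$time, ts1$F, xout = ts2$time[win], rule = 2)$y
    p2 <- max(ts2$F[win] - base)
    p2 / p1
  }, 0)
  data.frame(interval = intervals, recovery = rec)
}
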