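#' Release probability as a function of calcium
#'
#' First-order saturating (Hill-1) dependence of release probability on
#' the normalized presynaptic calcium elevation above baseline:
#' `P(c) = p_max_vm * c / (c + k_half)`. At rest (c = 0) no release; at
#' `c = k_half` half the maximum; the maximum is approached asymptotically.
#'
#' @param c Normalized calcium elevation above baseline (>= 0); vectorized.
#' @param params A [synapse_params()] object.
#' @return Release probability in `[0, p_max_vm)`.
#' @export
release_probability <- function(c, params) {
  stopifnot(inherits(params, "synapse_params"))
  if (any(!is.finite(c)) || any(c < 0)) {
    stop("calcium must be finite and >= 0", call. = FALSE)
  }
  params$p_max_vm * c / (c + params$k_half)
}

#' Calcium-dependent recovery rate of release sites
#'
#' The rate at which depleted release sites are replenished rises from its
#' resting value `k_min` toward `k_min + delta_k` with a Hill-1 dependence
#' on residual calcium: `k(c) = k_min + delta_k * c / (c + k_r_half)`.
#' This calcium-dependent recovery (CDR) is what lets high-frequency
#' activity, which accumulates calcium, speed up replenishment.
#'
#' @inheritParams release_probability
#' @return Recovery rate in per-ms units, in `[k_min, k_min + delta_k)`.
#' @export
recovery_rate <- function(c, params) {
  stopifnot(inherits(params, "synapse_params"))
  if (any(!is.finite(c)) || any(c < 0)) {
    stop("calcium must be finite and >= 0", call. = FALSE)
  }
  params$k_min_per_ms + params$delta_k_per_ms * c / (c + params$k_r_half)
}

#' Model state
#'
#' @param c Calcium elevation above baseline, normalized units (>= 0).
#' @param r Available fraction of releasable sites, in `[0, 1]`.
#' @return An object of class `model_state`.
#' @export
model_state <- function(c = 0, r = 1) {
  stopifnot(is_scalar_num(c), is_scalar_num(r))
  if (c < 0) stop("c must be >= 0", call. = FALSE)
  if (r < 0 || r > 1) stop("r must be in [0, 1]", call. = FALSE)
  structure(list(c = c, r = r), class = "model_state")
}

#' Propagate the model state across a stimulus-free interval
#'
#' Between pulses the continuous dynamics are `dc/dt = -c / tau_Ca` and
#' `dR/dt = k(c) (1 - R)`. Because calcium decays exponentially, the
#' integral of the recovery rate along the trajectory has the closed form
#' `I_k = k_min T + delta_k tau_Ca log((c_in + K_r) / (c_out + K_r))`,
#' so the interval map is exact:
#' `c_out = c_in exp(-T / tau_Ca)`, `R_out = 1 - (1 - R_in) exp(-I_k)`.
#'
#' @param state A [model_state()].
#' @param interval_ms Interval length, ms (>= 0).
#' @param params A [synapse_params()] object.
#' @return The propagated [model_state()].
#' @export
propagate_interval <- function(state, interval_ms, params) {
  stopifnot(inherits(state, "model_state"), inherits(params, "synapse_params"))
  if (!is_scalar_num(interval_ms) || interval_ms < 0) {
    stop("interval must be a finite scalar >= 0", call. = FALSE)
  }
  c_out <- state$c * exp(-interval_ms / params$tau_ca_ms)
  i_k <- params$k_min_per_ms * interval_ms +
    params$delta_k_per_ms * params$tau_ca_ms *
      log((state$c + params$k_r_half) / (c_out + params$k_r_half))
  model_state(c = c_out, r = 1 - (1 - state$r) * exp(-i_k))
}

# Tight inner loop shared by simulate_train() and the inference objective:
# returns the per-pulse observable release probability p_n for pulse times
# `times` (ms), starting from state (c0, r0). No S3 dispatch, no checks.
sim_pn <- function(times, tau, pmax, K, kmin, dk, Kr, jump, c0 = 0, r0 = 1) {
  n <- length(times)
  p <- numeric(n)
  cc <- c0
  r <- r0
  for (i in seq_len(n)) {
    if (i > 1L) {
      dt <- times[i] - times[i - 1L]
      cnew <- cc * exp(-dt / tau)
      ik <- kmin * dt + dk * tau * log((cc + Kr) / (cnew + Kr))
      r <- 1 - (1 - r) * exp(-ik)
      cc <- cnew
    }
    cc <- cc + jump
    P <- pmax * cc / (cc + K)
    p[i] <- P * r
    r <- r * (1 - P)
  }
  p
}

#' Simulate a stimulus train through the depletion/recovery model
#'
#' Iterates the per-pulse map from a resting state. At each pulse, in
#' order: calcium jumps by `delta_jump`; the release probability
#' `P(c_post)` is evaluated; the observable release probability
#' `p_n = P(c_post) * R_pre` is recorded (this is what IPSC amplitude
#' divided by N*q estimates); the available fraction is depleted,
#' `R <- R * (1 - P(c_post))`; then calcium and the available fraction
#' relax toward rest until the next pulse via [propagate_interval()].
#'
#' @param protocol A [stimulus_protocol()].
#' @param params A [synapse_params()] object.
#' @param initial Initial [model_state()]; rest (`c = 0, r = 1`) by default.
#' @return An object of class `train_response`: a data.frame with columns
#'   `pulse_index`, `time_ms`, `c_pre`, `c_post`, `r_pre`, `p_n`, with the
#'   protocol and parameters attached as attributes.
#' @examples
#' simulate_train(train_protocol(20, n_pulses = 20), table1_params("SH"))
#' @export
simulate_train <- function(protocol, params, initial = model_state()) {
  stopifnot(inherits(protocol, "stimulus_protocol"),
            inherits(params, "synapse_params"),
            inherits(initial, "model_state"))
  times <- protocol$pulse_times
  n <- length(times)
  c_pre <- c_post <- r_pre <- p_n <- numeric(n)
  state <- initial
  for (i in seq_len(n)) {
    if (i > 1L) {
      state <- propagate_interval(state, times[i] - times[i - 1L], params)
    }
    c_pre[i] <- state$c
    cpost <- state$c + params$delta_jump
    c_post[i] <- cpost
    r_pre[i] <- state$r
    P <- release_probability(cpost, params)
    p_n[i] <- P * state$r
    state <- model_state(c = cpost, r = state$r * (1 - P))
  }
  out <- data.frame(
    pulse_index = seq_len(n), time_ms = times,
    c_pre = c_pre, c_post = c_post, r_pre = r_pre, p_n = p_n
  )
  attr(out, "protocol") <- protocol
  attr(out, "params") <- params
  class(out) <- c("train_response", "data.frame")
  out
}

#' Recovery from paired-pulse depression
#'
#' For each interpulse interval, simulates a two-pulse protocol from rest
#' and returns the paired-pulse ratio p2/p1. The curve rises toward 1 as
#' the interval grows and the synapse recovers fully.
#'
#' @param intervals_ms Positive interpulse intervals, ms.
#' @param params A [synapse_params()] object.
#' @return A data.frame with columns `interval_ms`, `p1`, `p2`, `ppr`.
#' @examples
#' simulate_recovery_curve(c(20, 50, 100, 500, 1000, 3000), table1_params("SH"))
#' @export
simulate_recovery_curve <- function(intervals_ms, params) {
  stopifnot(inherits(params, "synapse_params"),
            is.numeric(intervals_ms), all(intervals_ms > 0))
  res <- vapply(intervals_ms, function(T) {
    p <- sim_pn(c(0, T), params$tau_ca_ms, params$p_max_vm, params$k_half,
                params$k_min_per_ms, params$delta_k_per_ms, params$k_r_half,
                params$delta_jump)
    c(p[1L], p[2L])
  }, numeric(2L))
  data.frame(
    interval_ms = intervals_ms,
    p1 = res[1L, ], p2 = res[2L, ],
    ppr = res[2L, ] / res[1L, ]
  )
}

#' Steady-state response during sustained stimulation
#'
#' Iterates the per-pulse map at a fixed frequency until the observable
#' release probability stops changing (relative change < `tol`), returning
#' the fixed point. The post-jump steady-state calcium has the closed form
#' `delta_jump / (1 - exp(-T / tau_Ca))` (geometric summation), which the
#' iteration converges to; the available fraction has no closed form when
#' recovery is calcium-dependent.
#'
#' @param frequency_hz Stimulation frequency, Hz (> 0).
#' @param params A [synapse_params()] object.
#' @param tol Relative-change convergence tolerance on p_n.
#' @param max_iter Iteration cap; exceeding it is an error.
#' @return A list with `c_ss_post` (post-jump calcium), `r_ss_pre`
#'   (pre-pulse available fraction), `p_ss` (observable release
#'   probability) and `iterations`.
#' @export
steady_state_response <- function(frequency_hz, params, tol = 1e-6,
                                  max_iter = 10000L) {
  stopifnot(inherits(params, "synapse_params"),
            is_scalar_num(frequency_hz), frequency_hz > 0,
            is_scalar_num(tol), tol > 0)
  dt <- 1000 / frequency_hz
  tau <- params$tau_ca_ms; jump <- params$delta_jump
  pmax <- params$p_max_vm; K <- params$k_half
  kmin <- params$k_min_per_ms; dk <- params$delta_k_per_ms
  Kr <- params$k_r_half
  cc <- 0; r <- 1; p_prev <- Inf
  for (i in seq_len(max_iter)) {
    cc <- cc + jump
    P <- pmax * cc / (cc + K)
    p <- P * r
    r_pre <- r
    if (abs(p - p_prev) <= tol * max(p, .Machine$double.eps)) {
      return(list(c_ss_post = cc, r_ss_pre = r_pre, p_ss = p, iterations = i))
    }
    p_prev <- p
    r <- r * (1 - P)
    cnew <- cc * exp(-dt / tau)
    ik <- kmin * dt + dk * tau * log((cc + Kr) / (cnew + Kr))
    r <- 1 - (1 - r) * exp(-ik)
    cc <- cnew
  }
  stop(sprintf("steady state not reached within %d iterations", max_iter),
       call. = FALSE)
}

#' Write a simulated train response to CSV
#'
#' Columns: `pulse_index` (1-based), `time_ms`, `c_pre`, `c_post`,
#' `r_pre`, `p_n`.
#'
#' @param response A `train_response` from [simulate_train()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_train_response_csv <- function(response, path) {
  stopifnot(inherits(response, "train_response"))
  utils::write.csv(as.data.frame(response), path, row.names = FALSE)
  invisible(path)
}
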