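#' Quantal ground truth for the stochastic generator
#'
#' @param n_sites Number of independent release sites (integer >= 1).
#' @param q_pa Mean quantal amplitude, pA (> 0).
#' @param cv_intra Intrasite quantal coefficient of variation (>= 0).
#' @param noise_sd_pa Additive per-amplitude measurement noise SD, pA
#'   (>= 0). The default emulates modest recording noise that is small
#'   next to the quantal variance.
#' @param seed Default RNG seed carried with the object (overridable at
#'   generation time).
#' @return An object of class `quantal_ground_truth`.
#' @export
quantal_ground_truth <- function(n_sites, q_pa, cv_intra = 0.3,
                                 noise_sd_pa = 2, seed = NULL) {
  stopifnot(is_scalar_num(n_sites), n_sites >= 1,
            is_scalar_num(q_pa), q_pa > 0,
            is_scalar_num(cv_intra), cv_intra >= 0,
            is_scalar_num(noise_sd_pa), noise_sd_pa >= 0)
  structure(
    list(n_sites = as.integer(round(n_sites)), q_pa = q_pa,
         cv_intra = cv_intra, noise_sd_pa = noise_sd_pa, seed = seed),
    class = "quantal_ground_truth"
  )
}

# One stochastic amplitude per (repeat, pulse): Binomial(n_sites, p) sites
# release, each contributing a zero-truncated Normal(q, cv*q) quantum,
# plus additive Gaussian measurement noise. Uses the current RNG stream.
draw_amplitudes <- function(p, repeats, gt) {
  np <- length(p)
  prob <- rep(p, each = repeats)
  k <- stats::rbinom(np * repeats, gt$n_sites, prob)
  quanta <- vapply(k, function(ki) {
    if (ki == 0L) return(0)
    sum(pmax(0, stats::rnorm(ki, gt$q_pa, gt$cv_intra * gt$q_pa)))
  }, 0.0)
  amp <- quanta + stats::rnorm(np * repeats, 0, gt$noise_sd_pa)
  matrix(pmax(amp, 0), nrow = repeats, ncol = np)
}

#' Generate a stochastic amplitude table from the synapse model
#'
#' Runs the deterministic depletion/recovery model over the protocol to
#' obtain per-pulse release probabilities p_n, then draws, per repeat and
#' pulse, a binomial quantal amplitude: each of `n_sites` sites releases
#' independently with probability p_n, each released quantum has a
#' zero-truncated Normal(q, cv_intra * q) amplitude, and Gaussian
#' measurement noise is added. This is exactly the generative model under
#' which the variance-mean parabola holds.
#'
#' @param params A [synapse_params()] object (or `NULL` when `p_n` is
#'   supplied directly).
#' @param gt A [quantal_ground_truth()].
#' @param protocol A [stimulus_protocol()].
#' @param repeats Number of train repetitions.
#' @param seed RNG seed (defaults to the ground truth's seed).
#' @param p_n Optional per-pulse release probabilities overriding the
#'   model's, e.g. to impose a measured p_r profile.
#' @param cell_id Cell identifier stored in the table.
#' @return An [amplitude_table()] with the generating `p_n` attached as
#'   attribute `"p_n"`.
#' @export
generate_amplitude_table <- function(params, gt, protocol, repeats = 7L,
                                     seed = NULL, p_n = NULL,
                                     cell_id = "synthetic") {
  stopifnot(inherits(gt, "quantal_ground_truth"),
            inherits(protocol, "stimulus_protocol"))
  if (is.null(p_n)) {
    stopifnot(inherits(params, "synapse_params"))
    p_n <- simulate_train(protocol, params)$p_n
  }
  stopifnot(length(p_n) == length(protocol), all(p_n >= 0), all(p_n <= 1))
  if (is.null(seed)) seed <- gt$seed
  amp <- with_seed(seed, draw_amplitudes(p_n, as.integer(repeats), gt))
  freq <- if (length(protocol) >= 2L) {
    1000 / (protocol$pulse_times[2L] - protocol$pulse_times[1L])
  } else 1
  tb <- amplitude_table(amp, frequency_hz = freq, cell_id = cell_id,
                        protocol = protocol)
  attr(tb, "p_n") <- p_n
  tb
}

#' Generate a full experiment-shaped synthetic dataset
#'
#' Emulates the experimental design used throughout the package: 20-pulse
#' trains at 5/10/20/50 Hz, each repeated 7 times, plus recovery from
#' paired-pulse depression (two pulses from rest) at
#' 20/50/100/500/1000/3000 ms intervals, each repeated 7 times. Trains are
#' assumed independent (full recovery between repetitions).
#'
#' @inheritParams generate_amplitude_table
#' @param frequencies_hz Train frequencies, Hz.
#' @param n_pulses Pulses per train.
#' @param recovery_intervals_ms Interpulse intervals for the recovery
#'   pairs, ms.
#' @param scale_p_max Optional target maximum release probability: the
#'   model's p_n profile is rescaled so its maximum equals this value
#'   (used to impose a cell's measured p_max on the model's STD shape).
#' @return An object of class `experiment_dataset`: a list with `tables`
#'   (one [amplitude_table()] per frequency), `recovery` (data.frame
#'   `interval_ms`, `repeat`, `p1_pa`, `p2_pa`), and `truth` (generating
#'   parameters and per-protocol p_n).
#' @export
generate_experiment <- function(params, gt,
                                frequencies_hz = c(5, 10, 20, 50),
                                n_pulses = 20L, repeats = 7L,
                                recovery_intervals_ms = c(20, 50, 100, 500, 1000, 3000),
                                seed = NULL, scale_p_max = NULL,
                                cell_id = "synthetic") {
  stopifnot(inherits(params, "synapse_params"),
            inherits(gt, "quantal_ground_truth"))
  if (is.null(seed)) seed <- gt$seed
  scale <- 1
  if (!is.null(scale_p_max)) {
    stopifnot(is_scalar_num(scale_p_max), scale_p_max > 0, scale_p_max <= 1)
    p1 <- simulate_train(stimulus_protocol(0), params)$p_n[1L]
    scale <- scale_p_max / p1
  }
  with_seed(seed, {
    tables <- lapply(frequencies_hz, function(f) {
      proto <- train_protocol(f, n_pulses)
      p_n <- pmin(simulate_train(proto, params)$p_n * scale, 1)
      tb <- amplitude_table(
        draw_amplitudes(p_n, as.integer(repeats), gt),
        frequency_hz = f, cell_id = cell_id, protocol = proto
      )
      attr(tb, "p_n") <- p_n
      tb
    })
    names(tables) <- paste0(frequencies_hz, "Hz")
    rec_pn <- lapply(recovery_intervals_ms, function(T) {
      pmin(simulate_train(paired_protocol(T), params)$p_n * scale, 1)
    })
    recovery <- do.call(rbind, lapply(seq_along(recovery_intervals_ms), function(i) {
      amp <- draw_amplitudes(rec_pn[[i]], as.integer(repeats), gt)
      data.frame(
        interval_ms = recovery_intervals_ms[i],
        rep = seq_len(repeats),
        p1_pa = amp[, 1L],
        p2_pa = amp[, 2L]
      )
    }))
    names(recovery)[names(recovery) == "rep"] <- "repeat"
    truth <- list(
      params = params, ground_truth = gt, scale = scale,
      frequencies_hz = frequencies_hz, n_pulses = as.integer(n_pulses),
      repeats = as.integer(repeats),
      recovery_intervals_ms = recovery_intervals_ms,
      p_n = lapply(tables, attr, "p_n"),
      recovery_p_n = rec_pn,
      seed = seed
    )
    structure(list(tables = tables, recovery = recovery, truth = truth),
              class = "experiment_dataset")
  })
}

#' @export
print.experiment_dataset <- function(x, ...) {
  cat(sprintf(
    "<experiment_dataset> %d train table(s) [%s], %d recovery interval(s), seed %s\n",
    length(x$tables),
    paste(names(x$tables), collapse = ", "),
    length(unique(x$recovery$interval_ms)),
    format(x$truth$seed)
  ))
  invisible(x)
}

#' IPSC waveform specification
#'
#' Biexponential kernel `exp(-t/decay) - exp(-t/rise)`, peak-normalized.
#' By default the rise constant is solved so the kernel's 10-90% rise
#' time matches `rise_10_90_ms` given the decay constant.
#'
#' @param decay_tau_ms Decay time constant, ms.
#' @param rise_tau_ms Rise time constant, ms; if `NULL`, solved from
#'   `rise_10_90_ms`.
#' @param rise_10_90_ms Target 10-90% rise time used when `rise_tau_ms`
#'   is `NULL`, ms.
#' @param sampling_khz Sampling rate, kHz.
#' @param baseline_noise_sd_pa Gaussian baseline noise SD, pA.
#' @return An object of class `waveform_spec`.
#' @export
waveform_spec <- function(decay_tau_ms = 8.5, rise_tau_ms = NULL,
                          rise_10_90_ms = 1.0, sampling_khz = 20,
                          baseline_noise_sd_pa = 0) {
  stopifnot(is_scalar_num(decay_tau_ms), decay_tau_ms > 0,
            is_scalar_num(sampling_khz), sampling_khz > 0,
            is_scalar_num(baseline_noise_sd_pa), baseline_noise_sd_pa >= 0)
  if (is.null(rise_tau_ms)) {
    rise_tau_ms <- rise_tau_for_rise_time(rise_10_90_ms, decay_tau_ms)
  }
  if (rise_tau_ms <= 0 || rise_tau_ms >= decay_tau_ms) {
    stop("need 0 < rise_tau_ms < decay_tau_ms", call. = FALSE)
  }
  structure(
    list(rise_tau_ms = rise_tau_ms, decay_tau_ms = decay_tau_ms,
         sampling_khz = sampling_khz,
         baseline_noise_sd_pa = baseline_noise_sd_pa),
    class = "waveform_spec"
  )
}

# Peak-normalized biexponential kernel evaluated at times t (>= 0).
biexp_kernel <- function(t, rise_tau, decay_tau) {
  tpk <- biexp_peak_time(rise_tau, decay_tau)
  gmax <- exp(-tpk / decay_tau) - exp(-tpk / rise_tau)
  (exp(-t / decay_tau) - exp(-t / rise_tau)) / gmax
}

# Analytic peak time of exp(-t/decay) - exp(-t/rise).
biexp_peak_time <- function(rise_tau, decay_tau) {
  rise_tau * decay_tau / (decay_tau - rise_tau) * log(decay_tau / rise_tau)
}

# 10-90% rise time of the peak-normalized kernel, found numerically.
biexp_rise_10_90 <- function(rise_tau, decay_tau) {
  tpk <- biexp_peak_time(rise_tau, decay_tau)
  g <- function(t) biexp_kernel(t, rise_tau, decay_tau)
  t10 <- stats::uniroot(function(t) g(t) - 0.1, c(0, tpk), tol = 1e-10)$root
  t90 <- stats::uniroot(function(t) g(t) - 0.9, c(t10, tpk), tol = 1e-10)$root
  t90 - t10
}

# Rise constant giving a target 10-90% rise time for a given decay.
rise_tau_for_rise_time <- function(rise_10_90, decay_tau) {
  stats::uniroot(
    function(r) biexp_rise_10_90(r, decay_tau) - rise_10_90,
    c(1e-4 * decay_tau, 0.99 * decay_tau), tol = 1e-10
  )$root
}

#' Synthesize raw current sweeps from an amplitude table
#'
#' Places one peak-normalized biexponential kernel, scaled to the stored
#' amplitude, at each pulse time; overlapping events sum linearly (so at
#' 50 Hz the tails summate as in real recordings) and Gaussian baseline
#' noise is added. One sweep is produced per repeat row.
#'
#' @param table An [amplitude_table()].
#' @param waveform A [waveform_spec()].
#' @param seed RNG seed for the baseline noise.
#' @param pre_ms,post_ms Padding before the first and after the last
#'   pulse, ms.
#' @return A list of data.frames (`time_ms`, `current_pa`), one per
#'   repeat.
#' @export
synthesize_trace <- function(table, waveform, seed = NULL,
                             pre_ms = 10, post_ms = 60) {
  stopifnot(inherits(table, "amplitude_table"),
            inherits(waveform, "waveform_spec"))
  pulses <- table$protocol$pulse_times
  dt <- 1 / waveform$sampling_khz
  t <- seq(min(pulses) - pre_ms, max(pulses) + post_ms, by = dt)
  with_seed(seed, {
    lapply(seq_len(nrow(table$amplitudes)), function(r) {
      y <- numeric(length(t))
      for (j in seq_along(pulses)) {
        a <- table$amplitudes[r, j]
        if (is.na(a) || a == 0) next
        after <- t >= pulses[j]
        y[after] <- y[after] +
          a * biexp_kernel(t[after] - pulses[j],
                           waveform$rise_tau_ms, waveform$decay_tau_ms)
      }
      if (waveform$baseline_noise_sd_pa > 0) {
        y <- y + stats::rnorm(length(t), 0, waveform$baseline_noise_sd_pa)
      }
      data.frame(time_ms = t, current_pa = y)
    })
  })
}
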