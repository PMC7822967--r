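#' Amplitude tables
#'
#' The unit of experimental data: a repeats x pulses matrix of IPSC peak
#' amplitudes (pA, sign-rectified magnitudes) recorded for one stimulus
#' protocol in one cell. Missing amplitudes are allowed as NA and are
#' skipped by the train statistics.
#'
#' @param amplitudes Numeric matrix, repeats x pulses, pA (>= 0 or NA).
#' @param frequency_hz Stimulation frequency, Hz.
#' @param cell_id Cell identifier.
#' @param protocol Optional [stimulus_protocol()]; defaults to a
#'   constant-frequency train matching `frequency_hz` and `ncol(amplitudes)`.
#' @return An object of class `amplitude_table`.
#' @export
amplitude_table <- function(amplitudes, frequency_hz, cell_id = "cell",
                            protocol = NULL) {
  amplitudes <- as.matrix(amplitudes)
  if (any(amplitudes < 0, na.rm = TRUE)) {
    stop("amplitudes must be sign-rectified magnitudes (>= 0)", call. = FALSE)
  }
  stopifnot(is_scalar_num(frequency_hz), frequency_hz > 0)
  if (is.null(protocol)) {
    protocol <- train_protocol(frequency_hz, n_pulses = ncol(amplitudes))
  }
  if (length(protocol) != ncol(amplitudes)) {
    stop("protocol length must equal the number of pulse columns", call. = FALSE)
  }
  structure(
    list(amplitudes = amplitudes, frequency_hz = frequency_hz,
         cell_id = as.character(cell_id)[1L], protocol = protocol),
    class = "amplitude_table"
  )
}

#' @export
print.amplitude_table <- function(x, ...) {
  cat(sprintf(
    "<amplitude_table> %s, %g Hz: %d repeat(s) x %d pulse(s), mean P1 = %.1f pA\n",
    x$cell_id, x$frequency_hz, nrow(x$amplitudes), ncol(x$amplitudes),
    mean(x$amplitudes[, 1L], na.rm = TRUE)
  ))
  invisible(x)
}

#' Extract stimulus-locked IPSC peak amplitudes from a current trace
#'
#' For each pulse, the baseline is estimated from the `baseline_ms`
#' preceding the pulse and the amplitude is the absolute peak of the
#' baseline-subtracted current in a detection window after the pulse
#' onset. The window is the stated detection window (`window_ms`) plus a
#' rise allowance so the peak itself, reached ~1-2 ms after onset, is
#' captured; at short interpulse intervals the window is truncated at the
#' next pulse. The per-pulse baseline removes the summating tail of
#' preceding IPSCs; by default it is a sloped (linear) baseline
#' extrapolated into the detection window, which tracks the decay of the
#' preceding tail over the ~1-2 ms to the peak (a constant baseline
#' under-measures summating 50 Hz trains by several percent).
#'
#' @param trace data.frame with columns `time_ms`, `current_pa`.
#' @param pulse_times Pulse onset times, ms.
#' @param window_ms Detection window after pulse onset, ms.
#' @param baseline_ms Baseline window before pulse onset, ms.
#' @param rise_allowance_ms Extra time after the detection window so the
#'   IPSC peak is included, ms.
#' @param polarity `"positive"`, `"negative"`, or `"auto"`: direction of
#'   evoked deflections relative to baseline (`"auto"` uses the larger
#'   absolute excursion).
#' @param baseline_method `"linear"` (sloped baseline extrapolated from
#'   the pre-pulse window; default) or `"constant"` (pre-pulse mean).
#' @return Numeric vector of amplitudes (pA, magnitudes), one per pulse.
#' @export
extract_amplitudes <- function(trace, pulse_times, window_ms = 2,
                               baseline_ms = 1, rise_allowance_ms = 3,
                               polarity = c("auto", "positive", "negative"),
                               baseline_method = c("linear", "constant")) {
  polarity <- match.arg(polarity)
  baseline_method <- match.arg(baseline_method)
  stop_missing_cols(trace, c("time_ms", "current_pa"), "trace")
  t <- trace$time_ms
  y <- trace$current_pa
  n <- length(pulse_times)
  out <- numeric(n)
  for (i in seq_len(n)) {
    p <- pulse_times[i]
    end <- p + window_ms + rise_allowance_ms
    if (i < n) end <- min(end, pulse_times[i + 1L])
    if (end > max(t)) {
      stop(sprintf("detection window for pulse %d extends past the trace end", i),
           call. = FALSE)
    }
    win_idx <- which(t > p & t <= end)
    if (length(win_idx) == 0L) {
      stop(sprintf("no samples in the detection window of pulse %d", i),
           call. = FALSE)
    }
    base_idx <- which(t >= p - baseline_ms & t < p)
    if (length(base_idx) >= 3L && baseline_method == "linear") {
      bfit <- stats::lm.fit(cbind(1, t[base_idx]), y[base_idx])
      baseline <- bfit$coefficients[1L] + bfit$coefficients[2L] * t[win_idx]
    } else {
      baseline <- if (length(base_idx) > 0L) mean(y[base_idx]) else 0
    }
    dev <- y[win_idx] - baseline
    out[i] <- switch(polarity,
      positive = max(dev),
      negative = -min(dev),
      auto = max(abs(dev))
    )
    out[i] <- max(out[i], 0)
  }
  out
}

#' Variance-mean (quantal) analysis
#'
#' Across conditions of differing release probability, the variance of a
#' binomial quantal response is a parabola in its mean:
#' `sigma^2 = (1 + CV^2) q I - I^2 / N_VM`, where `q` is the quantal
#' amplitude, `N_VM` the number of functional release sites and CV the
#' intrasite quantal coefficient of variation (fixed, 0.3 by convention).
#' Per-pulse means and variances are computed across repeats; P1 from each
#' frequency enters as its own point, while P2-P20 from all frequencies
#' are pooled and binned by mean amplitude (bin width 0.1 x the grand-mean
#' P1 amplitude, bins with fewer than `min_bin_points` points dropped),
#' averaging means and variances within bins. The parabola is linear in
#' `(I, I^2)` and is fit by unweighted least squares.
#'
#' @param tables A list of [amplitude_table()]s, one per stimulation
#'   frequency (or a single table).
#' @param cv_intra Intrasite quantal coefficient of variation (fixed).
#' @param bin_width_factor Bin width as a fraction of the grand-mean P1
#'   amplitude.
#' @param min_bin_points Minimum pooled points per kept bin.
#' @return An object of class `vm_fit`: a list with `q_pa`, `n_vm`,
#'   `cv_intra`, `p_max_hat` (maximum binned mean / (N q), clipped to
#'   `[0, 1]`), `binned_points` (data.frame `mean_pa`, `var_pa2`,
#'   `n_points`, `is_p1`) and the underlying `lm` fit.
#' @examples
#' gt <- quantal_ground_truth(n_sites = 12, q_pa = 30, seed = 1)
#' exp <- generate_experiment(table1_params("SH"), gt, seed = 1)
#' variance_mean_fit(exp$tables)
#' @export
variance_mean_fit <- function(tables, cv_intra = 0.3, bin_width_factor = 0.1,
                              min_bin_points = 2L) {
  if (inherits(tables, "amplitude_table")) tables <- list(tables)
  stopifnot(length(tables) >= 1L,
            all(vapply(tables, inherits, TRUE, "amplitude_table")))
  stopifnot(is_scalar_num(cv_intra), cv_intra >= 0)

  per_pulse <- lapply(tables, function(tb) {
    a <- tb$amplitudes
    n_rep <- colSums(!is.na(a))
    if (any(n_rep < 3L)) {
      stop("need >= 3 repeats per pulse for variance-mean analysis",
           call. = FALSE)
    }
    data.frame(
      frequency_hz = tb$frequency_hz,
      pulse_index = seq_len(ncol(a)),
      mean_pa = colMeans(a, na.rm = TRUE),
      var_pa2 = apply(a, 2L, stats::var, na.rm = TRUE)
    )
  })
  pts <- do.call(rbind, per_pulse)

  p1 <- pts[pts$pulse_index == 1L, , drop = FALSE]
  rest <- pts[pts$pulse_index > 1L, , drop = FALSE]
  bin_width <- bin_width_factor * mean(p1$mean_pa)
  if (!is.finite(bin_width) || bin_width <= 0) {
    stop("degenerate P1 amplitudes: cannot define variance-mean bins",
         call. = FALSE)
  }

  bin_id <- floor(rest$mean_pa / bin_width)
  binned <- do.call(rbind, lapply(split(rest, bin_id), function(b) {
    data.frame(mean_pa = mean(b$mean_pa), var_pa2 = mean(b$var_pa2),
               n_points = nrow(b))
  }))
  binned <- binned[binned$n_points >= min_bin_points, , drop = FALSE]

  points <- rbind(
    data.frame(mean_pa = p1$mean_pa, var_pa2 = p1$var_pa2,
               n_points = 1L, is_p1 = TRUE),
    if (nrow(binned) > 0L)
      data.frame(mean_pa = binned$mean_pa, var_pa2 = binned$var_pa2,
                 n_points = binned$n_points, is_p1 = FALSE)
  )
  if (nrow(points) < 2L || length(unique(round(points$mean_pa, 10))) < 2L) {
    stop("need >= 2 distinct mean-amplitude points to fit the parabola",
         call. = FALSE)
  }

  fit <- stats::lm(var_pa2 ~ 0 + mean_pa + I(mean_pa^2), data = points)
  a <- unname(stats::coef(fit)[1L])   # (1 + CV^2) q
  b <- unname(stats::coef(fit)[2L])   # -1 / N_VM
  q <- a / (1 + cv_intra^2)
  if (!is.finite(q) || q <= 0 || !is.finite(b) || b >= 0) {
    stop(sprintf(
      paste0("degenerate variance-mean fit (q = %.3g pA, quadratic ",
             "coefficient = %.3g): data do not define a downward parabola"),
      q, b), call. = FALSE)
  }
  n_vm <- -1 / b
  p_max_hat <- max(points$mean_pa) / (n_vm * q)
  if (p_max_hat > 1) {
    if (p_max_hat > 1 + 1e-6) {
      warning(sprintf("p_max estimate %.3f exceeds 1; clipped", p_max_hat))
    }
    p_max_hat <- 1
  }
  structure(
    list(q_pa = q, n_vm = n_vm, cv_intra = cv_intra,
         p_max_hat = max(p_max_hat, 0), binned_points = points, lm_fit = fit),
    class = "vm_fit"
  )
}

#' @export
print.vm_fit <- function(x, ...) {
  cat(sprintf(
    "<vm_fit> q = %.1f pA, N_VM = %.1f, p_max = %.2f (CV fixed at %.2g, %d points)\n",
    x$q_pa, x$n_vm, x$p_max_hat, x$cv_intra, nrow(x$binned_points)
  ))
  invisible(x)
}

#' Maximum release probability from a variance-mean fit
#'
#' `p_max = p_x / (N_VM q)` evaluated at the largest mean amplitude:
#' each mean amplitude divided by the maximum possible response `N_VM q`
#' estimates the release probability of that pulse, and the maximum
#' (normally P1) estimates the maximal release probability.
#'
#' @param fit A [variance_mean_fit()] result.
#' @param mean_amplitudes_pa Optional mean amplitudes to evaluate instead
#'   of the fit's own points.
#' @return Scalar in `[0, 1]` (values above 1 are clipped with a warning).
#' @export
p_max_from_fit <- function(fit, mean_amplitudes_pa = NULL) {
  stopifnot(inherits(fit, "vm_fit"))
  if (is.null(mean_amplitudes_pa)) return(fit$p_max_hat)
  p <- max(mean_amplitudes_pa) / (fit$n_vm * fit$q_pa)
  if (p > 1) {
    if (p > 1 + 1e-6) {
      warning(sprintf("p_max estimate %.3f exceeds 1; clipped", p))
    }
    p <- 1
  }
  max(p, 0)
}

#' Per-pulse release probability series
#'
#' Mean IPSC amplitude per pulse divided by the maximum possible response
#' `N q`.
#'
#' @param table An [amplitude_table()].
#' @param n_sites Number of functional release sites.
#' @param q_pa Quantal amplitude, pA.
#' @return Numeric vector of per-pulse release probabilities.
#' @export
pr_series <- function(table, n_sites, q_pa) {
  stopifnot(inherits(table, "amplitude_table"),
            is_scalar_num(n_sites), n_sites > 0,
            is_scalar_num(q_pa), q_pa > 0)
  p <- colMeans(table$amplitudes, na.rm = TRUE) / (n_sites * q_pa)
  if (any(p > 1.2, na.rm = TRUE)) {
    warning("release probabilities > 1.2: N*q is inconsistent with the amplitudes")
  }
  p
}

#' Readily-releasable pool size from cumulative amplitudes
#'
#' The cumulative mean IPSC amplitude versus pulse index approaches a line
#' once release reaches its depleted steady state; back-extrapolating an
#' ordinary least-squares line through the last `tail_pulses` points to
#' pulse 0 and dividing the intercept by the quantal amplitude estimates
#' the number of release sites in the readily-releasable pool, N_RP.
#'
#' @param table An [amplitude_table()] (a 20-pulse train; 50 Hz depletes
#'   most completely and gives the cleanest estimate).
#' @param q_pa Quantal amplitude, pA.
#' @param tail_pulses Number of final pulses for the line fit.
#' @return A list with `n_rp`, `intercept_pa`, `slope_pa`, and
#'   `cumulative_pa` (the cumulative mean amplitude series).
#' @export
rrp_from_cumulative <- function(table, q_pa, tail_pulses = 5L) {
  stopifnot(inherits(table, "amplitude_table"),
            is_scalar_num(q_pa), q_pa > 0)
  m <- colMeans(table$amplitudes, na.rm = TRUE)
  n <- length(m)
  if (n < tail_pulses + 2L) {
    stop(sprintf("need at least %d pulses for a %d-point tail fit",
                 tail_pulses + 2L, tail_pulses), call. = FALSE)
  }
  cum <- cumsum(m)
  idx <- seq.int(n - tail_pulses + 1L, n)
  fit <- stats::lm(cum[idx] ~ idx)
  intercept <- unname(stats::coef(fit)[1L])
  if (intercept < -1e-6 * max(cum)) {
    warning("negative cumulative-amplitude intercept: no depletion signature")
  }
  list(
    n_rp = intercept / q_pa,
    intercept_pa = intercept,
    slope_pa = unname(stats::coef(fit)[2L]),
    cumulative_pa = cum
  )
}

#' Per-pulse coefficient of variation
#'
#' Sample SD across repeats divided by the mean, per pulse. Pulses with a
#' zero (or missing) mean are returned as NA with a warning.
#'
#' @param table An [amplitude_table()] with >= 3 repeats.
#' @return Numeric vector of per-pulse CVs.
#' @export
cv_series <- function(table) {
  stopifnot(inherits(table, "amplitude_table"))
  a <- table$amplitudes
  if (any(colSums(!is.na(a)) < 3L)) {
    stop("need >= 3 repeats per pulse for a CV", call. = FALSE)
  }
  m <- colMeans(a, na.rm = TRUE)
  s <- apply(a, 2L, stats::sd, na.rm = TRUE)
  cv <- s / m
  if (any(!is.finite(cv))) {
    warning("zero-mean pulse(s): CV undefined, returned as NA")
    cv[!is.finite(cv)] <- NA_real_
  }
  cv
}

#' Paired-pulse ratio
#'
#' `mean(P2) / mean(P1)` across repeats.
#'
#' @param table An [amplitude_table()] with >= 2 pulses.
#' @return Scalar paired-pulse ratio.
#' @export
ppr <- function(table) {
  stopifnot(inherits(table, "amplitude_table"))
  a <- table$amplitudes
  if (ncol(a) < 2L) stop("need at least 2 pulses for a PPR", call. = FALSE)
  m1 <- mean(a[, 1L], na.rm = TRUE)
  if (!is.finite(m1) || m1 == 0) stop("mean P1 is zero: PPR undefined", call. = FALSE)
  mean(a[, 2L], na.rm = TRUE) / m1
}

#' Steady-state depression across frequencies
#'
#' For each frequency, the mean amplitude over pulses 16-20 (the
#' depressed plateau) normalized to the mean P1 amplitude, divided by the
#' same quantity at 5 Hz. By construction the 5 Hz entry is 1.
#' Normalization uses the repeat-averaged P1 (dividing by single-trial P1
#' amplitudes would add noise and bias the ratio upward).
#'
#' @param tables A list of 20-pulse [amplitude_table()]s including a 5 Hz
#'   table.
#' @param reference_hz Reference frequency (5 Hz).
#' @param plateau_pulses Pulse indices of the depressed plateau.
#' @return A data.frame with columns `frequency_hz` and `ssd`.
#' @export
ssd <- function(tables, reference_hz = 5, plateau_pulses = 16:20) {
  if (inherits(tables, "amplitude_table")) tables <- list(tables)
  stopifnot(all(vapply(tables, inherits, TRUE, "amplitude_table")))
  freqs <- vapply(tables, function(tb) tb$frequency_hz, 0.0)
  if (!any(abs(freqs - reference_hz) < 1e-9)) {
    stop(sprintf("missing the %g Hz reference table", reference_hz), call. = FALSE)
  }
  plateau <- vapply(tables, function(tb) {
    a <- tb$amplitudes
    if (ncol(a) < max(plateau_pulses)) {
      stop(sprintf("table at %g Hz has fewer than %d pulses",
                   tb$frequency_hz, max(plateau_pulses)), call. = FALSE)
    }
    mean(a[, plateau_pulses], na.rm = TRUE) / mean(a[, 1L], na.rm = TRUE)
  }, 0.0)
  ref <- plateau[which.min(abs(freqs - reference_hz))]
  out <- data.frame(frequency_hz = freqs, ssd = plateau / ref)
  out[order(out$frequency_hz), , drop = FALSE]
}

#' IPSC kinetics: 10-90% rise time and decay time constant
#'
#' From a trace segment containing one isolated IPSC: the rise time is the
#' interval between the linearly interpolated 10% and 90% crossings of the
#' peak on the rising phase; the decay time constant comes from a
#' single-exponential least-squares fit starting `fit_from_peak_ms` after
#' the peak (by default 1.5 ms, so the residual of the fast rise
#' component, which still contributes a few percent at the peak itself,
#' has decayed away) and running to the end of the segment.
#'
#' @param trace data.frame with columns `time_ms`, `current_pa`
#'   (baseline-subtracted, one IPSC, positive-going; use
#'   [extract_amplitudes()] conventions upstream).
#' @param pulse_time_ms Stimulus onset, ms; only samples after it are used.
#' @param fit_from_peak_ms Offset after the peak at which the decay fit
#'   starts, ms (0 = at the peak).
#' @return A list with `rise_10_90_ms`, `decay_tau_ms`, `peak_pa`,
#'   `peak_time_ms`.
#' @export
ipsc_kinetics <- function(trace, pulse_time_ms = 0, fit_from_peak_ms = 1.5) {
  stop_missing_cols(trace, c("time_ms", "current_pa"), "trace")
  keep <- trace$time_ms >= pulse_time_ms
  t <- trace$time_ms[keep]
  y <- trace$current_pa[keep]
  if (length(t) < 5L) stop("trace segment too short", call. = FALSE)
  ipk <- which.max(y)
  peak <- y[ipk]
  if (peak <= 0) stop("no positive-going IPSC in the segment", call. = FALSE)

  cross_up <- function(level) {
    # first upward crossing of `level` before the peak, linearly interpolated
    pre_t <- t[seq_len(ipk)]
    pre_y <- y[seq_len(ipk)]
    above <- which(pre_y >= level)
    if (length(above) == 0L) return(NA_real_)
    j <- above[1L]
    if (j == 1L) return(pre_t[1L])
    t0 <- pre_t[j - 1L]; t1 <- pre_t[j]
    y0 <- pre_y[j - 1L]; y1 <- pre_y[j]
    t0 + (level - y0) / (y1 - y0) * (t1 - t0)
  }
  rise <- cross_up(0.9 * peak) - cross_up(0.1 * peak)

  dec <- which(t >= t[ipk] + fit_from_peak_ms)
  td <- t[dec] - t[dec[1L]]
  yd <- y[dec]
  if (length(td) < 4L || all(yd <= 0)) {
    stop("not enough decay samples for an exponential fit", call. = FALSE)
  }
  # log-linear start values, then nonlinear least squares
  pos <- yd > peak * 1e-6
  start_fit <- stats::lm(log(yd[pos]) ~ td[pos])
  tau0 <- -1 / unname(stats::coef(start_fit)[2L])
  if (!is.finite(tau0) || tau0 <= 0) tau0 <- diff(range(td)) / 3
  # warnOnly: nls declares failure on data the start values fit exactly
  fit <- try(suppressWarnings(stats::nls(
    yd ~ A * exp(-td / tau),
    start = list(A = yd[1L], tau = tau0),
    control = stats::nls.control(maxiter = 200, warnOnly = TRUE)
  )), silent = TRUE)
  tau_hat <- if (inherits(fit, "try-error")) NA_real_ else
    unname(stats::coef(fit)[["tau"]])
  if (!is.finite(tau_hat) || tau_hat <= 0) {
    stop("single-exponential decay fit failed", call. = FALSE)
  }
  list(
    rise_10_90_ms = rise,
    decay_tau_ms = tau_hat,
    peak_pa = peak,
    peak_time_ms = t[ipk]
  )
}
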