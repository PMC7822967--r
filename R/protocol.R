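#' Stimulus protocols
#'
#' A stimulus protocol is an ordered set of pulse onset times (ms). Two
#' constructors cover the experimental designs used throughout the package:
#' constant-frequency trains (e.g. 20 light pulses at 5-50 Hz) and
#' conditioning/test pulse pairs separated by a recovery interval.
#'
#' @param pulse_times Strictly increasing numeric vector of pulse onset
#'   times in ms.
#' @param description Free-text label.
#' @return An object of class `stimulus_protocol`: a list with elements
#'   `pulse_times` (numeric, ms) and `description`.
#' @examples
#' train_protocol(20, n_pulses = 20)   # 20 pulses at 20 Hz
#' paired_protocol(100)                # P1/P2 pair, 100 ms apart
#' @export
stimulus_protocol <- function(pulse_times, description = "") {
  pulse_times <- as.numeric(pulse_times)
  if (length(pulse_times) < 1L) {
    stop("a protocol needs at least one pulse", call. = FALSE)
  }
  if (anyNA(pulse_times) || any(diff(pulse_times) <= 0)) {
    stop("pulse times must be strictly increasing and finite", call. = FALSE)
  }
  structure(
    list(pulse_times = pulse_times, description = as.character(description)[1L]),
    class = "stimulus_protocol"
  )
}

#' @rdname stimulus_protocol
#' @param frequency_hz Stimulation frequency in Hz.
#' @param n_pulses Number of pulses in the train.
#' @param t0 Onset of the first pulse, ms.
#' @export
train_protocol <- function(frequency_hz, n_pulses = 20L, t0 = 0) {
  stopifnot(is_scalar_num(frequency_hz), frequency_hz > 0, n_pulses >= 1)
  interval <- 1000 / frequency_hz
  stimulus_protocol(
    t0 + interval * (seq_len(n_pulses) - 1L),
    description = sprintf("%g Hz train, %d pulses", frequency_hz, as.integer(n_pulses))
  )
}

#' @rdname stimulus_protocol
#' @param interval_ms Interval between the conditioning (P1) and test (P2)
#'   pulse, ms.
#' @export
paired_protocol <- function(interval_ms, t0 = 0) {
  stopifnot(is_scalar_num(interval_ms), interval_ms > 0)
  stimulus_protocol(
    c(t0, t0 + interval_ms),
    description = sprintf("paired pulses, %g ms interval", interval_ms)
  )
}

#' @export
print.stimulus_protocol <- function(x, ...) {
  cat(sprintf(
    "<stimulus_protocol> %d pulse(s) over %g ms%s\n",
    length(x$pulse_times),
    diff(range(x$pulse_times)),
    if (nzchar(x$description)) paste0(": ", x$description) else ""
  ))
  invisible(x)
}

#' @export
length.stimulus_protocol <- function(x) length(x$pulse_times)
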