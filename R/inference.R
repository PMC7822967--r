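#' Assemble the fitting dataset
#'
#' The model is fit to observed release probabilities from two protocol
#' families at once: the STD trains (4 frequencies x 20 pulses = 80
#' values) and recovery from paired-pulse depression (P1 and P2 at each of
#' 6 interpulse intervals = 12 values), 92 target values in all.
#'
#' @param std_pr A list of per-pulse observed release-probability vectors,
#'   named by frequency (e.g. from [pr_series()]), or a matrix with one
#'   row per frequency.
#' @param frequencies_hz Frequencies of the STD trains, Hz.
#' @param recovery data.frame with columns `interval_ms`, `p1`, `p2`
#'   (observed release probabilities of the conditioning and test pulse).
#' @param require_standard_design Check the canonical design (4
#'   frequencies x 20 pulses, 6 intervals) and name any gaps.
#' @return An object of class `fit_dataset`: observed vector `observed`,
#'   the protocol bookkeeping (`protocols`, a list with `pulse_times` per
#'   entry and an index map), frequencies and intervals.
#' @export
assemble_fit_dataset <- function(std_pr, frequencies_hz = c(5, 10, 20, 50),
                                 recovery,
                                 require_standard_design = TRUE) {
  if (is.matrix(std_pr)) {
    std_pr <- lapply(seq_len(nrow(std_pr)), function(i) std_pr[i, ])
  }
  stopifnot(is.list(std_pr), length(std_pr) == length(frequencies_hz))
  stop_missing_cols(recovery, c("interval_ms", "p1", "p2"), "recovery data")
  if (require_standard_design) {
    gaps <- character(0)
    for (f in c(5, 10, 20, 50)) {
      if (!any(abs(frequencies_hz - f) < 1e-9)) {
        gaps <- c(gaps, sprintf("%g Hz train", f))
      }
    }
    for (T in c(20, 50, 100, 500, 1000, 3000)) {
      if (!any(abs(recovery$interval_ms - T) < 1e-9)) {
        gaps <- c(gaps, sprintf("%g ms recovery interval", T))
      }
    }
    if (any(vapply(std_pr, length, 0L) != 20L)) {
      gaps <- c(gaps, "20 pulses per train")
    }
    if (length(gaps) > 0L) {
      stop(sprintf("dataset is missing: %s", paste(gaps, collapse = "; ")),
           call. = FALSE)
    }
  }
  obs <- c(unlist(std_pr, use.names = FALSE),
           as.vector(rbind(recovery$p1, recovery$p2)))
  if (any(!is.finite(obs)) || any(obs < 0) || any(obs > 1.2)) {
    stop("observed release probabilities must be finite and in [0, 1.2]",
         call. = FALSE)
  }
  protocols <- c(
    lapply(seq_along(frequencies_hz), function(i) {
      list(pulse_times = (1000 / frequencies_hz[i]) *
             (seq_along(std_pr[[i]]) - 1L),
           kind = "train", frequency_hz = frequencies_hz[i])
    }),
    lapply(recovery$interval_ms, function(T) {
      list(pulse_times = c(0, T), kind = "recovery", interval_ms = T)
    })
  )
  structure(
    list(observed = obs, protocols = protocols,
         frequencies_hz = frequencies_hz,
         recovery_intervals_ms = recovery$interval_ms),
    class = "fit_dataset"
  )
}

# Model prediction vector matching dataset$observed ordering, for the free
# parameter vector theta = (tau_ca, k_half, k_min, delta_k, k_r_half) with
# fixed p_max and delta_jump. Returns NULL for invalid parameters.
predict_dataset <- function(theta, dataset, p_max_vm, delta_jump) {
  if (any(!is.finite(theta)) || any(theta <= 0)) return(NULL)
  unlist(lapply(dataset$protocols, function(pr) {
    sim_pn(pr$pulse_times, theta[1L], p_max_vm, theta[2L],
           theta[3L], theta[4L], theta[5L], delta_jump)
  }), use.names = FALSE)
}

#' Objective function for model fitting
#'
#' Mean squared error between the model-predicted observable release
#' probabilities (via the forward model, run over every protocol in the
#' dataset) and the observed values, with equal weight per point. The
#' free parameters are `{tau_ca, k_half, k_min, delta_k, k_r_half}`;
#' `p_max_vm` (from variance-mean analysis) and `delta_jump` (1) are
#' fixed. Invalid (non-positive or non-finite) parameters return `Inf`.
#'
#' @param free_params Numeric vector `(tau_ca_ms, k_half, k_min_per_ms,
#'   delta_k_per_ms, k_r_half)`.
#' @param dataset A [assemble_fit_dataset()] result.
#' @param p_max_vm,delta_jump Fixed parameters.
#' @return Scalar mean squared error.
#' @export
std_objective <- function(free_params, dataset, p_max_vm, delta_jump = 1) {
  stopifnot(inherits(dataset, "fit_dataset"), length(free_params) == 5L)
  pred <- predict_dataset(free_params, dataset, p_max_vm, delta_jump)
  if (is.null(pred)) return(Inf)
  mean((pred - dataset$observed)^2)
}

free_param_names <- c("tau_ca_ms", "k_half", "k_min_per_ms",
                      "delta_k_per_ms", "k_r_half")

#' Maximum a posteriori (point) fit of the synapse model
#'
#' Derivative-free Nelder-Mead minimization of [std_objective()] in
#' log-parameter space (which enforces positivity without explicit
#' constraints), started from `init`. Convergence is declared when the
#' relative change of the objective falls below `tol`.
#'
#' @param dataset A [assemble_fit_dataset()] result.
#' @param init A [synapse_params()] object supplying the starting values
#'   and the fixed `p_max_vm` / `delta_jump`.
#' @param tol Relative objective-change convergence tolerance.
#' @param max_iter Iteration cap; exceeding it errors with the
#'   best-so-far point attached to the condition.
#' @return A list with `params` (a [synapse_params()] at the optimum),
#'   `mse`, `iterations` (function evaluations), and `convergence`.
#' @export
fit_map <- function(dataset, init, tol = 1e-4, max_iter = 5000L) {
  stopifnot(inherits(dataset, "fit_dataset"), inherits(init, "synapse_params"))
  theta0 <- log(unlist(init[free_param_names]))
  obj <- function(lth) std_objective(exp(lth), dataset, init$p_max_vm,
                                     init$delta_jump)
  opt <- stats::optim(theta0, obj, method = "Nelder-Mead",
                      control = list(reltol = tol, maxit = max_iter))
  if (opt$convergence == 1L) {
    cond <- simpleError(sprintf(
      "MAP fit did not converge within %d iterations (best MSE %.3g)",
      max_iter, opt$value))
    cond$best_so_far <- exp(opt$par)
    stop(cond)
  }
  theta <- exp(opt$par)
  params <- synapse_params(
    tau_ca_ms = theta[1L], p_max_vm = init$p_max_vm, k_half = theta[2L],
    k_min_per_ms = theta[3L], delta_k_per_ms = theta[4L],
    k_r_half = theta[5L], delta_jump = init$delta_jump,
    label = init$label
  )
  list(params = params, mse = opt$value,
       iterations = unname(opt$counts[1L]), convergence = opt$convergence)
}

#' Adaptive-Metropolis posterior sampling
#'
#' Random-walk Metropolis over the 5 free log-parameters with a Gaussian
#' likelihood: observed values are modeled as the forward-model prediction
#' plus i.i.d. Normal(0, sigma^2) error. The error variance is Gibbs-
#' sampled from its conjugate inverse-gamma conditional under a weak
#' prior. Priors on the parameters are flat on the log scale within broad
#' bounds (a factor of 1000 either side of the start). After an initial
#' non-adaptive phase, the proposal covariance is adapted from the chain
#' history (scaled empirical covariance, 2.38^2/d, plus a small jitter).
#'
#' @param dataset A [assemble_fit_dataset()] result.
#' @param start A [synapse_params()] object, normally the [fit_map()]
#'   optimum; also supplies the fixed `p_max_vm` / `delta_jump`.
#' @param chain_length Number of MCMC iterations; lengths of
#'   50,000-150,000 are the intended operating range (shorter chains run
#'   with a warning).
#' @param seed RNG seed.
#' @param adapt_start Iteration at which covariance adaptation begins.
#' @param adapt_every Adaptation cadence, iterations.
#' @param sigma2_prior Weak inverse-gamma prior `(shape, rate)` on the
#'   error variance.
#' @return An object of class `posterior_result`: `chains` (matrix,
#'   iterations x 5 free parameters, natural scale), `sigma2` (error
#'   variance samples), `map_estimate` (the start), `acceptance_rate`,
#'   `chain_length`, `seed`, and the fixed parameters.
#' @export
run_mcmc <- function(dataset, start, chain_length = 50000L, seed = NULL,
                     adapt_start = 1000L, adapt_every = 100L,
                     sigma2_prior = c(shape = 1e-6, rate = 1e-6)) {
  stopifnot(inherits(dataset, "fit_dataset"), inherits(start, "synapse_params"))
  chain_length <- as.integer(chain_length)
  if (chain_length < 50000L) {
    warning(sprintf(
      "chain_length %d is below the intended 50,000-150,000 range", chain_length))
  }
  if (chain_length > 150000L) {
    warning(sprintf(
      "chain_length %d is above the intended 50,000-150,000 range", chain_length))
  }
  d <- 5L
  n_obs <- length(dataset$observed)
  pmax_fix <- start$p_max_vm
  jump_fix <- start$delta_jump
  lth0 <- log(unlist(start[free_param_names]))
  lo <- lth0 - log(1000)
  hi <- lth0 + log(1000)

  with_seed(seed, {
    chains <- matrix(NA_real_, chain_length, d,
                     dimnames = list(NULL, free_param_names))
    sigma2s <- numeric(chain_length)
    lth <- lth0
    pred <- predict_dataset(exp(lth), dataset, pmax_fix, jump_fix)
    sse <- sum((pred - dataset$observed)^2)
    sigma2 <- max(sse / n_obs, 1e-10)
    prop_chol <- chol(diag(rep(0.01^2, d)))
    n_acc <- 0L
    n_acc_window <- 0L

    for (i in seq_len(chain_length)) {
      prop <- lth + drop(stats::rnorm(d) %*% prop_chol)
      if (all(prop >= lo) && all(prop <= hi)) {
        pred_p <- predict_dataset(exp(prop), dataset, pmax_fix, jump_fix)
        if (!is.null(pred_p)) {
          sse_p <- sum((pred_p - dataset$observed)^2)
          log_alpha <- (sse - sse_p) / (2 * sigma2)
          if (log(stats::runif(1)) < log_alpha) {
            lth <- prop
            sse <- sse_p
            n_acc <- n_acc + 1L
            n_acc_window <- n_acc_window + 1L
          }
        }
      }
      # conjugate inverse-gamma Gibbs step for the error variance
      sigma2 <- 1 / stats::rgamma(1,
        shape = sigma2_prior[["shape"]] + n_obs / 2,
        rate = sigma2_prior[["rate"]] + sse / 2)
      chains[i, ] <- exp(lth)
      sigma2s[i] <- sigma2
      if (i %% adapt_every == 0L) {
        if (n_acc_window == 0L) {
          # nothing moved in this window: the proposal is far too wide
          # for the current error variance; shrink and retry
          prop_chol <- prop_chol * 0.5
        } else if (i >= adapt_start) {
          hist_cov <- stats::cov(log(chains[seq_len(i), , drop = FALSE]))
          adapted <- (2.38^2 / d) * hist_cov + diag(rep(1e-10, d))
          ch <- try(chol(adapted), silent = TRUE)
          if (!inherits(ch, "try-error")) prop_chol <- ch
        }
        n_acc_window <- 0L
      }
    }
    acc <- n_acc / chain_length
    if (acc < 0.01) {
      stop(sprintf(
        "MCMC acceptance rate %.4f after adaptation: sampler failed to mix",
        acc), call. = FALSE)
    }
    structure(
      list(chains = chains, sigma2 = sigma2s, map_estimate = start,
           acceptance_rate = acc, chain_length = chain_length, seed = seed,
           p_max_vm = pmax_fix, delta_jump = jump_fix),
      class = "posterior_result"
    )
  })
}

#' @export
print.posterior_result <- function(x, ...) {
  cat(sprintf(
    "<posterior_result> %d iterations, acceptance %.2f, %d free parameter(s)\n",
    x$chain_length, x$acceptance_rate, ncol(x$chains)))
  invisible(x)
}

#' Posterior summary in Table-1 form
#'
#' Post-burn-in posterior means and SDs per free parameter plus the
#' pairwise correlation matrix. The correlation between `k_r_half` and
#' `tau_ca_ms` is reported explicitly: these two parameters are
#' interdependent (a longer-lived calcium transient can trade off against
#' a recovery rate that saturates at higher calcium), which limits how
#' well either is constrained individually.
#'
#' @param result A [run_mcmc()] result.
#' @param burn_in_fraction Fraction of the chain discarded as burn-in.
#' @return A list with `summary` (data.frame `parameter`, `mean`, `sd`),
#'   `correlations` (matrix), `kr_tau_correlation`, `sigma2_mean`, and
#'   `n_samples`.
#' @export
posterior_summary <- function(result, burn_in_fraction = 0.2) {
  stopifnot(inherits(result, "posterior_result"),
            is_scalar_num(burn_in_fraction),
            burn_in_fraction >= 0, burn_in_fraction < 1)
  n <- nrow(result$chains)
  keep <- seq.int(floor(n * burn_in_fraction) + 1L, n)
  ch <- result$chains[keep, , drop = FALSE]
  summ <- data.frame(
    parameter = colnames(ch),
    mean = colMeans(ch),
    sd = apply(ch, 2L, stats::sd),
    row.names = NULL
  )
  corr <- suppressWarnings(stats::cor(ch))  # NA columns for frozen parameters
  list(
    summary = summ,
    correlations = corr,
    kr_tau_correlation = corr["k_r_half", "tau_ca_ms"],
    sigma2_mean = mean(result$sigma2[keep]),
    n_samples = length(keep)
  )
}

#' Write MCMC chains to CSV
#'
#' One column per free parameter plus `sigma2` (error variance).
#'
#' @param result A [run_mcmc()] result.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_chains_csv <- function(result, path) {
  stopifnot(inherits(result, "posterior_result"))
  df <- as.data.frame(result$chains)
  df$sigma2 <- result$sigma2
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
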