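# Shared fixtures and oracles, all built in code.

sh_params <- function() table1_params("SH")
hc_params <- function() table1_params("HC")

# Build an amplitude table whose per-pulse sample means and variances are
# exactly (m, v): 4 repeats at m +/- sqrt(3 v) / 2 have sample mean m and
# sample variance v.
table_with_moments <- function(means, vars, frequency_hz, cell_id = "exact") {
  s <- sqrt(3 * vars) / 2
  a <- rbind(means - s, means + s, means - s, means + s)
  amplitude_table(a, frequency_hz = frequency_hz, cell_id = cell_id)
}

# Population-averaged fitting dataset emulating the experimental design:
# `n_cells` cells, each with 7-repeat binomial trains at 5/10/20/50 Hz and
# recovery pairs, p_r averaged across cells.
make_population_dataset <- function(params, n_cells, n_sites, q_pa, seed) {
  intervals <- c(20, 50, 100, 500, 1000, 3000)
  prs <- vector("list", 4L)
  rec_p1 <- rec_p2 <- matrix(0, n_cells, length(intervals))
  for (ci in seq_len(n_cells)) {
    gt <- quantal_ground_truth(n_sites = n_sites, q_pa = q_pa)
    ex <- generate_experiment(params, gt, seed = seed * 1000L + ci)
    for (k in 1:4) {
      pr <- pr_series(ex$tables[[k]], n_sites, q_pa)
      prs[[k]] <- if (ci == 1L) pr else prs[[k]] + pr
    }
    rp <- recovery_pr(ex$recovery, n_sites, q_pa)
    rec_p1[ci, ] <- rp$p1
    rec_p2[ci, ] <- rp$p2
  }
  prs <- lapply(prs, function(x) pmin(x / n_cells, 1.2))
  assemble_fit_dataset(
    std_pr = prs, frequencies_hz = c(5, 10, 20, 50),
    recovery = data.frame(interval_ms = intervals,
                          p1 = pmin(colMeans(rec_p1), 1.2),
                          p2 = pmin(colMeans(rec_p2), 1.2))
  )
}

# Noiseless dataset: observed values are the model's own predictions.
make_noiseless_dataset <- function(params) {
  intervals <- c(20, 50, 100, 500, 1000, 3000)
  prs <- lapply(c(5, 10, 20, 50), function(f) {
    simulate_train(train_protocol(f, 20), params)$p_n
  })
  rec <- t(vapply(intervals, function(T) {
    simulate_train(paired_protocol(T), params)$p_n
  }, numeric(2L)))
  assemble_fit_dataset(
    std_pr = prs, frequencies_hz = c(5, 10, 20, 50),
    recovery = data.frame(interval_ms = intervals,
                          p1 = rec[, 1L], p2 = rec[, 2L])
  )
}

# Batch-means Monte-Carlo standard error of a chain's mean.
batch_mcse <- function(x, n_batches = 50L) {
  n <- length(x)
  bs <- floor(n / n_batches)
  bm <- vapply(seq_len(n_batches), function(b) {
    mean(x[((b - 1L) * bs + 1L):(b * bs)])
  }, 0.0)
  stats::sd(bm) / sqrt(n_batches)
}

# Continuous-time oracle for the two-state dynamics between pulses,
# integrated with deSolve; used only to check the closed-form map.
ode_propagate <- function(c0, r0, interval, params) {
  f <- function(t, y, p) {
    list(c(
      -y[1] / params$tau_ca_ms,
      (params$k_min_per_ms +
         params$delta_k_per_ms * y[1] / (y[1] + params$k_r_half)) * (1 - y[2])
    ))
  }
  out <- deSolve::lsoda(c(c0, r0), c(0, interval), f, parms = NULL,
                        rtol = 1e-10, atol = 1e-12)
  list(c = unname(out[2, 2]), r = unname(out[2, 3]))
}

random_params <- function() {
  synapse_params(
    tau_ca_ms = stats::runif(1, 5, 60),
    p_max_vm = stats::runif(1, 0.3, 1),
    k_half = stats::runif(1, 0.1, 3),
    k_min_per_ms = stats::runif(1, 1e-4, 5e-3),
    delta_k_per_ms = stats::runif(1, 0, 0.05),
    k_r_half = stats::runif(1, 0.05, 3),
    delta_jump = 1
  )
}
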