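#' Synapse model parameters
#'
#' The depletion/recovery model is fully parameterized by seven constants:
#' the presynaptic calcium decay time constant, the maximum release
#' probability (fixed from variance-mean analysis), the half-saturation
#' calcium of the release-probability function, the minimum (resting) rate
#' of recovery of release sites, the calcium-dependent increment of that
#' rate (k_max - k_min), the half-saturation calcium of the recovery-rate
#' function, and the per-stimulus calcium increment Delta (fixed to 1:
#' calcium is measured in units of the per-stimulus jump).
#'
#' @param tau_ca_ms Calcium decay time constant, ms (> 0).
#' @param p_max_vm Maximum release probability, dimensionless, in (0, 1].
#' @param k_half Half-saturation calcium of the release-probability
#'   function, normalized calcium units (> 0).
#' @param k_min_per_ms Minimum recovery rate of release sites, per ms (>= 0).
#' @param delta_k_per_ms Calcium-dependent span of the recovery rate,
#'   k_max - k_min, per ms (>= 0).
#' @param k_r_half Half-saturation calcium of the recovery-rate function,
#'   normalized calcium units (> 0).
#' @param delta_jump Per-stimulus calcium increment, normalized units
#'   (> 0; 1 by convention).
#' @param label Free-text synapse identity, e.g. "SH" or "HC".
#' @return An object of class `synapse_params` (a named list of the seven
#'   constants plus `label`).
#' @seealso [table1_params()] for the two fitted parameter sets shipped
#'   with the package, [simulate_train()] for the forward model.
#' @export
synapse_params <- function(tau_ca_ms, p_max_vm, k_half, k_min_per_ms,
                           delta_k_per_ms, k_r_half, delta_jump = 1,
                           label = "") {
  for (nm in c("tau_ca_ms", "p_max_vm", "k_half", "k_min_per_ms",
               "delta_k_per_ms", "k_r_half", "delta_jump")) {
    v <- get(nm)
    if (!is_scalar_num(v)) stop(sprintf("%s must be a finite scalar", nm), call. = FALSE)
  }
  if (tau_ca_ms <= 0) stop("tau_ca_ms must be > 0", call. = FALSE)
  if (k_half <= 0) stop("k_half must be > 0", call. = FALSE)
  if (k_r_half <= 0) stop("k_r_half must be > 0", call. = FALSE)
  if (p_max_vm <= 0 || p_max_vm > 1) stop("p_max_vm must be in (0, 1]", call. = FALSE)
  if (k_min_per_ms < 0) stop("k_min_per_ms must be >= 0", call. = FALSE)
  if (delta_k_per_ms < 0) stop("delta_k_per_ms must be >= 0", call. = FALSE)
  if (delta_jump <= 0) stop("delta_jump must be > 0", call. = FALSE)
  structure(
    list(
      tau_ca_ms = tau_ca_ms, p_max_vm = p_max_vm, k_half = k_half,
      k_min_per_ms = k_min_per_ms, delta_k_per_ms = delta_k_per_ms,
      k_r_half = k_r_half, delta_jump = delta_jump,
      label = as.character(label)[1L]
    ),
    class = "synapse_params"
  )
}

#' @export
print.synapse_params <- function(x, ...) {
  cat(sprintf("<synapse_params>%s\n",
              if (nzchar(x$label)) paste0(" ", x$label) else ""))
  cat(sprintf("  tau_Ca = %g ms, P_max = %g, K = %g\n",
              x$tau_ca_ms, x$p_max_vm, x$k_half))
  cat(sprintf("  k_min = %g /ms, delta_k = %g /ms, K_r = %g, Delta = %g\n",
              x$k_min_per_ms, x$delta_k_per_ms, x$k_r_half, x$delta_jump))
  invisible(x)
}

#' Fitted parameter sets for the two synapse types
#'
#' Posterior-mean parameter sets for the septohippocampal PV projection
#' synapse ("SH", PV neurons of the medial septum / diagonal band of Broca
#' onto hippocampal stratum oriens interneurons) and the local hippocampal
#' PV interneuron synapse ("HC"). Shipped as JSON under
#' `inst/extdata/params/` and read with [read_synapse_params()].
#'
#' @param which `"SH"` or `"HC"`.
#' @return A [synapse_params()] object.
#' @examples
#' sh <- table1_params("SH")
#' simulate_train(train_protocol(20, 2), sh)
#' @export
table1_params <- function(which = c("SH", "HC")) {
  which <- match.arg(which)
  path <- system.file("extdata", "params", paste0(which, ".json"),
                      package = "synstd", mustWork = TRUE)
  read_synapse_params(path)
}

#' Fold differences between two fitted parameter sets
#'
#' Tabulates the ratio of each kinetic constant between two synapse models
#' (first relative to second), the standard way the two synapse types are
#' compared: e.g. a ~6-fold larger K_r at the septohippocampal synapse
#' means its recovery rate needs much more residual calcium to saturate.
#'
#' @param a,b [synapse_params()] objects; folds are `a / b`.
#' @return A data.frame with columns `parameter`, `a`, `b`, `fold`.
#' @examples
#' fold_change_table(table1_params("SH"), table1_params("HC"))
#' @export
fold_change_table <- function(a, b) {
  stopifnot(inherits(a, "synapse_params"), inherits(b, "synapse_params"))
  fields <- c(tau_ca_ms = "tau_Ca", p_max_vm = "P_max", k_half = "K",
              k_min_per_ms = "k_min", delta_k_per_ms = "delta_k",
              k_r_half = "K_r")
  av <- unlist(a[names(fields)])
  bv <- unlist(b[names(fields)])
  data.frame(
    parameter = unname(fields),
    a = unname(av),
    b = unname(bv),
    fold = unname(av / bv),
    row.names = NULL,
    stringsAsFactors = FALSE
  )
}

#' Read / write synapse parameters as JSON
#'
#' The JSON schema uses keys `tau_ca_ms`, `p_max_vm`, `k_half`,
#' `k_min_per_ms`, `delta_k_per_ms`, `k_r_half`, `delta_jump`, `label`.
#'
#' @param path File path.
#' @return `read_synapse_params()` returns a [synapse_params()] object;
#'   `write_synapse_params()` returns `path` invisibly.
#' @export
read_synapse_params <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  required <- c("tau_ca_ms", "p_max_vm", "k_half", "k_min_per_ms",
                "delta_k_per_ms", "k_r_half", "delta_jump")
  missing <- setdiff(required, names(x))
  if (length(missing) > 0L) {
    stop(sprintf("parameter JSON is missing key(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  synapse_params(
    tau_ca_ms = x$tau_ca_ms, p_max_vm = x$p_max_vm, k_half = x$k_half,
    k_min_per_ms = x$k_min_per_ms, delta_k_per_ms = x$delta_k_per_ms,
    k_r_half = x$k_r_half, delta_jump = x$delta_jump,
    label = if (is.null(x$label)) "" else x$label
  )
}

#' @rdname read_synapse_params
#' @param params A [synapse_params()] object.
#' @export
write_synapse_params <- function(params, path) {
  stopifnot(inherits(params, "synapse_params"))
  jsonlite::write_json(unclass(params), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
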