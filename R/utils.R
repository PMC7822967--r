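# Internal helpers shared across modules.

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's RNG afterwards. `seed = NULL` leaves the RNG alone.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(as.integer(seed))
  expr
}

stop_missing_cols <- function(df, required, what) {
  missing <- setdiff(required, names(df))
  if (length(missing) > 0L) {
    stop(sprintf(
      "%s is missing required column(s): %s",
      what, paste(missing, collapse = ", ")
    ), call. = FALSE)
  }
  invisible(df)
}

is_scalar_num <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
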