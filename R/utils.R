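# Classed conditions so callers can distinguish user errors from I/O or
# format problems programmatically.
stop_confland <- function(msg, class, call. = FALSE) {
  stop(errorCondition(msg, class = c(class, "confland_error", "error", "condition")))
}

abort_format    <- function(msg) stop_confland(msg, "confland_format_error")
abort_argument  <- function(msg) stop_confland(msg, "confland_argument_error")
abort_io        <- function(msg) stop_confland(msg, "confland_io_error")
abort_selection <- function(msg) stop_confland(msg, "confland_selection_error")
abort_config    <- function(msg) stop_confland(msg, "confland_config_error")
abort_predictor <- function(msg) stop_confland(msg, "confland_predictor_error")

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else suppressWarnings(rm(".Random.seed", envir = env))
  }, add = TRUE)
  set.seed(seed)
  force(code)
}

# Deterministic per-job seed below 2^31, derived from a user seed and a
# cluster label.
derive_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 7919 + as.numeric(k) * 104729) %% 2147483647)
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

is_count <- function(x, min = 0L) {
  is.numeric(x) && length(x) == 1L && !is.na(x) && x >= min && x == floor(x)
}
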