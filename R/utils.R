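# Shared internal helpers: classed error conditions, seed handling,
# half-up rounding for reported percentages.

voc_stop <- function(msg, class, call. = FALSE) {
  stop(errorCondition(msg, class = c(class, "voc_error")))
}

stop_io        <- function(msg) voc_stop(msg, "voc_io_error")
stop_format    <- function(msg) voc_stop(msg, "voc_format_error")
stop_bounds    <- function(msg) voc_stop(msg, "voc_bounds_error")
stop_argument  <- function(msg) voc_stop(msg, "voc_argument_error")
stop_degenerate<- function(msg) voc_stop(msg, "voc_degenerate_error")
stop_config    <- function(msg) voc_stop(msg, "voc_config_error")

#' Evaluate code with a temporary RNG seed
#'
#' Runs `code` with the global random-number state set from `seed`, then
#' restores whatever state existed before, so library code never perturbs a
#' caller's random stream.
#'
#' @param seed Integer seed.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = env)
    } else if (exists(".Random.seed", envir = env, inherits = FALSE)) {
      rm(".Random.seed", envir = env)
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

# One user-facing seed expands into independent sub-seeds for the named
# random decisions (balancing, fold shuffling, classifier training, ...),
# so adding a consumer never shifts the stream of another.
derive_seeds <- function(seed, n) {
  with_seed(seed, sample.int(2147483646L, n))
}

# round() uses banker's rounding; reported percentages use conventional
# half-up rounding (e.g. 59.0909... -> 59.1).
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

is_count <- function(x, min = 0L) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x == as.integer(x) && x >= min
}

is_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

check_binary_labels <- function(labels) {
  if (!all(labels %in% c(0, 1))) {
    stop_argument("labels must be binary (0/1)")
  }
  as.integer(labels)
}
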