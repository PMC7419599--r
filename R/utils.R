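#' @importFrom rlang %||%
#' @importFrom stats coef lm pf pchisq pt sd setNames t.test var
#' @importFrom utils head tail
NULL

# Internal argument checks -----------------------------------------------

abort_config <- function(msg) {
  stop(structure(
    class = c("postprime_config_error", "error", "condition"),
    list(message = msg, call = NULL)
  ))
}

abort_data <- function(msg) {
  stop(structure(
    class = c("postprime_data_error", "error", "condition"),
    list(message = msg, call = NULL)
  ))
}

check_scalar_number <- function(x, name, positive = FALSE, integerish = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    abort_config(sprintf("`%s` must be a single finite number", name))
  if (positive && x <= 0)
    abort_config(sprintf("`%s` must be positive", name))
  if (integerish && abs(x - round(x)) > 1e-8)
    abort_config(sprintf("`%s` must be a whole number", name))
  invisible(x)
}

# Counter-based seed expansion: one master seed deterministically spawns an
# independent stream per (participant, condition, trial) so single trials can
# be regenerated without replaying the whole cohort.
derive_seed <- function(master, ...) {
  idx <- c(...)
  h <- as.double(master) %% 2147483647
  for (k in idx) {
    h <- (h * 48271 + as.double(k) * 10007 + 12345) %% 2147483647
  }
  as.integer(h)
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Reflect-pad a numeric vector by `n` samples at each end.
reflect_pad <- function(x, n) {
  len <- length(x)
  n <- min(n, len - 1L)
  if (n <= 0L) return(list(x = x, n = 0L))
  list(x = c(x[(n + 1L):2L], x, x[(len - 1L):(len - n)]), n = n)
}
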