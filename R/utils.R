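## internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

## round half away from zero (base round() is round-half-even)
round_half_up <- function(x) floor(x + 0.5)

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

## uniform-spacing check with a tolerance proportional to the step
is_uniform_ascending <- function(x, step = NULL, tol = 1e-6) {
  if (length(x) < 2L) return(TRUE)
  d <- diff(x)
  if (any(d <= 0)) return(FALSE)
  if (is.null(step)) step <- d[1L]
  all(abs(d - step) < tol * max(1, abs(step)))
}

## derive a stream of child seeds from one integer seed, staying < 2^31
derive_seeds <- function(seed, n) {
  (as.integer(seed) + 104729L * seq_len(n)) %% 2147483647L
}

log_msg <- function(module, event, ..., verbose = TRUE, logfile = NULL) {
  if (!verbose && is.null(logfile)) return(invisible(NULL))
  line <- sprintf("%s [%s] %s", format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
                  module, sprintf(event, ...))
  if (verbose) message(line)
  if (!is.null(logfile)) cat(line, "\n", sep = "", file = logfile, append = TRUE)
  invisible(NULL)
}
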