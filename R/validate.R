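# Internal validation helpers: collect human-readable problems and fail once
# with an aggregated report, so configuration errors surface together.

new_problems <- function() new.env(parent = emptyenv())

add_problem <- function(env, fmt, ...) {
  msg <- sprintf(fmt, ...)
  env$problems <- c(env$problems, msg)
  invisible(NULL)
}

report_problems <- function(env, context) {
  if (length(env$problems)) {
    stop(sprintf("%s: %d problem(s) found:\n%s", context, length(env$problems),
                 paste0("  - ", env$problems, collapse = "\n")), call. = FALSE)
  }
  invisible(TRUE)
}

check_scalar <- function(x, name, min = -Inf, strict = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x))
    stop(sprintf("'%s' must be a single non-NA number", name), call. = FALSE)
  if (strict && x <= min)
    stop(sprintf("'%s' must be > %g (got %g)", name, min, x), call. = FALSE)
  if (!strict && x < min)
    stop(sprintf("'%s' must be >= %g (got %g)", name, min, x), call. = FALSE)
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
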