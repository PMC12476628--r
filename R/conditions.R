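# Classed conditions so callers (and the CLI) can dispatch on failure mode.
# Every error carries class c(<specific>, "cardioquantError", "error").

cqStop <- function(class, message, ...) {
  cond <- structure(
    class = c(class, "cardioquantError", "error", "condition"),
    list(message = message, call = sys.call(-1), ...)
  )
  stop(cond)
}

cqWarn <- function(class, message, ...) {
  cond <- structure(
    class = c(class, "cardioquantWarning", "warning", "condition"),
    list(message = message, call = sys.call(-1), ...)
  )
  warning(cond)
}
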