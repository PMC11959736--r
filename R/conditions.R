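# Typed conditions so callers can distinguish bad input from degenerate
# statistics (e.g. zero-variance ratings) without string-matching messages.

stop_rfstab <- function(msg, class, call. = FALSE, ...) {
  cond <- structure(
    class = c(class, "rfstab_error", "error", "condition"),
    list(message = msg, call = if (call.) sys.call(-1) else NULL, ...)
  )
  stop(cond)
}

stop_input <- function(msg, ...) stop_rfstab(msg, "rfstab_input_error", ...)
stop_schema <- function(msg, ...) stop_rfstab(msg, "rfstab_schema_error", ...)

# Stability is undefined when the ratings matrix carries no information
# (all cells identical, or expected agreement is already 1).
stop_undefined_stability <- function(msg, ...) {
  stop_rfstab(msg, "rfstab_undefined_stability", ...)
}

stop_fit <- function(msg, ...) stop_rfstab(msg, "rfstab_fit_error", ...)
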