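# Error constructors. Every user-facing failure carries a class under
# "firegrade_error" so callers (and the CLI) can branch on the kind of
# failure instead of matching message strings.

fg_stop <- function(msg, class, ...) {
  stop(errorCondition(msg, ..., class = c(class, "firegrade_error", "error")))
}

fg_validate <- function(ok, msg) {
  if (!isTRUE(ok)) fg_stop(msg, "firegrade_validation_error")
  invisible(TRUE)
}

# scalar finite numeric check used by the index functions
check_scalar <- function(x, name) {
  if (!is.numeric(x) || length(x) < 1L || anyNA(x) || any(!is.finite(x))) {
    fg_stop(sprintf("`%s` must be finite numeric", name),
            "firegrade_validation_error")
  }
  invisible(TRUE)
}
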