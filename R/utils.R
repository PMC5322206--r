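# Internal helpers shared across modules.

# Signal a classed error so callers can condition on failure modes
# (e.g. "ep_insufficient_data") rather than matching message text.
ep_stop <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "eccperiod_error")))
}

ep_warn <- function(msg, class) {
  warning(warningCondition(msg, class = c(class, "eccperiod_warning")))
}

# scalar numeric check
is_num1 <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

deg2rad <- function(deg) deg * pi / 180
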