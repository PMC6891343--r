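# Classed conditions so callers (and tests) can discriminate failure modes.

leafthz_error <- function(msg, class, call = sys.call(-1)) {
  stop(structure(
    class = c(class, "leafthz_error", "error", "condition"),
    list(message = msg, call = call)
  ))
}

leafthz_warning <- function(msg, class) {
  warning(structure(
    class = c(class, "leafthz_warning", "warning", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

check_positive <- function(x, name, class = "leafthz_domain_error") {
  if (length(x) == 0 || anyNA(x) || any(!is.finite(x)) || any(x <= 0)) {
    leafthz_error(sprintf("`%s` must be finite and strictly positive", name),
                  class)
  }
  invisible(x)
}
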