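# Typed error conditions.  Every validation failure raised by the package
# carries a specific class under the "propsel_error" umbrella so callers
# (and the test suite) can distinguish failure modes.

psel_abort <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "propsel_error")))
}

abort_shape        <- function(msg) psel_abort(msg, "propsel_shape_error")
abort_frame        <- function(msg) psel_abort(msg, "propsel_frame_error")
abort_alphabet     <- function(msg) psel_abort(msg, "propsel_alphabet_error")
abort_label        <- function(msg) psel_abort(msg, "propsel_label_error")
abort_parse        <- function(msg) psel_abort(msg, "propsel_parse_error")
abort_completeness <- function(msg) psel_abort(msg, "propsel_completeness_error")
abort_value        <- function(msg) psel_abort(msg, "propsel_value_error")
abort_lookup       <- function(msg) psel_abort(msg, "propsel_lookup_error")
abort_degenerate   <- function(msg) psel_abort(msg, "propsel_degenerate_error")
abort_config       <- function(msg) psel_abort(msg, "propsel_config_error")
abort_site_frame   <- function(msg) psel_abort(msg, "propsel_site_frame_error")
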