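# Classed conditions so callers can trap specific pipeline failures.

fab_abort <- function(class, message, ...) {
  stop(structure(
    class = c(class, "fab_error", "error", "condition"),
    list(message = message, call = sys.call(-1), ...)
  ))
}

#' @keywords internal
parse_error <- function(msg) fab_abort("parse_error", msg)
missing_chain_error <- function(msg) fab_abort("missing_chain_error", msg)
discontinuity_error <- function(msg, gaps = NULL)
  fab_abort("discontinuity_error", msg, gaps = gaps)
span_error <- function(msg) fab_abort("span_error", msg)
shape_error <- function(msg) fab_abort("shape_error", msg)
degenerate_error <- function(msg) fab_abort("degenerate_error", msg)
anchor_not_found_error <- function(msg, anchor = NULL)
  fab_abort("anchor_not_found_error", msg, anchor = anchor)
anchor_identity_error <- function(msg) fab_abort("anchor_identity_error", msg)
anchor_mismatch_error <- function(msg) fab_abort("anchor_mismatch_error", msg)
empty_span_error <- function(msg) fab_abort("empty_span_error", msg)
pairing_error <- function(msg) fab_abort("pairing_error", msg)
spec_error <- function(msg) fab_abort("spec_error", msg)
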