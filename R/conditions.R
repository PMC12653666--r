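# Typed conditions so batch drivers and the command-line wrapper can triage
# failures (input/dialect problems vs analyzable-but-degenerate traces)
# without parsing message strings.

pk_stop <- function(message, class, data = list()) {
  stop(structure(
    class = c(class, "pendknee_error", "error", "condition"),
    list(message = message, call = sys.call(-1), data = data)
  ))
}

pk_warn <- function(message, class) {
  warning(structure(
    class = c(class, "pendknee_warning", "warning", "condition"),
    list(message = message, call = sys.call(-1))
  ))
}

#' Retrieve partial results attached to a pendknee condition
#'
#' Degenerate analyses (for example an overdamped trace with no second
#' swing) signal typed errors that carry whatever landmarks could still be
#' measured. `pk_condition_data()` extracts that payload from a caught
#' condition.
#'
#' @param cond A condition object caught from a pendknee operation.
#' @return The condition's data list (possibly empty).
#' @export
pk_condition_data <- function(cond) {
  if (!is.null(cond$data)) cond$data else list()
}
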