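# ---------------------------------------------------------------------------
# EC behavior transitions: change the micro-environment around a settled
# cell and follow the dynamics into the new attractor.
# ---------------------------------------------------------------------------

#' Simulate an EC behavior transition after a micro-environment change
#'
#' Starting from a state of an attractor (a settled cell), the input bits are
#' overwritten with the new micro-environment while every internal variable
#' keeps its value; the synchronous dynamics are then iterated until a new
#' attractor is reached.
#'
#' @param net A `boolean_network` with declared inputs.
#' @param start A full network state, normally taken from an attractor of the
#'   previous behavior.
#' @param new_env The new micro-environment (named 0/1 vector over the
#'   inputs, or an integer code).
#' @param check_start `"error"` (default), `"warn"` or `"none"`: what to do
#'   when `start` is not a state of an attractor of its own environment.
#' @return A list of class `ec_transition`: `attractor` (the new
#'   `bn_attractor`), `behavior` (its label), `transient` (steps needed) and
#'   `trajectory` (matrix of visited states).
#' @examples
#' \donttest{
#' net <- angiogenesis_network()
#' refs <- reference_environments(net)
#' ph <- iterate_to_attractor(net, network_state(net), )  # not run
#' }
#' @export
behavior_transition <- function(net, start, new_env,
                                check_start = c("error", "warn", "none")) {
  check_start <- match.arg(check_start)
  s <- as_state(net, start)
  if (check_start != "none") {
    r0 <- iterate_to_attractor(net, s)
    if (r0$transient != 0L) {
      msg <- "start state is not part of an attractor of its own environment"
      if (check_start == "error") abort(msg) else warn(msg)
    }
  }
  if (is.numeric(new_env) && length(new_env) == 1L && is.null(names(new_env))) {
    new_env <- micro_environment(net, code = new_env)
  }
  bad <- setdiff(names(new_env), net$inputs)
  if (length(bad) > 0) abort(sprintf("'%s' is not an input node", bad[1]))
  s[names(new_env)] <- as.integer(new_env)
  r <- iterate_to_attractor(net, s, keep_trajectory = TRUE)
  structure(
    list(attractor = r$attractor,
         behavior = classify_attractor(r$attractor),
         transient = r$transient,
         trajectory = r$trajectory,
         new_env = new_env),
    class = "ec_transition")
}

#' @export
print.ec_transition <- function(x, ...) {
  cat(sprintf("EC behavior transition -> %s (attractor length %d, transient %d steps)\n",
              x$behavior, x$attractor$length, x$transient))
  invisible(x)
}

#' Tidy a transition trajectory
#' @param x An `ec_transition`.
#' @param ... Unused.
#' @return Tibble with `step`, `state` (0/1 string) and the state-level
#'   behavior label along the trajectory.
#' @export
tidy.ec_transition <- function(x, ...) {
  tr <- x$trajectory
  tibble(
    step = seq_len(nrow(tr)) - 1L,
    state = apply(tr, 1, paste, collapse = ""),
    label = apply(tr, 1, classify_state))
}
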