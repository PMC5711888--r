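# ---------------------------------------------------------------------------
# Network states and the synchronous update map.
#
# A state is a named integer vector of 0/1 over the network's nodes, in node
# order.  The plain-R evaluator here is the package's reference semantics;
# analysis functions use the compiled engine, and the test suite checks the
# two against each other.
# ---------------------------------------------------------------------------

#' Construct a network state
#'
#' @param net A `boolean_network`.
#' @param ... Named node values (0/1); unnamed nodes default to `default`.
#' @param default Fill value for unspecified nodes (default 0).
#' @return Named integer vector over all nodes, in node order.
#' @examples
#' net <- boolean_network(list(A = "!B", B = "A"))
#' network_state(net, A = 1)
#' @export
network_state <- function(net, ..., default = 0L) {
  vals <- c(...)
  s <- rep(as.integer(default), length(net$nodes))
  names(s) <- net$nodes
  if (length(vals) > 0) {
    bad <- setdiff(names(vals), net$nodes)
    if (length(bad) > 0) abort(sprintf("unknown node '%s'", bad[1]))
    s[names(vals)] <- as.integer(vals)
  }
  if (!all(s %in% c(0L, 1L))) abort("state values must be 0 or 1")
  s
}

as_state <- function(net, state) {
  n <- length(net$nodes)
  if (is.character(state) && length(state) == 1L && nchar(state) == n) {
    s <- as.integer(strsplit(state, "")[[1]])
  } else if (length(state) == n) {
    s <- as.integer(state)
    if (!is.null(names(state)) && !identical(names(state), net$nodes)) {
      if (!setequal(names(state), net$nodes)) abort("state names do not match nodes")
      s <- as.integer(state[net$nodes])
    }
  } else {
    abort(sprintf("state must have one value per node (%d)", n))
  }
  if (anyNA(s) || !all(s %in% c(0L, 1L))) abort("state values must be 0 or 1")
  names(s) <- net$nodes
  s
}

state_string <- function(state) paste(state, collapse = "")

#' Evaluate a Boolean expression on a state
#'
#' Standard Boolean semantics; every referenced node must be assigned.
#'
#' @param expr An expression AST (or rule text).
#' @param state Named 0/1 vector.
#' @return 0 or 1.
#' @examples
#' evaluate_expression("A & !B", c(A = 1, B = 0))
#' @export
evaluate_expression <- function(expr, state) {
  if (is.character(expr)) expr <- parse_expression(expr)
  ev <- function(e) {
    switch(e$op,
      var = {
        if (!e$name %in% names(state) || is.na(state[[e$name]])) {
          abort(sprintf("node '%s' is not assigned", e$name))
        }
        as.integer(state[[e$name]])
      },
      const = e$value,
      not = 1L - ev(e$x),
      and = { for (a in e$args) if (ev(a) == 0L) return(0L); 1L },
      or = { for (a in e$args) if (ev(a) == 1L) return(1L); 0L })
  }
  ev(expr)
}

#' Synchronous update step
#'
#' Every component of the successor is computed from the same frozen
#' pre-update state; input nodes keep their values through their self-loops.
#'
#' @param net A `boolean_network`.
#' @param state A state (named 0/1 vector, plain vector in node order, or a
#'   0/1 string).
#' @param engine `"cpp"` (compiled, networks up to 64 nodes) or `"r"` (the
#'   plain-R reference evaluator).
#' @return The successor state, a named 0/1 vector.
#' @examples
#' net <- boolean_network(list(A = "!B", B = "A"))
#' synchronous_step(net, c(A = 1, B = 0))
#' @export
synchronous_step <- function(net, state, engine = c("cpp", "r")) {
  engine <- match.arg(engine)
  s <- as_state(net, state)
  if (engine == "cpp" && length(net$nodes) <= 64) {
    out <- .cpp_step(compile_program(net), length(net$nodes), unname(s))
  } else {
    out <- vapply(net$rules, function(r) evaluate_expression(r, s), 0L)
  }
  names(out) <- net$nodes
  out
}
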