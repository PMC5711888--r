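# ---------------------------------------------------------------------------
# Attractor-preserving network simplification: removal of fixed inputs,
# iterative removal of output nodes, and edge contraction of intermediary
# nodes.  Every operator returns the reduced network together with a replay
# log.
# ---------------------------------------------------------------------------

new_reduction_log <- function(steps = list()) {
  structure(list(steps = steps), class = "reduction_log")
}

#' @export
print.reduction_log <- function(x, ...) {
  cat(sprintf("Reduction log: %d step(s)\n", length(x$steps)))
  for (s in x$steps) {
    cat("  ", switch(s$op,
      removed_input = sprintf("removed input %s (fixed to %d)", s$node, s$value),
      removed_output = sprintf("removed output %s", s$node),
      contracted = sprintf("contracted %s into %s", s$node, s$into)), "\n")
  }
  invisible(x)
}

#' Tidy a reduction log
#' @param x A `reduction_log`.
#' @param ... Unused.
#' @return Tibble with one row per operation.
#' @export
tidy.reduction_log <- function(x, ...) {
  dplyr::bind_rows(lapply(x$steps, function(s) {
    tibble(op = s$op, node = s$node,
           value = if (!is.null(s$value)) s$value else NA_integer_,
           into = if (!is.null(s$into)) s$into else NA_character_)
  }))
}

# substitute an expression for a variable inside an AST, with constant folding
substitute_node <- function(expr, node, replacement) {
  sub <- function(e) {
    switch(e$op,
      var = if (e$name == node) replacement else e,
      const = e,
      not = {
        x <- sub(e$x)
        if (x$op == "const") bx_const(1L - x$value) else bx_not(x)
      },
      {
        args <- lapply(e$args, sub)
        absorb <- if (e$op == "and") 0L else 1L
        if (any(vapply(args, function(a) a$op == "const" && a$value == absorb, TRUE))) {
          return(bx_const(absorb))
        }
        args <- args[!vapply(args, function(a) a$op == "const", TRUE)]
        if (length(args) == 0) return(bx_const(1L - absorb))
        if (length(args) == 1) return(args[[1]])
        list(op = e$op, args = args)
      })
  }
  sub(expr)
}

#' Remove input nodes fixed to a constant
#'
#' Deletes each named input node and substitutes its constant into all rules
#' (constant folding only, no other simplification).  Attractors of the
#' reduced network correspond to attractors of the original restricted to
#' the fixed input values, projected onto the surviving nodes.
#'
#' @param net A `boolean_network`.
#' @param assignments Named 0/1 vector over input (self-loop) nodes.
#' @return List with `net` (reduced) and `log` (a `reduction_log`).
#' @examples
#' net <- boolean_network(list(A = "A", B = "A & C", C = "C"),
#'                        inputs = c("A", "C"))
#' remove_constant_inputs(net, c(A = 1))$net
#' @export
remove_constant_inputs <- function(net, assignments) {
  bad <- setdiff(names(assignments), net$nodes)
  if (length(bad) > 0) abort(sprintf("unknown node '%s'", bad[1]))
  for (nm in names(assignments)) {
    r <- net$rules[[nm]]
    if (!(identical(r$op, "var") && identical(r$name, nm))) {
      abort(sprintf("'%s' is not an input (self-loop) node", nm))
    }
  }
  rules <- net$rules
  steps <- list()
  for (nm in names(assignments)) {
    v <- as.integer(assignments[[nm]])
    rules[[nm]] <- NULL
    rules <- lapply(rules, substitute_node, node = nm,
                    replacement = bx_const(v))
    steps[[length(steps) + 1L]] <- list(op = "removed_input", node = nm, value = v)
  }
  list(net = boolean_network(rules,
                             inputs = setdiff(net$inputs, names(assignments))),
       log = new_reduction_log(steps))
}

node_out_degree <- function(net) {
  refs <- unlist(lapply(net$rules, expression_support))
  vapply(net$nodes, function(nm) sum(refs == nm), 0L)
}

#' Iteratively remove output nodes
#'
#' Deletes nodes with out-degree zero (no rule references them) until none
#' remain; the projection of the original attractors onto the surviving
#' nodes equals the attractors of the reduced network.
#'
#' @param net A `boolean_network`.
#' @return List with `net` and `log`.
#' @examples
#' remove_outputs(boolean_network(list(A = "A", B = "A")))$net
#' @export
remove_outputs <- function(net) {
  rules <- net$rules
  inputs <- net$inputs
  steps <- list()
  repeat {
    nodes <- names(rules)
    refs <- unlist(lapply(rules, function(r) expression_support(r)))
    sinks <- setdiff(nodes, refs)
    if (length(sinks) == 0) break
    if (length(sinks) == length(nodes)) break  # keep a non-empty network
    for (nm in sinks) {
      rules[[nm]] <- NULL
      steps[[length(steps) + 1L]] <- list(op = "removed_output", node = nm)
    }
    inputs <- setdiff(inputs, sinks)
  }
  list(net = boolean_network(rules, inputs = inputs),
       log = new_reduction_log(steps))
}

#' Contract intermediary nodes by edge contraction
#'
#' Repeatedly eliminates a non-protected node with in-degree or out-degree
#' one by inline substitution: a node `v` regulated only by `u` relays `u`
#' (possibly negated) and is replaced by `u` with the relay's polarity in
#' every rule that reads `v`; a node `u` whose only reader is `v` is inlined
#' by substituting `f_u` for `u` in `f_v`.  Contractions that would create a
#' self-loop are skipped, nodes are processed in declaration order, and the
#' pass repeats until no eligible node remains.  Under the synchronous
#' update the contraction preserves fixed points exactly; cyclic attractors
#' keep their existence but may change period (inlining removes one step of
#' delay), which is why contraction is a modeling aid rather than a
#' dynamics-preserving transform.
#'
#' @param net A `boolean_network`.
#' @param protected Character vector of nodes never contracted (the bundled
#'   model protects transcription factors); declared inputs are always
#'   protected.
#' @return List with `net` and `log`.
#' @examples
#' net <- boolean_network(list(A = "A", B = "A", C = "B"))
#' contract_intermediaries(net, protected = c("A", "C"))$net
#' @export
contract_intermediaries <- function(net, protected = character()) {
  rules <- net$rules
  inputs <- net$inputs
  protected <- union(protected, inputs)
  steps <- list()
  repeat {
    nodes <- names(rules)
    supports <- lapply(rules, expression_support)
    indeg <- vapply(supports, length, 0L)
    readers <- lapply(nodes, function(nm) {
      nodes[vapply(supports, function(s) nm %in% s, TRUE)]
    })
    names(readers) <- nodes
    outdeg <- vapply(readers, length, 0L)
    done <- TRUE
    for (nm in nodes) {
      if (nm %in% protected) next
      sup <- supports[[nm]]
      # pure relay: exactly one regulator -> replace nm by (possibly negated)
      # regulator everywhere
      if (indeg[[nm]] == 1L && outdeg[[nm]] >= 1L) {
        reg <- sup[1]
        if (reg == nm) next                     # self-loop, not a relay
        r <- rules[[nm]]
        repl <- if (identical(r$op, "var")) bx_var(reg)
                else if (identical(r$op, "not") && identical(r$x$op, "var")) bx_not(bx_var(reg))
                else NULL                        # single regulator, complex rule
        if (is.null(repl)) repl <- r             # substitute the whole rule
        if (nm %in% readers[[nm]]) next
        rules[[nm]] <- NULL
        rules <- lapply(rules, substitute_node, node = nm, replacement = repl)
        steps[[length(steps) + 1L]] <- list(op = "contracted", node = nm, into = reg)
        done <- FALSE
        break
      }
      # single reader: substitute f_nm into the reader's rule
      if (outdeg[[nm]] == 1L && indeg[[nm]] >= 1L) {
        reader <- readers[[nm]][1]
        if (reader == nm) next
        if (nm %in% supports[[nm]]) next         # own rule reads itself
        if (reader %in% expression_support(rules[[nm]])) next  # would self-loop
        rules[[reader]] <- substitute_node(rules[[reader]], nm, rules[[nm]])
        rules[[nm]] <- NULL
        steps[[length(steps) + 1L]] <- list(op = "contracted", node = nm, into = reader)
        done <- FALSE
        break
      }
    }
    if (done) break
  }
  list(net = boolean_network(rules, inputs = intersect(inputs, names(rules))),
       log = new_reduction_log(steps))
}

#' Replay a reduction log
#'
#' Applies the recorded operations to a network, reproducing the reduced
#' network bit for bit.
#'
#' @param net The original `boolean_network`.
#' @param log A `reduction_log`.
#' @return The reduced `boolean_network`.
#' @export
replay_reduction <- function(net, log) {
  rules <- net$rules
  inputs <- net$inputs
  for (s in log$steps) {
    if (s$op == "removed_input") {
      rules[[s$node]] <- NULL
      rules <- lapply(rules, substitute_node, node = s$node,
                      replacement = bx_const(s$value))
      inputs <- setdiff(inputs, s$node)
    } else if (s$op == "removed_output") {
      rules[[s$node]] <- NULL
      inputs <- setdiff(inputs, s$node)
    } else {
      r <- rules[[s$node]]
      sup <- expression_support(r)
      # relay contraction recorded "into = regulator"; inline contraction
      # recorded "into = reader" -- distinguish by where the node appears
      if (s$into %in% sup || identical(r$op, "var") ||
          (identical(r$op, "not") && identical(r$x$op, "var"))) {
        repl <- if (identical(r$op, "var")) bx_var(s$into)
                else if (identical(r$op, "not") && identical(r$x$op, "var")) bx_not(bx_var(s$into))
                else r
        rules[[s$node]] <- NULL
        rules <- lapply(rules, substitute_node, node = s$node, replacement = repl)
      } else {
        rules[[s$into]] <- substitute_node(rules[[s$into]], s$node, r)
        rules[[s$node]] <- NULL
      }
      inputs <- setdiff(inputs, s$node)
    }
  }
  boolean_network(rules, inputs = inputs)
}
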