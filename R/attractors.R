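# ---------------------------------------------------------------------------
# Exact attractor computation.
#
# An attractor is a set of states closed and minimal under the synchronous
# update map, stored as the cyclic state sequence rotated to start at the
# minimum state under the fixed bit-order comparison (node 1 = lowest bit).
# ---------------------------------------------------------------------------

new_attractor <- function(states_matrix, nodes) {
  colnames(states_matrix) <- nodes
  structure(list(states = states_matrix, length = nrow(states_matrix)),
            class = "bn_attractor")
}

#' @export
print.bn_attractor <- function(x, ...) {
  kind <- if (x$length == 1L) "fixed point" else sprintf("cycle of length %d", x$length)
  cat(sprintf("Attractor (%s)\n", kind))
  active <- colnames(x$states)[colSums(x$states) == x$length]
  cat("always active:", if (length(active)) paste(active, collapse = ", ") else "(none)", "\n")
  if (x$length > 1) {
    osc <- colnames(x$states)[colSums(x$states) %in% seq_len(x$length - 1L)]
    cat("oscillating:", if (length(osc)) paste(osc, collapse = ", ") else "(none)", "\n")
  }
  invisible(x)
}

#' Tidy an attractor into a long state table
#' @param x A `bn_attractor`.
#' @param ... Unused.
#' @return Tibble with columns `step`, `node`, `value`.
#' @export
tidy.bn_attractor <- function(x, ...) {
  tibble(
    step = rep(seq_len(x$length), each = ncol(x$states)),
    node = rep(colnames(x$states), x$length),
    value = as.integer(t(x$states)))
}

#' Stable identifier of an attractor
#'
#' A digest of the canonical rotation's 0/1 state strings, stable across runs
#' and discovery orders.
#' @param a A `bn_attractor`.
#' @return Character scalar.
#' @export
attractor_id <- function(a) {
  txt <- paste(apply(a$states, 1, paste, collapse = ""), collapse = ";")
  # FNV-1a, folded to 16 hex digits; plain R so the id is engine-independent
  h <- 0
  for (ch in utf8ToInt(txt)) {
    h <- bitwXor(h, ch)
    lo <- h %% 65536; hi <- h %/% 65536
    h <- (lo * 0x193 + (hi * 0x193 %% 65536) * 65536) %% 2^31
  }
  sprintf("%08x-%d", h, nchar(txt))
}

canonical_states <- function(states_matrix) {
  keys <- apply(states_matrix[, rev(seq_len(ncol(states_matrix))), drop = FALSE],
                1, paste, collapse = "")
  start <- which.min(keys)
  if (start > 1) {
    ix <- c(start:nrow(states_matrix), seq_len(start - 1L))
    states_matrix <- states_matrix[ix, , drop = FALSE]
  }
  states_matrix
}

#' Iterate a trajectory to its attractor
#'
#' Runs the synchronous dynamics from `start`, recording visited states in a
#' hash set until the trajectory closes; guaranteed to terminate on the
#' finite deterministic state space without any step cap.
#'
#' @param net A `boolean_network` (at most 64 nodes for the compiled path).
#' @param start Starting state.
#' @param keep_trajectory If `TRUE`, the transient states are returned too.
#' @return A list with `attractor` (a `bn_attractor`), `transient` (number of
#'   steps before entering the cycle) and optionally `trajectory` (matrix).
#' @examples
#' net <- boolean_network(list(A = "!A"))
#' iterate_to_attractor(net, c(A = 0))$attractor$length  # 2-cycle
#' @export
iterate_to_attractor <- function(net, start, keep_trajectory = FALSE) {
  s <- as_state(net, start)
  n <- length(net$nodes)
  if (n <= 64) {
    r <- .cpp_iterate(compile_program(net), n, unname(s), keep_trajectory)
    out <- list(attractor = new_attractor(r$states, net$nodes),
                transient = r$transient)
    if (keep_trajectory) {
      colnames(r$trajectory) <- net$nodes
      out$trajectory <- r$trajectory
    }
    return(out)
  }
  # plain-R fallback for oversized networks
  seen <- new.env(hash = TRUE)
  traj <- list()
  t <- 0L
  repeat {
    key <- state_string(s)
    hit <- seen[[key]]
    if (!is.null(hit)) {
      cyc <- do.call(rbind, traj[(hit + 1L):length(traj)])
      out <- list(attractor = new_attractor(canonical_states(cyc), net$nodes),
                  transient = hit)
      if (keep_trajectory) out$trajectory <- do.call(rbind, traj)
      return(out)
    }
    seen[[key]] <- t
    traj[[t + 1L]] <- unname(s)
    s <- synchronous_step(net, s, engine = "r")
    t <- t + 1L
  }
}

attractor_set <- function(att_matrices, nodes, environment = NULL,
                          backend = NA_character_, basins = NULL) {
  atts <- lapply(att_matrices, new_attractor, nodes = nodes)
  structure(list(attractors = atts, environment = environment,
                 backend = backend, basins = basins),
            class = "bn_attractor_set")
}

#' @export
print.bn_attractor_set <- function(x, ...) {
  lens <- vapply(x$attractors, function(a) a$length, 0L)
  cat(sprintf("Attractor set: %d attractor(s); lengths: %s\n",
              length(lens), paste(lens, collapse = ", ")))
  if (!is.null(x$environment)) {
    cat(sprintf("environment code: %d\n", attr(x$environment, "code")))
  }
  if (!is.na(x$backend)) cat("backend:", x$backend, "\n")
  invisible(x)
}

#' @export
length.bn_attractor_set <- function(x) length(x$attractors)

#' Tidy an attractor set
#' @param x A `bn_attractor_set`.
#' @param ... Unused.
#' @return Tibble with one row per attractor: `attractor`, `length`, `id`,
#'   `states` (list column of matrices) and `basin` when available.
#' @export
tidy.bn_attractor_set <- function(x, ...) {
  out <- tibble(
    attractor = seq_along(x$attractors),
    length = vapply(x$attractors, function(a) a$length, 0L),
    id = vapply(x$attractors, attractor_id, ""),
    states = lapply(x$attractors, function(a) a$states))
  if (!is.null(x$basins)) out$basin <- x$basins
  out
}

# ---------------------------------------------------------------------------
# micro-environments
# ---------------------------------------------------------------------------

#' Encode / decode micro-environments
#'
#' A micro-environment is a truth assignment over the network's declared
#' input nodes.  Codes pack the assignment into an integer with the FIRST
#' declared input as the most significant bit (for the bundled model:
#' VEGFC_Dp is the most significant of the 16 inputs, AMPATP the least).
#'
#' @param net A `boolean_network` with declared inputs.
#' @param ... Named input values (0/1) for `micro_environment()`; omitted
#'   inputs default to 0.
#' @param code Integer environment code for decoding.
#' @return `micro_environment()` returns a named 0/1 vector over the inputs
#'   with the code in `attr(, "code")`; `environment_code()` the integer code.
#' @examples
#' net <- boolean_network(list(A = "A", B = "B", C = "A & B"),
#'                        inputs = c("A", "B"))
#' environment_code(net, micro_environment(net, A = 1))  # A is the MSB: 2
#' @export
micro_environment <- function(net, ..., code = NULL) {
  k <- length(net$inputs)
  if (k == 0) abort("network has no declared inputs")
  if (!is.null(code)) {
    code <- as.integer(code)
    if (is.na(code) || code < 0 || code >= 2^k) {
      abort(sprintf("environment code must be in [0, %d]", 2^k - 1))
    }
    bits <- as.integer(bitwAnd(bitwShiftR(code, (k - 1L):0L), 1L))
    env <- stats::setNames(bits, net$inputs)
  } else {
    vals <- c(...)
    bad <- setdiff(names(vals), net$inputs)
    if (length(bad) > 0) abort(sprintf("'%s' is not an input node", bad[1]))
    env <- stats::setNames(rep(0L, k), net$inputs)
    if (length(vals) > 0) env[names(vals)] <- as.integer(vals)
  }
  attr(env, "code") <- sum(env * 2^((k - 1L):0L))
  env
}

#' @rdname micro_environment
#' @param env A named 0/1 vector over the inputs.
#' @export
environment_code <- function(net, env) {
  k <- length(net$inputs)
  env <- env[net$inputs]
  if (anyNA(env)) abort("environment must assign every declared input")
  as.integer(sum(as.integer(env) * 2^((k - 1L):0L)))
}

# ---------------------------------------------------------------------------
# clamping and exact enumeration
# ---------------------------------------------------------------------------

#' Clamp input nodes to a micro-environment
#'
#' Replaces each input's self-loop rule by the constant from `env`.  The
#' propagated consequences (nodes whose rules become constant once the
#' clamped constants are known, iterated to a fixpoint) are available via
#' [network_constants()]; the propagation is sound for attractors: a node is
#' only fixed when its rule's ternary value is determined by already-fixed
#' nodes, so it necessarily holds that value in every attractor state.
#'
#' @param net A `boolean_network`.
#' @param env A micro-environment (named 0/1 vector over the inputs, or an
#'   integer code), or for general clamping a named 0/1 vector over any
#'   subset of nodes.
#' @return A `boolean_network` with constant rules for the clamped nodes and
#'   the clamp recorded in `attr(, "clamped")`.
#' @export
clamp_inputs <- function(net, env) {
  if (is.numeric(env) && length(env) == 1L && is.null(names(env))) {
    env <- micro_environment(net, code = env)
  }
  bad <- setdiff(names(env), net$nodes)
  if (length(bad) > 0) abort(sprintf("unknown node '%s'", bad[1]))
  rules <- net$rules
  for (nm in names(env)) rules[[nm]] <- bx_const(env[[nm]])
  out <- boolean_network(rules, inputs = setdiff(net$inputs, names(env)))
  attr(out, "clamped") <- stats::setNames(as.integer(env), names(env))
  out
}

#' Propagated constants of a clamped network
#'
#' @param net A `boolean_network`, typically from [clamp_inputs()].
#' @return Named integer vector: 0/1 for nodes that are constant in every
#'   attractor, `NA` for free nodes.
#' @export
network_constants <- function(net) {
  n <- length(net$nodes)
  if (n > 64) abort("constant propagation requires the compiled engine (<= 64 nodes)")
  r <- .cpp_enumerate_clamped(compile_program(net), n, integer(), integer(),
                              0L, 1, "propagate_only")
  stats::setNames(r$constants, net$nodes)
}

#' Enumerate all attractors by exhaustive state-space search
#'
#' Visits all `2^n` states; exact by construction and used as the oracle for
#' the scalable backends.
#'
#' @param net A `boolean_network`.
#' @param basins If `TRUE`, also count each attractor's basin of attraction.
#' @param cap Refuse networks with more than this many nodes (default 20).
#' @return A `bn_attractor_set`.
#' @examples
#' enumerate_attractors_bruteforce(boolean_network(list(A = "A")))
#' @export
enumerate_attractors_bruteforce <- function(net, basins = FALSE, cap = 20L) {
  n <- length(net$nodes)
  if (n > cap) {
    abort(sprintf("network has %d nodes, above the brute-force cap of %d", n, cap))
  }
  r <- .cpp_enumerate_bruteforce(compile_program(net), n, basins)
  attractor_set(r$attractors, net$nodes, backend = "brute",
                basins = if (basins) r$basins else NULL)
}

#' Enumerate all attractors of a network under a fixed micro-environment
#'
#' Exact enumeration of the clamped network: inputs are clamped to `env`,
#' constants are propagated, and the remaining free core is enumerated either
#' by exhaustive successor tabulation (cores up to `brute_cap` nodes) or with
#' a binary decision diagram backend that computes the eventual image of the
#' core state space and peels off its cycles.  Both paths certify
#' completeness; if the BDD backend exceeds its node budget the call fails
#' rather than return a silent partial result.
#'
#' @param net A `boolean_network`.
#' @param env Micro-environment (named vector or integer code); `NULL`
#'   enumerates the unclamped network (inputs stay free self-loops).
#' @param backend `"auto"` (default), `"brute"`, or `"bdd"`.
#' @param brute_cap Largest free core enumerated explicitly under `"auto"`.
#' @param bdd_node_budget Node budget for the BDD arena.
#' @return A `bn_attractor_set` of full-network attractors (clamped inputs
#'   re-embedded), tagged with the environment.
#' @examples
#' net <- boolean_network(list(I = "I", A = "I | B", B = "A"), inputs = "I")
#' length(enumerate_attractors_env(net, micro_environment(net, I = 1)))
#' @export
enumerate_attractors_env <- function(net, env = NULL,
                                     backend = c("auto", "brute", "bdd"),
                                     brute_cap = 22L, bdd_node_budget = 3e7) {
  backend <- match.arg(backend)
  n <- length(net$nodes)
  if (n > 64) abort("exact enumeration requires the compiled engine (<= 64 nodes)")
  clamp_idx <- integer(); clamp_val <- integer()
  if (!is.null(env)) {
    if (is.numeric(env) && length(env) == 1L && is.null(names(env))) {
      env <- micro_environment(net, code = env)
    }
    bad <- setdiff(names(env), net$nodes)
    if (length(bad) > 0) abort(sprintf("unknown node '%s'", bad[1]))
    clamp_idx <- match(names(env), net$nodes) - 1L
    clamp_val <- as.integer(env)
  }
  r <- .cpp_enumerate_clamped(compile_program(net), n, clamp_idx, clamp_val,
                              as.integer(brute_cap), bdd_node_budget, backend)
  attractor_set(r$attractors, net$nodes, environment = env, backend = r$backend)
}
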