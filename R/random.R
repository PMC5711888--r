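# ---------------------------------------------------------------------------
# Seed-deterministic random network generation (property-test fixtures).
# ---------------------------------------------------------------------------

#' Generate a random Boolean network
#'
#' Builds a network of `n` nodes where each rule is a random AND/OR/NOT
#' combination of `k` regulators sampled uniformly (with `k` drawn from
#' `in_degrees`), each literal negated with probability `neg_prob`.
#' Generation is fully determined by `seed`, making the fixtures
#' reproducible across runs and machines.
#'
#' @param n Number of nodes (capped at 20 so every fixture stays
#'   brute-force verifiable).
#' @param seed Integer seed.
#' @param in_degrees Candidate in-degrees, sampled uniformly per node.
#' @param neg_prob Probability of negating each literal.
#' @param n_inputs Number of leading nodes turned into identity self-loop
#'   inputs.
#' @return A `boolean_network`.
#' @examples
#' random_network(6, seed = 1)
#' @export
random_network <- function(n, seed, in_degrees = 1:3, neg_prob = 0.4,
                           n_inputs = 0L) {
  if (n > 20) abort("random fixtures are capped at 20 nodes")
  if (n_inputs > n) abort("more inputs than nodes")
  nodes <- sprintf("N%02d", seq_len(n))
  rules <- withr::with_seed(seed, {
    lapply(seq_len(n), function(i) {
      if (i <= n_inputs) return(bx_var(nodes[i]))
      k <- if (length(in_degrees) == 1) in_degrees else sample(in_degrees, 1)
      regs <- sample(nodes, min(k, n))
      lits <- lapply(seq_along(regs), function(j) {
        v <- bx_var(regs[j])
        if (stats::runif(1) < neg_prob) bx_not(v) else v
      })
      expr <- lits[[1]]
      for (j in seq_along(lits)[-1]) {
        op <- if (stats::runif(1) < 0.5) "and" else "or"
        expr <- list(op = op, args = list(expr, lits[[j]]))
      }
      expr
    })
  })
  names(rules) <- nodes
  boolean_network(rules, inputs = nodes[seq_len(n_inputs)])
}
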