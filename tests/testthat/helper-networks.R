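# Shared fixtures and oracles for the test suite.

# -- tiny named toys --------------------------------------------------------

toy_oscillator <- function() boolean_network(list(A = "!A"))

toy_swap <- function() boolean_network(list(A = "B", B = "A"))

toy_rotor <- function() boolean_network(list(A = "!B", B = "A"))

toy_identity <- function() boolean_network(list(A = "A"))

# -- plain-R brute-force oracle --------------------------------------------
# Independent of the compiled engine: enumerates all 2^n states with the
# plain-R evaluator and extracts cycles by following trajectories.

oracle_attractors <- function(net) {
  n <- length(net$nodes)
  stopifnot(n <= 10)
  # expand.grid varies the first column fastest: node 1 is the low bit of
  # the row index, matching the successor formula below
  all_states <- as.matrix(expand.grid(rep(list(0:1), n)))
  colnames(all_states) <- net$nodes
  succ <- apply(all_states, 1, function(s) {
    nx <- vapply(net$rules, function(r) evaluate_expression(r, stats::setNames(s, net$nodes)), 0L)
    sum(nx * 2^(seq_len(n) - 1L)) + 1L
  })
  found <- character()
  basins <- integer()
  for (s0 in seq_len(2^n)) {
    seen <- integer()
    s <- s0
    while (!s %in% seen) { seen <- c(seen, s); s <- succ[s] }
    cyc <- seen[which(seen == s)[1]:length(seen)]
    # canonical rotation: start at the minimum state index
    k <- which.min(cyc)
    cyc <- c(cyc[k:length(cyc)], cyc[seq_len(k - 1L)])
    key <- paste(apply(all_states[cyc, , drop = FALSE], 1, paste, collapse = ""),
                 collapse = ";")
    if (!key %in% found) { found <- c(found, key); basins <- c(basins, 0L) }
    basins[match(key, found)] <- basins[match(key, found)] + 1L
  }
  list(keys = sort(found), basins = basins[order(found)])
}

attractor_set_keys <- function(aset) {
  sort(vapply(aset$attractors, function(a) {
    paste(apply(a$states, 1, paste, collapse = ""), collapse = ";")
  }, ""))
}

# -- bundled model, loaded once --------------------------------------------

angio_net <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- angiogenesis_network()
    cache
  }
})

# The wild-type sweep takes a couple of minutes; compute it at most once per
# test run and share it between the acceptance blocks that consume it.
angio_wt_sweep <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- sweep_environments(angio_net())
    cache
  }
})
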