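test_that("fixing an input substitutes its constant with folding", {
  net <- boolean_network(list(A = "A", B = "A & C", C = "C"),
                         inputs = c("A", "C"))
  r <- remove_constant_inputs(net, c(A = 1))
  expect_identical(r$net$nodes, c("B", "C"))
  expect_identical(deparse_expression(r$net$rules$B), "C")
  r0 <- remove_constant_inputs(net, c(A = 0))
  expect_identical(deparse_expression(r0$net$rules$B), "0")
  expect_error(remove_constant_inputs(net, c(B = 1)), "input")
})

test_that("output removal iterates until no sink remains", {
  net <- boolean_network(list(A = "A", B = "A"))
  expect_identical(remove_outputs(net)$net$nodes, "A")
  chain <- boolean_network(list(A = "A", B = "A", C = "B"))
  r <- remove_outputs(chain)
  expect_identical(r$net$nodes, "A")
  expect_equal(vapply(r$log$steps, function(s) s$node, ""), c("C", "B"))
})

test_that("contraction inlines relays with polarity", {
  net <- boolean_network(list(A = "A", B = "A", C = "B"))
  r <- contract_intermediaries(net, protected = c("A", "C"))
  expect_identical(deparse_expression(r$net$rules$C), "A")
  neg <- boolean_network(list(A = "A", B = "!A", C = "B"))
  rn <- contract_intermediaries(neg, protected = c("A", "C"))
  expect_identical(deparse_expression(rn$net$rules$C), "!A")
})

test_that("input removal preserves the restricted, projected attractors", {
  for (seed in 1:15) {
    net <- random_network(8, seed = seed + 300, n_inputs = 2)
    inp <- net$inputs[1]
    for (v in 0:1) {
      red <- remove_constant_inputs(net, stats::setNames(v, inp))$net
      reduced_atts <- attractor_set_keys(enumerate_attractors_bruteforce(red))
      # oracle: brute-force original, keep attractors where the input is v,
      # project onto surviving nodes
      full <- enumerate_attractors_bruteforce(net)
      keep <- Filter(function(a) all(a$states[, inp] == v), full$attractors)
      projected <- sort(vapply(keep, function(a) {
        m <- a$states[, red$nodes, drop = FALSE]
        m <- canonical_states(m)
        paste(apply(m, 1, paste, collapse = ""), collapse = ";")
      }, ""))
      expect_identical(reduced_atts, projected)
    }
  }
})

test_that("output removal preserves projected attractors", {
  for (seed in 1:15) {
    net <- random_network(8, seed = seed + 400)
    red <- remove_outputs(net)$net
    if (length(red$nodes) == length(net$nodes)) next
    reduced_atts <- attractor_set_keys(enumerate_attractors_bruteforce(red))
    full <- enumerate_attractors_bruteforce(net)
    projected <- sort(unique(vapply(full$attractors, function(a) {
      m <- a$states[, red$nodes, drop = FALSE]
      m <- unique(m)          # projection can collapse cycle states
      m <- canonical_states(m)
      paste(apply(m, 1, paste, collapse = ""), collapse = ";")
    }, "")))
    # every projected original attractor appears among the reduced attractors
    # and vice versa, up to cycle-state collapsing
    reduced_states <- unique(unlist(strsplit(reduced_atts, ";")))
    projected_states <- unique(unlist(strsplit(projected, ";")))
    expect_setequal(reduced_states, projected_states)
  }
})

test_that("contraction off feedback circuits preserves fixed points", {
  fixed_point_keys <- function(net) {
    aset <- enumerate_attractors_bruteforce(net)
    keep <- Filter(function(a) a$length == 1L, aset$attractors)
    vapply(keep, function(a) paste(a$states[1, ], collapse = ""), "")
  }
  checked <- 0L
  for (seed in 1:40) {
    net <- random_network(7, seed = seed + 500)
    # protect everything on a feedback circuit: contract only tree-like parts
    g <- lapply(net$rules, expression_support)
    on_cycle <- vapply(net$nodes, function(nm) {
      # reachable from itself through the support graph
      frontier <- g[[nm]]
      seen <- character()
      while (length(frontier) > 0) {
        if (nm %in% frontier) return(TRUE)
        seen <- union(seen, frontier)
        frontier <- setdiff(unique(unlist(g[frontier])), seen)
      }
      FALSE
    }, TRUE)
    r <- contract_intermediaries(net, protected = net$nodes[on_cycle])
    if (length(r$log$steps) == 0) next
    checked <- checked + 1L
    red <- r$net
    fp_red <- sort(fixed_point_keys(red))
    fp_orig <- sort(unique(vapply(
      Filter(function(a) a$length == 1L,
             enumerate_attractors_bruteforce(net)$attractors),
      function(a) paste(a$states[1, red$nodes], collapse = ""), "")))
    expect_identical(fp_red, fp_orig)
  }
  expect_gte(checked, 10L)
})

test_that("replaying a reduction log reproduces the reduced network", {
  net <- boolean_network(list(I = "I", A = "I & B", B = "!A", C = "B", D = "C"),
                         inputs = "I")
  r1 <- remove_constant_inputs(net, c(I = 1))
  r2 <- remove_outputs(r1$net)
  r3 <- contract_intermediaries(r2$net, protected = "A")
  combined <- new_reduction_log(c(r1$log$steps, r2$log$steps, r3$log$steps))
  replayed <- replay_reduction(net, combined)
  expect_identical(write_network(replayed), write_network(r3$net))
})
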