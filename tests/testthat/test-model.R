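test_that("the bundled model has the documented shape", {
  net <- angio_net()
  expect_equal(n_nodes(net), 64L)
  expect_length(net$inputs, 16L)
  # every input rule is the identity self-loop
  for (nm in net$inputs) {
    expect_identical(net$rules[[nm]], bx_var(nm))
  }
  # round-trip through the writer preserves all 64 rules
  net2 <- read_network(text = paste(write_network(net), collapse = "\n"),
                       inputs = net$inputs)
  expect_identical(tidy(net)$rule, tidy(net2)$rule)
})

test_that("metadata, signatures and the model agree on marker nodes", {
  meta <- angiogenesis_metadata()
  net <- angio_net()
  expect_identical(meta$inputs, net$inputs)
  expect_true(all(unlist(lapply(ec_signatures(), names)) %in% net$nodes))
  expect_true(all(meta$proliferation_markers %in% net$nodes))
})

test_that("reference micro-environments induce their expected behaviors", {
  net <- angio_net()
  refs <- reference_environments(net)
  for (i in seq_len(nrow(refs))) {
    # from the all-zero internal state
    s <- network_state(net)
    s[names(refs$env[[i]])] <- refs$env[[i]]
    r <- iterate_to_attractor(net, s)
    expect_equal(classify_attractor(r$attractor), refs$expected[i],
                 label = sprintf("behavior from zero state in %s", refs$name[i]))
    # and the full exact attractor set of the environment agrees
    aset <- enumerate_attractors_env(net, refs$env[[i]])
    labs <- unique(vapply(aset$attractors, classify_attractor, ""))
    expect_identical(labs, refs$expected[i],
                     label = sprintf("attractor set of %s", refs$name[i]))
  }
})

test_that("micro-environment changes drive the documented behavior transitions", {
  net <- angio_net()
  refs <- reference_environments(net)
  # every reference behavior reaches every other behavior via an environment
  # switch from each attractor state of the source behavior
  for (i in seq_len(nrow(refs))) {
    src <- enumerate_attractors_env(net, refs$env[[i]])
    for (j in seq_len(nrow(refs))) {
      if (i == j) next
      for (a in src$attractors) {
        start <- stats::setNames(a$states[1, ], net$nodes)
        tr <- behavior_transition(net, start, refs$env[[j]])
        expect_equal(tr$behavior, refs$expected[j],
                     label = sprintf("%s -> %s", refs$name[i], refs$name[j]))
      }
    }
  }
  # switching to the same environment keeps the attractor with no transient
  a1 <- enumerate_attractors_env(net, refs$env[[1]])$attractors[[1]]
  start <- stats::setNames(a1$states[1, ], net$nodes)
  same <- behavior_transition(net, start, refs$env[[1]])
  expect_equal(same$transient, 0L)
  expect_identical(same$attractor$states, a1$states)
})

test_that("transition start states are checked", {
  net <- angio_net()
  s <- network_state(net, AKT = 1)   # almost surely not an attractor state
  r0 <- iterate_to_attractor(net, s)
  expect_gt(r0$transient, 0L)
  expect_error(behavior_transition(net, s, micro_environment(net, code = 0)),
               "attractor")
  expect_warning(
    behavior_transition(net, s, micro_environment(net, code = 0),
                        check_start = "warn"),
    "attractor")
})
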