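test_that("trajectory iteration finds cycles with their transient length", {
  # negation oscillator: 2-cycle, no transient
  r <- iterate_to_attractor(toy_oscillator(), c(A = 0))
  expect_equal(r$attractor$length, 2L)
  expect_equal(r$transient, 0L)

  # rotor A <- !B, B <- A: single 4-cycle through all states
  r2 <- iterate_to_attractor(toy_rotor(), c(A = 0, B = 0))
  expect_equal(r2$attractor$length, 4L)
  expect_equal(r2$transient, 0L)

  # a fixed point has transient 0 and maps to itself
  net <- boolean_network(list(A = "A & B", B = "B"))
  r3 <- iterate_to_attractor(net, c(A = 1, B = 1))
  expect_equal(r3$attractor$length, 1L)
  expect_equal(r3$transient, 0L)
})

test_that("brute-force enumeration matches the plain-R oracle", {
  expect_identical(
    attractor_set_keys(enumerate_attractors_bruteforce(toy_identity())),
    c("0", "1"))
  for (seed in 1:30) {
    net <- random_network(sample(4:8, 1), seed = seed)
    oracle <- oracle_attractors(net)
    got <- enumerate_attractors_bruteforce(net, basins = TRUE)
    expect_identical(attractor_set_keys(got), oracle$keys)
  }
})

test_that("basin sizes partition the state space", {
  for (seed in c(3, 14, 15)) {
    n <- 9
    net <- random_network(n, seed = seed)
    got <- enumerate_attractors_bruteforce(net, basins = TRUE, cap = 12)
    expect_equal(sum(got$basins), 2^n)
  }
})

test_that("canonical forms are independent of discovery order", {
  net <- toy_rotor()
  keys <- vapply(0:3, function(code) {
    s <- c(A = bitwAnd(code, 1L), B = bitwAnd(bitwShiftR(code, 1L), 1L))
    r <- iterate_to_attractor(net, s)
    attractor_id(r$attractor)
  }, "")
  expect_length(unique(keys), 1L)
})

test_that("environment clamping propagates constants soundly", {
  net <- angio_net()
  clamped <- clamp_inputs(net, micro_environment(net, ShearStress = 1))
  consts <- network_constants(clamped)
  expect_equal(consts[["KLF2"]], 1L)
  clamped0 <- clamp_inputs(net, micro_environment(net))  # all inputs off
  consts0 <- network_constants(clamped0)
  expect_equal(consts0[["betacatenin"]], 0L)
  expect_equal(consts0[["KLF2"]], 0L)
  # clamping all 16 inputs leaves at most 48 free nodes
  expect_lte(sum(is.na(consts0)), 48L)
})

test_that("environment enumeration is exact (brute-force oracle) and tagged", {
  for (seed in 1:25) {
    net <- random_network(sample(6:10, 1), seed = seed + 100, n_inputs = 2)
    env <- micro_environment(net, code = seed %% 4)
    aset <- enumerate_attractors_env(net, env)
    # oracle: clamp by rewriting rules, then brute-force the full network
    clamped <- clamp_inputs(net, env)
    brute <- enumerate_attractors_bruteforce(clamped)
    expect_identical(attractor_set_keys(aset), attractor_set_keys(brute))
    # every attractor state projects onto the environment
    for (a in aset$attractors) {
      proj <- a$states[, names(env), drop = FALSE]
      expect_true(all(t(proj) == as.integer(env)))
    }
  }
})

test_that("closure and minimality hold for enumerated attractors", {
  net <- random_network(8, seed = 555)
  aset <- enumerate_attractors_env(net, env = NULL)
  for (a in aset$attractors) {
    l <- a$length
    states <- apply(a$states, 1, paste, collapse = "")
    s <- stats::setNames(a$states[1, ], net$nodes)
    for (k in seq_len(l)) s <- synchronous_step(net, s)
    expect_identical(paste(s, collapse = ""), states[1])  # closure after l steps
    expect_identical(anyDuplicated(states), 0L)           # minimality
  }
})

test_that("backend selection is explicit and the BDD path matches brute force", {
  for (seed in 41:60) {
    n <- sample(8:12, 1)
    net <- random_network(n, seed = seed)
    brute <- enumerate_attractors_env(net, backend = "brute")
    bdd <- enumerate_attractors_env(net, backend = "bdd")
    expect_identical(attractor_set_keys(brute), attractor_set_keys(bdd))
  }
})

test_that("an exhausted node budget is an error, not a partial result", {
  net <- random_network(14, seed = 9)
  expect_error(
    enumerate_attractors_env(net, backend = "bdd", bdd_node_budget = 64),
    "budget")
})

test_that("micro-environment codes round-trip with the declared bit order", {
  net <- angio_net()
  env <- micro_environment(net, ANG1 = 1, Oxygen = 1, ShearStress = 1)
  expect_equal(attr(env, "code"), 14336)   # ANG1, Oxygen, ShearStress bits
  expect_equal(environment_code(net, env), 14336L)
  rt <- micro_environment(net, code = 14336)
  expect_identical(unname(rt), unname(env))
  # first declared input is the most significant bit
  msb <- micro_environment(net, VEGFC_Dp = 1)
  expect_equal(attr(msb, "code"), 2^15)
})
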