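test_that("mutations clamp a node's rule to a constant", {
  net <- boolean_network(list(A = "B", B = "A"))
  loss <- apply_mutation(net, "A", "loss")
  expect_identical(deparse_expression(loss$rules$A), "0")
  gain <- apply_mutation(net, "B", "gain")
  expect_identical(deparse_expression(gain$rules$B), "1")
  expect_error(apply_mutation(net, "Z", "loss"), "unknown node")
})

test_that("wild-type attractors that satisfy a clamp survive the mutation", {
  for (seed in 1:10) {
    net <- random_network(7, seed = seed + 700)
    full <- enumerate_attractors_bruteforce(net)
    node <- net$nodes[3]
    for (kind in c("loss", "gain")) {
      v <- if (kind == "loss") 0L else 1L
      mut <- apply_mutation(net, node, kind)
      mut_keys <- attractor_set_keys(enumerate_attractors_bruteforce(mut))
      for (a in full$attractors) {
        if (all(a$states[, node] == v)) {
          key <- paste(apply(a$states, 1, paste, collapse = ""), collapse = ";")
          expect_true(key %in% mut_keys)
        }
      }
    }
  }
})

test_that("perturb_state flips exactly one uniformly chosen variable", {
  net <- angio_net()
  s <- network_state(net)
  set.seed(11)
  counts <- integer(64)
  for (k in 1:6400) {
    p <- perturb_state(s)
    d <- which(p != s)
    expect_length(d, 1L)
    counts[d] <- counts[d] + 1L
    # double flip restores the original
    p2 <- p; p2[d] <- 1L - p2[d]
    expect_identical(p2, s)
  }
  chi <- chisq.test(counts)
  expect_gt(chi$p.value, 1e-4)
})

test_that("robustness is 1 on a single-attractor network", {
  # strong convergence: every rule a constant -> one fixed point
  rules <- c(list(NRP1 = "0", DLL4a = "0", AKT = "1", JAGa = "0",
                  betacatenin = "0", LEF1 = "0"),
             stats::setNames(as.list(rep("1", 4)), paste0("X", 1:4)))
  net <- boolean_network(rules)
  for (mode in c("behavior", "attractor")) {
    r <- robustness_experiment(net, mode = mode, n = 2000, seed = 3,
                               cache_log2 = 16)
    expect_equal(r$fraction_same, 1)
  }
})

test_that("robustness results are seed-deterministic and seed-stable", {
  net <- angio_net()
  r1 <- robustness_experiment(net, "behavior", n = 20000, seed = 42,
                              cache_log2 = 20)
  r2 <- robustness_experiment(net, "behavior", n = 20000, seed = 42,
                              cache_log2 = 18)   # cache size must not matter
  expect_identical(r1$fraction_same, r2$fraction_same)
  expect_identical(r1$per_behavior, r2$per_behavior)
  r3 <- robustness_experiment(net, "behavior", n = 20000, seed = 43,
                              cache_log2 = 20)
  expect_false(identical(r1$fraction_same, r3$fraction_same))
  # different seeds agree within generous sampling error
  expect_lt(abs(r1$fraction_same - r3$fraction_same), 0.01)
})

test_that("sensitivity estimates track the analytic influence sums", {
  net <- angio_net()
  se <- rule_sensitivity(net, n_samples = 50000, seed = 5)
  expect_false(anyNA(se$analytic))          # all supports are small
  se_binom <- sqrt(se$analytic * (1 - se$analytic) / se$n)
  expect_true(all(abs(se$estimate - se$analytic) <= 4 * se_binom + 1e-12))
  # the AKT rule copies one regulator: influence 1, sensitivity 1/64
  expect_equal(se$analytic[se$node == "AKT"], 1 / 64)
  # a pure 6-literal OR flips only when the other five literals are 0
  expect_equal(se$analytic[se$node == "VegfA"], 6 * 2^-5 / 64)
  # determinism
  se2 <- rule_sensitivity(net, n_samples = 50000, seed = 5)
  expect_identical(se$estimate, se2$estimate)
})

test_that("mutation scans classify against the wild type on a toy model", {
  net <- boolean_network(
    list(I = "I",
         NRP1 = "I", DLL4a = "I", AKT = "!I", JAGa = "!I & betacatenin",
         betacatenin = "betacatenin", LEF1 = "betacatenin & LEF1"),
    inputs = "I")
  wt <- sweep_environments(net)
  expect_equal(nrow(wt), 2L)
  scan <- mutation_scan(net, wild_type = wt,
                        mutations = tibble::tibble(
                          node = c("NRP1", "NRP1", "LEF1"),
                          kind = c("loss", "gain", "loss")))
  expect_equal(nrow(scan), 3L)
  expect_false(scan$tip_exists[scan$node == "NRP1" & scan$kind == "loss"])
  g <- glance(scan)
  expect_equal(g$n_mutations, 3L)
  expect_equal(g$no_effect + g$response_changed + g$behavior_lost, 3L)
})
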