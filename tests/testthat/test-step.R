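test_that("expression evaluation follows standard Boolean semantics", {
  # AMPK rule shape: (AMPATP | !Oxygen) & !AKT
  e <- "(AMPATP | !Oxygen) & !AKT"
  expect_equal(evaluate_expression(e, c(AMPATP = 0, Oxygen = 0, AKT = 0)), 1L)
  expect_equal(evaluate_expression(e, c(AMPATP = 0, Oxygen = 1, AKT = 0)), 0L)
  # Calcium rule shape: PLCg | ShearStress | !NO
  e2 <- "PLCg | ShearStress | !NO"
  expect_equal(evaluate_expression(e2, c(PLCg = 0, ShearStress = 0, NO = 0)), 1L)
  # constants evaluate on any state
  expect_equal(evaluate_expression("1", c(A = 0)), 1L)
  expect_equal(evaluate_expression("0 | A", c(A = 0)), 0L)
  expect_error(evaluate_expression("B", c(A = 1)), "not assigned")
})

test_that("the synchronous step is simultaneous, not sequential", {
  # swap network: sequential in-place update would give (0,0) or (1,1)
  s <- synchronous_step(toy_swap(), c(A = 1, B = 0))
  expect_identical(s, c(A = 0L, B = 1L))
  s_r <- synchronous_step(toy_swap(), c(A = 1, B = 0), engine = "r")
  expect_identical(s_r, c(A = 0L, B = 1L))
})

test_that("fixed points map to themselves", {
  net <- boolean_network(list(A = "A & B", B = "A | B"))
  for (st in list(c(A = 0, B = 0), c(A = 1, B = 1))) {
    expect_identical(synchronous_step(net, st), as_state(net, st))
  }
})

test_that("compiled and plain-R engines agree on random networks", {
  for (seed in 1:20) {
    net <- random_network(8, seed = seed)
    states <- withr::with_seed(seed, {
      replicate(5, sample(0:1, 8, replace = TRUE), simplify = FALSE)
    })
    for (s in states) {
      expect_identical(synchronous_step(net, s, engine = "cpp"),
                       synchronous_step(net, s, engine = "r"))
    }
  }
})

test_that("input bits are conserved along any trajectory", {
  net <- angio_net()
  set.seed(7)
  for (rep in 1:5) {
    s <- network_state(net)
    s[] <- sample(0:1, length(s), replace = TRUE)
    r <- iterate_to_attractor(net, s, keep_trajectory = TRUE)
    proj <- r$trajectory[, net$inputs, drop = FALSE]
    expect_true(all(apply(proj, 2, function(x) length(unique(x)) == 1)))
    expect_identical(unname(proj[1, ]), unname(s[net$inputs]))
  }
})
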