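test_that("rule lines parse into the expected expression trees", {
  net <- read_network(text = "targets, factors\nAKT, PIP3\nPIP3, AKT")
  expect_identical(net$nodes, c("AKT", "PIP3"))
  expect_identical(net$rules$AKT, bx_var("PIP3"))

  expect_error(read_network(text = "targets, factors\nA"), "line 2")
})

test_that("operator precedence is NOT > AND > OR", {
  e <- parse_expression("!B & (C | A)")
  expect_identical(e$op, "and")
  expect_identical(e$args[[1]]$op, "not")
  expect_identical(e$args[[2]]$op, "or")

  # A | B & C groups as A | (B & C)
  e2 <- parse_expression("A | B & C")
  expect_identical(e2$op, "or")
  expect_identical(e2$args[[2]]$op, "and")

  # !A & B negates only A
  s <- c(A = 1L, B = 1L)
  expect_equal(evaluate_expression("!A & B", s), 0L)
  expect_equal(evaluate_expression("!(A & B)", c(A = 1L, B = 0L)), 1L)
})

test_that("parse/write round-trips are the identity up to normalization", {
  doc <- "targets, factors\nA, !B & (C | A)\nB, A | 1\nC, !(A & B)"
  net <- read_network(text = doc)
  doc2 <- write_network(net)
  net2 <- read_network(text = paste(doc2, collapse = "\n"))
  expect_identical(tidy(net)$rule, tidy(net2)$rule)
  # write . parse . write is idempotent
  doc3 <- write_network(net2)
  expect_identical(doc2, doc3)
})

test_that("single-rule serialization is direct", {
  net <- boolean_network(list(A = "!A"))
  expect_identical(write_network(net), c("targets, factors", "A, !A"))
})

test_that("parser errors carry context", {
  expect_error(read_network(text = "A, B"), "targets, factors")
  expect_error(read_network(text = "targets, factors\nA, B & &"), "line 2")
  expect_error(read_network(text = "targets, factors\nA, B"), "undeclared")
  expect_error(read_network(text = "targets, factors\nA, A\nA, !A"), "duplicate")
})

test_that("input nodes must be identity self-loops (strict by default)", {
  doc <- "targets, factors\nI, !I\nA, I"
  expect_error(read_network(text = doc, inputs = "I"), "self-loop")
  expect_warning(read_network(text = doc, inputs = "I", strict = FALSE),
                 "self-loop")
  expect_error(read_network(text = "targets, factors\nA, A", inputs = "Z"),
               "not a node")
})

test_that("comments and blank lines are ignored", {
  doc <- "# a model\ntargets, factors\n\n# rule\nA, !A"
  expect_identical(read_network(text = doc)$nodes, "A")
})
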