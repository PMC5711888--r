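test_that("states classify by their marker signature", {
  expect_equal(classify_state(c(NRP1 = 1, DLL4a = 1, AKT = 0, JAGa = 0)), "Tip")
  expect_equal(classify_state(c(NRP1 = 0, DLL4a = 1, AKT = 1, JAGa = 1)), "Stalk")
  expect_equal(classify_state(c(NRP1 = 0, DLL4a = 0, AKT = 1, JAGa = 0)), "Phalanx")
  expect_equal(classify_state(c(NRP1 = 0, DLL4a = 0, AKT = 0, JAGa = 0)), "Other")
  expect_error(classify_state(c(NRP1 = 1, DLL4a = 1)), "marker")
})

test_that("the three signatures are pairwise unsatisfiable", {
  combos <- expand.grid(NRP1 = 0:1, DLL4a = 0:1, AKT = 0:1, JAGa = 0:1)
  labels <- apply(combos, 1, function(s) {
    hits <- vapply(ec_signatures(), function(sig) {
      all(s[names(sig)] == sig)
    }, TRUE)
    sum(hits)
  })
  expect_true(all(labels <= 1))
})

test_that("attractor-level labels require unanimity", {
  mk <- function(...) {
    m <- rbind(...)
    colnames(m) <- c("NRP1", "DLL4a", "AKT", "JAGa")
    m
  }
  expect_equal(classify_attractor(mk(c(0, 0, 1, 0))), "Phalanx")
  # a cycle alternating Tip and Stalk patterns is atypical
  expect_equal(classify_attractor(mk(c(1, 1, 0, 0), c(0, 1, 1, 1))), "Atypical")
  # a cycle of unlabeled states is atypical
  expect_equal(classify_attractor(mk(c(0, 0, 0, 0), c(1, 0, 0, 1))), "Atypical")
})

test_that("proliferation needs beta-catenin and LEF1 throughout the cycle", {
  mk <- function(...) {
    m <- rbind(...)
    colnames(m) <- c("betacatenin", "LEF1")
    m
  }
  expect_true(classify_proliferation(mk(c(1, 1), c(1, 1))))
  expect_false(classify_proliferation(mk(c(1, 1), c(1, 0))))
  expect_true(classify_proliferation(mk(c(1, 0), c(1, 1)), mode = "any_state"))
})
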