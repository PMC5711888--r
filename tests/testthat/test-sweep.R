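toy_sweep_net <- function() {
  # 3 inputs, 2^3 = 8 environments; markers wired so every behavior occurs
  boolean_network(
    list(V = "V", W = "W", S = "S",
         NRP1 = "V", DLL4a = "V | W", AKT = "!V & S",
         JAGa = "W & !V", betacatenin = "W", LEF1 = "betacatenin & (LEF1 | W)"),
    inputs = c("V", "W", "S"))
}

test_that("a sweep labels every environment and partitions the space", {
  net <- toy_sweep_net()
  sw <- sweep_environments(net)
  expect_equal(nrow(sw), 8L)
  expect_false(anyNA(sw$behavior))
  g <- glance(sw)
  expect_equal(g$phalanx + g$stalk + g$tip + g$atypical, 8L)
  expect_equal(g$prolif_all + g$prolif_some + g$prolif_none, 8L)
  # environment code columns decode the row index
  expect_equal(sw$V * 4L + sw$W * 2L + sw$S, sw$env)
})

test_that("sweep rows agree with per-environment enumeration + classification", {
  net <- toy_sweep_net()
  sw <- sweep_environments(net)
  for (code in sw$env) {
    aset <- enumerate_attractors_env(net, code)
    labs <- vapply(aset$attractors, classify_attractor, "")
    expected <- if (length(unique(labs)) == 1 && labs[1] != "Atypical") {
      labs[1]
    } else "Atypical"
    expect_equal(as.character(sw$behavior[sw$env == code]), expected)
    expect_equal(sw$n_attractors[sw$env == code], length(aset))
    div <- vapply(aset$attractors, classify_proliferation, TRUE)
    expected_pro <- if (all(div)) "all" else if (any(div)) "some" else "none"
    expect_equal(as.character(sw$proliferation[sw$env == code]), expected_pro)
  }
})

test_that("a clamped input restricts the sweep to matching environments", {
  net <- toy_sweep_net()
  sw <- sweep_environments(net, mutations = c(V = 1L))
  expect_equal(nrow(sw), 8L)              # codes still enumerate 2^3
  # behavior of every environment equals that of its V=1 counterpart
  base <- sweep_environments(net)
  for (code in 0:7) {
    twin <- bitwOr(code, 4L)              # V is the most significant bit
    expect_equal(as.character(sw$behavior[sw$env == code]),
                 as.character(base$behavior[base$env == twin]))
  }
})

test_that("environment grouping covers each behavior class exactly", {
  net <- toy_sweep_net()
  sw <- sweep_environments(net)
  for (beh in levels(sw$behavior)) {
    n_beh <- sum(sw$behavior == beh)
    if (n_beh == 0) next
    gr <- environment_groups(sw, beh)
    expect_equal(sum(gr$n_environments), n_beh)
  }
})

test_that("sweep results are invariant across backend thresholds", {
  net <- toy_sweep_net()
  sw_brute <- sweep_environments(net, brute_cap = 22L)
  sw_bdd <- sweep_environments(net, brute_cap = 0L)   # force the BDD path
  expect_identical(sw_brute$behavior, sw_bdd$behavior)
  expect_identical(sw_brute$n_attractors, sw_bdd$n_attractors)
  expect_identical(sw_brute$proliferation, sw_bdd$proliferation)
})
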