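test_that("survival probability rule is 1 - IPD * d with domain checks", {
  expect_equal(survival_probability(1, 1), 0)
  expect_equal(survival_probability(0, 0.7), 1)
  expect_equal(survival_probability(0.5, 0.5), 0.75)
  expect_error(survival_probability(1.2, 0.5), "\\[0, 1\\]")
  expect_error(survival_probability(0.5, -0.1), "\\[0, 1\\]")
})

test_that("model variants transform dependence and weights without mutation", {
  net <- toy_net()
  dep <- c(A = 0.3, B = 0.9)
  f <- apply_variant(net, dep, "F")
  expect_identical(f$network$visits, net$visits)
  expect_equal(f$dep, dep)

  d <- apply_variant(net, dep, "D")
  expect_equal(unname(d$dep), c(1, 1))
  expect_identical(d$network$visits, net$visits)

  h <- apply_variant(net, dep, "H")
  expect_equal(h$dep, dep)
  # homogenised weights: plant A's two partners get equal d = 1/2
  st <- cascade_state(h$network)
  expect_equal(relative_dependence(st, "A"), c(x = 0.5, y = 0.5))
  expect_identical(h$network$visits > 0, net$visits > 0)  # topology kept

  dh <- apply_variant(net, dep, "DH")
  expect_equal(unname(dh$dep), c(1, 1))
  expect_equal(unname(dh$network$visits[1, ]), c(1, 1))

  expect_error(apply_variant(net, dep, "Z"))
  expect_equal(dep, c(A = 0.3, B = 0.9))  # caller's objects untouched
})

test_that("scenario orders sort by initial degree with uniform tie-breaks", {
  V <- matrix(c(1, 1, 1, 1, 1, 0, 1, 0, 0), 3, 3,
              dimnames = list(paste0("pl", 1:3), c("x", "y", "z")))
  net <- interaction_network(V)  # degrees x:3 y:2 z:1
  set.seed(1)
  expect_equal(scenario_order(net, "generalist"), c("x", "y", "z"))
  expect_equal(scenario_order(net, "specialist"), c("z", "y", "x"))
  expect_setequal(scenario_order(net, "random"), c("x", "y", "z"))

  tie <- interaction_network(matrix(c(1, 1, 1, 1), 2, 2,
    dimnames = list(c("A", "B"), c("x", "y"))))
  set.seed(42)
  first <- replicate(400, scenario_order(tie, "generalist")[1])
  expect_gt(mean(first == "x"), 0.4)
  expect_lt(mean(first == "x"), 0.6)
})

test_that("single-event removal follows the cascade rules", {
  # sole partner of a fully dependent plant: coextinction is certain
  net1 <- interaction_network(matrix(1, 1, 1, dimnames = list("A", "x")))
  st <- cascade_state(net1)
  out <- remove_pollinator(st, "x", c(A = 1))
  expect_equal(out$state$extant_plants, character(0))
  expect_equal(out$state$extant_pollinators, character(0))
  expect_setequal(out$log$type, c("primary", "stochastic"))

  # plant not connected to the removed pollinator draws nothing
  V <- matrix(c(1, 0, 0, 1), 2, 2, dimnames = list(c("A", "B"), c("x", "y")))
  net2 <- interaction_network(V)
  out2 <- remove_pollinator(cascade_state(net2), "x", c(A = 1, B = 1))
  expect_true("B" %in% out2$state$extant_plants)
  # A dies certainly (d = 1, IPD = 1); y starves once B... B stays: y has B
  expect_false("A" %in% out2$state$extant_plants)
  expect_equal(out2$state$extant_pollinators, "y")

  # starved secondary pollinator: y loses its only partner when A dies
  V3 <- matrix(c(1, 1), 1, 2, dimnames = list("A", c("x", "y")))
  set.seed(7)  # A dies with probability 1/2; loop until the death branch
  repeat {
    o <- remove_pollinator(cascade_state(interaction_network(V3)), "x", c(A = 1))
    if (!length(o$state$extant_plants)) break
  }
  expect_true("y" %in% o$log$species[o$log$type == "secondary"])

  expect_error(remove_pollinator(out2$state, "x", c(A = 1, B = 1)),
               "sequencing error")
})

test_that("replicates are monotone, complete, and event indices include skips", {
  inst <- rand_instance(5, 6, seed = 1)
  rep1 <- run_replicate(inst$network, inst$dep,
                        scenario_order(inst$network, "random"), seed = 9)
  expect_equal(ncol(rep1$plants), 7)  # events 0..N_P even with skips
  expect_true(all(rep1$plants[, 1]))
  expect_true(all(diff(t(rep1$plants)) <= 0))  # extinction is absorbing
  expect_true(all(diff(rep1$n_pollinators) <= 0))
  expect_equal(rep1$n_pollinators[7], 0)
  expect_error(run_replicate(inst$network, inst$dep, c("po1", "po2")),
               "permutation")
})

test_that("fast engine and reference cascade path agree draw for draw", {
  for (s in 1:10) {
    inst <- rand_instance(4, 5, seed = 400 + s)
    ord <- paste0("po", c(3, 1, 5, 2, 4))
    ref <- run_replicate(inst$network, inst$dep, ord, seed = s)
    set.seed(s)
    fast <- pollcoex:::.scm_replicate(inst$network$visits, unname(inst$dep),
                                      match(ord, pollinator_ids(inst$network)))
    expect_identical(unname(ref$plants), fast$plants)
    expect_identical(ref$n_pollinators, fast$n_pollinators)
  }
})

test_that("simulation surfaces are reproducible, monotone, and validated", {
  inst <- rand_instance(4, 5, seed = 2)
  s1 <- run_simulation(inst$network, inst$dep, replicates = 50, seed = 5)
  s2 <- run_simulation(inst$network, inst$dep, replicates = 50, seed = 5)
  expect_identical(s1$survival, s2$survival)
  expect_identical(s1$frac_species, s2$frac_species)
  s3 <- run_simulation(inst$network, inst$dep, replicates = 50, seed = 6)
  expect_false(identical(s1$survival, s3$survival))

  expect_true(all(s1$survival[, 1] == 1))
  expect_true(all(apply(s1$survival, 1, function(tr) all(diff(tr) <= 1e-12))))
  expect_error(run_simulation(inst$network, inst$dep[-1], replicates = 2),
               "missing plant")
})

test_that("dependence extremes pin the boundary outcomes", {
  inst <- rand_instance(4, 5, seed = 3)
  zero <- structure(rep(0, 4), names = plant_ids(inst$network))
  s0 <- run_simulation(inst$network, zero, replicates = 100, seed = 1)
  expect_true(all(s0$survival == 1))

  one <- structure(rep(1, 4), names = plant_ids(inst$network))
  s1 <- run_simulation(inst$network, one, replicates = 100, seed = 1)
  expect_true(all(s1$survival[, 6] == 0))
})

test_that("two-partner toy matches the enumerated two-event outcome tree", {
  # plant with IPD 0.5 and equal-weight partners: survive j (P = 0.75) then
  # k (d = 1, P = 0.5) -> 0.375 overall
  net <- interaction_network(matrix(c(1, 1), 1, 2,
    dimnames = list("A", c("j", "k"))))
  dep <- c(A = 0.5)
  ex <- exhaustive_expected_survival(net, dep)
  expect_equal(unname(ex[1, ]), c(1, 0.75, 0.375), tolerance = 1e-12)
  s <- run_simulation(net, dep, replicates = 10000, seed = 11)
  expect_lt(abs(s$survival[1, 3] - 0.375), mc_band(0.375, 10000))
})

test_that("dynamic re-ranking targets the currently best-connected pollinator", {
  inst <- rand_instance(5, 6, seed = 8)
  sd_ <- run_simulation(inst$network, inst$dep, scenario = "generalist",
                        replicates = 30, seed = 2, dynamic_rank = TRUE)
  expect_true(all(sd_$survival[, 1] == 1))
  expect_true(all(apply(sd_$survival, 1, function(tr) all(diff(tr) <= 1e-12))))
  expect_equal(ncol(sd_$survival), 7)
})
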