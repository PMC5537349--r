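test_that("edge-list reader builds the matrix, sums duplicates, rejects bad input", {
  p <- write_tmp_csv(c("plant,pollinator,weight",
                       "A,x,2.0", "A,y,1.0", "B,y,4.0"))
  net <- read_network(p)
  expect_equal(net$visits,
               matrix(c(2, 0, 1, 4), 2, 2,
                      dimnames = list(c("A", "B"), c("x", "y"))))

  p2 <- write_tmp_csv(c("plant,pollinator,weight", "A,x,1.0", "A,x,2.0"))
  expect_equal(unname(read_network(p2)$visits[1, 1]), 3)

  p3 <- write_tmp_csv(c("plant,pollinator,weight", "A,x,-1"))
  expect_error(read_network(p3), "negative weight.*1")
  p4 <- write_tmp_csv(c("plant,weight", "A,1"))
  expect_error(read_network(p4), "missing required column")
})

test_that("guild column survives reading and writing round-trips bit-exactly", {
  p <- write_tmp_csv(c("plant,pollinator,weight,guild",
                       "A,x,0.123456789012345,beetles",
                       "A,y,1.0,flies", "B,y,4.0,flies"))
  net <- read_network(p)
  expect_equal(unname(net$guild), c("beetles", "flies"))
  out <- tempfile(fileext = ".csv")
  write_network(net, out)
  net2 <- read_network(out)
  expect_identical(net2$visits, net$visits)
  expect_identical(net2$guild, net$guild)

  # adjacency-matrix convenience dialect
  pm <- write_tmp_csv(c(",x,y", "A,2,1", "B,0,4"))
  expect_equal(read_network_matrix(pm)$visits, read_network(write_tmp_csv(
    c("plant,pollinator,weight", "A,x,2", "A,y,1", "B,y,4")))$visits)
})

test_that("network validation enforces the structural invariants", {
  m <- function(...) matrix(..., dimnames = list(c("A", "B"), c("x", "y")))
  expect_error(interaction_network(m(c(1, 0, 0, 0), 2, 2)),
               "no positive interaction")
  expect_error(interaction_network(m(c(-1, 1, 1, 1), 2, 2)), "negative")
  expect_error(interaction_network(
    matrix(1, 2, 2, dimnames = list(c("A", "B"), c("A", "y")))), "disjoint")
})

test_that("relative dependence renormalises over surviving partners", {
  net <- interaction_network(matrix(c(3, 1, 2, 1, 0, 2), 1, 6,
    dimnames = list("A", paste0("p", 1:6)))[, 1:3, drop = FALSE])
  st <- cascade_state(net)
  expect_equal(relative_dependence(st, "A"),
               c(p1 = 0.5, p2 = 1 / 6, p3 = 1 / 3))
  st$extant_pollinators <- c("p1", "p3")
  expect_equal(relative_dependence(st, "A"), c(p1 = 0.6, p3 = 0.4))
  st$extant_pollinators <- "p3"  # last surviving partner takes d = 1
  expect_equal(relative_dependence(st, "A"), c(p3 = 1))
  st$extant_plants <- character(0)
  expect_error(relative_dependence(st, "A"), "not extant")

  # sums to 1 for every extant plant of random networks
  for (s in 1:5) {
    inst <- rand_instance(4, 5, seed = 100 + s)
    st <- cascade_state(inst$network)
    for (pl in plant_ids(inst$network))
      expect_equal(sum(relative_dependence(st, pl)), 1, tolerance = 1e-12)
  }
})

test_that("degree and evenness metrics match hand values and bounds", {
  net <- interaction_network(matrix(c(2, 1, 1, 1, 0, 1), 2, 3,
    dimnames = list(c("A", "B"), c("x", "y", "z"))))
  expect_equal(species_degree(net, "A"), 2)
  expect_equal(species_degree(net, "A", normalised = TRUE), 2 / 3)
  expect_equal(species_degree(net, "z", normalised = TRUE), 0.5)
  expect_error(species_degree(net, "nope"), "unknown species")

  expect_equal(interaction_evenness(
    interaction_network(matrix(c(2, 2, 2), 1, 3,
      dimnames = list("A", c("x", "y", "z")))), "A"), 1)
  expect_equal(interaction_evenness(toy_net(), "A"),
               -(0.75 * log(0.75) + 0.25 * log(0.25)) / log(2),
               tolerance = 1e-12)
  skewed <- interaction_network(matrix(c(1, 1e-4), 1, 2,
    dimnames = list("A", c("x", "y"))))
  expect_lt(interaction_evenness(skewed, "A"), 0.01)
  expect_equal(interaction_evenness(toy_net(), "x"), 1)  # single partner

  inst <- rand_instance(6, 8, seed = 7)
  for (sp in c(plant_ids(inst$network), pollinator_ids(inst$network))) {
    nd <- species_degree(inst$network, sp, normalised = TRUE)
    expect_true(nd > 0 && nd <= 1)
    ev <- interaction_evenness(inst$network, sp)
    expect_true(ev >= 0 && ev <= 1 + 1e-12)
  }
})

test_that("eigenvector centrality matches dense eigendecomposition and hub logic", {
  # star: single pollinator linked to all plants dominates
  star <- interaction_network(matrix(1, 4, 1,
    dimnames = list(paste0("pl", 1:4), "hub")))
  ev <- eigenvector_centrality(star)
  expect_equal(names(which.max(ev)), "hub")

  # full symmetry: all four scores equal
  sym <- interaction_network(matrix(1, 2, 2,
    dimnames = list(c("A", "B"), c("x", "y"))))
  expect_equal(unname(eigenvector_centrality(sym)), rep(0.5, 4))

  # random weighted networks against base eigen() as oracle
  for (s in 1:5) {
    inst <- rand_instance(3, 3, seed = 200 + s)
    B <- inst$network$visits
    S <- rbind(cbind(matrix(0, 3, 3), B), cbind(t(B), matrix(0, 3, 3)))
    ref <- eigen(S, symmetric = TRUE)$vectors[, 1]
    ref <- abs(ref) / sqrt(sum(ref^2))
    # some random draws are disconnected; the dominant component still
    # matches the dense decomposition (dedicated test covers the warning)
    got <- suppressWarnings(eigenvector_centrality(inst$network))
    expect_equal(unname(got), unname(ref), tolerance = 1e-8)
    expect_true(all(got >= 0))
    expect_equal(sum(got^2), 1, tolerance = 1e-12)
  }
})

test_that("centrality on a disconnected network scores the largest component", {
  V <- matrix(0, 3, 3, dimnames = list(paste0("pl", 1:3), paste0("po", 1:3)))
  V[1, 1] <- 1; V[2, 1] <- 1  # component of 3 species
  V[3, 2] <- 1; V[3, 3] <- 1  # component of 3 species -> tie, first wins
  V[2, 2] <- 0
  net <- interaction_network(V)
  expect_warning(ev <- eigenvector_centrality(net), "disconnected")
  expect_true(any(ev == 0))
  expect_equal(sum(ev^2), 1, tolerance = 1e-12)
})

test_that("species strength sums to the number of plants", {
  expect_equal(species_strength(toy_net(), "x"), 0.75)
  expect_equal(species_strength(toy_net(), "y"), 1.25)
  expect_error(species_strength(toy_net(), "A"), "not a pollinator")

  # near-sole partner of 3 plants -> strength ~3 (each d close to 1)
  V <- matrix(c(1, 1, 1, 0, 0, 1e-9), 3, 2,
              dimnames = list(paste0("pl", 1:3), c("solo", "other")))
  net <- interaction_network(V)
  expect_equal(species_strength(net, "solo"), 3, tolerance = 1e-6)

  for (s in 1:5) {
    inst <- rand_instance(5, 7, seed = 300 + s)
    strengths <- vapply(pollinator_ids(inst$network), species_strength,
                        numeric(1), network = inst$network)
    expect_equal(sum(strengths), 5, tolerance = 1e-12)
  }
})

test_that("species metrics table covers all species with guilds", {
  inst <- rand_instance(4, 6, seed = 11)
  met <- species_metrics(inst$network)
  expect_equal(nrow(met), 10)
  expect_equal(sum(met$role == "pollinator"), 6)
  expect_true(all(is.na(met$strength[met$role == "plant"])))
  expect_equal(sum(met$strength, na.rm = TRUE), 4, tolerance = 1e-12)
})
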