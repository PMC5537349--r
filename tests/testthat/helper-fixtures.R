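# shared fixtures: built in code, no files

# 2x2 toy used across modules: plants A,B; pollinators x,y
toy_net <- function() {
  interaction_network(matrix(c(3, 0, 1, 4), 2, 2,
                             dimnames = list(c("A", "B"), c("x", "y"))))
}
toy_dep <- c(A = 0.5, B = 1)

# random valid instance: weights ~ U(0.2, 2) with ~30% structural zeros,
# repaired so no species is isolated; ipd ~ U(0, 1)
rand_instance <- function(n_plants, n_pollinators, seed) {
  set.seed(seed)
  repeat {
    V <- matrix(stats::runif(n_plants * n_pollinators, 0.2, 2),
                n_plants, n_pollinators)
    V[stats::runif(length(V)) < 0.3] <- 0
    if (all(rowSums(V) > 0) && all(colSums(V) > 0)) break
  }
  dimnames(V) <- list(paste0("pl", seq_len(n_plants)),
                      paste0("po", seq_len(n_pollinators)))
  net <- interaction_network(V)
  dep <- structure(stats::runif(n_plants), names = plant_ids(net))
  list(network = net, dep = dep)
}

# tolerance band for a Monte-Carlo estimate of a known probability
mc_band <- function(p_true, n, k = 3) k * sqrt(p_true * (1 - p_true) / n) + 1e-9

write_tmp_csv <- function(lines) {
  path <- tempfile(fileext = ".csv")
  writeLines(lines, path)
  path
}
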