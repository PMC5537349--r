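#' Survival probability of a plant after losing one pollinator
#'
#' Core stochastic rule of the coextinction model: plant i survives the
#' extinction of partner pollinator j with probability
#' \deqn{P_{ij} = 1 - IPD_i \, d_{ij},}
#' where `IPD_i` is the plant's intrinsic dependence on pollinators and
#' `d_ij` its relative dependence on j among surviving partners. Coextinction
#' is certain (`P = 0`) only for a fully dependent plant losing its last
#' partner.
#'
#' @param ipd dependence value(s) in \[0, 1\].
#' @param d relative dependence value(s) in \[0, 1\].
#' @return `1 - ipd * d`, in \[0, 1\].
#' @export
survival_probability <- function(ipd, d) {
  if (any(ipd < 0 | ipd > 1) || any(d < 0 | d > 1))
    stop("ipd and d must lie in [0, 1]")
  1 - ipd * d
}

#' Apply a model variant to a network and dependence vector
#'
#' The four variants factor out the two empirical ingredients of the full
#' model: `"F"` keeps empirical IPD and visitation weights; `"D"` forces
#' `IPD = 1` for every plant (obligate dependence); `"H"` homogenises each
#' plant's positive weights (so `d_ij = 1/k_i` among its k partners) while
#' keeping empirical IPD; `"DH"` applies both. Inputs are never mutated.
#'
#' @param network an `interaction_network`.
#' @param dep named dependence vector covering the network's plants.
#' @param variant one of `"F"`, `"D"`, `"H"`, `"DH"`.
#' @return List with elements `network` and `dep` after transformation.
#' @export
apply_variant <- function(network, dep, variant = c("F", "D", "H", "DH")) {
  variant <- match.arg(variant)
  dep <- dependence_vector(dep, network)
  if (variant %in% c("D", "DH")) dep[] <- 1
  if (variant %in% c("H", "DH")) {
    V <- network$visits
    V[V > 0] <- 1
    network <- interaction_network(V, guild = network$guild)
  }
  list(network = network, dep = dep)
}

#' Primary pollinator removal order for a scenario
#'
#' Returns a permutation of all pollinators: `"random"` is a uniform
#' permutation; `"generalist"` sorts by descending initial degree (hub
#' attack, as in the attack-tolerance literature); `"specialist"` by
#' ascending degree. Ties in degree are broken by a fresh uniform shuffle at
#' every call, so repeated calls under different RNG states give unbiased
#' species-level estimates. Uses the current RNG state.
#'
#' @param network an `interaction_network`.
#' @param scenario one of `"random"`, `"generalist"`, `"specialist"`.
#' @return Character vector: all pollinator ids in removal order.
#' @export
scenario_order <- function(network,
                           scenario = c("random", "generalist", "specialist")) {
  scenario <- match.arg(scenario)
  pollinator_ids(network)[.scenario_order_idx(network$visits, scenario)]
}

.scenario_order_idx <- function(V, scenario) {
  nP <- ncol(V)
  if (scenario == "random") return(sample.int(nP))
  deg <- colSums(V > 0)
  tie <- sample.int(nP)  # fresh shuffle breaks degree ties uniformly
  if (scenario == "generalist") order(-deg, tie) else order(deg, tie)
}

## ---- fast replicate engine --------------------------------------------
## One replicate of the hybrid cascade on raw matrices, using the current
## RNG state. V: nA x nP weights; ipd: length-nA; ord: integer permutation
## of pollinator columns. Returns plant-extancy indicators after each of
## the nP events (column 1 = event 0) and the count of extant pollinators.
.scm_replicate <- function(V, ipd, ord) {
  nA <- nrow(V); nP <- ncol(V)
  alive_p <- rep(TRUE, nA)
  alive_a <- rep(TRUE, nP)
  surv <- matrix(FALSE, nA, nP + 1L)
  surv[, 1L] <- TRUE
  n_poll <- integer(nP + 1L)
  n_poll[1L] <- nP
  for (k in seq_len(nP)) {
    j <- ord[k]
    if (alive_a[j]) {
      # a scheduled target already secondarily extinct is skipped but the
      # event index still advances (branch below)
      cand <- which(alive_p & V[, j] > 0)
      if (length(cand)) {
        # d over extant partners INCLUDING j (pre-removal denominator)
        denom <- rowSums(V[cand, alive_a, drop = FALSE])
        d <- V[cand, j] / denom
        dies <- stats::runif(length(cand)) < ipd[cand] * d
        alive_p[cand[dies]] <- FALSE
      }
      alive_a[j] <- FALSE
      if (any(alive_a)) {
        la <- which(alive_a)
        starved <- colSums(V[alive_p, la, drop = FALSE] > 0) == 0
        alive_a[la[starved]] <- FALSE
      }
    }
    surv[, k + 1L] <- alive_p
    n_poll[k + 1L] <- sum(alive_a)
  }
  list(plants = surv, n_pollinators = n_poll)
}

## dynamic re-ranking variant: the next target is chosen each event from the
## degree of the masked (current) network
.scm_replicate_dynamic <- function(V, ipd, scenario) {
  nA <- nrow(V); nP <- ncol(V)
  alive_p <- rep(TRUE, nA)
  alive_a <- rep(TRUE, nP)
  surv <- matrix(FALSE, nA, nP + 1L)
  surv[, 1L] <- TRUE
  n_poll <- integer(nP + 1L)
  n_poll[1L] <- nP
  for (k in seq_len(nP)) {
    la <- which(alive_a)
    if (length(la)) {
      deg <- colSums(V[alive_p, la, drop = FALSE] > 0)
      tie <- stats::runif(length(la))
      j <- la[if (scenario == "generalist") order(-deg, tie)[1]
              else order(deg, tie)[1]]
      cand <- which(alive_p & V[, j] > 0)
      if (length(cand)) {
        denom <- rowSums(V[cand, alive_a, drop = FALSE])
        d <- V[cand, j] / denom
        dies <- stats::runif(length(cand)) < ipd[cand] * d
        alive_p[cand[dies]] <- FALSE
      }
      alive_a[j] <- FALSE
      if (any(alive_a)) {
        la2 <- which(alive_a)
        starved <- colSums(V[alive_p, la2, drop = FALSE] > 0) == 0
        alive_a[la2[starved]] <- FALSE
      }
    }
    surv[, k + 1L] <- alive_p
    n_poll[k + 1L] <- sum(alive_a)
  }
  list(plants = surv, n_pollinators = n_poll)
}

#' Remove one pollinator and settle the resulting cascade
#'
#' Reference single-event step of the hybrid model: (1) every extant plant
#' with a positive (masked) weight to pollinator `j` draws Bernoulli
#' survival with probability `1 - IPD_i * d_ij`, where `d_ij` is computed
#' over the plant's extant partners including `j` itself; draws are
#' simultaneous and independent. (2) `j` and the failed plants are removed.
#' (3) Any pollinator left with zero extant plant partners is removed
#' topologically; by construction such losses cannot trigger further plant
#' draws, so the cascade settles. Uses the current RNG state.
#'
#' @param state a `cascade_state`.
#' @param pollinator an extant pollinator id (passing an already-extinct
#'   pollinator is a sequencing error; callers skip those).
#' @param dep named dependence vector covering the network's plants.
#' @return List with the new `state` and a `log` data.frame
#'   (`species`, `role`, `type`) of this event's extinctions, where `type`
#'   is `"primary"`, `"stochastic"` (plant coextinction) or `"secondary"`
#'   (starved pollinator).
#' @export
remove_pollinator <- function(state, pollinator, dep) {
  stopifnot(inherits(state, "cascade_state"))
  if (!pollinator %in% state$extant_pollinators)
    stop("sequencing error: pollinator ", pollinator, " is not extant")
  dep <- dependence_vector(dep, state$network)
  V <- state$network$visits
  alive_p <- plant_ids(state$network) %in% state$extant_plants
  alive_a <- pollinator_ids(state$network) %in% state$extant_pollinators
  j <- match(pollinator, pollinator_ids(state$network))
  log <- data.frame(species = pollinator, role = "pollinator",
                    type = "primary", stringsAsFactors = FALSE)
  cand <- which(alive_p & V[, j] > 0)
  if (length(cand)) {
    denom <- rowSums(V[cand, alive_a, drop = FALSE])
    d <- V[cand, j] / denom
    dies <- stats::runif(length(cand)) < dep[cand] * d
    if (any(dies)) {
      alive_p[cand[dies]] <- FALSE
      log <- rbind(log, data.frame(species = plant_ids(state$network)[cand[dies]],
                                   role = "plant", type = "stochastic",
                                   stringsAsFactors = FALSE))
    }
  }
  alive_a[j] <- FALSE
  la <- which(alive_a)
  if (length(la)) {
    starved <- la[colSums(V[alive_p, la, drop = FALSE] > 0) == 0]
    if (length(starved)) {
      alive_a[starved] <- FALSE
      log <- rbind(log, data.frame(
        species = pollinator_ids(state$network)[starved],
        role = "pollinator", type = "secondary", stringsAsFactors = FALSE))
    }
  }
  state$extant_plants <- plant_ids(state$network)[alive_p]
  state$extant_pollinators <- pollinator_ids(state$network)[alive_a]
  list(state = state, log = log)
}

#' Run one cascade replicate over a full removal order
#'
#' Iterates [remove_pollinator()] over a scheduled order of primary
#' removals, skipping targets already secondarily extinct. A skipped
#' scheduled removal still consumes its event index, so every replicate has
#' exactly N_P events and survival curves share a common x-axis (fraction of
#' extinction events relative to the total number of pollinators).
#'
#' @param network an `interaction_network`.
#' @param dep named dependence vector covering the network's plants.
#' @param order character vector: a permutation of all pollinator ids.
#' @param seed optional integer seed; if `NULL`, the current RNG state is
#'   used.
#' @return List with `plants` (logical plants x (N_P + 1) extancy matrix,
#'   column k + 1 = after event k), `n_pollinators` (extant pollinator count
#'   per event) and `log` (data.frame of all extinctions with `event`).
#' @export
run_replicate <- function(network, dep, order, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (!setequal(order, pollinator_ids(network)) ||
      length(order) != ncol(network$visits))
    stop("order must be a permutation of all pollinator ids")
  dep <- dependence_vector(dep, network)
  state <- cascade_state(network)
  nP <- length(order)
  nA <- nrow(network$visits)
  surv <- matrix(FALSE, nA, nP + 1L,
                 dimnames = list(plant_ids(network), NULL))
  surv[, 1L] <- TRUE
  n_poll <- integer(nP + 1L)
  n_poll[1L] <- nP
  logs <- list()
  for (k in seq_len(nP)) {
    j <- order[k]
    if (j %in% state$extant_pollinators) {
      step <- remove_pollinator(state, j, dep)
      state <- step$state
      step$log$event <- k
      logs[[length(logs) + 1L]] <- step$log
    }
    surv[, k + 1L] <- plant_ids(network) %in% state$extant_plants
    n_poll[k + 1L] <- length(state$extant_pollinators)
  }
  list(plants = surv, n_pollinators = n_poll,
       log = if (length(logs)) do.call(rbind, logs)
             else data.frame(species = character(), role = character(),
                             type = character(), event = integer()))
}

.child_seed <- function(seed, r) {
  # per-replicate seeds from a counter keep replicates individually
  # reproducible; kept below 2^31 - 1
  as.integer((as.double(seed) %% 2147483647 * 48271 + r) %% 2147483647)
}

#' Simulate pollinator extinction cascades (stochastic coextinction model)
#'
#' Monte-Carlo estimate of per-plant survival through full pollinator
#' removal sequences. Each replicate draws a removal order for the scenario,
#' runs the hybrid cascade (stochastic plant survival, topological
#' pollinator survival, no rewiring) until no pollinators are left, and
#' records extancy after every event. Survival of plant i after event k is
#' the fraction of replicates in which i is extant after event k.
#'
#' @param network an `interaction_network`.
#' @param dep named dependence vector covering the network's plants.
#' @param scenario removal scenario, see [scenario_order()].
#' @param variant model variant, see [apply_variant()].
#' @param replicates number of removal sequences (study protocol: 10,000).
#' @param seed integer root seed; per-replicate child seeds are derived by a
#'   counter, so results are exactly reproducible and replicates
#'   independent.
#' @param dynamic_rank logical; re-rank generalist/specialist targets by the
#'   degree of the masked network after each event instead of using the
#'   initial degree (static attack sequence, the default).
#' @return A `survival_surface`: list with `survival` (plants x (N_P + 1)
#'   matrix of survival probabilities, column k + 1 = after event k),
#'   `frac_species` and `frac_plants` (mean surviving fractions per event)
#'   and `meta`.
#' @export
run_simulation <- function(network, dep, scenario = "random", variant = "F",
                           replicates = 10000L, seed = 1L,
                           dynamic_rank = FALSE) {
  stopifnot(replicates >= 1)
  scenario <- match.arg(scenario, c("random", "generalist", "specialist"))
  av <- apply_variant(network, dep, variant)
  V <- av$network$visits
  ipd <- unname(av$dep)
  nA <- nrow(V); nP <- ncol(V)
  counts <- matrix(0, nA, nP + 1L)
  poll_acc <- numeric(nP + 1L)
  for (r in seq_len(replicates)) {
    set.seed(.child_seed(seed, r))
    res <- if (dynamic_rank && scenario != "random")
      .scm_replicate_dynamic(V, ipd, scenario)
    else
      .scm_replicate(V, ipd, .scenario_order_idx(V, scenario))
    counts <- counts + res$plants
    poll_acc <- poll_acc + res$n_pollinators
  }
  surv <- counts / replicates
  dimnames(surv) <- list(plant_ids(network), paste0("event_", 0:nP))
  plants_frac <- colMeans(surv)
  new_survival_surface(
    survival = surv,
    frac_plants = plants_frac,
    frac_species = (plants_frac * nA + poll_acc / replicates) / (nA + nP),
    meta = list(model = "SCM", scenario = scenario, variant = variant,
                replicates = replicates, seed = seed,
                dynamic_rank = dynamic_rank,
                n_plants = nA, n_pollinators = nP))
}

new_survival_surface <- function(survival, frac_plants, frac_species, meta) {
  structure(list(survival = survival, frac_plants = frac_plants,
                 frac_species = frac_species, meta = meta),
            class = "survival_surface")
}

#' @export
print.survival_surface <- function(x, ...) {
  m <- x$meta
  cat(sprintf("Survival surface: %s%s, %s scenario, %d replicates\n",
              m$model, if (m$model == "SCM") paste0(" (variant ", m$variant, ")") else "",
              m$scenario, m$replicates))
  cat(sprintf("  %d plants x %d extinction events\n", m$n_plants,
              m$n_pollinators))
  cat(sprintf("  surviving plant fraction after all events: %.3f\n",
              x$frac_plants[length(x$frac_plants)]))
  invisible(x)
}
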