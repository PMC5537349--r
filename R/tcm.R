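#' Topological coextinction model baseline
#'
#' The static baseline against which the stochastic model is compared: a
#' plant goes extinct only when all of its pollinator partners have been
#' removed, regardless of interaction weights or dependence. Pollinators are
#' removed primarily according to the scenario; under the plant-side rule an
#' unremoved pollinator always retains at least one living plant partner, so
#' no secondary pollinator losses occur and pollinator richness declines as
#' `(N_P - k)/N_P` exactly.
#'
#' The model is deterministic given a removal order; randomness enters only
#' through random orders and degree-tie shuffles, so replicates matter only
#' for the random scenario (and for tied degrees).
#'
#' @param network an `interaction_network`.
#' @param scenario removal scenario, see [scenario_order()].
#' @param replicates number of removal sequences to average over.
#' @param seed integer root seed (same child-seed scheme as
#'   [run_simulation()]).
#' @return A `survival_surface` with `meta$model == "TCM"`.
#' @export
run_tcm <- function(network, scenario = "random", replicates = 10000L,
                    seed = 1L) {
  stopifnot(replicates >= 1)
  scenario <- match.arg(scenario, c("random", "generalist", "specialist"))
  V <- network$visits
  nA <- nrow(V); nP <- ncol(V)
  counts <- matrix(0, nA, nP + 1L)
  for (r in seq_len(replicates)) {
    set.seed(.child_seed(seed, r))
    ord <- .scenario_order_idx(V, scenario)
    counts <- counts + .tcm_replicate(V, ord)
  }
  surv <- counts / replicates
  dimnames(surv) <- list(plant_ids(network), paste0("event_", 0:nP))
  plants_frac <- colMeans(surv)
  new_survival_surface(
    survival = surv,
    frac_plants = plants_frac,
    frac_species = (plants_frac * nA + (nP - 0:nP)) / (nA + nP),
    meta = list(model = "TCM", scenario = scenario, variant = NA_character_,
                replicates = replicates, seed = seed,
                dynamic_rank = FALSE, n_plants = nA, n_pollinators = nP))
}

## deterministic extancy indicators for one order: plant i dies at the event
## that removes its last partner
.tcm_replicate <- function(V, ord) {
  nP <- ncol(V)
  pos <- integer(nP)
  pos[ord] <- seq_len(nP)
  death <- apply(V > 0, 1L, function(row) max(pos[row]))
  outer(death, 0:nP, ">")
}

#' Per-plant robustness from a topological-model surface
#'
#' Convenience wrapper: applies [plant_robustness()] to each plant's
#' trajectory of a [run_tcm()] surface.
#'
#' @param surface a `survival_surface`.
#' @return Data.frame with columns `plant`, `R`, `model`, `scenario`.
#' @export
tcm_robustness <- function(surface) surface_robustness(surface)
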