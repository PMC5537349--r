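#' Robustness of one plant to pollinator loss
#'
#' Area below the decaying survival-probability curve of a plant, with the
#' x-axis measured as the fraction of extinction events relative to the
#' total number of pollinators (so x runs over \[0, 1\]) and the area taken
#' by the trapezoid rule. R is bounded between 0 — survival collapses at the
#' first events (fragility) — and 1 — survival barely decreases (tolerance).
#'
#' @param trajectory numeric vector of survival probabilities indexed by
#'   event k = 0..N_P; must start at 1, lie in \[0, 1\] and be
#'   non-increasing.
#' @param tol numerical slack allowed on the monotonicity/range checks.
#' @return Robustness R in \[0, 1\].
#' @examples
#' plant_robustness(rep(1, 11))          # 1: never affected
#' plant_robustness(c(1, rep(0, 10)))    # 0.05: first-event collapse
#' plant_robustness(seq(1, 0, length.out = 11))  # 0.5: linear decay
#' @export
plant_robustness <- function(trajectory, tol = 1e-9) {
  n <- length(trajectory)
  if (n < 2) stop("trajectory needs at least events 0 and 1")
  if (anyNA(trajectory) || any(trajectory < -tol | trajectory > 1 + tol))
    stop("survival values must lie in [0, 1]")
  if (any(diff(trajectory) > tol))
    stop("survival trajectory must be non-increasing in the event index")
  (sum(trajectory) - (trajectory[1] + trajectory[n]) / 2) / (n - 1)
}

#' Robustness table for every plant of a surface
#'
#' @param surface a `survival_surface` from [run_simulation()] or
#'   [run_tcm()].
#' @return Data.frame with columns `plant`, `R`, `model`, `scenario`.
#' @export
surface_robustness <- function(surface) {
  stopifnot(inherits(surface, "survival_surface"))
  m <- surface$meta
  data.frame(
    plant = rownames(surface$survival),
    R = apply(surface$survival, 1L, plant_robustness),
    model = if (m$model == "SCM") paste0("SCM-", m$variant) else m$model,
    scenario = m$scenario,
    row.names = NULL, stringsAsFactors = FALSE)
}

#' Expected survival after the first random removal, in closed form
#'
#' Under the random scenario the first removed pollinator j is uniform over
#' all N_P pollinators, and averaging `P_ij = 1 - IPD_i d_ij` over j gives
#' \deqn{P_i = 1 - IPD_i / N_P,}
#' because a plant's relative dependences sum to 1 over its partners and
#' vanish elsewhere. Serves as an analytic cross-check on the simulator's
#' event-1 estimate.
#'
#' @param network an `interaction_network`.
#' @param dep named dependence vector covering the network's plants.
#' @param plant optional plant id(s); default all plants.
#' @return Named numeric vector of expected event-1 survival.
#' @export
analytic_expected_survival <- function(network, dep, plant = NULL) {
  dep <- dependence_vector(dep, network)
  if (is.null(plant)) plant <- plant_ids(network)
  1 - dep[plant] / ncol(network$visits)
}

#' Exact per-event expected survival by exhaustive enumeration
#'
#' Independent oracle for small networks: enumerates the full outcome tree
#' — every removal order (for the random scenario) and every joint Bernoulli
#' branch of the plant draws — and accumulates exact extancy expectations
#' per plant and event. Cost grows as N_P! times 2^(plants per event), so a
#' cap guards against combinatorial explosion.
#'
#' @param network an `interaction_network`.
#' @param dep named dependence vector covering the network's plants.
#' @param max_pollinators refuse networks with more pollinators than this.
#' @param order optional fixed removal order (character ids); if `NULL`,
#'   expectations are averaged over all N_P! orders (random scenario).
#' @return Matrix plants x (N_P + 1) of exact survival probabilities.
#' @export
exhaustive_expected_survival <- function(network, dep, max_pollinators = 5L,
                                         order = NULL) {
  dep <- dependence_vector(dep, network)
  V <- network$visits
  nA <- nrow(V); nP <- ncol(V)
  if (nP > max_pollinators)
    stop("network has ", nP, " pollinators; enumeration capped at ",
         max_pollinators)
  orders <- if (is.null(order)) {
    perms <- .permutations(nP)
    lapply(seq_len(nrow(perms)), function(i) perms[i, ])
  } else {
    if (!setequal(order, colnames(V)) || length(order) != nP)
      stop("order must be a permutation of all pollinator ids")
    list(match(order, colnames(V)))
  }
  acc <- matrix(0, nA, nP + 1L)
  for (ord in orders)
    acc <- acc + .exhaustive_one_order(V, unname(dep), ord)
  acc <- acc / length(orders)
  dimnames(acc) <- list(rownames(V), paste0("event_", 0:nP))
  acc
}

.permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- .permutations(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(i)
    cbind(i, sub + (sub >= i))))
}

.exhaustive_one_order <- function(V, ipd, ord) {
  nA <- nrow(V); nP <- ncol(V)
  acc <- matrix(0, nA, nP + 1L)
  acc[, 1L] <- 1
  recurse <- function(alive_p, alive_a, k, prob) {
    if (k > nP) return()
    j <- ord[k]
    if (!alive_a[j]) {  # skipped event: state unchanged, index advances
      acc[, k + 1L] <<- acc[, k + 1L] + prob * alive_p
      recurse(alive_p, alive_a, k + 1L, prob)
      return()
    }
    cand <- which(alive_p & V[, j] > 0)
    m <- length(cand)
    pdie <- if (m) ipd[cand] * V[cand, j] /
      rowSums(V[cand, alive_a, drop = FALSE]) else numeric(0)
    for (mask in seq_len(2^m) - 1L) {
      dies <- as.logical(bitwAnd(mask, 2^(seq_len(m) - 1L)))
      bp <- prod(ifelse(dies, pdie, 1 - pdie))
      if (bp == 0) next
      ap <- alive_p; aa <- alive_a
      ap[cand[dies]] <- FALSE
      aa[j] <- FALSE
      la <- which(aa)
      if (length(la)) {
        starved <- la[colSums(V[ap, la, drop = FALSE] > 0) == 0]
        aa[starved] <- FALSE
      }
      acc[, k + 1L] <<- acc[, k + 1L] + prob * bp * ap
      recurse(ap, aa, k + 1L, prob * bp)
    }
  }
  recurse(rep(TRUE, nA), rep(TRUE, nP), 1L, 1)
  acc
}

#' Keystone scan: selective single-pollinator extinctions
#'
#' For each pollinator, simulates its selective extinction from the intact
#' network (single primary removal, cascade settled) over many replicates
#' and records the mean number and fraction of surviving plant species,
#' together with the pollinator's trait covariates (normalised degree,
#' interaction evenness, eigenvector centrality, species strength) and
#' guild. Keystone pollinators are those whose loss causes the most plant
#' coextinctions.
#'
#' @param network an `interaction_network`.
#' @param dep named dependence vector covering the network's plants.
#' @param replicates Monte-Carlo replicates per pollinator (study protocol:
#'   10,000).
#' @param seed integer root seed.
#' @return Data.frame, one row per pollinator: `pollinator`, `guild`,
#'   `mean_survivors`, `mean_frac_surviving`, `mean_coextinctions`, and the
#'   covariates.
#' @export
keystone_scan <- function(network, dep, replicates = 10000L, seed = 1L) {
  dep <- dependence_vector(dep, network)
  V <- network$visits
  nA <- nrow(V); nP <- ncol(V)
  met <- species_metrics(network)
  met <- met[met$role == "pollinator", ]
  mean_surv <- numeric(nP)
  for (j in seq_len(nP)) {
    cand <- which(V[, j] > 0)
    d <- V[cand, j] / rowSums(V[cand, , drop = FALSE])
    pdie <- unname(dep[cand]) * d
    set.seed(.child_seed(seed, j))
    draws <- matrix(stats::runif(length(cand) * replicates),
                    nrow = length(cand))
    deaths <- colSums(draws < pdie)
    mean_surv[j] <- nA - mean(deaths)
  }
  data.frame(
    pollinator = colnames(V),
    guild = if (is.null(network$guild)) NA_character_
            else unname(network$guild),
    mean_survivors = mean_surv,
    mean_frac_surviving = mean_surv / nA,
    mean_coextinctions = nA - mean_surv,
    normalised_degree = met$normalised_degree,
    degree = met$degree,
    evenness = met$evenness,
    eigenvector = met$eigenvector,
    strength = met$strength,
    row.names = NULL, stringsAsFactors = FALSE)
}

#' Mean surviving plant fraction per pollinator functional group
#'
#' Aggregates a [keystone_scan()] table by guild, with species weighted
#' equally, and reports the overall single-removal average (the reference
#' line of guild-impact plots).
#'
#' @param records a data.frame as returned by [keystone_scan()].
#' @return List with `groups` (data.frame `guild`, `n`,
#'   `mean_frac_surviving`, sorted ascending so the most damaging guilds
#'   come first) and `overall_mean`.
#' @export
functional_group_summary <- function(records) {
  stopifnot(is.data.frame(records), "mean_frac_surviving" %in% names(records))
  g <- records$guild
  if (is.null(g)) g <- rep(NA_character_, nrow(records))
  if (anyNA(g) | any(g == "", na.rm = TRUE)) {
    warning("records without a guild label grouped under 'unassigned'")
    g[is.na(g) | g == ""] <- "unassigned"
  }
  agg <- stats::aggregate(records$mean_frac_surviving, by = list(guild = g),
                          FUN = mean)
  names(agg)[2] <- "mean_frac_surviving"
  agg$n <- as.integer(table(g)[agg$guild])
  agg <- agg[order(agg$mean_frac_surviving), c("guild", "n",
                                               "mean_frac_surviving")]
  rownames(agg) <- NULL
  list(groups = agg, overall_mean = mean(records$mean_frac_surviving))
}

#' Spearman rank correlation between a trait and an outcome
#'
#' Spearman's rho with average ranks for ties; two-sided p-value, exact for
#' n <= 10 and by the t-approximation for larger n.
#'
#' @param x,y paired numeric vectors, n >= 3.
#' @return List with `rho`, `p`, `n`.
#' @export
trait_correlations <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must be paired")
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) stop("need at least 3 paired observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("correlation undefined for a constant vector")
  ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman",
                                         exact = n <= 10))
  list(rho = unname(ct$estimate), p = ct$p.value, n = n)
}
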