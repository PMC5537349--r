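#' Quantitative bipartite plant-pollinator network
#'
#' Constructs and validates an `interaction_network`: a weighted bipartite
#' visitation matrix (rows = plants, columns = pollinators, entries =
#' interaction strength in visits per flower per hour) plus an optional map
#' from pollinator to functional group (guild).
#'
#' Invariants enforced: all weights are finite and non-negative; every plant
#' row and every pollinator column has at least one positive entry; plant and
#' pollinator label sets are duplicate-free and disjoint.
#'
#' @param visits numeric matrix of non-negative visitation rates with plant
#'   row names and pollinator column names.
#' @param guild optional named character vector mapping pollinator ids to
#'   functional-group labels. Pollinators without a label are reported as
#'   `"unassigned"` by downstream summaries.
#' @return An object of class `interaction_network` with elements `visits`
#'   and `guild`.
#' @examples
#' v <- matrix(c(2, 0, 1, 4), 2, 2, dimnames = list(c("A", "B"), c("x", "y")))
#' net <- interaction_network(v)
#' plant_ids(net)
#' @export
interaction_network <- function(visits, guild = NULL) {
  visits <- as.matrix(visits)
  storage.mode(visits) <- "double"
  if (is.null(rownames(visits)) || is.null(colnames(visits)))
    stop("visits must have plant row names and pollinator column names")
  if (anyNA(visits) || any(!is.finite(visits)))
    stop("visits must be finite and non-missing")
  if (any(visits < 0))
    stop("negative interaction weight found; all weights must be >= 0")
  pl <- rownames(visits); po <- colnames(visits)
  if (anyDuplicated(pl)) stop("duplicate plant ids: ",
                              paste(unique(pl[duplicated(pl)]), collapse = ", "))
  if (anyDuplicated(po)) stop("duplicate pollinator ids: ",
                              paste(unique(po[duplicated(po)]), collapse = ", "))
  if (length(intersect(pl, po)))
    stop("plant and pollinator label sets must be disjoint; shared: ",
         paste(intersect(pl, po), collapse = ", "))
  zr <- rowSums(visits) == 0
  if (any(zr)) stop("plant(s) with no positive interaction: ",
                    paste(pl[zr], collapse = ", "))
  zc <- colSums(visits) == 0
  if (any(zc)) stop("pollinator(s) with no positive interaction: ",
                    paste(po[zc], collapse = ", "))
  if (!is.null(guild)) {
    if (is.null(names(guild)))
      stop("guild must be a named character vector (names = pollinator ids)")
    bad <- setdiff(names(guild), po)
    if (length(bad)) stop("guild entries for unknown pollinators: ",
                          paste(bad, collapse = ", "))
    g <- structure(rep(NA_character_, length(po)), names = po)
    g[names(guild)] <- as.character(guild)
    guild <- g
  }
  structure(list(visits = visits, guild = guild),
            class = "interaction_network")
}

#' @export
print.interaction_network <- function(x, ...) {
  cat("Quantitative bipartite plant-pollinator network\n")
  cat(sprintf("  %d plants x %d pollinators, %d links, connectance %.3f\n",
              nrow(x$visits), ncol(x$visits), sum(x$visits > 0),
              mean(x$visits > 0)))
  cat(sprintf("  total visitation %.4g visits flower^-1 h^-1\n", sum(x$visits)))
  if (!is.null(x$guild))
    cat("  functional groups:", length(unique(x$guild[!is.na(x$guild)])), "\n")
  invisible(x)
}

#' Species labels of a network
#'
#' @param network an `interaction_network`.
#' @return Character vector of plant (or pollinator) ids in matrix order.
#' @export
plant_ids <- function(network) rownames(network$visits)

#' @rdname plant_ids
#' @export
pollinator_ids <- function(network) colnames(network$visits)

#' Read a quantitative network from an edge-list CSV
#'
#' The canonical exchange format is an edge list with header columns
#' `plant,pollinator,weight` and an optional `guild` column carrying the
#' pollinator functional group. Species order is first-appearance order;
#' duplicate (plant, pollinator) rows have their weights summed.
#'
#' @param path path to a delimited text file.
#' @param sep field separator (default comma).
#' @return An `interaction_network`.
#' @seealso [write_network()], [read_network_matrix()]
#' @export
read_network <- function(path, sep = ",") {
  df <- utils::read.csv(path, sep = sep, stringsAsFactors = FALSE,
                        check.names = FALSE)
  need <- c("plant", "pollinator", "weight")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("edge list is missing required column(s): ",
         paste(miss, collapse = ", "))
  w <- suppressWarnings(as.numeric(df$weight))
  if (anyNA(w))
    stop("non-numeric weight at row(s): ",
         paste(which(is.na(w)), collapse = ", "))
  if (any(w < 0))
    stop("negative weight at row(s): ",
         paste(which(w < 0), collapse = ", "))
  pl <- unique(as.character(df$plant))
  po <- unique(as.character(df$pollinator))
  V <- matrix(0, length(pl), length(po), dimnames = list(pl, po))
  for (r in seq_len(nrow(df)))
    V[as.character(df$plant[r]), as.character(df$pollinator[r])] <-
      V[as.character(df$plant[r]), as.character(df$pollinator[r])] + w[r]
  guild <- NULL
  if ("guild" %in% names(df)) {
    g <- as.character(df$guild)
    guild <- vapply(po, function(j) {
      gj <- unique(g[as.character(df$pollinator) == j & !is.na(g) & g != ""])
      if (length(gj)) gj[1] else NA_character_
    }, character(1))
  }
  interaction_network(V, guild = guild)
}

#' Read a network from an adjacency-matrix CSV
#'
#' Convenience reader: first column holds plant ids, remaining column names
#' are pollinator ids, cells are visitation weights. No guild information.
#'
#' @inheritParams read_network
#' @return An `interaction_network`.
#' @export
read_network_matrix <- function(path, sep = ",") {
  df <- utils::read.csv(path, sep = sep, row.names = 1, check.names = FALSE)
  interaction_network(as.matrix(df))
}

#' Write a network as an edge-list CSV
#'
#' Writes the canonical edge-list dialect. Weights are serialised with 17
#' significant digits so that a read/write cycle round-trips the visitation
#' matrix bit-exactly. Rows are ordered plant-major in matrix order.
#'
#' @param network an `interaction_network`.
#' @param path output file path.
#' @return Invisibly, the path.
#' @export
write_network <- function(network, path) {
  V <- network$visits
  idx <- which(t(V) > 0)  # transpose -> plant-major when unwound below
  po_i <- (idx - 1L) %% ncol(V) + 1L
  pl_i <- (idx - 1L) %/% ncol(V) + 1L
  df <- data.frame(plant = rownames(V)[pl_i],
                   pollinator = colnames(V)[po_i],
                   weight = sprintf("%.17g", V[cbind(pl_i, po_i)]),
                   stringsAsFactors = FALSE)
  if (!is.null(network$guild))
    df$guild <- unname(network$guild[df$pollinator])
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Cascade state of a simulation replicate
#'
#' Tracks the extant species sets over one extinction cascade. Weights of
#' extinct species are masked (their rows/columns are ignored), never
#' rewired: interactions lost after a primary extinction are not recovered.
#'
#' @param network an `interaction_network`; the cascade starts with all
#'   species extant.
#' @return An object of class `cascade_state` with elements `network`,
#'   `extant_plants`, `extant_pollinators`.
#' @export
cascade_state <- function(network) {
  stopifnot(inherits(network, "interaction_network"))
  structure(list(network = network,
                 extant_plants = plant_ids(network),
                 extant_pollinators = pollinator_ids(network)),
            class = "cascade_state")
}

#' Relative dependence of a plant on each surviving pollinator
#'
#' For plant i and each of its currently extant partners j, `d_ij` is the
#' fraction of visits by j to i divided by the total visits to i by all
#' surviving partners (including j). Recomputed from the masked visitation
#' matrix at every call, so the surviving pollinators "compensate" the
#' visitation of lost ones: `d_ij = 1` when j is the last surviving partner.
#'
#' @param state a `cascade_state`.
#' @param plant an extant plant id.
#' @return Named numeric vector over the plant's extant partners; sums to 1.
#' @export
relative_dependence <- function(state, plant) {
  stopifnot(inherits(state, "cascade_state"))
  if (!plant %in% state$extant_plants)
    stop("plant ", plant, " is not extant")
  V <- state$network$visits
  w <- structure(V[plant, state$extant_pollinators],
                 names = state$extant_pollinators)
  w <- w[w > 0]
  if (!length(w))
    stop("plant ", plant, " has no extant pollinator partners")
  w / sum(w)
}

## role lookup shared by the metric functions
.species_role <- function(network, species) {
  if (species %in% plant_ids(network)) "plant"
  else if (species %in% pollinator_ids(network)) "pollinator"
  else stop("unknown species: ", species)
}

.species_weights <- function(network, species) {
  if (.species_role(network, species) == "plant") network$visits[species, ]
  else network$visits[, species]
}

#' Degree of a species
#'
#' Number of partners with a positive interaction weight. The normalised
#' form divides by the size of the opposite set (plants' degree by the
#' number of pollinators and vice versa) and lies in (0, 1].
#'
#' @param network an `interaction_network`.
#' @param species a plant or pollinator id.
#' @param normalised logical; divide by the opposite-set size.
#' @return A count, or a fraction if `normalised`.
#' @export
species_degree <- function(network, species, normalised = FALSE) {
  w <- .species_weights(network, species)
  k <- sum(w > 0)
  if (normalised) k / length(w) else k
}

#' Interaction evenness of a species
#'
#' Normalised Shannon entropy of the species' interaction-strength
#' distribution: with shares `p_j = w_j / sum(w)` over its k partners,
#' `E = -sum(p log p) / log k`. Defined as 1 for a single-partner species
#' (a one-partner distribution is trivially even).
#'
#' @inheritParams species_degree
#' @return Evenness in \[0, 1\].
#' @export
interaction_evenness <- function(network, species) {
  w <- .species_weights(network, species)
  w <- w[w > 0]
  if (length(w) == 1) return(1)
  p <- w / sum(w)
  -sum(p * log(p)) / log(length(p))
}

#' Species strength of a pollinator
#'
#' Sum over the pollinator's plant partners of their relative dependence on
#' it, computed on the full (initial) network. Strengths over all
#' pollinators sum to the number of plants.
#'
#' @param network an `interaction_network`.
#' @param pollinator a pollinator id.
#' @return Non-negative strength, bounded by the number of plants.
#' @export
species_strength <- function(network, pollinator) {
  if (.species_role(network, pollinator) != "pollinator")
    stop(pollinator, " is not a pollinator")
  D <- network$visits / rowSums(network$visits)
  sum(D[, pollinator])
}

## connected components of the bipartite graph (indices over plants then
## pollinators in the stacked symmetric adjacency)
.bipartite_components <- function(B) {
  n <- nrow(B) + ncol(B)
  A <- rbind(cbind(matrix(FALSE, nrow(B), nrow(B)), B > 0),
             cbind(t(B > 0), matrix(FALSE, ncol(B), ncol(B))))
  comp <- integer(n)
  cur <- 0L
  for (s in seq_len(n)) {
    if (comp[s]) next
    cur <- cur + 1L
    queue <- s
    comp[s] <- cur
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      nb <- which(A[v, ] & comp == 0L)
      comp[nb] <- cur
      queue <- c(queue, nb)
    }
  }
  comp
}

#' Eigenvector centrality of all species
#'
#' Leading-eigenvector scores of the bipartite adjacency in its symmetric
#' (N_A + N_P)-square form, computed by power iteration. Species interacting
#' with many, well-connected partners score higher. Weighted by default;
#' `weighted = FALSE` uses the binary adjacency. On a disconnected network
#' the score is computed on the largest component and species outside it
#' score 0 (with a warning). Scores are non-negative and normalised to unit
#' Euclidean norm.
#'
#' @param network an `interaction_network`.
#' @param weighted logical; use visitation weights (default) or the binary
#'   adjacency.
#' @param tol convergence tolerance on the iterate difference.
#' @param max_iter iteration cap; exceeding it is an error.
#' @return Named numeric vector over plants then pollinators.
#' @export
eigenvector_centrality <- function(network, weighted = TRUE,
                                   tol = 1e-10, max_iter = 10000L) {
  B <- network$visits
  if (!weighted) B <- (B > 0) * 1
  nA <- nrow(B); nP <- ncol(B)
  ids <- c(rownames(B), colnames(B))
  comp <- .bipartite_components(B)
  sizes <- tabulate(comp)
  keep <- comp == which.max(sizes)
  if (!all(keep))
    warning("network is disconnected; centrality computed on the largest ",
            "component (", sum(keep), " of ", length(keep), " species), ",
            "others score 0")
  S <- rbind(cbind(matrix(0, nA, nA), B), cbind(t(B), matrix(0, nP, nP)))
  S <- S[keep, keep, drop = FALSE]
  m <- nrow(S)
  x <- rep(1 / sqrt(m), m)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    # +I shift: the bipartite spectrum is symmetric about 0, so unshifted
    # iteration oscillates with period 2; the shift keeps the Perron vector
    y <- as.vector(S %*% x) + x
    y <- y / sqrt(sum(y^2))
    if (max(abs(y - x)) < tol) { x <- y; converged <- TRUE; break }
    x <- y
  }
  if (!converged)
    stop("eigenvector centrality failed to converge within ", max_iter,
         " iterations (last delta ", format(max(abs(y - x))), ")")
  out <- numeric(length(ids))
  out[keep] <- abs(x)
  out <- out / sqrt(sum(out^2))
  names(out) <- ids
  out
}

#' Per-species structural metrics table
#'
#' Tidy table of the trait covariates used in sensitivity and keystone
#' analyses, computed once on the initial (pre-extinction) network: degree,
#' normalised degree, interaction evenness, eigenvector centrality, and (for
#' pollinators) species strength.
#'
#' @param network an `interaction_network`.
#' @param weighted_centrality logical, passed to [eigenvector_centrality()].
#' @return A data.frame with one row per species in input order.
#' @export
species_metrics <- function(network, weighted_centrality = TRUE) {
  pl <- plant_ids(network); po <- pollinator_ids(network)
  ev <- eigenvector_centrality(network, weighted = weighted_centrality)
  ids <- c(pl, po)
  data.frame(
    species = ids,
    role = rep(c("plant", "pollinator"), c(length(pl), length(po))),
    degree = vapply(ids, species_degree, numeric(1), network = network),
    normalised_degree = vapply(ids, species_degree, numeric(1),
                               network = network, normalised = TRUE),
    evenness = vapply(ids, interaction_evenness, numeric(1),
                      network = network),
    eigenvector = unname(ev[ids]),
    strength = c(rep(NA_real_, length(pl)),
                 vapply(po, species_strength, numeric(1), network = network)),
    guild = c(rep(NA_character_, length(pl)),
              if (is.null(network$guild)) rep(NA_character_, length(po))
              else unname(network$guild)),
    row.names = NULL, stringsAsFactors = FALSE
  )
}
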