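#' Intrinsic dependence on insect pollinators (IPD)
#'
#' Estimates, per plant species, the fraction of seed set attributable to
#' pollinator visits from a paired pollination experiment: mean seed set per
#' marked flower unit under open pollination (`ss_op`) versus under
#' pollinator exclusion (`ss_pe`, fine mesh bags letting wind-borne pollen
#' through). The estimator is
#' \deqn{IPD = (SS_{op} - SS_{pe}) / SS_{op} = 1 - SS_{pe}/SS_{op},}
#' 0 for plants that set seed independently of pollinators (selfing and/or
#' wind) and 1 for plants fully reliant on them.
#'
#' Sampling noise can make exclusion out-yield open pollination; with
#' `clamp = TRUE` (default) such negative raw values are set to 0 and
#' reported via a message, keeping IPD a valid probability for the
#' coextinction simulator.
#'
#' @param ss_op numeric vector of open-pollination mean seed set; must be
#'   strictly positive (a plant setting no seed under open pollination has
#'   no estimable dependence).
#' @param ss_pe numeric vector of pollinator-exclusion mean seed set,
#'   non-negative, recycled against `ss_op`.
#' @param clamp logical; clamp negative estimates to 0.
#' @return Numeric vector of IPD values (named like `ss_op` if named).
#' @examples
#' compute_ipd(10, 4)       # 0.6
#' compute_ipd(7, 0)        # fully dependent
#' compute_ipd(5, 5)        # independent of pollinators
#' @export
compute_ipd <- function(ss_op, ss_pe, clamp = TRUE) {
  if (anyNA(ss_op) || anyNA(ss_pe))
    stop("seed-set values must not be missing")
  if (any(ss_op <= 0))
    stop("IPD undefined: open-pollination seed set must be > 0 ",
         "(offending index ", paste(which(ss_op <= 0), collapse = ", "), ")")
  if (any(ss_pe < 0))
    stop("pollinator-exclusion seed set must be >= 0")
  ipd <- 1 - ss_pe / ss_op
  neg <- ipd < 0
  if (any(neg)) {
    if (clamp) {
      message(sum(neg), " plant(s) with exclusion seed set exceeding open ",
              "pollination; IPD clamped to 0")
      ipd[neg] <- 0
    }
  }
  ipd
}

#' Validate a per-plant dependence vector
#'
#' @param dep named numeric vector, plant id -> IPD in \[0, 1\].
#' @param network optional `interaction_network`; if given, `dep` must cover
#'   exactly its plants and is returned in network plant order.
#' @return The validated (and possibly reordered) vector.
#' @export
dependence_vector <- function(dep, network = NULL) {
  if (is.null(names(dep)) || anyDuplicated(names(dep)))
    stop("dependence vector must have unique plant names")
  if (anyNA(dep) || any(dep < 0 | dep > 1))
    stop("IPD values must lie in [0, 1]")
  if (!is.null(network)) {
    pl <- plant_ids(network)
    miss <- setdiff(pl, names(dep))
    if (length(miss))
      stop("dependence vector missing plant(s): ", paste(miss, collapse = ", "))
    dep <- dep[pl]
  }
  dep
}

#' Read an IPD table from CSV
#'
#' Two dialects, auto-detected by header: `(plant, ipd)` carrying the
#' dependence values directly, or `(plant, ss_op, ss_pe)` carrying seed-set
#' pairs, converted through [compute_ipd()].
#'
#' @param path path to the CSV file.
#' @param clamp passed to [compute_ipd()] for the seed-set dialect.
#' @return Named numeric vector of IPD values in file order.
#' @export
read_ipd <- function(path, clamp = TRUE) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!"plant" %in% names(df))
    stop("IPD table must have a 'plant' column")
  if (anyDuplicated(df$plant))
    stop("duplicate plant ids in IPD table")
  if ("ipd" %in% names(df)) {
    dep <- structure(as.numeric(df$ipd), names = as.character(df$plant))
  } else if (all(c("ss_op", "ss_pe") %in% names(df))) {
    dep <- structure(compute_ipd(df$ss_op, df$ss_pe, clamp = clamp),
                     names = as.character(df$plant))
  } else {
    stop("IPD table must have either an 'ipd' column or 'ss_op'/'ss_pe' columns")
  }
  dependence_vector(dep)
}

#' Community-level IPD summary
#'
#' Arithmetic mean and sample standard deviation (n - 1 denominator) of a
#' community's plant dependence values.
#'
#' @param dep named numeric vector of IPD values.
#' @return List with `mean`, `sd` (NA for a single plant) and `n`.
#' @export
community_ipd_summary <- function(dep) {
  if (!length(dep)) stop("empty dependence vector")
  list(mean = mean(dep), sd = stats::sd(dep), n = length(dep))
}
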