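#' Construct a constrained metabolic model
#'
#' The static data of the growth-maximizing linear program: stoichiometry,
#' reversibility classes, per-direction flux costs with a crowding budget,
#' biomass composition, maintenance demands, and exchange annotations for
#' external metabolites.
#'
#' Units follow the conventions used throughout the package: fluxes and
#' maintenance rates in mmol/gDW/h, biomass coefficients in mmol/gDW,
#' concentrations in mM, the crowding budget in the same (arbitrary) cost
#' units as the cost coefficients.
#'
#' @param stoichiometry numeric matrix (metabolites x reactions) of
#'   stoichiometric coefficients; positive entries produce, negative consume.
#'   Must carry row (metabolite) and column (reaction) names.
#' @param lb,ub reversibility bounds per reaction, each in \{-Inf, 0, Inf\}.
#'   Defaults: irreversible forward (lb = 0, ub = Inf).
#' @param cost_fwd,cost_rev nonnegative cost coefficients per reaction and
#'   direction (cost units per mmol/gDW/h).
#' @param budget crowding budget C > 0 bounding the cost-weighted flux sum.
#' @param biomass named nonnegative vector: mmol of each metabolite consumed
#'   per gDW of biomass produced. Names must be metabolites.
#' @param maintenance named nonnegative vector of growth-independent drains
#'   (mmol/gDW/h). Missing metabolites default to 0.
#' @param external character vector of metabolites exchangeable with the
#'   culture medium.
#' @param uptake_max named vector V_i of maximum uptake rates for external
#'   metabolites; missing entries default to Inf.
#' @param secretion named vector L_i in \{0, Inf\}: 0 forbids secretion of
#'   that external metabolite, Inf allows it. Missing entries default to Inf.
#' @return object of class `metabolic_model`.
#' @seealso [solve_fba()], [read_model()], [toy_as_generic_model()]
#' @export
metabolic_model <- function(stoichiometry, lb = NULL, ub = NULL,
                            cost_fwd = NULL, cost_rev = NULL, budget,
                            biomass, maintenance = NULL, external,
                            uptake_max = NULL, secretion = NULL) {
  S <- as.matrix(stoichiometry)
  if (is.null(rownames(S)) || is.null(colnames(S)))
    stop("stoichiometry must have metabolite row names and reaction column names")
  mets <- rownames(S); rxns <- colnames(S)
  nr <- length(rxns)

  lb <- fill_named(lb, rxns, 0)
  ub <- fill_named(ub, rxns, Inf)
  cost_fwd <- fill_named(cost_fwd, rxns, 0)
  cost_rev <- fill_named(cost_rev, rxns, 0)
  y <- fill_named(biomass, mets, 0)
  e <- fill_named(maintenance, mets, 0)
  if (!all(names(biomass) %in% mets))
    stop("biomass refers to unknown metabolites: ",
         paste(setdiff(names(biomass), mets), collapse = ", "))
  if (!all(external %in% mets))
    stop("external metabolites not in model: ",
         paste(setdiff(external, mets), collapse = ", "))
  V <- fill_named(uptake_max, external, Inf)
  L <- fill_named(secretion, external, Inf)
  if (!is.null(uptake_max) && !all(names(uptake_max) %in% external))
    stop("uptake annotation for non-external metabolite")
  if (!is.null(secretion) && !all(names(secretion) %in% external))
    stop("secretion annotation for non-external metabolite")

  m <- structure(list(
    metabolites = mets, reactions = rxns, S = S,
    lb = lb, ub = ub, cost_fwd = cost_fwd, cost_rev = cost_rev,
    budget = budget, biomass = y, maintenance = e,
    external = external, uptake_max = V, secretion = L
  ), class = "metabolic_model")
  validate_model(m)
  m
}

fill_named <- function(x, names, default) {
  out <- rep(default, length(names))
  names(out) <- names
  if (!is.null(x)) {
    if (is.null(names(x))) {
      stopifnot(length(x) == length(names))
      out[] <- x
    } else out[intersect(names(x), names)] <- x[intersect(names(x), names)]
  }
  out
}

validate_model <- function(m) {
  stopifnot(inherits(m, "metabolic_model"))
  if (any(m$biomass < 0)) stop("biomass coefficients must be >= 0")
  if (any(m$maintenance < 0)) stop("maintenance rates must be >= 0")
  if (any(m$cost_fwd < 0) || any(m$cost_rev < 0)) stop("costs must be >= 0")
  if (!is.numeric(m$budget) || length(m$budget) != 1 || m$budget <= 0)
    stop("crowding budget C must be a single positive number")
  if (any(m$lb > m$ub)) stop("lb > ub for some reaction")
  if (!all(m$lb %in% c(-Inf, 0)) || !all(m$ub %in% c(0, Inf)))
    stop("reversibility bounds must lie in {-Inf, 0, Inf}")
  if (!all(m$secretion %in% c(0, Inf)))
    stop("secretion permissions must be 0 or Inf")
  if (any(m$uptake_max < 0)) stop("uptake_max must be >= 0")
  invisible(TRUE)
}

#' @export
print.metabolic_model <- function(x, ...) {
  cat("<metabolic_model> ", length(x$metabolites), " metabolites (",
      length(x$external), " external), ", length(x$reactions),
      " reactions, budget C = ", format(x$budget), "\n", sep = "")
  invisible(x)
}

#' Define a culture medium
#'
#' A medium is a named vector of feed concentrations (mM). Metabolites absent
#' from the definition have concentration zero; `Inf` is allowed for
#' compounds supplied in practical excess (water, protons, oxygen).
#'
#' @param ... named concentrations, or a single named numeric vector.
#' @return named numeric vector of class `medium`.
#' @export
medium <- function(...) {
  args <- list(...)
  conc <- if (length(args) == 1 && is.null(names(args)) && !is.null(names(args[[1]])))
    unlist(args[[1]]) else unlist(args)
  if (is.null(conc)) conc <- stats::setNames(numeric(0), character(0))
  if (length(conc) && (is.null(names(conc)) || any(names(conc) == "")))
    stop("all medium concentrations must be named")
  if (any(conc < 0)) stop("medium concentrations must be >= 0")
  structure(conc, class = "medium")
}

medium_conc <- function(med, metabolites) {
  out <- rep(0, length(metabolites))
  names(out) <- metabolites
  hit <- intersect(names(med), metabolites)
  out[hit] <- unclass(med)[hit]
  out
}

#' Specify a toxicity mechanism
#'
#' Couples waste accumulation in the culture back onto the effective growth
#' rate. Two mechanisms are supported: `"death_rate"` subtracts a death rate
#' linear in the toxic concentrations (mu = z - sum tau_j s_j), and
#' `"yield_factor"` multiplies growth by hyperbolic inhibition factors
#' (mu = z * prod (1 + s_j/K_j)^-1), as used for lactate and ammonia.
#'
#' @param mechanism `"death_rate"` or `"yield_factor"`.
#' @param coefficients named nonnegative vector: per-metabolite linear death
#'   coefficients tau (1/h/mM) for `"death_rate"`, or half-inhibition
#'   constants K (mM) for `"yield_factor"`. An empty vector means no
#'   toxicity.
#' @return object of class `toxicity_spec`.
#' @export
toxicity_spec <- function(mechanism = c("death_rate", "yield_factor"),
                          coefficients = numeric(0)) {
  mechanism <- match.arg(mechanism)
  if (length(coefficients)) {
    if (is.null(names(coefficients)) || any(names(coefficients) == ""))
      stop("toxicity coefficients must be named by metabolite")
    if (any(coefficients < 0)) stop("toxicity coefficients must be >= 0")
    if (mechanism == "yield_factor" && any(coefficients == 0))
      stop("half-inhibition constants must be > 0")
  }
  structure(list(mechanism = mechanism, coefficients = coefficients),
            class = "toxicity_spec")
}

#' @export
print.toxicity_spec <- function(x, ...) {
  cat("<toxicity_spec> mechanism:", x$mechanism, "\n")
  if (length(x$coefficients))
    print(x$coefficients) else cat("  (no toxic metabolites)\n")
  invisible(x)
}
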