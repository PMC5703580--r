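#' Parameters of the analytically solvable overflow-metabolism network
#'
#' A four-metabolite network (external nutrient S and waste W, internal
#' intermediate P and energy currency E) with a fermentation-like branch
#' (S -> P + N_F E), a capped respiration-like branch (P -> N_R E,
#' r <= r_max), waste secretion (P -> W), an ATP maintenance drain e and a
#' biomass yield y on E. Waste is toxic through a linear death rate tau * w.
#' Every steady-state quantity of this network has a closed form, which the
#' rest of the package uses as an exact oracle.
#'
#' Defaults are literature-derived values for a generic mammalian cell:
#' glycolytic and respiratory ATP yields 2 and 38, maintenance 1.0625
#' mmol ATP/gDW/h, respiratory cap 0.45 and maximum glucose uptake 0.5
#' mmol/gDW/h, biomass yield 348 mmol ATP/gDW (tuned so the maximum growth
#' rate is about one doubling per day), feed glucose 15 mM, waste toxicity
#' 0.0022 per h per mM, and 0.9 ng dry weight per cell.
#'
#' @param N_F,N_R energy units produced per unit substrate in the
#'   fermentation and respiration branches (N_F < N_R).
#' @param r_max respiratory flux cap (mmol/gDW/h).
#' @param e ATP maintenance demand (mmol/gDW/h).
#' @param y biomass yield on energy (mmol/gDW).
#' @param V maximum substrate uptake rate (mmol/gDW/h).
#' @param tau waste toxicity, death rate per unit concentration (1/h/mM).
#' @param c substrate concentration in the feed (mM).
#' @param dw_per_cell cell dry weight (g), used only for unit conversions.
#' @return object of class `toy_params`.
#' @export
toy_params <- function(N_F = 2, N_R = 38, r_max = 0.45, e = 1.0625,
                       y = 348, V = 0.5, tau = 0.0022, c = 15,
                       dw_per_cell = 0.9e-9) {
  p <- structure(list(N_F = N_F, N_R = N_R, r_max = r_max, e = e, y = y,
                      V = V, tau = tau, c = c, dw_per_cell = dw_per_cell),
                 class = "toy_params")
  stopifnot(N_F < N_R, N_F > 0, r_max > 0, e > 0, y > 0, V > 0, c > 0,
            dw_per_cell > 0, tau >= 0)
  u_m <- e / (N_F + N_R)
  if (u_m > r_max)
    stop("maintenance uptake u_m = e/(N_F+N_R) exceeds r_max; ",
         "the respiration-only regime would be unable to sustain the cell")
  p
}

#' Closed-form steady-state fluxes of the toy network
#'
#' u = min\{V, c/xi\} (u = V at xi = 0), r = min\{u, r_max\}, v = r - u <= 0
#' (waste secretion rate, negative = secretion).
#'
#' @param params a [toy_params()].
#' @param xi nonnegative scalar or vector, gDW h/L.
#' @return data frame with columns xi, u, r, v (mmol/gDW/h).
#' @export
toy_fluxes <- function(params, xi) {
  stopifnot(inherits(params, "toy_params"), all(xi >= 0))
  u <- ifelse(xi == 0, params$V, pmin(params$V, params$c / xi))
  r <- pmin(u, params$r_max)
  data.frame(xi = xi, u = u, r = r, v = r - u)
}

#' Closed-form steady-state culture concentrations of the toy network
#'
#' Substrate s* = c - min\{V xi, c\} and waste
#' w* = max\{0, c - s* - r_max xi\}; s* is decreasing in xi and w* has at
#' most one interior maximum.
#'
#' @inheritParams toy_fluxes
#' @return data frame with columns xi, s, w (mM).
#' @export
toy_concentrations <- function(params, xi) {
  stopifnot(inherits(params, "toy_params"), all(xi >= 0))
  s <- params$c - pmin(params$V * xi, params$c)
  w <- pmax(0, params$c - s - params$r_max * xi)
  data.frame(xi = xi, s = s, w = w)
}

#' Closed-form steady-state growth of the toy network
#'
#' Biomass synthesis z = (N_F u + N_R r - e)/y and effective growth
#' mu = z - tau w* with the steady waste concentration w*(xi).
#'
#' @inheritParams toy_fluxes
#' @return data frame with columns xi, z, mu (1/h). Values of xi at or
#'   beyond the medium depth (where maintenance cannot be met and z would be
#'   negative) yield NA with a warning.
#' @export
toy_growth <- function(params, xi) {
  fl <- toy_fluxes(params, xi)
  cc <- toy_concentrations(params, xi)
  z <- (params$N_F * fl$u + params$N_R * fl$r - params$e) / params$y
  bad <- z < 0
  if (any(bad)) {
    warning("xi at or beyond the medium depth: maintenance unmet, growth undefined")
    z[bad] <- NA_real_
  }
  data.frame(xi = xi, z = z, mu = z - params$tau * cc$w)
}

#' Critical xi thresholds of the toy network
#'
#' Three thresholds partition the xi axis: xi_0 = c/V (nutrient excess ends,
#' substrate becomes limiting), xi_sec = c/r_max (overflow secretion stops),
#' and the medium depth xi_m = c (N_F + N_R)/e = c/u_m beyond which the
#' maintenance demand cannot be met.
#'
#' @inheritParams toy_fluxes
#' @return list with elements xi_0, xi_sec, xi_m (gDW h/L).
#' @export
toy_thresholds <- function(params) {
  stopifnot(inherits(params, "toy_params"))
  u_m <- params$e / (params$N_F + params$N_R)
  list(xi_0 = params$c / params$V,
       xi_sec = params$c / params$r_max,
       xi_m = params$c / u_m)
}

#' Encode the toy network as a generic metabolic model
#'
#' Builds the [metabolic_model()] / [medium()] / [toxicity_spec()] triple
#' whose LP solution reproduces the closed forms. The respiratory cap is
#' realized through the crowding budget (cost C/r_max on respiration, zero
#' elsewhere), so solving it exercises the cost-constraint machinery; set
#' `hard_bound_cap = TRUE` to instead encode r <= r_max as a hard bound via
#' a respiratory cofactor with a finite uptake rate (used for differential
#' testing of the two constructions).
#'
#' @inheritParams toy_fluxes
#' @param budget crowding budget C (cost units); the respiration cost is
#'   C/r_max so the cap is invariant to this choice.
#' @param hard_bound_cap realize the respiratory cap as an uptake-style hard
#'   bound instead of a cost (alternate construction).
#' @return list with elements `model`, `medium`, `toxicity`, `params`.
#' @export
toy_as_generic_model <- function(params = toy_params(), budget = 1,
                                 hard_bound_cap = FALSE) {
  stopifnot(inherits(params, "toy_params"))
  mets <- c("S", "P", "E", "W")
  ##               gly  resp  sec
  S <- matrix(c(  -1,    0,   0,     # S
                   1,   -1,  -1,     # P
            params$N_F, params$N_R, 0, # E
                   0,    0,   1),    # W
              nrow = 4, byrow = TRUE,
              dimnames = list(mets, c("gly", "resp", "sec")))
  cost_fwd <- c(gly = 0, resp = budget / params$r_max, sec = 0)
  mdl <- metabolic_model(
    stoichiometry = S,
    lb = c(gly = 0, resp = 0, sec = 0),
    ub = c(gly = Inf, resp = Inf, sec = Inf),
    cost_fwd = if (hard_bound_cap) NULL else cost_fwd,
    budget = budget,
    biomass = c(E = params$y),
    maintenance = c(E = params$e),
    external = c("S", "W"),
    uptake_max = c(S = params$V, W = 0),
    secretion = c(S = 0, W = Inf))
  med <- medium(S = params$c)
  if (hard_bound_cap) {
    ## alternate construction: respiration consumes a cofactor Q supplied at
    ## infinite concentration but finite uptake rate r_max
    S2 <- rbind(mdl$S, Q = c(0, -1, 0))
    mdl <- metabolic_model(
      stoichiometry = S2, budget = budget,
      biomass = c(E = params$y), maintenance = c(E = params$e),
      external = c("S", "W", "Q"),
      uptake_max = c(S = params$V, W = 0, Q = params$r_max),
      secretion = c(S = 0, W = Inf, Q = 0))
    med <- medium(S = params$c, Q = Inf)
  }
  list(model = mdl,
       medium = med,
       toxicity = toxicity_spec("death_rate", c(W = params$tau)),
       params = params)
}
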