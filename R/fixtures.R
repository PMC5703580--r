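#' Generate a synthetic metabolic-model fixture
#'
#' Deterministic (seeded) small networks for testing every layer of the
#' package without external model files. Three topologies:
#' \describe{
#'   \item{toy}{the overflow network of [toy_as_generic_model()] with
#'     default parameters.}
#'   \item{chain}{a linear pathway S -> I1 -> ... -> E with a single energy
#'     yield at the end; its optimum has the closed form
#'     z(xi) = (yield * min\{V, c/xi\} - e)/y, returned in `info` for
#'     differential testing.}
#'   \item{branched}{a randomized overflow network (toy topology with drawn
#'     parameters respecting the parameter invariants), exposing the full
#'     secretion/limitation phase structure.}
#' }
#'
#' @param topology "toy", "chain" or "branched".
#' @param n_reactions chain length for "chain" (>= 2).
#' @param seed integer seed; the same seed yields an identical fixture. The
#'   global RNG state is left untouched.
#' @param cost_range range of random cost coefficients.
#' @return list with `model`, `medium`, `toxicity`, and `info` (topology,
#'   drawn parameters, and for "chain"/"branched" the closed-form `z_star`
#'   function of xi).
#' @export
generate_fixture <- function(topology = c("toy", "chain", "branched"),
                             n_reactions = 4, seed = 1,
                             cost_range = c(0.5, 2)) {
  topology <- match.arg(topology)
  if (topology == "toy") {
    out <- toy_as_generic_model()
    out$info <- list(topology = "toy", params = out$params)
    return(out)
  }
  runif_d <- local_rng(seed)

  if (topology == "chain") {
    stopifnot(n_reactions >= 2)
    yield <- round(runif_d(1, 5, 40))
    V <- runif_d(1, 0.2, 1)
    conc <- runif_d(1, 5, 30)
    y <- runif_d(1, 100, 500)
    e <- runif_d(1, 0.1, 0.9) * yield * V   # feasible at xi = 0
    mets <- c("S", paste0("I", seq_len(n_reactions - 1)), "E")
    rxns <- paste0("step", seq_len(n_reactions))
    S <- matrix(0, length(mets), n_reactions,
                dimnames = list(mets, rxns))
    for (k in seq_len(n_reactions)) {
      S[k, k] <- -1
      S[k + 1, k] <- if (k == n_reactions) yield else 1
    }
    cost <- stats::setNames(runif_d(n_reactions, cost_range[1], cost_range[2]),
                            rxns)
    budget <- 10 * max(cost) * V        # non-binding: keeps the closed form
    mdl <- metabolic_model(
      stoichiometry = S, cost_fwd = cost, budget = budget,
      biomass = c(E = y), maintenance = c(E = e),
      external = "S", uptake_max = c(S = V), secretion = c(S = 0))
    z_star <- function(xi) {
      u <- ifelse(xi == 0, V, pmin(V, conc / xi))
      (yield * u - e) / y
    }
    return(list(model = mdl, medium = medium(S = conc),
                toxicity = toxicity_spec("death_rate"),
                info = list(topology = "chain", yield = yield, V = V,
                            conc = conc, y = y, e = e, z_star = z_star)))
  }

  ## branched: randomized overflow network
  for (attempt in 1:20) {
    N_F <- round(runif_d(1, 1, 4))
    N_R <- round(runif_d(1, 20, 50))
    V <- runif_d(1, 0.3, 1)
    r_max <- runif_d(1, 0.5, 0.95) * V
    e <- runif_d(1, 0.2, 0.8) * (N_F + N_R) * r_max
    y <- runif_d(1, 100, 500)
    tau <- runif_d(1, 5e-4, 5e-3)
    conc <- runif_d(1, 5, 30)
    p <- try(toy_params(N_F = N_F, N_R = N_R, r_max = r_max, e = e, y = y,
                        V = V, tau = tau, c = conc), silent = TRUE)
    if (!inherits(p, "try-error")) {
      out <- toy_as_generic_model(p)
      out$info <- list(topology = "branched", params = p,
                       z_star = function(xi) toy_growth(p, xi)$z)
      return(out)
    }
  }
  stop("could not draw a feasible branched fixture in 20 attempts")
}

## Seeded uniform draws that do not disturb the caller's RNG.
local_rng <- function(seed) {
  env <- new.env()
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  set.seed(seed)
  env$state <- get(".Random.seed", globalenv())
  if (!is.null(old)) assign(".Random.seed", old, globalenv())
  else rm(".Random.seed", envir = globalenv())
  function(n, lo, hi) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
    assign(".Random.seed", env$state, globalenv())
    x <- stats::runif(n, lo, hi)
    env$state <- get(".Random.seed", globalenv())
    if (!is.null(old)) assign(".Random.seed", old, globalenv())
    x
  }
}
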