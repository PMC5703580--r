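## Readers and writers: COBRA-style JSON and SBML L3 FBC for the network,
## sidecar TSV tables for culture annotations (media, uptake caps, costs,
## maintenance), TSV writers for curves, trajectories and diagrams. The
## tabular dialect is tab-separated, "." decimal, literal inf/-inf.

read_tsv_strict <- function(path) {
  utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                    comment.char = "#", check.names = FALSE)
}

parse_inf <- function(x) {
  if (is.numeric(x)) return(x)
  v <- suppressWarnings(as.numeric(x))
  v[trimws(x) %in% c("inf", "Inf", "+inf")] <- Inf
  v[trimws(x) %in% c("-inf", "-Inf")] <- -Inf
  if (anyNA(v)) stop("non-numeric value in table: ",
                     paste(x[is.na(v)], collapse = ", "))
  v
}

num_to_chr <- function(x) {
  out <- sprintf("%.17g", x)
  out[is.infinite(x) & x > 0] <- "inf"
  out[is.infinite(x) & x < 0] <- "-inf"
  out[is.na(x)] <- "NA"
  out
}

#' Read a metabolic model with culture annotations
#'
#' Assembles a [metabolic_model()], [medium()] and [toxicity_spec()] from a
#' COBRA-style JSON or SBML Level 3 FBC file plus sidecar TSV tables:
#' `costs` (reaction_id, alpha_fwd, alpha_rev), `media` (metabolite_id,
#' conc_mM; literal `inf` allowed), `uptake` (metabolite_id, V_max) and
#' `maintenance` (metabolite_id, rate). Reactions without a cost entry get
#' the median of the provided costs; metabolites without an uptake entry get
#' V = Inf. Single-metabolite exchange reactions are stripped from the
#' stoichiometry and their metabolite is marked external (together with any
#' metabolite named in the media/uptake tables).
#'
#' @param path model file (`.json` or `.xml`/`.sbml`).
#' @param costs,media,uptake,maintenance paths to the sidecar TSV tables
#'   (each optional).
#' @param budget crowding budget C; overrides any value stored in the file.
#' @param toxicity path to a YAML toxicity config with keys `mechanism` and
#'   `coefficients` (metabolite: value), or NULL for no toxicity.
#' @param amino_acids optional metabolite ids to which the convention
#'   V_i = V_glc/10 is applied (requires `V_glc`).
#' @param V_glc glucose uptake cap used by the amino-acid convention.
#' @return list with `model`, `medium`, `toxicity`.
#' @export
read_model <- function(path, costs = NULL, media = NULL, uptake = NULL,
                       maintenance = NULL, budget = NULL, toxicity = NULL,
                       amino_acids = NULL, V_glc = NULL) {
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE))
    read_cobra_json(path)
  else read_sbml_fbc(path)

  ext <- raw$external
  med_tab <- if (!is.null(media)) read_tsv_strict(media)
  upt_tab <- if (!is.null(uptake)) read_tsv_strict(uptake)
  if (!is.null(med_tab)) ext <- union(ext, med_tab[[1]])
  if (!is.null(upt_tab)) ext <- union(ext, upt_tab[[1]])
  if (!length(ext)) stop("no external metabolites: provide exchange ",
                         "reactions or media/uptake tables")
  unknown <- setdiff(ext, raw$metabolites)
  if (length(unknown))
    stop("annotation tables name unknown metabolites: ",
         paste(unknown, collapse = ", "))

  cost_fwd <- raw$cost_fwd; cost_rev <- raw$cost_rev
  if (!is.null(costs)) {
    ct <- read_tsv_strict(costs)
    if (any(!ct$reaction_id %in% raw$reactions))
      stop("cost table names unknown reactions: ",
           paste(setdiff(ct$reaction_id, raw$reactions), collapse = ", "))
    af <- parse_inf(ct$alpha_fwd); ar <- parse_inf(ct$alpha_rev)
    provided <- c(af[!is.na(af)], ar[!is.na(ar)])
    med_cost <- if (length(provided)) stats::median(provided) else 0
    cost_fwd <- stats::setNames(rep(med_cost, length(raw$reactions)),
                                raw$reactions)
    cost_rev <- cost_fwd
    cost_fwd[ct$reaction_id[!is.na(af)]] <- af[!is.na(af)]
    cost_rev[ct$reaction_id[!is.na(ar)]] <- ar[!is.na(ar)]
  }

  mnt <- raw$maintenance
  if (!is.null(maintenance)) {
    mt <- read_tsv_strict(maintenance)
    mnt <- stats::setNames(parse_inf(mt[[2]]), mt[[1]])
  }
  V <- raw$uptake_max
  if (!is.null(upt_tab))
    V <- stats::setNames(parse_inf(upt_tab[[2]]), upt_tab[[1]])
  if (!is.null(amino_acids)) {
    if (is.null(V_glc)) stop("amino_acids convention requires V_glc")
    V2 <- fill_named(V, ext, Inf)
    V2[intersect(amino_acids, ext)] <- V_glc / 10
    V <- V2
  }

  conc <- raw$medium %||% numeric(0)
  if (!is.null(med_tab))
    conc <- stats::setNames(parse_inf(med_tab[[2]]), med_tab[[1]])

  if (is.null(budget)) budget <- raw$budget
  if (is.null(budget)) stop("no crowding budget: pass budget = C")
  if (is.null(raw$biomass) || !length(raw$biomass))
    stop("no biomass reaction found (objective coefficient 1)")

  mdl <- metabolic_model(
    stoichiometry = raw$S, lb = raw$lb, ub = raw$ub,
    cost_fwd = cost_fwd, cost_rev = cost_rev, budget = budget,
    biomass = raw$biomass, maintenance = mnt, external = ext,
    uptake_max = if (is.null(V)) NULL else V[intersect(names(V), ext)],
    secretion = raw$secretion)

  tox <- if (is.null(toxicity)) toxicity_spec("death_rate")
  else {
    cfg <- yaml::read_yaml(toxicity)
    toxicity_spec(cfg$mechanism, unlist(cfg$coefficients))
  }
  list(model = mdl, medium = medium(conc), toxicity = tox)
}

## COBRA-style JSON. Recognized extensions (written by write_model_json and
## ignored by other tools): per-reaction cost_fwd/cost_rev, and a top-level
## "culture" object with budget, maintenance, external, uptake_max,
## secretion.
read_cobra_json <- function(path) {
  j <- jsonlite::read_json(path)
  mets <- vapply(j$metabolites, `[[`, "", "id")
  rx <- j$reactions
  ids <- vapply(rx, `[[`, "", "id")
  objc <- vapply(rx, function(r) as.numeric(r$objective_coefficient %||% 0), 0)

  is_exchange <- vapply(rx, function(r)
    length(r$metabolites) == 1 && grepl("^EX_", r$id), TRUE)
  is_biomass <- objc != 0

  biomass <- NULL
  if (any(is_biomass)) {
    bm <- rx[[which(is_biomass)[1]]]$metabolites
    coefs <- -unlist(bm)
    if (any(coefs < 0))
      stop("biomass reaction produces metabolites; only consumption ",
           "coefficients (y_i >= 0) are supported")
    biomass <- coefs
  }

  keep <- !is_exchange & !is_biomass
  S <- matrix(0, length(mets), sum(keep),
              dimnames = list(mets, ids[keep]))
  lb <- ub <- cf <- cr <- stats::setNames(numeric(sum(keep)), ids[keep])
  kk <- which(keep)
  for (i in seq_along(kk)) {
    r <- rx[[kk[i]]]
    cc <- unlist(r$metabolites)
    S[names(cc), i] <- cc
    lb[i] <- if (as.numeric(r$lower_bound %||% 0) < 0) -Inf else 0
    ub[i] <- if (as.numeric(r$upper_bound %||% 1000) > 0) Inf else 0
    cf[i] <- as.numeric(r$cost_fwd %||% 0)
    cr[i] <- as.numeric(r$cost_rev %||% 0)
  }
  ext <- unique(unlist(lapply(rx[is_exchange],
                              function(r) names(r$metabolites))))

  cult <- j$culture
  list(metabolites = mets, reactions = ids[keep], S = S, lb = lb, ub = ub,
       cost_fwd = cf, cost_rev = cr,
       biomass = biomass,
       maintenance = if (!is.null(cult$maintenance)) unlist(cult$maintenance),
       external = union(ext, unlist(cult$external)),
       uptake_max = if (!is.null(cult$uptake_max))
         vapply(cult$uptake_max, parse_json_num, 0),
       secretion = if (!is.null(cult$secretion))
         vapply(cult$secretion, parse_json_num, 0),
       medium = if (!is.null(cult$medium))
         vapply(cult$medium, parse_json_num, 0),
       budget = if (!is.null(cult$budget)) as.numeric(cult$budget))
}

parse_json_num <- function(x)
  if (is.character(x)) parse_inf(x) else as.numeric(x)

#' Write a model bundle as annotated COBRA-style JSON
#'
#' Serializes a model (with its medium and culture annotations) so that
#' [read_model()] recovers it field-wise. The output is a valid COBRA JSON
#' (metabolites, reactions with bounds and a biomass objective) with the
#' culture-specific data under a top-level `culture` key and per-reaction
#' cost entries.
#'
#' @param model a [metabolic_model()].
#' @param med a [medium()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_model_json <- function(model, med, path) {
  enc_num <- function(x) if (is.infinite(x)) ifelse(x > 0, "inf", "-inf") else x
  rxns <- lapply(seq_along(model$reactions), function(k) {
    nz <- which(model$S[, k] != 0)
    list(id = model$reactions[k],
         metabolites = as.list(model$S[nz, k]),
         lower_bound = if (model$lb[k] < 0) -1000 else 0,
         upper_bound = if (model$ub[k] > 0) 1000 else 0,
         objective_coefficient = 0,
         cost_fwd = model$cost_fwd[[k]],
         cost_rev = model$cost_rev[[k]])
  })
  ybm <- model$biomass[model$biomass != 0]
  rxns <- c(rxns, list(list(
    id = "biomass", metabolites = as.list(-ybm),
    lower_bound = 0, upper_bound = 1000, objective_coefficient = 1)))
  rxns <- c(rxns, lapply(model$external, function(m) list(
    id = paste0("EX_", m), metabolites = stats::setNames(list(-1), m),
    lower_bound = -1000, upper_bound = 1000, objective_coefficient = 0)))
  obj <- list(
    metabolites = lapply(model$metabolites, function(m) list(id = m)),
    reactions = rxns,
    culture = list(
      budget = model$budget,
      maintenance = as.list(model$maintenance[model$maintenance != 0]),
      external = as.list(model$external),
      uptake_max = lapply(as.list(model$uptake_max), enc_num),
      secretion = lapply(as.list(model$secretion), enc_num),
      medium = lapply(as.list(unclass(med)), enc_num)))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

## Minimal SBML Level 3 FBC reader: species, reactions with stoichiometry,
## reversibility/flux bounds mapped to sign classes, fbc objective as the
## biomass reaction, boundary-condition species as external metabolites.
read_sbml_fbc <- function(path) {
  doc <- xml2::read_xml(path)
  xml2::xml_ns_strip(doc)
  ## attributes may keep their fbc: prefix after namespace stripping
  attr2 <- function(node, name) {
    v <- xml2::xml_attr(node, name)
    if (is.na(v)) v <- xml2::xml_attr(node, paste0("fbc:", name))
    v
  }
  sp <- xml2::xml_find_all(doc, ".//listOfSpecies/species")
  mets <- xml2::xml_attr(sp, "id")
  boundary <- xml2::xml_attr(sp, "boundaryCondition") %in% "true"

  params <- xml2::xml_find_all(doc, ".//listOfParameters/parameter")
  pvals <- stats::setNames(as.numeric(xml2::xml_attr(params, "value")),
                           xml2::xml_attr(params, "id"))

  rxn_nodes <- xml2::xml_find_all(doc, ".//listOfReactions/reaction")
  ids <- xml2::xml_attr(rxn_nodes, "id")

  obj_node <- xml2::xml_find_first(doc, ".//*[local-name()='fluxObjective']")
  biomass_id <- if (!inherits(obj_node, "xml_missing"))
    attr2(obj_node, "reaction") else NA_character_

  S <- matrix(0, length(mets), length(ids), dimnames = list(mets, ids))
  lb <- ub <- stats::setNames(numeric(length(ids)), ids)
  biomass <- NULL
  for (k in seq_along(rxn_nodes)) {
    rn <- rxn_nodes[[k]]
    for (ref in xml2::xml_find_all(rn, "./listOfReactants/speciesReference")) {
      m <- xml2::xml_attr(ref, "species")
      S[m, k] <- S[m, k] - as.numeric(xml2::xml_attr(ref, "stoichiometry") %||% 1)
    }
    for (ref in xml2::xml_find_all(rn, "./listOfProducts/speciesReference")) {
      m <- xml2::xml_attr(ref, "species")
      S[m, k] <- S[m, k] + as.numeric(xml2::xml_attr(ref, "stoichiometry") %||% 1)
    }
    lo_ref <- attr2(rn, "lowerFluxBound")
    hi_ref <- attr2(rn, "upperFluxBound")
    lo <- if (!is.na(lo_ref) && lo_ref %in% names(pvals)) pvals[lo_ref]
          else if (xml2::xml_attr(rn, "reversible") %in% "true") -1 else 0
    hi <- if (!is.na(hi_ref) && hi_ref %in% names(pvals)) pvals[hi_ref] else 1
    lb[k] <- if (lo < 0) -Inf else 0
    ub[k] <- if (hi > 0) Inf else 0
  }
  if (!is.na(biomass_id) && biomass_id %in% ids) {
    coefs <- -S[, biomass_id]
    biomass <- coefs[coefs != 0]
    keep <- setdiff(ids, biomass_id)
    S <- S[, keep, drop = FALSE]; lb <- lb[keep]; ub <- ub[keep]; ids <- keep
  }
  list(metabolites = mets, reactions = ids, S = S, lb = lb, ub = ub,
       cost_fwd = NULL, cost_rev = NULL, biomass = biomass,
       maintenance = NULL, external = mets[boundary], uptake_max = NULL,
       secretion = NULL, budget = NULL)
}

write_tsv_units <- function(df, path, comments = character(0)) {
  con <- file(path, "w")
  on.exit(close(con))
  for (cm in comments) writeLines(paste0("# ", cm), con)
  chr <- df
  for (nm in names(chr))
    if (is.numeric(chr[[nm]])) chr[[nm]] <- num_to_chr(chr[[nm]])
  utils::write.table(chr, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a steady-state curve as TSV
#'
#' One row per xi with all steady-state fields in internal units
#' (h, mM, gDW) plus day/cell-count convenience columns. Numeric values are
#' written at full precision so a written curve re-reads bitwise.
#'
#' @param curve a `steady_state_curve`.
#' @param path output path.
#' @param dw_per_cell dry weight per cell (g) for the convenience columns.
#' @return `path`, invisibly.
#' @export
write_curve <- function(curve, path, dw_per_cell = 0.9e-9) {
  df <- as.data.frame(curve)
  df$xi_Mcell_day_mL <- convert_units(df$xi, "gDW*h/L", "1e6cells*day/mL",
                                      dw_per_cell)
  df$D_per_day <- df$D * 24
  df$X_Mcell_mL <- convert_units(df$X, "gDW/L", "1e6cells/mL", dw_per_cell)
  write_tsv_units(df, path, comments = c(
    "steady-state curve; units: xi gDW*h/L, z/mu/D 1/h, X gDW/L, s mM, u mmol/gDW/h",
    paste0("phi=", num_to_chr(attr(curve, "phi")),
           " eps_u=", num_to_chr(attr(curve, "eps_u")))))
}

#' Re-read a curve written by [write_curve()]
#'
#' @param path TSV path.
#' @return a `steady_state_curve`.
#' @export
read_curve <- function(path) {
  lines <- readLines(path, n = 10)
  meta <- grep("^# phi=", lines, value = TRUE)
  phi <- eps_u <- NA_real_
  if (length(meta)) {
    kv <- strsplit(sub("^# ", "", meta[1]), " ")[[1]]
    phi <- as.numeric(sub("phi=", "", kv[1]))
    eps_u <- as.numeric(sub("eps_u=", "", kv[2]))
  }
  df <- read_tsv_strict(path)
  df$xi_Mcell_day_mL <- df$D_per_day <- df$X_Mcell_mL <- NULL
  for (nm in names(df)) {
    if (nm %in% c("secreted", "limiting")) df[[nm]] <- as.character(df[[nm]])
    else if (is.numeric(df[[nm]])) df[[nm]] <- as.double(df[[nm]])
  }
  structure(df, phi = phi, eps_u = eps_u,
            class = c("steady_state_curve", "data.frame"))
}

#' Write a simulated trajectory as TSV
#'
#' @param traj a `culture_trajectory`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path) {
  df <- as.data.frame(traj)
  df$time_day <- df$time / 24
  df$D_per_day <- df$D * 24
  ev <- attr(traj, "events")
  write_tsv_units(df, path, comments = c(
    "trajectory; units: time h, D/z/mu 1/h, X gDW/L, s mM, u mmol/gDW/h",
    if (nrow(ev)) paste0("event ", num_to_chr(ev$time), "h ", ev$event)))
}

#' Write a bifurcation diagram as TSV
#'
#' One row per branch sample plus comment blocks summarizing folds,
#' multistable windows (in 1/h and 1/day) and the washout branch.
#'
#' @param diagram a `bifurcation_diagram`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_diagram <- function(diagram, path) {
  rows <- do.call(rbind, lapply(seq_along(diagram$branches), function(i) {
    br <- diagram$branches[[i]]
    data.frame(branch = i, xi = br$xi, D = br$D, X = br$X,
               stable = br$stable)
  }))
  cm <- c("bifurcation diagram; units: xi gDW*h/L, D 1/h, X gDW/L",
          paste0("phi=", num_to_chr(diagram$phi)),
          paste0("washout_branch X=0 any D; D_max=",
                 num_to_chr(diagram$washout$D_max), " 1/h"))
  if (nrow(diagram$folds))
    cm <- c(cm, sprintf("fold %s xi=%s D=%s", diagram$folds$kind,
                        num_to_chr(diagram$folds$xi),
                        num_to_chr(diagram$folds$D)))
  if (nrow(diagram$windows))
    cm <- c(cm, sprintf(
      "window D=(%s,%s) 1/h = (%s,%s) 1/day branches=%d",
      num_to_chr(diagram$windows$D_lo), num_to_chr(diagram$windows$D_hi),
      num_to_chr(diagram$windows$D_lo * 24),
      num_to_chr(diagram$windows$D_hi * 24), diagram$windows$n_branches))
  write_tsv_units(rows, path, comments = cm)
}
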