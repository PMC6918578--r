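# Formaldehyde assimilation pathway extensions and the pathway comparison.
#
# Three heterologous routes from formaldehyde to central carbon metabolism,
# all placed in the cytosol:
#   RuMP         HPS (HCHO + Ru5P -> hexulose 6-phosphate) and PHI
#                (H6P -> F6P);
#   XuMP         DHAS (HCHO + Xu5P -> DHA + GAP) and dihydroxyacetone
#                kinase (DHA + ATP -> DHAP);
#   serine cycle spontaneous/enzymatic THF loading of formaldehyde, serine
#                hydroxymethyltransferase, serine-glyoxylate
#                aminotransferase, hydroxypyruvate reductase, glycerate
#                kinase, PEP carboxylase, malate dehydrogenase (host),
#                malate thiokinase and malyl-CoA lyase.
# Every reaction is written carbon- and cofactor-explicit and conserves
# carbon.

PATHWAY_NAMES <- c("RuMP", "XuMP", "serine_cycle")

# canonical reaction definitions: id, equation, reversible lb
pathway_defs <- function(name) {
  switch(
    name,
    RuMP = list(
      c("HPS", "hcho + ru5p -> h6p", 0),
      c("PHI", "h6p -> f6p", 0)),
    XuMP = list(
      c("DHAS", "hcho + xu5p -> dha + gap", 0),
      c("DAK", "dha + atp -> dhap + adp", 0)),
    serine_cycle = list(
      c("FTHFC", "hcho + thf -> mlthf", 0),                      # THF loading
      c("SHMT", "mlthf + gly -> ser + thf", 0),
      c("SGAT", "ser + glx -> hpyr + gly", 0),
      c("HPR", "hpyr + nadh -> glyca + nad", 0),
      c("GLYCERK", "glyca + atp -> pg3 + adp", 0),
      c("PEPC", "pep + co2 -> oaa", 0),
      c("MDH_SER", "oaa + nadh <-> mal + nad", -DEFAULT_BOUND),
      c("MTK", "mal + atp + coa -> malcoa + adp", 0),
      c("MCL", "malcoa -> accoa + glx", 0)),
    stop_mp("unknown pathway '%s'; expected one of %s", name,
            paste(PATHWAY_NAMES, collapse = ", "))
  )
}

# carbon counts of metabolites the extensions may introduce
PATHWAY_CARBON <- c(h6p = 6, dha = 3, thf = 0, mlthf = 1, gly = 2, ser = 3,
                    glx = 2, hpyr = 3, glyca = 3, malcoa = 4)

#' Build a formaldehyde-assimilation pathway extension
#'
#' @param name one of `RuMP`, `XuMP`, `serine_cycle`.
#' @param compartment compartment the heterologous reactions are placed in
#'   (cytosol by default, matching the engineering aim of co-localising
#'   methanol oxidation and formaldehyde assimilation).
#' @param doc_override optional named list replacing the default equation of
#'   a reaction id, for use when a curated reaction set is available.
#' @return a list of class `pathway_extension` with elements `name`,
#'   `compartment`, `reactions` (data.frame id/lb/ub), `stoichiometry` and
#'   `carbon` (new-metabolite carbon counts).
#' @export
build_extension <- function(name, compartment = "c", doc_override = NULL) {
  assert_that(name %in% PATHWAY_NAMES,
              "unknown pathway '%s'; expected one of %s", name,
              paste(PATHWAY_NAMES, collapse = ", "))
  defs <- pathway_defs(name)
  for (id in names(doc_override %||% list())) {
    k <- which(vapply(defs, `[[`, character(1), 1) == id)
    assert_that(length(k) == 1, "doc_override names unknown reaction '%s'", id)
    defs[[k]][2] <- doc_override[[id]]
  }
  ids <- vapply(defs, `[[`, character(1), 1)
  assert_that(!anyDuplicated(ids), "duplicate reaction ids in extension")
  st <- lapply(defs, function(d) parse_equation(d[2])$stoichiometry)
  names(st) <- ids
  reactions <- data.frame(
    id = ids,
    lb = as.numeric(vapply(defs, `[[`, character(1), 3)),
    ub = DEFAULT_BOUND,
    gene_note = sprintf("%s extension", name),
    stringsAsFactors = FALSE)
  structure(list(name = name, compartment = compartment,
                 reactions = reactions, stoichiometry = st,
                 carbon = PATHWAY_CARBON),
            class = "pathway_extension")
}

#' Apply a pathway extension to a model
#'
#' Returns a new model with the extension reactions added (metabolites
#' created on demand in the extension compartment) and, optionally, the
#' alcohol-dehydrogenase reaction opened so methanol and formaldehyde
#' interconvert. The input model is not modified.
#'
#' @param model a `metabolic_model`.
#' @param extension a [build_extension()] result.
#' @param enable_adh open the methanol/formaldehyde interconversion
#'   (reaction id `adh_id`) to `[-1000, 1000]`.
#' @param adh_id id of the alcohol-dehydrogenase reaction.
#' @return a new `metabolic_model`.
#' @export
apply_extension <- function(model, extension, enable_adh = TRUE,
                            adh_id = "ADH") {
  assert_that(inherits(extension, "pathway_extension"),
              "extension must be built with build_extension()")
  out <- add_reactions(model, extension$reactions, extension$stoichiometry,
                       compartment = extension$compartment,
                       carbon = extension$carbon)
  if (enable_adh && adh_id %in% out$reactions$id) {
    out <- set_bounds(out, adh_id, lb = -DEFAULT_BOUND, ub = DEFAULT_BOUND)
  }
  attr(out, "pathway") <- extension$name
  out
}

#' Compare formaldehyde-assimilation pathways on a model
#'
#' Adds each pathway extension in turn, opens methanol uptake at the stated
#' rate, and optimises the growth and triacylglycerol objectives. Carbon
#' yield (cmol product per cmol methanol), molar yield and oxygen demand
#' (mmol O2 per cmol methanol consumed and supplied) are reported per row.
#'
#' @param model a `metabolic_model` with biomass and TAG reactions recorded.
#' @param uptake methanol uptake rate (flux units of the model; the value is
#'   in carbon-mole units for the one-carbon substrate).
#' @param pathways pathway names to compare.
#' @param objectives subset of `c("growth", "TAG")`.
#' @param methanol_exchange id of the methanol exchange reaction.
#' @param enable_adh open the alcohol-dehydrogenase reaction.
#' @return data.frame with one row per pathway x objective.
#' @export
compare_pathways <- function(model, uptake = 6,
                             pathways = PATHWAY_NAMES,
                             objectives = c("growth", "TAG"),
                             methanol_exchange = "EX_meoh",
                             enable_adh = TRUE) {
  assert_that(!is.na(model$biomass_reaction_id) &&
                !is.na(model$tag_reaction_id),
              "model must record biomass and TAG reaction ids")
  objectives <- match.arg(objectives, c("growth", "TAG"), several.ok = TRUE)
  rows <- list()
  for (p in pathways) {
    ext <- build_extension(p)
    m <- apply_extension(model, ext, enable_adh = enable_adh)
    up <- stats::setNames(uptake, methanol_exchange)
    for (obj in objectives) {
      obj_id <- if (obj == "growth") m$biomass_reaction_id else
        m$tag_reaction_id
      sol <- fba(m, objective_id = obj_id, uptake = up)
      if (sol$status == "optimal" && sol$objective_value > FEAS_TOL) {
        # for the growth objective, the yield columns report the biomass
        # product; for the TAG objective, the TAG sink
        prod <- if (obj == "growth") "EX_biomass" else "EX_tag"
        yo <- yield_and_oxygen(sol, substrate_exchange = methanol_exchange,
                               product_id = prod)
      } else {
        yo <- list(carbon_yield = 0, mol_yield = 0, oxygen_demand = NA_real_,
                   oxygen_demand_supplied = NA_real_)
      }
      rows[[length(rows) + 1]] <- data.frame(
        pathway = p, objective = obj, status = sol$status,
        objective_value = if (sol$status == "optimal")
          sol$objective_value else NA_real_,
        carbon_yield = yo$carbon_yield,
        mol_yield = yo$mol_yield,
        oxygen_demand = yo$oxygen_demand,
        oxygen_demand_supplied = yo$oxygen_demand_supplied,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
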