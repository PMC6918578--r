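# Reduced yeast-like core metabolic model.
#
# A deliberately small (~40 reaction) single-compartment network covering
# glycolysis/gluconeogenesis, the pentose phosphate shunt with transketolase
# and transaldolase recycling, the TCA cycle, oxidative phosphorylation with
# a configurable P/O ratio, exchanges for glucose, glycerol, methanol, O2
# and CO2, a seven-carbon lumped biomass equation and a 55-carbon
# triacylglycerol sink. The alcohol-dehydrogenase reaction interconverting
# methanol and formaldehyde is present but closed by default, and no native
# formaldehyde-consuming reaction exists, so methanol supports no growth
# until a formaldehyde assimilation pathway is added. All internal
# reactions conserve carbon; the CO2 exchange is secretion-only so carbon
# yields cannot exceed one.

#' Parameters of the synthetic core model
#'
#' @param p_o_ratio ATP produced per NADH oxidised (P/O), default 1.5.
#' @param atp_maintenance growth-associated maintenance ATP added to the
#'   biomass equation (mol ATP per unit biomass flux). Maintenance is tied
#'   to growth rather than enforced as a fixed demand so that the model
#'   stays feasible -- with zero objective -- under starvation.
#' @param tag_carbon_atoms carbon atoms per triacylglycerol (glycerol
#'   backbone plus acyl carbon; default 55).
#' @param biomass_carbon carbon atoms consumed per unit biomass flux
#'   (fixed by the lumped biomass equation; informational).
#' @param seed integer seed recorded on the model (the network itself is
#'   deterministic).
#' @return a list of class `core_model_params`.
#' @export
core_model_params <- function(p_o_ratio = 1.5, atp_maintenance = 10,
                              tag_carbon_atoms = 55, biomass_carbon = 7,
                              seed = 1L) {
  assert_that(p_o_ratio > 0 && atp_maintenance > 0 && tag_carbon_atoms > 0 &&
                biomass_carbon > 0, "core_model_params must all be positive")
  structure(list(p_o_ratio = p_o_ratio, atp_maintenance = atp_maintenance,
                 tag_carbon_atoms = tag_carbon_atoms,
                 biomass_carbon = biomass_carbon, seed = as.integer(seed)),
            class = "core_model_params")
}

#' Generate the bundled yeast-like core model
#'
#' @param params a [core_model_params()].
#' @return a `metabolic_model`, feasible for growth on glucose or glycerol,
#'   infeasible on methanol until a formaldehyde-assimilation extension is
#'   applied.
#' @export
generate_core_model <- function(params = core_model_params()) {
  assert_that(inherits(params, "core_model_params"),
              "params must be built with core_model_params()")
  po <- params$p_o_ratio
  # glycerol backbone (3 C) plus acetyl (2 C) units
  n_acetyl <- (params$tag_carbon_atoms - 3) / 2
  assert_that(n_acetyl >= 1 && n_acetyl == round(n_acetyl),
              "tag_carbon_atoms must be 3 + an even acyl carbon count")

  mets <- data.frame(
    id = c("glc", "glyc", "meoh", "hcho", "co2", "o2",
           "atp", "adp", "nad", "nadh", "nadp", "nadph", "coa",
           "g6p", "f6p", "fbp", "dhap", "gap", "pg3", "pep", "pyr",
           "accoa", "oaa", "cit", "akg", "succ", "mal", "glx",
           "ru5p", "xu5p", "r5p", "s7p", "e4p", "biomass", "tag"),
    carbon = c(6, 3, 1, 1, 1, 0,
               0, 0, 0, 0, 0, 0, 0,
               6, 6, 6, 3, 3, 3, 3, 3,
               2, 4, 6, 5, 4, 4, 2,
               5, 5, 5, 7, 4, 7, 55),
    stringsAsFactors = FALSE)
  mets$carbon[mets$id == "tag"] <- params$tag_carbon_atoms

  # id, equation, lb, ub
  defs <- list(
    # exchanges (positive = secretion; carbon uptakes closed by default)
    c("EX_glc",  "glc ->",  0, 0),
    c("EX_glyc", "glyc ->", 0, 0),
    c("EX_meoh", "meoh ->", 0, 0),
    c("EX_o2",   "o2 ->",   -DEFAULT_BOUND, DEFAULT_BOUND),
    c("EX_co2",  "co2 ->",  0, DEFAULT_BOUND),
    c("EX_biomass", "biomass ->", 0, DEFAULT_BOUND),
    c("EX_tag",  "tag ->",  0, DEFAULT_BOUND),
    # glycolysis / gluconeogenesis
    c("HXK",  "glc + atp -> g6p + adp", 0, DEFAULT_BOUND),
    c("PGI",  "g6p <-> f6p", -DEFAULT_BOUND, DEFAULT_BOUND),
    c("PFK",  "f6p + atp -> fbp + adp", 0, DEFAULT_BOUND),
    c("FBPASE", "fbp -> f6p", 0, DEFAULT_BOUND),
    c("FBA",  "fbp <-> dhap + gap", -DEFAULT_BOUND, DEFAULT_BOUND),
    c("TPI",  "dhap <-> gap", -DEFAULT_BOUND, DEFAULT_BOUND),
    c("GAPD", "gap + nad + adp <-> pg3 + nadh + atp",
      -DEFAULT_BOUND, DEFAULT_BOUND),
    c("PGM",  "pg3 <-> pep", -DEFAULT_BOUND, DEFAULT_BOUND),
    c("PYK",  "pep + adp -> pyr + atp", 0, DEFAULT_BOUND),
    # anaplerosis and pyruvate oxidation
    c("PC",   "pyr + co2 + atp -> oaa + adp", 0, DEFAULT_BOUND),
    c("PDH",  "pyr + nad + coa -> accoa + nadh + co2", 0, DEFAULT_BOUND),
    # TCA cycle (lumped; succinate dehydrogenase FADH2 counted as NADH)
    c("CS",   "accoa + oaa -> cit + coa", 0, DEFAULT_BOUND),
    c("IDH",  "cit + nad -> akg + nadh + co2", 0, DEFAULT_BOUND),
    c("AKGD", "akg + nad + adp -> succ + nadh + co2 + atp", 0, DEFAULT_BOUND),
    c("SDHFUM", "succ + nad -> mal + nadh", 0, DEFAULT_BOUND),
    c("MDH",  "mal + nad <-> oaa + nadh", -DEFAULT_BOUND, DEFAULT_BOUND),
    # glyoxylate shunt (the oleaginous host grows on acetyl units) and
    # PEP carboxykinase for gluconeogenesis from C4 acids
    c("ICL",  "cit -> succ + glx", 0, DEFAULT_BOUND),
    c("MALS", "accoa + glx -> mal + coa", 0, DEFAULT_BOUND),
    c("PEPCK", "oaa + atp -> pep + co2 + adp", 0, DEFAULT_BOUND),
    # pentose phosphate pathway
    c("G6PDH", "g6p + 2 nadp -> ru5p + co2 + 2 nadph", 0, DEFAULT_BOUND),
    c("RPI",  "ru5p <-> r5p", -DEFAULT_BOUND, DEFAULT_BOUND),
    c("RPE",  "ru5p <-> xu5p", -DEFAULT_BOUND, DEFAULT_BOUND),
    c("TKT1", "xu5p + r5p <-> s7p + gap", -DEFAULT_BOUND, DEFAULT_BOUND),
    c("TAL",  "s7p + gap <-> e4p + f6p", -DEFAULT_BOUND, DEFAULT_BOUND),
    c("TKT2", "xu5p + e4p <-> f6p + gap", -DEFAULT_BOUND, DEFAULT_BOUND),
    # substrate entry
    c("GLYCK", "glyc + atp + nad -> dhap + adp + nadh", 0, DEFAULT_BOUND),
    c("ADH",  "meoh + nad <-> hcho + nadh", 0, 0),  # closed until enabled
    # energy metabolism
    c("OXPHOS", sprintf("nadh + 0.5 o2 + %g adp -> nad + %g atp", po, po),
      0, DEFAULT_BOUND),
    c("ATPM", "atp -> adp", 0, DEFAULT_BOUND),
    # lumped biomass: 7 carbon atoms per unit flux; ATP cost includes the
    # growth-associated maintenance
    c("BIOMASS",
      sprintf(paste(
        "0.5 f6p + 0.2 r5p + 0.5 pyr + 0.25 accoa + 0.1 oaa + 0.12 akg",
        "+ %g atp + 0.3 nadph -> biomass + %g adp + 0.3 nadp + 0.25 coa"),
        3 + params$atp_maintenance, 3 + params$atp_maintenance),
      0, DEFAULT_BOUND),
    # triacylglycerol: acetyl units on a glycerol (DHAP) backbone; the
    # acetyl count follows the configured TAG carbon number
    c("TAGS",
      sprintf("%g accoa + dhap + %g atp + %g nadph -> tag + %g coa + %g adp + %g nadp",
              n_acetyl, n_acetyl - 1, 2 * n_acetyl,
              n_acetyl, n_acetyl - 1, 2 * n_acetyl),
      0, DEFAULT_BOUND)
  )
  rx <- data.frame(id = vapply(defs, `[[`, character(1), 1),
                   lb = as.numeric(vapply(defs, `[[`, character(1), 3)),
                   ub = as.numeric(vapply(defs, `[[`, character(1), 4)),
                   gene_note = NA_character_, stringsAsFactors = FALSE)
  st <- lapply(defs, function(d) parse_equation(d[2])$stoichiometry)
  names(st) <- rx$id
  model <- metabolic_model(mets, rx, st,
                           biomass_reaction_id = "BIOMASS",
                           tag_reaction_id = "TAGS")
  attr(model, "params") <- params
  model
}
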