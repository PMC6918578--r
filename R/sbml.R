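# Minimal SBML Level 3 core reader (fbc flux bounds honoured).

read_sbml_model <- function(path, biomass_reaction_id = NA_character_,
                            tag_reaction_id = NA_character_) {
  doc <- xml2::read_xml(path)
  ns <- xml2::xml_ns(doc)
  # strip namespaces for simple XPath over the core document
  xml2::xml_ns_strip(doc)

  sp <- xml2::xml_find_all(doc, ".//listOfSpecies/species")
  assert_that(length(sp) > 0, "SBML file has no species: %s", path)
  met_id <- xml2::xml_attr(sp, "id")
  boundary <- xml2::xml_attr(sp, "boundaryCondition") %in% c("true", "1")
  mets <- data.frame(
    id = met_id,
    name = ifelse(is.na(xml2::xml_attr(sp, "name")), met_id,
                  xml2::xml_attr(sp, "name")),
    compartment = xml2::xml_attr(sp, "compartment"),
    carbon = carbon_from_formula(xml2::xml_attr(sp, "chemicalFormula")),
    formula = xml2::xml_attr(sp, "chemicalFormula"),
    stringsAsFactors = FALSE)

  # fbc parameters used as flux bounds
  pars <- xml2::xml_find_all(doc, ".//listOfParameters/parameter")
  par_val <- stats::setNames(as.numeric(xml2::xml_attr(pars, "value")),
                             xml2::xml_attr(pars, "id"))

  rxn_nodes <- xml2::xml_find_all(doc, ".//listOfReactions/reaction")
  assert_that(length(rxn_nodes) > 0, "SBML file has no reactions: %s", path)
  ids <- xml2::xml_attr(rxn_nodes, "id")
  st <- vector("list", length(rxn_nodes))
  lb <- ub <- numeric(length(rxn_nodes))
  unknown_note <- FALSE
  for (i in seq_along(rxn_nodes)) {
    node <- rxn_nodes[[i]]
    refs <- function(xp, sign) {
      rr <- xml2::xml_find_all(node, xp)
      if (length(rr) == 0) return(numeric(0))
      coef <- as.numeric(xml2::xml_attr(rr, "stoichiometry"))
      coef[is.na(coef)] <- 1
      stats::setNames(sign * coef, xml2::xml_attr(rr, "species"))
    }
    s <- c(refs("./listOfReactants/speciesReference", -1),
           refs("./listOfProducts/speciesReference", +1))
    # drop boundary-condition metabolites (external sinks/sources)
    s <- s[!names(s) %in% met_id[boundary]]
    st[[i]] <- s
    rev <- xml2::xml_attr(node, "reversible") %in% c("true", "1", NA)
    lbid <- xml2::xml_attr(node, "lowerFluxBound")
    ubid <- xml2::xml_attr(node, "upperFluxBound")
    lb[i] <- if (!is.na(lbid) && lbid %in% names(par_val)) {
      max(par_val[[lbid]], -DEFAULT_BOUND)
    } else if (rev) -DEFAULT_BOUND else 0
    ub[i] <- if (!is.na(ubid) && ubid %in% names(par_val)) {
      min(par_val[[ubid]], DEFAULT_BOUND)
    } else DEFAULT_BOUND
    if (length(xml2::xml_find_all(node, "./annotation")) > 0) {
      unknown_note <- TRUE
    }
  }
  if (unknown_note) {
    warning("SBML annotations ignored", call. = FALSE)
  }
  names(st) <- ids
  empty <- ids[vapply(st, length, integer(1)) == 0]
  st[empty] <- NULL
  keep <- !ids %in% empty
  mets <- mets[!boundary, , drop = FALSE]
  metabolic_model(mets,
                  data.frame(id = ids[keep], lb = lb[keep], ub = ub[keep],
                             gene_note = NA_character_,
                             stringsAsFactors = FALSE),
                  st,
                  biomass_reaction_id = biomass_reaction_id,
                  tag_reaction_id = tag_reaction_id)
}

# number of carbon atoms in a chemical formula such as C6H12O6 (NA if the
# formula is missing or carbon-free formulas return 0)
carbon_from_formula <- function(formula) {
  vapply(formula, function(f) {
    if (is.na(f) || f == "") return(NA_real_)
    m <- regmatches(f, regexpr("C(?![a-z])[0-9]*", f, perl = TRUE))
    if (length(m) == 0) return(0)
    n <- sub("^C", "", m)
    if (n == "") 1 else as.numeric(n)
  }, numeric(1), USE.NAMES = FALSE)
}
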