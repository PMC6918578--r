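# Metabolic model container and tabular I/O.
#
# A metabolic_model is a list with:
#   metabolites    data.frame(id, name, compartment, carbon, formula)
#   reactions      data.frame(id, lb, ub, gene_note)
#   stoichiometry  named list: reaction id -> named numeric vector over
#                  metabolite ids (negative = consumed)
#   objective      named numeric vector: reaction id -> weight
#   biomass_reaction_id, tag_reaction_id
#
# Exchange (boundary) reactions touch a single metabolite; by the usual
# convention their positive direction is secretion, so uptake is a negative
# flux enabled by a negative lower bound.

DEFAULT_BOUND <- 1000

#' Construct a metabolic model
#'
#' @param metabolites data.frame with columns `id`, `name`, `compartment`,
#'   `carbon` (atoms per molecule; NA if unknown) and optionally `formula`.
#' @param reactions data.frame with columns `id`, `lb`, `ub` and optionally
#'   `gene_note`.
#' @param stoichiometry named list mapping each reaction id to a named
#'   numeric vector of metabolite coefficients.
#' @param objective named numeric vector of reaction weights (default: the
#'   biomass reaction).
#' @param biomass_reaction_id,tag_reaction_id ids of the growth and
#'   triacylglycerol objectives, if present.
#' @return a validated object of class `metabolic_model`.
#' @export
metabolic_model <- function(metabolites, reactions, stoichiometry,
                            objective = NULL,
                            biomass_reaction_id = NA_character_,
                            tag_reaction_id = NA_character_) {
  if (is.null(metabolites$name)) metabolites$name <- metabolites$id
  if (is.null(metabolites$compartment)) metabolites$compartment <- "c"
  if (is.null(metabolites$carbon)) metabolites$carbon <- NA_real_
  if (is.null(metabolites$formula)) metabolites$formula <- NA_character_
  if (is.null(reactions$gene_note)) reactions$gene_note <- NA_character_
  if (is.null(objective) && !is.na(biomass_reaction_id)) {
    objective <- stats::setNames(1, biomass_reaction_id)
  }
  model <- structure(
    list(metabolites = as.data.frame(metabolites),
         reactions = as.data.frame(reactions),
         stoichiometry = stoichiometry,
         objective = objective,
         biomass_reaction_id = biomass_reaction_id,
         tag_reaction_id = tag_reaction_id),
    class = "metabolic_model")
  validate_model(model)
}

#' Validate a metabolic model's invariants
#'
#' Checks id uniqueness, bound ordering, dangling metabolite references and
#' objective references; errors list every offender.
#'
#' @param model a `metabolic_model`.
#' @return the model, invisibly usable (returned unchanged).
#' @export
validate_model <- function(model) {
  mets <- model$metabolites; rxns <- model$reactions
  dup_m <- mets$id[duplicated(mets$id)]
  dup_r <- rxns$id[duplicated(rxns$id)]
  assert_that(length(dup_m) == 0, "duplicated metabolite id(s): %s",
              paste(unique(dup_m), collapse = ", "))
  assert_that(length(dup_r) == 0, "duplicated reaction id(s): %s",
              paste(unique(dup_r), collapse = ", "))
  bad_b <- rxns$id[rxns$lb > rxns$ub]
  assert_that(length(bad_b) == 0, "lb > ub for reaction(s): %s",
              paste(bad_b, collapse = ", "))
  assert_that(setequal(names(model$stoichiometry), rxns$id),
              "stoichiometry entries do not match reaction ids")
  dangling <- unique(unlist(lapply(model$stoichiometry, function(s)
    setdiff(names(s), mets$id))))
  assert_that(length(dangling) == 0,
              "reaction(s) reference missing metabolite(s): %s",
              paste(dangling, collapse = ", "))
  if (!is.null(model$objective)) {
    bad_o <- setdiff(names(model$objective), rxns$id)
    assert_that(length(bad_o) == 0,
                "objective references missing reaction(s): %s",
                paste(bad_o, collapse = ", "))
  }
  model
}

#' Stoichiometric matrix of a model
#'
#' @param model a `metabolic_model`.
#' @return dense numeric matrix S, one row per metabolite, one column per
#'   reaction.
#' @export
stoich_matrix <- function(model) {
  S <- matrix(0, nrow(model$metabolites), nrow(model$reactions),
              dimnames = list(model$metabolites$id, model$reactions$id))
  for (r in model$reactions$id) {
    s <- model$stoichiometry[[r]]
    S[names(s), r] <- s
  }
  S
}

#' Identify exchange reactions
#'
#' @param model a `metabolic_model`.
#' @return character vector of reaction ids touching a single metabolite.
#' @export
exchange_reactions <- function(model) {
  model$reactions$id[vapply(model$stoichiometry[model$reactions$id],
                            length, integer(1)) == 1]
}

# --- reaction-equation syntax -------------------------------------------

#' Parse a reaction-equation string
#'
#' Accepts `2 A + B -> C` (irreversible) or `A <-> B` / `A <=> B`
#' (reversible); an empty side denotes a boundary reaction, e.g. `tag ->`.
#' Species appearing on both sides are collapsed to their net coefficient.
#'
#' @param eq equation string.
#' @return list with `stoichiometry` (named numeric, negative = consumed)
#'   and `reversible`.
#' @export
parse_equation <- function(eq) {
  arrow <- if (grepl("<->|<=>", eq)) "<->" else "->"
  parts <- strsplit(sub("<=>", "<->", eq), arrow, fixed = TRUE)[[1]]
  assert_that(length(parts) <= 2 && length(parts) >= 1,
              "cannot parse reaction equation: '%s'", eq)
  side <- function(txt, sign) {
    txt <- trimws(txt)
    if (is.na(txt) || txt == "") return(numeric(0))
    terms <- trimws(strsplit(txt, "+", fixed = TRUE)[[1]])
    out <- numeric(0)
    for (tm in terms[terms != ""]) {
      tok <- strsplit(tm, "[ \t]+")[[1]]
      if (length(tok) == 2 && !is.na(suppressWarnings(as.numeric(tok[1])))) {
        out[tok[2]] <- sign * as.numeric(tok[1])
      } else if (length(tok) == 1) {
        out[tok[1]] <- sign * 1
      } else {
        stop_mp("cannot parse term '%s' in equation '%s'", tm, eq)
      }
    }
    out
  }
  lhs <- side(parts[1], -1)
  rhs <- side(if (length(parts) == 2) parts[2] else "", +1)
  both <- intersect(names(lhs), names(rhs))
  st <- c(lhs, rhs[setdiff(names(rhs), both)])
  for (m in both) st[m] <- st[m] + rhs[m]
  st <- st[st != 0]
  list(stoichiometry = st, reversible = arrow == "<->")
}

format_equation <- function(st, reversible = FALSE) {
  fmt <- function(v) paste(vapply(names(v), function(m) {
    cf <- abs(v[[m]])
    if (isTRUE(all.equal(cf, 1))) m else paste(format(cf, digits = 10), m)
  }, character(1)), collapse = " + ")
  lhs <- fmt(st[st < 0]); rhs <- fmt(st[st > 0])
  paste(lhs, if (reversible) "<->" else "->", rhs)
}

# --- tabular model format ------------------------------------------------

#' Read a metabolic model
#'
#' Two on-disk formats are supported. `tabular` is a directory with
#' `metabolites.tsv` (`id`, `name`, `compartment`, `carbon`, `formula`) and
#' `reactions.tsv` (`id`, `equation` in `2 A + B -> C` syntax, `lb`, `ub`);
#' `sbml` is an SBML Level 3 core document (fbc bounds honoured, other
#' annotations ignored with a warning).
#'
#' @param path directory (tabular) or file (sbml).
#' @param format `tabular` or `sbml`.
#' @param biomass_reaction_id,tag_reaction_id objective reaction ids to
#'   record on the model (optional).
#' @return a `metabolic_model`.
#' @export
read_model <- function(path, format = c("tabular", "sbml"),
                       biomass_reaction_id = NA_character_,
                       tag_reaction_id = NA_character_) {
  format <- match.arg(format)
  if (format == "sbml") {
    return(read_sbml_model(path, biomass_reaction_id, tag_reaction_id))
  }
  mets <- utils::read.delim(file.path(path, "metabolites.tsv"),
                            stringsAsFactors = FALSE, comment.char = "#")
  rx <- utils::read.delim(file.path(path, "reactions.tsv"),
                          stringsAsFactors = FALSE, comment.char = "#")
  st <- lapply(rx$equation, parse_equation)
  names(st) <- rx$id
  reactions <- data.frame(id = rx$id, lb = as.numeric(rx$lb),
                          ub = as.numeric(rx$ub),
                          gene_note = rx$gene_note %||% NA_character_,
                          stringsAsFactors = FALSE)
  metabolic_model(mets, reactions,
                  lapply(st, `[[`, "stoichiometry"),
                  biomass_reaction_id = biomass_reaction_id,
                  tag_reaction_id = tag_reaction_id)
}

#' Write a metabolic model in the tabular format
#'
#' @param model a `metabolic_model`.
#' @param path output directory (created if needed).
#' @return `path`, invisibly.
#' @export
write_model <- function(model, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(model$metabolites,
                     file.path(path, "metabolites.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  rx <- model$reactions
  rx$equation <- vapply(rx$id, function(r)
    format_equation(model$stoichiometry[[r]], model$reactions$lb[
      model$reactions$id == r] < 0), character(1))
  utils::write.table(rx[, c("id", "equation", "lb", "ub", "gene_note")],
                     file.path(path, "reactions.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Add reactions (and missing metabolites) to a model
#'
#' @param model a `metabolic_model`.
#' @param reactions data.frame(id, lb, ub, gene_note).
#' @param stoichiometry named list of coefficient vectors, one per new
#'   reaction.
#' @param compartment compartment assigned to metabolites created on demand.
#' @param carbon named vector of carbon counts for new metabolites.
#' @return a new `metabolic_model`; the input is not modified.
#' @export
add_reactions <- function(model, reactions, stoichiometry,
                          compartment = "c", carbon = numeric(0)) {
  clash <- intersect(reactions$id, model$reactions$id)
  assert_that(length(clash) == 0, "reaction id(s) already in model: %s",
              paste(clash, collapse = ", "))
  new_mets <- setdiff(unique(unlist(lapply(stoichiometry, names))),
                      model$metabolites$id)
  if (length(new_mets) > 0) {
    model$metabolites <- rbind(model$metabolites, data.frame(
      id = new_mets, name = new_mets, compartment = compartment,
      carbon = ifelse(new_mets %in% names(carbon), carbon[new_mets], NA_real_),
      formula = NA_character_, stringsAsFactors = FALSE))
  }
  if (is.null(reactions$gene_note)) reactions$gene_note <- NA_character_
  model$reactions <- rbind(model$reactions,
                           reactions[, c("id", "lb", "ub", "gene_note")])
  model$stoichiometry <- c(model$stoichiometry, stoichiometry)
  validate_model(model)
}

#' Remove reactions from a model
#'
#' Metabolites left unreferenced by any reaction are dropped as well, so
#' removing a freshly added extension restores the original model.
#'
#' @param model a `metabolic_model`.
#' @param ids reaction ids to remove.
#' @return a new `metabolic_model`.
#' @export
remove_reactions <- function(model, ids) {
  missing <- setdiff(ids, model$reactions$id)
  assert_that(length(missing) == 0, "reaction(s) not in model: %s",
              paste(missing, collapse = ", "))
  model$reactions <- model$reactions[!model$reactions$id %in% ids, ,
                                     drop = FALSE]
  model$stoichiometry <- model$stoichiometry[model$reactions$id]
  used <- unique(unlist(lapply(model$stoichiometry, names)))
  model$metabolites <- model$metabolites[model$metabolites$id %in% used, ,
                                         drop = FALSE]
  rownames(model$metabolites) <- NULL
  rownames(model$reactions) <- NULL
  validate_model(model)
}

#' Set reaction bounds
#'
#' @param model a `metabolic_model`.
#' @param id reaction id.
#' @param lb,ub new bounds (either may be NULL to keep the current value).
#' @return a new `metabolic_model`.
#' @export
set_bounds <- function(model, id, lb = NULL, ub = NULL) {
  i <- match(id, model$reactions$id)
  assert_that(!is.na(i), "no reaction '%s' in model", id)
  if (!is.null(lb)) model$reactions$lb[i] <- lb
  if (!is.null(ub)) model$reactions$ub[i] <- ub
  validate_model(model)
}

#' @export
print.metabolic_model <- function(x, ...) {
  cat(sprintf("metabolic_model: %d metabolites, %d reactions (%d exchanges)\n",
              nrow(x$metabolites), nrow(x$reactions),
              length(exchange_reactions(x))))
  if (!is.na(x$biomass_reaction_id))
    cat("  biomass:", x$biomass_reaction_id, "\n")
  if (!is.na(x$tag_reaction_id))
    cat("  TAG sink:", x$tag_reaction_id, "\n")
  invisible(x)
}
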