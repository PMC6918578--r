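# Flux balance analysis, flux variability analysis and yield accounting.
#
# The LP kernel solves
#   maximise  c' v   s.t.  S v = 0,  lb <= v <= ub
# with the package's two-phase simplex (see lp.R) after shifting fluxes to
# nonnegative variables x = v - lb. Deterministic, and exact enough for the
# reduced models used here; feasibility is verified post hoc against
# ||S v||_inf.

FEAS_TOL <- 1e-6

# Solve max c'v s.t. Sv = 0, lb <= v <= ub (+ optional a'v >= b row).
# Returns list(status, value, v).
solve_fba_lp <- function(S, lb, ub, c_obj, extra_ge = NULL) {
  n <- length(c_obj)
  shift <- lb
  A <- rbind(S, diag(n))
  b <- c(as.numeric(-S %*% shift), ub - lb)
  sense <- c(rep("=", nrow(S)), rep("<=", n))
  if (!is.null(extra_ge)) {
    A <- rbind(A, extra_ge$a)
    b <- c(b, extra_ge$b - sum(extra_ge$a * shift))
    sense <- c(sense, ">=")
  }
  res <- lp_solve(c_obj, A, b, sense, maximize = TRUE)
  if (res$status != "optimal") {
    return(list(status = res$status, value = NA_real_, v = NULL))
  }
  v <- res$x + shift
  list(status = "optimal", value = sum(c_obj * v), v = v)
}

#' Flux balance analysis
#'
#' Maximises an objective reaction subject to steady state (`S v = 0`) and
#' flux bounds. Infeasibility is reported in the solution status, not
#' raised.
#'
#' @param model a `metabolic_model`.
#' @param objective_id reaction id to maximise; defaults to the model
#'   objective (or biomass reaction).
#' @param uptake optional named vector mapping exchange reaction ids to
#'   maximal uptake rates (applied as lower bound `-rate`).
#' @return a `flux_solution` list: `status` (`optimal`, `infeasible` or
#'   `unbounded`), `objective_value`, `objective_id`, and named `fluxes`.
#' @export
fba <- function(model, objective_id = NULL, uptake = NULL) {
  model <- validate_model(model)
  if (is.null(objective_id)) {
    objective_id <- names(model$objective)[which.max(model$objective)] %||%
      model$biomass_reaction_id
  }
  assert_that(objective_id %in% model$reactions$id,
              "objective reaction '%s' not in model", objective_id)
  if (!is.null(uptake)) {
    exch <- exchange_reactions(model)
    bad <- setdiff(names(uptake), exch)
    assert_that(length(bad) == 0,
                "uptake id(s) are not exchange reactions: %s",
                paste(bad, collapse = ", "))
    for (r in names(uptake)) {
      model <- set_bounds(model, r, lb = -abs(uptake[[r]]))
    }
  }
  S <- stoich_matrix(model)
  c_obj <- as.numeric(model$reactions$id == objective_id)
  sol <- solve_fba_lp(S, model$reactions$lb, model$reactions$ub, c_obj)
  fluxes <- NULL
  if (sol$status == "optimal") {
    fluxes <- stats::setNames(sol$v, model$reactions$id)
    resid <- max(abs(S %*% sol$v))
    assert_that(resid < FEAS_TOL,
                "solver returned an unbalanced flux vector (|Sv| = %g)", resid)
  }
  structure(list(status = sol$status,
                 objective_value = if (sol$status == "optimal") sol$value else NA_real_,
                 objective_id = objective_id,
                 fluxes = fluxes,
                 model = model),
            class = "flux_solution")
}

#' @export
print.flux_solution <- function(x, ...) {
  cat(sprintf("flux_solution: %s, objective %s = %s\n", x$status,
              x$objective_id,
              format(x$objective_value, digits = 6)))
  invisible(x)
}

#' Flux variability analysis
#'
#' Per-reaction minimal and maximal fluxes compatible with at least
#' `fraction` of the optimal objective.
#'
#' @param model a `metabolic_model`.
#' @param objective_id objective reaction id (as in [fba()]).
#' @param fraction fraction of the optimum to enforce, in `[0, 1]`.
#' @param reactions reaction ids to scan (default: all).
#' @param uptake passed to [fba()].
#' @return data.frame with columns `reaction`, `min`, `max`.
#' @export
fva <- function(model, objective_id = NULL, fraction = 1,
                reactions = NULL, uptake = NULL) {
  assert_that(fraction >= 0 && fraction <= 1, "fraction must be in [0, 1]")
  base <- fba(model, objective_id, uptake)
  assert_that(base$status == "optimal",
              "fva: base FBA problem is %s", base$status)
  model <- base$model  # uptake bounds applied
  S <- stoich_matrix(model)
  ids <- reactions %||% model$reactions$id
  c_base <- as.numeric(model$reactions$id == base$objective_id)
  extra <- list(a = c_base, b = fraction * base$objective_value)
  out <- data.frame(reaction = ids, min = NA_real_, max = NA_real_)
  for (k in seq_along(ids)) {
    c_obj <- as.numeric(model$reactions$id == ids[k])
    hi <- solve_fba_lp(S, model$reactions$lb, model$reactions$ub, c_obj,
                       extra_ge = extra)
    lo <- solve_fba_lp(S, model$reactions$lb, model$reactions$ub, -c_obj,
                       extra_ge = extra)
    out$max[k] <- hi$value
    out$min[k] <- -lo$value
  }
  out
}

#' Carbon yield and oxygen demand of a flux solution
#'
#' Carbon yield is (product flux x product carbon) / (substrate uptake flux
#' x substrate carbon), i.e. cmol product per cmol substrate. Oxygen demand
#' is reported per cmol of substrate consumed and, alongside, per cmol of
#' substrate supplied (the uptake bound); the two coincide when uptake is
#' saturated.
#'
#' @param solution an optimal `flux_solution`.
#' @param model the model the solution was computed on (defaults to the one
#'   recorded in the solution).
#' @param substrate_exchange exchange reaction id of the carbon substrate.
#' @param product_id exchange/sink reaction id of the product (e.g. the TAG
#'   sink).
#' @return list with `carbon_yield`, `mol_yield` (product mol per substrate
#'   mol), `oxygen_demand` (mmol O2 per cmol substrate consumed) and
#'   `oxygen_demand_supplied`.
#' @export
yield_and_oxygen <- function(solution, model = solution$model,
                             substrate_exchange, product_id) {
  assert_that(inherits(solution, "flux_solution") &&
                solution$status == "optimal",
              "yield_and_oxygen: solution must be an optimal flux_solution")
  single_met <- function(r) {
    s <- model$stoichiometry[[r]]
    assert_that(!is.null(s), "no reaction '%s' in model", r)
    assert_that(length(s) == 1,
                "'%s' is not a single-metabolite exchange/sink", r)
    names(s)
  }
  carbon_of <- function(m)
    model$metabolites$carbon[match(m, model$metabolites$id)]
  sub_c <- carbon_of(single_met(substrate_exchange))
  prod_c <- carbon_of(single_met(product_id))
  assert_that(is.finite(sub_c) && is.finite(prod_c),
              "carbon counts must be known for substrate and product")
  v_sub <- abs(solution$fluxes[[substrate_exchange]])
  assert_that(v_sub > FEAS_TOL, "substrate uptake flux is zero")
  v_prod <- abs(solution$fluxes[[product_id]])
  o2 <- grep("o2$|oxygen", model$metabolites$id, ignore.case = TRUE,
             value = TRUE)
  o2 <- setdiff(o2, grep("co2", o2, value = TRUE))
  v_o2 <- 0
  exch <- exchange_reactions(model)
  for (r in exch) {
    if (names(model$stoichiometry[[r]]) %in% o2) {
      v_o2 <- v_o2 + max(0, -solution$fluxes[[r]])
    }
  }
  supplied <- abs(model$reactions$lb[match(substrate_exchange,
                                           model$reactions$id)])
  list(carbon_yield = (v_prod * prod_c) / (v_sub * sub_c),
       mol_yield = v_prod / v_sub,
       oxygen_demand = v_o2 / (v_sub * sub_c),
       oxygen_demand_supplied = if (supplied > 0)
         v_o2 / (supplied * sub_c) else NA_real_)
}

#' Check carbon balance of every internal reaction
#'
#' @param model a `metabolic_model`.
#' @param tol imbalance tolerance in carbon atoms.
#' @param exempt reaction ids excluded from the check in addition to
#'   single-metabolite exchanges/sinks and the recorded biomass and TAG
#'   reactions.
#' @return character vector of reaction ids whose stoichiometry does not
#'   conserve carbon.
#' @export
carbon_balance_check <- function(model, tol = 1e-9, exempt = character(0)) {
  model <- validate_model(model)
  carbon <- stats::setNames(model$metabolites$carbon, model$metabolites$id)
  skip <- unique(c(exchange_reactions(model), exempt,
                   model$biomass_reaction_id, model$tag_reaction_id))
  bad <- character(0)
  for (r in setdiff(model$reactions$id, skip)) {
    s <- model$stoichiometry[[r]]
    cs <- carbon[names(s)]
    if (any(is.na(cs))) next  # carbon unknown: cannot judge
    if (abs(sum(s * cs)) > tol) bad <- c(bad, r)
  }
  bad
}
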