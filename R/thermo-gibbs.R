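# Temperature extrapolation of reaction Gibbs energies and the
# alcohol-dehydrogenase equilibrium.
#
# Species Gibbs energies are extrapolated from a reference temperature with
# the Gibbs-Helmholtz relation,
#   G(T) = H(Tref) + Int[Tref,T] Cp dT - T * ( S(Tref) + Int[Tref,T] Cp/T dT ),
# where H is the formation enthalpy, S the formation entropy derived from
# (H - G)/Tref, and Cp a constant or quadratic polynomial a + b T + c T^2.
# Both integrals are evaluated in closed form.

#' Define a reaction by its stoichiometry
#'
#' @param stoichiometry named numeric vector mapping species ids to signed
#'   coefficients (negative = consumed). Zeros are dropped.
#' @param name reaction name.
#' @return a list of class `reaction_spec`.
#' @export
reaction_spec <- function(stoichiometry, name = "reaction") {
  stoichiometry <- stoichiometry[stoichiometry != 0]
  assert_that(length(stoichiometry) > 0 && !is.null(names(stoichiometry)),
              "reaction_spec: stoichiometry must be a named numeric vector")
  assert_that(any(stoichiometry < 0) && any(stoichiometry > 0),
              "reaction_spec: need at least one reactant and one product")
  structure(list(stoichiometry = stoichiometry, name = name),
            class = "reaction_spec")
}

#' Define a rapidly equilibrating species pool
#'
#' A pseudo-species whose chemical potential is that of an equilibrium
#' mixture of its components (e.g. free formaldehyde plus its hydrate,
#' methylene glycol, with the hydration water at unit activity).
#'
#' @param pool_id identifier of the pseudo-species.
#' @param component_ids identifiers of at least two pool members.
#' @param note free-text remark.
#' @return a list of class `pooled_species`.
#' @export
pooled_species <- function(pool_id, component_ids, note = "") {
  assert_that(length(component_ids) >= 2,
              "pooled_species: need at least 2 components")
  structure(list(pool_id = pool_id, component_ids = component_ids,
                 note = note), class = "pooled_species")
}

#' The aqueous formaldehyde/methylene-glycol pool
#' @return a `pooled_species` with components `formaldehyde` and
#'   `methylene_glycol`.
#' @export
formaldehyde_pool <- function() {
  pooled_species("formaldehyde_pool", c("formaldehyde", "methylene_glycol"),
                 note = "hydration water at unit activity")
}

#' The NAD-dependent alcohol-dehydrogenase reaction on the formaldehyde pool
#'
#' methanol + NAD+ -> formaldehyde pool + NADH (transformed standard state,
#' the proton folded into the pH-dependent convention).
#'
#' @return a `reaction_spec`.
#' @export
adh_reaction <- function() {
  reaction_spec(c(methanol = -1, nad_ox = -1,
                  formaldehyde_pool = 1, nad_red = 1),
                name = "alcohol dehydrogenase (methanol -> formaldehyde pool)")
}

#' Reaction-medium conditions
#'
#' @param temperature temperature, kelvin unless `celsius = TRUE`.
#' @param concentrations named numeric vector of molar concentrations; the
#'   alcohol-dehydrogenase equilibrium requires `methanol`, `nad_ox` and
#'   `nad_red` entries.
#' @param pH medium pH (record-keeping only; the packaged formation data are
#'   already on a transformed, pH-dependent standard state).
#' @param celsius set to `TRUE` when `temperature` is given in Celsius.
#' @return a list of class `medium_conditions`.
#' @export
medium_conditions <- function(temperature, concentrations, pH = 7,
                              celsius = FALSE) {
  if (celsius) temperature <- celsius_to_kelvin(temperature)
  assert_that(all(temperature > 0), "temperature must be > 0 K")
  assert_that(!is.null(names(concentrations)) && all(concentrations > 0),
              "concentrations must be a named vector of positive mol/L values")
  structure(list(temperature = temperature,
                 concentrations = concentrations, pH = pH),
            class = "medium_conditions")
}

# Collapse a thermo table to one set of canonical per-species parameters:
# g (formation Gibbs, kJ/mol), h (formation enthalpy, kJ/mol),
# cp coefficients (J/(mol K) basis), sigma_g, and Tref. Repeated records of
# one property are reconciled first.
species_params <- function(tab, species) {
  rows <- tab[tab$species_id == species, , drop = FALSE]
  grab <- function(prop) {
    r <- rows[rows$property == prop, , drop = FALSE]
    if (nrow(r) == 0) return(NULL)
    if (nrow(r) == 1 || all(r$uncertainty == 0)) {
      list(value = r$value[1], uncertainty = r$uncertainty[1],
           tref = r$temperature_ref[1])
    } else {
      rec <- reconcile(r)
      list(value = rec$value, uncertainty = rec$uncertainty,
           tref = r$temperature_ref[1])
    }
  }
  g <- grab("formation_gibbs")
  h <- grab("formation_enthalpy")
  s <- grab("entropy")
  cpa <- grab("heat_capacity")
  cpb <- grab("heat_capacity_b")
  cpc <- grab("heat_capacity_c")
  tref <- (g$tref %||% h$tref) %||% 298.15
  if (is.null(g) && !is.null(h) && !is.null(s)) {
    # formation entropy in J/(mol K)
    g <- list(value = h$value - tref * s$value / 1000, uncertainty = 0)
  }
  list(
    g = g$value %||% NA_real_,
    h = h$value %||% NA_real_,
    sigma_g = g$uncertainty %||% 0,
    cp = c(a = cpa$value %||% 0, b = cpb$value %||% 0, c = cpc$value %||% 0),
    tref = tref
  )
}

# Gibbs energy of formation of one species at temperature T (kJ/mol).
species_gibbs <- function(tab, species, T) {
  p <- species_params(tab, species)
  assert_that(is.finite(p$g),
              "no formation Gibbs energy (or enthalpy+entropy) for species '%s'",
              species)
  T0 <- p$tref
  if (isTRUE(all.equal(T, T0))) return(p$g)
  assert_that(is.finite(p$h),
              "no formation enthalpy for species '%s': cannot extrapolate from %.2f K to %.2f K",
              species, T0, T)
  a <- p$cp[["a"]] / 1000  # kJ basis
  b <- p$cp[["b"]] / 1000
  cc <- p$cp[["c"]] / 1000
  sf <- (p$h - p$g) / T0   # formation entropy, kJ/(mol K)
  int_cp <- a * (T - T0) + b / 2 * (T^2 - T0^2) + cc / 3 * (T^3 - T0^3)
  int_cp_over_t <- a * log(T / T0) + b * (T - T0) + cc / 2 * (T^2 - T0^2)
  p$h + int_cp - T * (sf + int_cp_over_t)
}

#' Gibbs energy of formation of an equilibrated species pool
#'
#' The chemical potential of a pool of rapidly interconverting species
#' (water at unit activity) is
#' `-RT log( sum_i exp(-G_i/RT) )`, i.e. a soft minimum over the component
#' formation energies weighted by their equilibrium abundance.
#'
#' @param pool a [pooled_species()]; a single-component pool degenerates to
#'   that component's formation energy.
#' @param thermo_table a `thermo_table` covering all components.
#' @param T temperature in kelvin.
#' @return list with `value` (kJ/mol), `uncertainty` (kJ/mol, propagated
#'   through the equilibrium weights) and `weights` (equilibrium fraction of
#'   each component).
#' @export
pool_formation_energy <- function(pool, thermo_table, T = 298.15) {
  comps <- if (inherits(pool, "pooled_species")) pool$component_ids else pool
  assert_that(length(comps) >= 1, "pool_formation_energy: empty pool")
  thermo_table <- validate_thermo_table(as.data.frame(thermo_table))
  g <- vapply(comps, species_gibbs, numeric(1), tab = thermo_table, T = T)
  sig <- vapply(comps, function(s) species_params(thermo_table, s)$sigma_g,
                numeric(1))
  rt <- RGAS * T
  value <- -rt * logsumexp(-g / rt)
  w <- exp(-(g - value) / rt)   # d value / d g_i
  list(value = value,
       uncertainty = sqrt(sum(w^2 * sig^2)),
       weights = stats::setNames(w, comps))
}

#' Reaction Gibbs energy at temperature T
#'
#' Sums stoichiometry-weighted species formation energies, each extrapolated
#' from its reference temperature by the Gibbs-Helmholtz relation with a
#' constant or polynomial heat capacity. Species named like a supplied pool
#' are valued at the pool chemical potential.
#'
#' @param reaction a [reaction_spec()].
#' @param thermo_table a `thermo_table` covering every species.
#' @param T temperature in kelvin.
#' @param pools optional list of [pooled_species()] consulted by id.
#' @return list with `value` (kJ/mol) and `uncertainty` (kJ/mol,
#'   `sqrt(sum(nu^2 sigma^2))` over independent species).
#' @export
delta_r_g <- function(reaction, thermo_table, T = 298.15, pools = NULL) {
  assert_that(inherits(reaction, "reaction_spec"),
              "delta_r_g: reaction must be a reaction_spec")
  thermo_table <- validate_thermo_table(as.data.frame(thermo_table))
  pool_ids <- vapply(pools %||% list(), `[[`, character(1), "pool_id")
  nu <- reaction$stoichiometry
  g <- numeric(length(nu))
  sig <- numeric(length(nu))
  for (i in seq_along(nu)) {
    sp <- names(nu)[i]
    if (sp %in% pool_ids) {
      pe <- pool_formation_energy(pools[[match(sp, pool_ids)]],
                                  thermo_table, T)
      g[i] <- pe$value
      sig[i] <- pe$uncertainty
    } else {
      g[i] <- species_gibbs(thermo_table, sp, T)
      sig[i] <- species_params(thermo_table, sp)$sigma_g
    }
  }
  list(value = sum(nu * g), uncertainty = sqrt(sum(nu^2 * sig^2)))
}

#' Equilibrium constant from a reaction Gibbs energy
#'
#' @param delta_r_g reaction Gibbs energy in kJ/mol (a number, or the list
#'   returned by [delta_r_g()]).
#' @param T temperature in kelvin.
#' @return dimensionless K = exp(-dG / RT), R = 8.314 J/(mol K).
#' @export
equilibrium_constant <- function(delta_r_g, T) {
  if (is.list(delta_r_g)) delta_r_g <- delta_r_g$value
  assert_that(all(T > 0), "equilibrium_constant: T must be > 0")
  exp(-delta_r_g / (RGAS * T))
}

#' Equilibrium formaldehyde-pool concentration of the ADH reaction
#'
#' Predicts the equilibrium concentration of partially hydrolysed
#' formaldehyde (free formaldehyde plus methylene glycol) produced by the
#' NAD-dependent alcohol-dehydrogenase reaction in a defined medium. In the
#' dilute-product approximation
#' `[pool] = K(T) [MeOH] [NAD+]/[NADH]`; the `mass_balance` mode instead
#' solves the full equilibrium condition
#' `K = x (NADH0 + x) / ((MeOH0 - x)(NAD0 - x))` by root finding and agrees
#' with the approximation whenever the product is far below the substrate.
#'
#' @param conditions a [medium_conditions()] with `methanol`, `nad_ox` and
#'   `nad_red` concentrations (mol/L).
#' @param thermo_table a `thermo_table`; defaults to the packaged reference
#'   table.
#' @param mode `dilute` (closed form) or `mass_balance` (root finding).
#' @param reaction,pool the reaction and pool definitions; defaults model
#'   methanol oxidation to the formaldehyde pool.
#' @return equilibrium pool concentration in micromolar (vectorised over the
#'   temperatures in `conditions`).
#' @export
adh_equilibrium_formaldehyde <- function(conditions,
                                         thermo_table = reference_thermo_table(),
                                         mode = c("dilute", "mass_balance"),
                                         reaction = adh_reaction(),
                                         pool = formaldehyde_pool()) {
  mode <- match.arg(mode)
  assert_that(inherits(conditions, "medium_conditions"),
              "conditions must be built with medium_conditions()")
  conc <- conditions$concentrations
  need <- c("methanol", "nad_ox", "nad_red")
  missing <- setdiff(need, names(conc))
  assert_that(length(missing) == 0,
              "missing medium concentration(s): %s",
              paste(missing, collapse = ", "))
  vapply(conditions$temperature, function(T) {
    K <- equilibrium_constant(
      delta_r_g(reaction, thermo_table, T, pools = list(pool)), T)
    if (mode == "dilute") {
      x <- K * conc[["methanol"]] * conc[["nad_ox"]] / conc[["nad_red"]]
    } else {
      m0 <- conc[["methanol"]]; a0 <- conc[["nad_ox"]]; h0 <- conc[["nad_red"]]
      f <- function(x) x * (h0 + x) - K * (m0 - x) * (a0 - x)
      upper <- min(m0, a0) * (1 - 1e-12)
      x <- if (f(upper) <= 0) upper else
        stats::uniroot(f, c(0, upper), tol = 1e-15)$root
    }
    x * 1e6
  }, numeric(1))
}

#' Tabulate the ADH equilibrium over temperatures
#'
#' @param temperatures_c temperatures in degrees Celsius.
#' @param conditions_template named concentrations (mol/L) and pH used at
#'   every temperature.
#' @param thermo_table a `thermo_table`.
#' @return data.frame with columns `temperature_C`, `delta_r_g_kJ_mol`,
#'   `K`, `hcho_pool_uM`.
#' @export
thermo_report <- function(temperatures_c = c(28, 30, 50),
                          conditions_template = list(
                            concentrations = c(methanol = 0.5,
                                               nad_ox = 1e-3, nad_red = 1e-3),
                            pH = 7),
                          thermo_table = reference_thermo_table()) {
  rows <- lapply(temperatures_c, function(tc) {
    T <- celsius_to_kelvin(tc)
    drg <- delta_r_g(adh_reaction(), thermo_table, T,
                     pools = list(formaldehyde_pool()))
    cond <- medium_conditions(T, conditions_template$concentrations,
                              pH = conditions_template$pH %||% 7)
    data.frame(
      temperature_C = tc,
      delta_r_g_kJ_mol = drg$value,
      K = equilibrium_constant(drg, T),
      hcho_pool_uM = adh_equilibrium_formaldehyde(cond, thermo_table)
    )
  })
  do.call(rbind, rows)
}
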