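# Reconciliation, Gibbs-energy extrapolation and the ADH equilibrium.

test_that("reconcile reduces to the identity on a single record", {
  rec <- reconcile(thermo_records("x", "formation_gibbs", 123.4,
                                  uncertainty = 2.5))
  expect_equal(rec$value, 123.4)
  expect_equal(rec$uncertainty, 2.5)
  expect_equal(rec$birge_ratio, 1)
})

test_that("reconcile matches the closed-form inverse-variance mean", {
  # two records (100, 2) and (100, 2): mean 100, se = 1/sqrt(1/4 + 1/4)
  rec <- reconcile(thermo_records("x", "formation_gibbs", c(100, 100),
                                  uncertainty = c(2, 2)))
  expect_equal(rec$value, 100)
  expect_equal(rec$uncertainty, sqrt(2))
  # unequal weights: oracle evaluated directly
  v <- c(10, 14); s <- c(1, 3)
  rec2 <- reconcile(thermo_records("x", "formation_gibbs", v, uncertainty = s))
  w <- 1 / s^2
  m <- sum(w * v) / sum(w)
  se <- sqrt(1 / sum(w))
  chi2 <- sum(w * (v - m)^2) / 1
  expect_equal(rec2$value, m)
  expect_equal(rec2$uncertainty, max(1, sqrt(chi2)) * se)
})

test_that("reconcile inflates by the Birge ratio only when data disagree", {
  tight <- reconcile(thermo_records("x", "formation_gibbs", c(100, 100.1),
                                    uncertainty = c(1, 1)))
  expect_equal(tight$uncertainty, 1 / sqrt(2))  # chi2_red < 1: no inflation
  loose <- reconcile(thermo_records("x", "formation_gibbs", c(95, 105),
                                    uncertainty = c(1, 1)))
  expect_gt(loose$birge_ratio, 1)
  expect_equal(loose$uncertainty, loose$birge_ratio / sqrt(2))
})

test_that("reconcile is permutation-invariant and bounded by the data", {
  set.seed(42)
  for (i in 1:20) {
    n <- sample(2:8, 1)
    v <- rnorm(n, 100, 5)
    s <- runif(n, 0.5, 4)
    recs <- thermo_records("x", "formation_gibbs", v, uncertainty = s)
    perm <- recs[sample(n), ]
    r1 <- reconcile(recs); r2 <- reconcile(perm)
    expect_equal(r1$value, r2$value)
    expect_equal(r1$uncertainty, r2$uncertainty)
    expect_gte(r1$value, min(v))
    expect_lte(r1$value, max(v))
  }
})

test_that("reconcile rejects degenerate inputs", {
  recs <- thermo_records("x", "formation_gibbs", c(1, 2), uncertainty = 1)
  expect_error(reconcile(recs[0, ]), "empty")
  mixed_sp <- thermo_records(c("x", "y"), "formation_gibbs", c(1, 2),
                             uncertainty = 1)
  expect_error(reconcile(mixed_sp), "mix species")
  mixed_pr <- thermo_records("x", c("formation_gibbs", "formation_enthalpy"),
                             c(1, 2), uncertainty = 1)
  expect_error(reconcile(mixed_pr), "mix properties")
  zero_u <- thermo_records("x", "formation_gibbs", c(1, 2), uncertainty = 0)
  expect_error(reconcile(zero_u), "> 0")
})

# a small self-consistent table used by the extrapolation tests:
# one reaction A -> B with constant-Cp and polynomial-Cp variants
extrap_table <- function(cp_poly = FALSE) {
  rows <- rbind(
    data.frame(species_id = "A", property = "formation_gibbs", value = -50,
               uncertainty = 0.5, temperature_ref = 298.15, source_label = "t"),
    data.frame(species_id = "A", property = "formation_enthalpy", value = -80,
               uncertainty = 1, temperature_ref = 298.15, source_label = "t"),
    data.frame(species_id = "B", property = "formation_gibbs", value = -70,
               uncertainty = 0.8, temperature_ref = 298.15, source_label = "t"),
    data.frame(species_id = "B", property = "formation_enthalpy", value = -60,
               uncertainty = 1.5, temperature_ref = 298.15, source_label = "t"))
  if (cp_poly) {
    rows <- rbind(rows,
      data.frame(species_id = "A", property = "heat_capacity", value = 75,
                 uncertainty = 0, temperature_ref = 298.15, source_label = "t"),
      data.frame(species_id = "A", property = "heat_capacity_b", value = 0.12,
                 uncertainty = 0, temperature_ref = 298.15, source_label = "t"),
      data.frame(species_id = "A", property = "heat_capacity_c",
                 value = -2e-4, uncertainty = 0, temperature_ref = 298.15,
                 source_label = "t"),
      data.frame(species_id = "B", property = "heat_capacity", value = 40,
                 uncertainty = 0, temperature_ref = 298.15, source_label = "t"))
  }
  validate_thermo_table(rows)
}

test_that("delta_r_g at the reference temperature is dH - T*dS = sum(nu g)", {
  tab <- extrap_table()
  rxn <- reaction_spec(c(A = -1, B = 1))
  expect_equal(delta_r_g(rxn, tab, 298.15)$value, -70 - (-50))
})

test_that("delta_r_g with polynomial Cp matches numerical quadrature", {
  tab <- extrap_table(cp_poly = TRUE)
  rxn <- reaction_spec(c(A = -1, B = 1))
  T0 <- 298.15; T1 <- 323.15
  # oracle: dG(T) = dH0 + int Cp dT - T (dS0 + int Cp/T dT), integrals by
  # adaptive quadrature on the reaction Cp polynomial (J -> kJ)
  dcp <- function(T) (40 - (75 + 0.12 * T - 2e-4 * T^2)) / 1000
  dh0 <- -60 - (-80)
  ds0 <- (dh0 - (-20)) / T0
  i1 <- integrate(dcp, T0, T1, rel.tol = 1e-12)$value
  i2 <- integrate(function(T) dcp(T) / T, T0, T1, rel.tol = 1e-12)$value
  oracle <- dh0 + i1 - T1 * (ds0 + i2)
  expect_lt(abs(delta_r_g(rxn, tab, T1)$value - oracle), 1e-6)
})

test_that("with Cp = 0 the van't Hoff slope of ln K equals -dH/R", {
  tab <- extrap_table()
  rxn <- reaction_spec(c(A = -1, B = 1))
  dh <- -60 - (-80)
  temps <- seq(280, 330, by = 5)
  lnk <- vapply(temps, function(T)
    log(equilibrium_constant(delta_r_g(rxn, tab, T), T)), numeric(1))
  slope <- stats::coef(stats::lm(lnk ~ I(1 / temps)))[[2]]
  expect_equal(slope, -dh / 8.314e-3, tolerance = 1e-9)
})

test_that("delta_r_g is linear in the stoichiometric coefficients", {
  tab <- extrap_table(cp_poly = TRUE)
  r1 <- reaction_spec(c(A = -1, B = 1))
  r2 <- reaction_spec(c(A = -2, B = 2))
  for (T in c(280, 298.15, 330)) {
    expect_equal(delta_r_g(r2, tab, T)$value,
                 2 * delta_r_g(r1, tab, T)$value)
  }
})

test_that("delta_r_g names the species whose data are missing", {
  tab <- extrap_table()
  rxn <- reaction_spec(c(A = -1, ghost = 1))
  expect_error(delta_r_g(rxn, tab, 298.15), "ghost")
  # enthalpy missing: extrapolation impossible, identity at T_ref fine
  tab2 <- validate_thermo_table(data.frame(
    species_id = c("A", "B"), property = "formation_gibbs",
    value = c(-50, -70), uncertainty = 0, temperature_ref = 298.15,
    source_label = "t"))
  rxn2 <- reaction_spec(c(A = -1, B = 1))
  expect_equal(delta_r_g(rxn2, tab2, 298.15)$value, -20)
  expect_error(delta_r_g(rxn2, tab2, 310), "enthalpy.*'A'")
})

test_that("reported reaction sigma matches Monte-Carlo propagation", {
  tab <- extrap_table()
  rxn <- reaction_spec(c(A = -2, B = 1))
  drg <- delta_r_g(rxn, tab, 298.15)
  expect_equal(drg$uncertainty, sqrt(4 * 0.5^2 + 1 * 0.8^2))
  set.seed(7)
  draws <- replicate(1e5, {
    ga <- rnorm(1, -50, 0.5); gb <- rnorm(1, -70, 0.8)
    -2 * ga + gb
  })
  expect_lt(abs(sd(draws) - drg$uncertainty) / drg$uncertainty, 0.03)
})

test_that("pool formation energy has its closed-form degenerate cases", {
  tab <- extrap_table()
  # one-component pool collapses to the component
  expect_equal(pool_formation_energy("A", tab, 298.15)$value, -50)
  # equal components: g - RT log 2
  tab2 <- validate_thermo_table(data.frame(
    species_id = c("p1", "p2"), property = "formation_gibbs", value = -30,
    uncertainty = 1, temperature_ref = 298.15, source_label = "t"))
  pe <- pool_formation_energy(pooled_species("pp", c("p1", "p2")), tab2,
                              298.15)
  expect_equal(pe$value, -30 - 8.314e-3 * 298.15 * log(2))
  expect_equal(unname(pe$weights), c(0.5, 0.5))
  expect_error(pool_formation_energy(character(0), tab), "empty")
})

test_that("pooling lowers free energy and is monotone in each component", {
  set.seed(11)
  for (i in 1:20) {
    g <- sort(runif(3, -100, 0))
    tab <- validate_thermo_table(data.frame(
      species_id = c("a", "b", "c"), property = "formation_gibbs",
      value = g, uncertainty = 0, temperature_ref = 298.15,
      source_label = "t"))
    pool <- pooled_species("pp", c("a", "b", "c"))
    pe <- pool_formation_energy(pool, tab, 298.15)$value
    expect_lte(pe, min(g))
    # raising one component's energy raises the pool energy
    tab2 <- tab; tab2$value[2] <- tab2$value[2] + 5
    expect_gt(pool_formation_energy(pool, tab2, 298.15)$value, pe)
  }
})

test_that("equilibrium_constant inverts the Gibbs energy analytically", {
  expect_equal(equilibrium_constant(0, 298.15), 1)
  T <- 310
  expect_equal(equilibrium_constant(-8.314e-3 * T * log(10), T), 10)
})

test_that("ADH equilibrium vanishes without oxidised cofactor", {
  tab <- reference_thermo_table()
  cond <- medium_conditions(301.15, c(methanol = 0.5, nad_ox = 1e-15,
                                      nad_red = 1e-3))
  expect_lt(adh_equilibrium_formaldehyde(cond, tab), 1e-6)
})

test_that("mass-balance root finding agrees with the dilute closed form", {
  # regime engineered so the product is far below every reactant:
  # K * [MeOH] * ratio ~ 5e-5 M while cofactors are at 1 M
  tab <- validate_thermo_table(data.frame(
    species_id = c("methanol", "formaldehyde", "methylene_glycol",
                   "nad_ox", "nad_red"),
    property = "formation_gibbs",
    value = c(0, 30, 8.314e-3 * 298.15 * log(1e4), 0, 0),
    uncertainty = 0, temperature_ref = 298.15, source_label = "t"))
  cond <- medium_conditions(298.15, c(methanol = 0.5, nad_ox = 1,
                                      nad_red = 1))
  dil <- adh_equilibrium_formaldehyde(cond, tab, mode = "dilute")
  full <- adh_equilibrium_formaldehyde(cond, tab, mode = "mass_balance")
  expect_lt(abs(full - dil) / dil, 1e-3)
})

test_that("ADH equilibrium is monotone in T, methanol and cofactor ratio", {
  tab <- reference_thermo_table()
  conc <- c(methanol = 0.5, nad_ox = 1e-3, nad_red = 1e-3)
  temps <- celsius_to_kelvin(c(20, 28, 35, 50))
  x <- adh_equilibrium_formaldehyde(medium_conditions(temps, conc), tab)
  expect_true(all(diff(x) > 0))  # the reaction is endothermic
  meoh <- c(0.1, 0.5, 1)
  xm <- vapply(meoh, function(m) adh_equilibrium_formaldehyde(
    medium_conditions(301.15, c(methanol = m, nad_ox = 1e-3,
                                nad_red = 1e-3)), tab), numeric(1))
  expect_true(all(diff(xm) > 0))
  ratio <- c(0.1, 1, 10)
  xr <- vapply(ratio, function(r) adh_equilibrium_formaldehyde(
    medium_conditions(301.15, c(methanol = 0.5, nad_ox = 1e-3 * r,
                                nad_red = 1e-3)), tab), numeric(1))
  expect_true(all(diff(xr) > 0))
})

test_that("thermo tables round-trip through the TSV interchange format", {
  tab <- extrap_table(cp_poly = TRUE)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_thermo_table(tab, path)
  back <- read_thermo_table(path)
  expect_equal(back$value, tab$value)
  expect_equal(back$property, tab$property)
  expect_equal(back$species_id, tab$species_id)
})
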