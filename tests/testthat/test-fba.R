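# LP kernel, FBA, FVA, yields and carbon bookkeeping.

test_that("the LP kernel handles the three solver outcomes", {
  # max x1 + x2 s.t. x1 + x2 <= 4, x1 <= 2
  r <- lp_solve(c(1, 1), rbind(c(1, 1), c(1, 0)), c(4, 2), c("<=", "<="))
  expect_equal(r$status, "optimal")
  expect_equal(r$value, 4)
  # infeasible: x <= 1 and x >= 2
  r2 <- lp_solve(1, rbind(1, 1), c(1, 2), c("<=", ">="))
  expect_equal(r2$status, "infeasible")
  # unbounded: max x s.t. -x <= 1
  r3 <- lp_solve(1, matrix(-1, 1, 1), 1, "<=")
  expect_equal(r3$status, "unbounded")
})

test_that("starvation gives a zero objective, not an error", {
  m <- generate_core_model()
  sol <- fba(m)  # all carbon uptakes closed by default
  expect_equal(sol$status, "optimal")
  expect_equal(sol$objective_value, 0, tolerance = 1e-9)
})

test_that("a 1:1 linear chain transmits the full uptake", {
  sol <- fba(toy_chain_model(10))
  expect_equal(sol$objective_value, 10, tolerance = 1e-9)
  expect_equal(unname(sol$fluxes["EX_A"]), -10, tolerance = 1e-9)
})

test_that("FBA equals the vertex-enumeration oracle on small toys", {
  for (build in list(toy_chain_model, toy_branch_model, toy_parallel_model)) {
    m <- build()
    sol <- fba(m)
    oracle <- lp_vertex_oracle(stoich_matrix(m), m$reactions$lb,
                               m$reactions$ub,
                               as.numeric(m$reactions$id ==
                                            names(m$objective)[1]))
    expect_equal(sol$objective_value, oracle, tolerance = 1e-8,
                 info = class(m))
  }
  # the branch toy's optimum is also hand-solvable: KEEP carries its cap 6
  # (1 P per A) and the lossy branch pairs two C per P, so
  # P = 6 + (10 - 6)/2 = 8
  expect_equal(fba(toy_branch_model())$objective_value, 8, tolerance = 1e-9)
})

test_that("optimal objective matches the hand-derived dual bound", {
  # primal: max 3x1 + 2x2 s.t. x1 + x2 <= 4, x1 <= 2, x >= 0
  # dual:   min 4y1 + 2y2 s.t. y1 + y2 >= 3, y1 >= 2, y >= 0
  p <- lp_solve(c(3, 2), rbind(c(1, 1), c(1, 0)), c(4, 2), c("<=", "<="))
  d <- lp_solve(c(4, 2), rbind(c(1, 1), c(1, 0)), c(3, 2), c(">=", ">="),
                maximize = FALSE)
  expect_equal(p$value, d$value, tolerance = 1e-9)
  expect_equal(p$value, 10)  # x = (2, 2)
})

test_that("the FBA objective is invariant to reaction order", {
  m <- generate_core_model()
  base <- fba(m, uptake = c(EX_glyc = 10))$objective_value
  set.seed(3)
  for (i in 1:3) {
    perm <- sample(nrow(m$reactions))
    m2 <- m
    m2$reactions <- m$reactions[perm, ]
    m2$stoichiometry <- m$stoichiometry[m2$reactions$id]
    rownames(m2$reactions) <- NULL
    expect_equal(fba(m2, uptake = c(EX_glyc = 10))$objective_value, base,
                 tolerance = 1e-8)
  }
})

test_that("LP homogeneity: scaling uptake scales the optimum exactly", {
  m <- generate_core_model()
  base <- fba(m, uptake = c(EX_glyc = 5))$objective_value
  for (k in c(0.5, 2, 4)) {
    expect_equal(fba(m, uptake = c(EX_glyc = 5 * k))$objective_value,
                 k * base, tolerance = 1e-7)
  }
  t_base <- fba(toy_branch_model())$objective_value
  m2 <- toy_branch_model()
  m2 <- set_bounds(m2, "EX_A", lb = -20)
  m2 <- set_bounds(m2, "KEEP", ub = 12)  # internal caps scale too
  expect_equal(fba(m2)$objective_value, 2 * t_base, tolerance = 1e-9)
})

test_that("optimal flux vectors satisfy steady state and bounds", {
  m <- generate_core_model()
  sol <- fba(m, uptake = c(EX_glc = 2))
  S <- stoich_matrix(sol$model)
  expect_lt(max(abs(S %*% sol$fluxes)), 1e-6)
  expect_true(all(sol$fluxes >= sol$model$reactions$lb - 1e-9))
  expect_true(all(sol$fluxes <= sol$model$reactions$ub + 1e-9))
})

test_that("FVA brackets the FBA flux and resolves alternate optima", {
  # unique chain: zero-width ranges
  m <- toy_chain_model(10)
  rng <- fva(m, "EX_B", fraction = 1)
  expect_true(all(abs(rng$max - rng$min) < 1e-8))
  sol <- fba(m)
  expect_true(all(rng$min - 1e-6 <= sol$fluxes[rng$reaction] &
                    sol$fluxes[rng$reaction] <= rng$max + 1e-6))
  # two redundant parallel paths of total 10: each spans (0, 10)
  mp <- toy_parallel_model(10)
  rp <- fva(mp, "EX_B", fraction = 1, reactions = c("P1", "P2"))
  expect_equal(rp$min, c(0, 0), tolerance = 1e-8)
  expect_equal(rp$max, c(10, 10), tolerance = 1e-8)
  # fraction 0 relaxes to plain bounds-constrained min/max
  r0 <- fva(mp, "EX_B", fraction = 0, reactions = "EX_A")
  expect_equal(r0$min, -10, tolerance = 1e-8)
  expect_equal(r0$max, 0, tolerance = 1e-8)
})

test_that("carbon yield is exact on conservative and lossy toys", {
  m <- toy_chain_model(10)
  sol <- fba(m)
  yo <- yield_and_oxygen(sol, substrate_exchange = "EX_A",
                         product_id = "EX_B")
  expect_equal(yo$carbon_yield, 1)
  # stoichiometric half-carbon loss: A(2C) -> C(1C) + loss, P from 2 C(1C)
  m2 <- toy_branch_model()
  m2 <- set_bounds(m2, "KEEP", ub = 0)  # force the lossy branch
  sol2 <- fba(m2)
  yo2 <- yield_and_oxygen(sol2, substrate_exchange = "EX_A",
                          product_id = "EX_P")
  expect_equal(yo2$carbon_yield, 0.5)
  # zero substrate flux errors
  m3 <- set_bounds(toy_chain_model(10), "EX_A", lb = 0)
  expect_error(yield_and_oxygen(fba(m3), substrate_exchange = "EX_A",
                                product_id = "EX_B"), "zero")
})

test_that("carbon balance check flags exactly the imbalanced reactions", {
  m <- toy_chain_model()
  expect_equal(carbon_balance_check(m), character(0))
  bad <- metabolic_model(
    metabolites = data.frame(id = c("A", "B"), carbon = c(3, 2)),
    reactions = data.frame(id = c("EX_A", "R", "EX_B"),
                           lb = c(-10, 0, 0), ub = 1000),
    stoichiometry = list(EX_A = c(A = -1), R = c(A = -1, B = 1),
                         EX_B = c(B = -1)),
    objective = c(EX_B = 1))
  expect_equal(carbon_balance_check(bad), "R")
})

test_that("carbon yield never exceeds one on carbon-balanced models", {
  m <- generate_core_model()
  expect_length(carbon_balance_check(m), 0)
  set.seed(5)
  subs <- c("EX_glc", "EX_glyc")
  for (i in 1:6) {
    sub <- sample(subs, 1)
    up <- runif(1, 1, 10)
    o2cap <- sample(c(1000, runif(1, 1, 5)), 1)
    m2 <- set_bounds(m, "EX_o2", lb = -o2cap)
    for (obj in c("BIOMASS", "TAGS")) {
      sol <- fba(m2, objective_id = obj, uptake = stats::setNames(up, sub))
      if (sol$status != "optimal" || sol$objective_value < 1e-9) next
      prod <- if (obj == "BIOMASS") "EX_biomass" else "EX_tag"
      yo <- yield_and_oxygen(sol, substrate_exchange = sub, product_id = prod)
      expect_lte(yo$carbon_yield, 1 + 1e-9)
    }
  }
})
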