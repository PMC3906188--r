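# FBA fits: steady state, duality audit, closed-uptake degeneracy, and the
# cycle-removal post-process.

test_that("optimal fits satisfy steady state and bounds", {
  for (model in list(toy_cerevisiae(), toy_stipitis())) {
    m <- toy_with_uptakes(model, 8, 3)
    f <- fba(m)
    expect_identical(f$status, "optimal")
    expect_lt(max(abs(m$S %*% f$fluxes)), 1e-6)
    expect_true(all(f$fluxes >= m$lb - 1e-9 & f$fluxes <= m$ub + 1e-9))
    expect_equal(f$objective, unname(f$fluxes[objective_reaction(m)]),
                 tolerance = 1e-9)
  }
})

test_that("closing all uptakes forces zero growth", {
  m <- toy_cerevisiae()
  m <- set_uptake(m, "EX_glc", 0)
  m <- set_uptake(m, "EX_o2", 0)
  m$lb[["ATPM"]] <- 0; m$ub[["ATPM"]] <- 0   # nothing enters, nothing demanded
  f <- fba(m, degeneracy = FALSE)
  expect_equal(f$objective, 0, tolerance = 1e-12)
})

test_that("infeasible constraint sets return status infeasible", {
  m <- toy_cerevisiae()
  m <- set_uptake(m, "EX_glc", 0)
  m <- set_uptake(m, "EX_o2", 0)            # maintenance ATP now unpayable
  f <- fba(m, degeneracy = FALSE)
  expect_identical(f$status, "infeasible")
  expect_length(f$fluxes, 0)
})

test_that("remove_loops collapses a planted futile cycle and nothing else", {
  m <- cycle_model()
  f <- fba(m, degeneracy = FALSE)
  loopy <- f
  loopy$fluxes[c("C1", "C2", "C3")] <- loopy$fluxes[c("C1", "C2", "C3")] + 7.3
  expect_lt(max(abs(m$S %*% loopy$fluxes)), 1e-9)   # still a valid optimum
  clean <- remove_loops(m, loopy)
  expect_equal(unname(clean$fluxes[c("C1", "C2", "C3")]), c(0, 0, 0),
               tolerance = 1e-9)
  ex <- exchanges(m)
  expect_equal(clean$fluxes[ex], f$fluxes[ex], tolerance = 1e-9)
  expect_equal(clean$fluxes[["BIOMASS"]], f$objective, tolerance = 1e-9)
})

test_that("remove_loops leaves a loop-free optimum unchanged and is exchange-safe on the toys", {
  for (model in list(toy_cerevisiae(), toy_stipitis())) {
    m <- toy_with_uptakes(model, 10, 5)
    f <- fba(m, degeneracy = FALSE)
    clean <- remove_loops(m, f)
    ex <- exchanges(m)
    expect_equal(clean$fluxes[ex], f$fluxes[ex], tolerance = 1e-6)
    expect_equal(clean$fluxes[[objective_reaction(m)]], f$objective,
                 tolerance = 1e-6)
    expect_lte(sum(abs(clean$fluxes[!m$exchange])),
               sum(abs(f$fluxes[!m$exchange])) + 1e-9)
  }
})

test_that("remove_loops refuses non-optimal input", {
  m <- toy_cerevisiae()
  bad <- structure(list(status = "infeasible"), class = "fba_fit")
  expect_error(remove_loops(m, bad), "optimal")
})

test_that("fit accessors expose fluxes and duals coherently", {
  m <- toy_with_uptakes(toy_cerevisiae(), 10, 4)
  f <- fba(m)
  expect_identical(coef(f), f$fluxes)
  expect_named(f$duals, m$mets$id)
  expect_output(print(f), "optimal")
})
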