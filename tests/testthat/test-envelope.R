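# Production envelopes: endpoints, convexity of the feasible band, coupling
# verdicts and the redox-overflow monotonicity.

test_that("using biomass itself as product gives the identity envelope", {
  m <- toy_with_uptakes(toy_cerevisiae(), 10, 5)
  env <- production_envelope(m, "BIOMASS", n_points = 8)
  expect_equal(env$min_product, env$growth_points, tolerance = 1e-6)
  expect_equal(env$max_product, env$growth_points, tolerance = 1e-6)
})

test_that("envelope bounds are ordered, concave above and convex below", {
  m <- toy_with_uptakes(toy_cerevisiae(), 10, 4)
  env <- production_envelope(m, "EX_etoh", n_points = 15)
  expect_true(all(env$min_product <= env$max_product + 1e-9))
  x <- env$growth_points
  chord_ok <- function(y, concave) {
    mid <- 2:(length(x) - 1)
    interp <- y[1] + (y[length(y)] - y[1]) * (x[mid] - x[1]) / (x[length(x)] - x[1])
    if (concave) all(y[mid] >= interp - 1e-6) else all(y[mid] <= interp + 1e-6)
  }
  expect_true(chord_ok(env$max_product, concave = TRUE))
  expect_true(chord_ok(env$min_product, concave = FALSE))
})

test_that("zero-growth endpoint reaches the pure-fermentation maximum", {
  m <- toy_with_uptakes(toy_cerevisiae(), 10, 4)
  env <- production_envelope(m, "EX_etoh", n_points = 10)
  # oracle: max ethanol with growth pinned to zero, by vertex enumeration
  m0 <- m
  j <- match("BIOMASS", m0$rxns$id)
  m0$lb[j] <- m0$ub[j] <- 0
  want <- vertex_lp(m0$S, rep(0, nrow(m0$S)),
                    as.numeric(m0$rxns$id == "EX_etoh"), m0$lb, m0$ub)$obj
  expect_equal(env$max_product[1], want, tolerance = 1e-6)
})

test_that("coupling verdicts separate the two toys", {
  sc <- toy_cerevisiae()
  loo <- line_of_optimality(sc, 10)$o2[1]
  env_sc <- production_envelope(toy_with_uptakes(sc, 10, loo / 2), "EX_etoh")
  expect_identical(env_sc$coupling, "coupled")
  expect_gt(env_sc$min_product[length(env_sc$min_product)], 1e-6)

  ss <- set_uptake(toy_stipitis(), "EX_o2", "unbounded")
  ss <- set_uptake(ss, "EX_glc", 10)
  env_ss <- production_envelope(ss, "EX_etoh")
  expect_identical(env_ss$coupling, "non_coupled")
  expect_lte(env_ss$min_product[length(env_ss$min_product)], 1e-6)
})

test_that("an all-zero envelope is non-coupled and warns on zero bounds", {
  m <- toy_with_uptakes(toy_cerevisiae(), 10, 1000)
  j <- match("EX_etoh", m$rxns$id)
  m$lb[j] <- m$ub[j] <- 0
  expect_warning(env <- production_envelope(m, "EX_etoh", n_points = 5),
                 "zero bounds")
  expect_identical(env$coupling, "non_coupled")
  expect_true(all(abs(env$max_product) <= 1e-9))
})

test_that("tightening oxygen never lowers max ethanol at fixed growth", {
  sc <- toy_cerevisiae()
  zprobe <- 0.3
  vals <- sapply(c(6, 4, 2), function(o2) {
    m <- toy_with_uptakes(sc, 10, o2)
    fx <- stats::setNames(list(zprobe + c(-1e-9, 1e-9)), "BIOMASS")
    redoxplane:::optimize_flux(m, "EX_etoh", maximize = TRUE, fix = fx)$obj
  })
  expect_true(all(diff(vals) >= -1e-8))
})
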