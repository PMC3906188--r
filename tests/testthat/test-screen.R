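# Deletion analyses: presets, the pattern screen, coupled-design search vs
# exhaustive enumeration, the NADH-sink variant, and idempotence.

test_that("a priori presets resolve through the id map and report patterns", {
  ss <- toy_stipitis()
  ap <- a_priori_presets(ss, grid_steps = 8)
  expect_named(ap, c("ndh1_aox", "cox"))
  expect_setequal(ap$ndh1_aox$deletion_set, c("AOX", "RESP"))
  expect_identical(ap$cox$deletion_set, "RESP")
  expect_true(all(vapply(ap, function(r) r$max_growth, 0) > 0))
  # unresolvable preset names are skipped with a warning, not an error
  expect_warning(ap2 <- a_priori_presets(toy_cerevisiae(), grid_steps = 8),
                 "unresolvable")
  expect_false("ndh1_aox" %in% names(ap2))
})

test_that("pattern screen finds the transhydrogenase bypass as a flip and rejects lethal sets", {
  ss <- toy_stipitis()
  sur <- pattern_screen(ss, c("AOX", "THD", "POLYOL"), max_size = 1)
  expect_true("THD" %in% names(sur))
  expect_true(sur$THD$pattern$all_excess_o2_limited)
  # deleting the biomass reaction can never survive the growth filter
  none <- pattern_screen(ss, "BIOMASS", min_growth = 0.01)
  expect_length(none, 0)
  expect_error(pattern_screen(ss, character(0)), "non-empty")
})

test_that("deleting the full recycling set replicates the all-excess pattern", {
  ss <- toy_stipitis()
  del <- apply_deletions(ss, c("AOX", "THD", "POLYOL"))
  pat <- availability_pattern(phpp_scan(del, steps = 20))
  expect_true(pat$all_excess_o2_limited)
})

test_that("local search recovers exactly the exhaustively enumerated coupled designs", {
  ss <- toy_stipitis()
  enum <- enumerate_coupled_sets(ss, "EX_etoh", max_deletions = 3,
                                 min_growth = 0.1)
  expect_gt(nrow(enum), 0)
  found <- growth_coupled_search(ss, "EX_etoh", max_deletions = 3)
  keys <- unname(vapply(found, function(r)
    paste(r$deletion_set, collapse = "+"), ""))
  expect_setequal(keys, enum$deletion_set)
  expect_true(all(vapply(found, function(r) r$coupling, "") == "coupled"))
  # the strongest design agrees
  expect_identical(keys[1], enum$deletion_set[1])
  expect_error(growth_coupled_search(ss, "EX_etoh", max_deletions = 0),
               "max_deletions")
})

test_that("returned deletion sets reproduce their verdicts from scratch", {
  ss <- toy_stipitis()
  found <- growth_coupled_search(ss, "EX_etoh", max_deletions = 2)
  for (r in found) {
    md <- apply_deletions(toy_stipitis(), r$deletion_set)
    f <- fba(md, degeneracy = FALSE)
    expect_equal(f$objective, r$max_growth, tolerance = 1e-8)
    expect_identical(production_envelope(md, "EX_etoh")$coupling, r$coupling)
  }
})

test_that("the NADH sink drains growth monotonically and respects bounds", {
  ss <- toy_stipitis()
  v <- nadh_sink_variant(ss)               # defaults (0.1, 0.6), 0.20 h^-1
  expect_true("NADH_SINK" %in% v$rxns$id)
  f <- fba(v, degeneracy = FALSE)
  expect_identical(f$status, "optimal")
  expect_gte(f$objective, 0.20)
  # an inactive sink leaves the optimum untouched
  v0 <- nadh_sink_variant(ss, c(0, 0), 0)
  expect_equal(fba(v0, degeneracy = FALSE)$objective,
               fba(ss, degeneracy = FALSE)$objective, tolerance = 1e-9)
  # growth strictly decreases as the forced drain grows
  zs <- vapply(c(0, 0.2, 0.4), function(lb)
    fba(nadh_sink_variant(ss, c(lb, 0.6), 0), degeneracy = FALSE)$objective,
    numeric(1))
  expect_true(all(diff(zs) < 0))
  expect_error(nadh_sink_variant(ss, c(0.6, 0.1)), "lb <= ub")
  expect_error(nadh_sink_variant(ss, c(900, 900), 0.2), "maximal feasible")
})
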