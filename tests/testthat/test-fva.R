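# Flux variability: bin bookkeeping, containment of the FBA point,
# permutation invariance, loopless tightening and the span-vs-oxygen
# profiles.

test_that("span bins follow the stated edge convention", {
  b <- redoxplane:::span_bins(c(12, 5, 0.5, 0.001))
  expect_identical(unlist(b), c(S1 = 1L, S2 = 1L, S3 = 1L, excluded = 1L))
  edges <- redoxplane:::span_bins(c(10, 1, 0.01))
  expect_identical(unlist(edges), c(S1 = 0L, S2 = 1L, S3 = 2L, excluded = 0L))
})

test_that("a blocked reaction has zero span and is excluded", {
  m <- toy_with_uptakes(toy_cerevisiae(), 10, 4)
  m <- apply_deletions(m, "TCA")
  r <- fva(m)
  expect_equal(r$span[match("TCA", r$reaction)], 0)
  expect_gte(r$bins$excluded, 1)
})

test_that("the FBA flux vector lies within the FVA band everywhere", {
  for (model in list(toy_cerevisiae(), toy_stipitis())) {
    for (o2 in c(2, 6)) {
      m <- toy_with_uptakes(model, 10, o2)
      r <- fva(m)
      expect_true(all(r$fba_fluxes >= r$v_min - 1e-7),
                  info = paste(model$model_id, o2))
      expect_true(all(r$fba_fluxes <= r$v_max + 1e-7),
                  info = paste(model$model_id, o2))
      expect_true(all(r$span >= 0))
      expect_identical(r$bins$S1 + r$bins$S2 + r$bins$S3 + r$bins$excluded,
                       as.integer(nrow(model$rxns)))
    }
  }
})

test_that("FVA bounds are invariant to reaction column order", {
  m <- toy_with_uptakes(toy_cerevisiae(), 10, 3)
  r <- fva(m)
  set.seed(3)
  perm <- sample(ncol(m$S))
  mp <- m
  mp$S <- m$S[, perm]
  mp$rxns <- m$rxns[perm, ]
  mp$lb <- m$lb[perm]; mp$ub <- m$ub[perm]
  mp$obj <- m$obj[perm]; mp$exchange <- m$exchange[perm]
  rp <- fva(mp)
  o <- match(r$reaction, rp$reaction)
  expect_equal(rp$v_min[o], r$v_min, tolerance = 1e-7)
  expect_equal(rp$v_max[o], r$v_max, tolerance = 1e-7)
})

test_that("loopless FVA never widens any span", {
  m <- toy_with_uptakes(toy_stipitis(), 10, 3)
  plain <- fva(m)
  clean <- fva(m, loopless = TRUE)
  expect_true(all(clean$span <= plain$span + 1e-7))
})

test_that("the overflow toy gains small spans under oxygen limitation", {
  sc <- toy_cerevisiae()
  loo <- line_of_optimality(sc, 10)$o2[1]
  low <- fva(toy_with_uptakes(sc, 10, 2))
  online <- fva(toy_with_uptakes(sc, 10, loo))
  expect_gt(low$bins$S3, online$bins$S3)
})

test_that("span profile separates the toys: invariant vs varying flexibility", {
  p_sc <- span_profile(toy_cerevisiae())
  p_ss <- span_profile(toy_stipitis())
  expect_lt(p_ss$invariance_metric, p_sc$invariance_metric)
  expect_equal(nrow(p_sc$bin_table), 8L)
  expect_error(span_profile(toy_cerevisiae(), o2_values = c(3, 1)),
               "sorted")
})
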