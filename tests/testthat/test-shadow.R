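# Shadow-price semantics: finite-difference agreement, sign conventions,
# free-exchange nulls, and the antisymmetry of the reducing-capacity price.

test_that("finite-difference probe agrees with LP duals for all non-degenerate metabolites", {
  ups <- random_uptakes(5)
  for (model in list(toy_cerevisiae(), toy_stipitis())) {
    for (k in seq_len(nrow(ups))) {
      m <- toy_with_uptakes(model, ups$glc[k], ups$o2[k])
      f <- fba(m)
      if (f$status != "optimal" || f$objective < 1e-8) next
      for (met in m$mets$id) {
        v <- tryCatch(verify_fd(m, met), error = function(e) NULL)
        if (is.null(v) || v$degenerate) next
        expect_true(v$agrees,
                    info = sprintf("%s %s at glc=%.2f o2=%.2f: fd=%.6g dual=%.6g",
                                   model$model_id, met, ups$glc[k], ups$o2[k],
                                   v$fd_estimate, v$gamma))
      }
    }
  }
})

test_that("a metabolite with a free reversible exchange has zero shadow price", {
  m <- toy_with_uptakes(toy_cerevisiae(), 10, 4)
  j <- match("EX_etoh", m$rxns$id)
  m$lb[j] <- -1000                       # ethanol freely importable too
  m$rxns$reversible[j] <- TRUE
  f <- fba(m)
  expect_equal(as.numeric(shadow_price(f, "etoh_e")), 0, tolerance = 1e-9)
})

test_that("limiting metabolites probe as limiting (growth rises with supply)", {
  m <- toy_with_uptakes(toy_cerevisiae(), 4, 1000)   # glucose-limited
  f <- fba(m)
  v <- verify_fd(m, "glc_e")
  expect_lt(v$fd_estimate, 0)
  expect_lt(as.numeric(shadow_price(f, "glc_e")), 0)
})

test_that("gamma_red is the NADH/NAD dual difference and is antisymmetric", {
  m <- toy_with_uptakes(toy_stipitis(), 10, 3)
  f <- fba(m)
  g <- gamma_red(f, "c")
  if (!g$degenerate)
    expect_equal(g$gamma_red,
                 unname(f$duals[["nadh_c"]] - f$duals[["nad_c"]]),
                 tolerance = 1e-12)
  swapped <- unname(f$duals[["nad_c"]] - f$duals[["nadh_c"]])
  expect_equal(swapped, -unname(f$duals[["nadh_c"]] - f$duals[["nad_c"]]))
})

test_that("classification obeys the sign convention with epsilon 1e-6", {
  expect_identical(redoxplane:::classify_gamma(2e-6), "excess")
  expect_identical(redoxplane:::classify_gamma(-2e-6), "limiting")
  expect_identical(redoxplane:::classify_gamma(5e-7), "neutral")
})

test_that("probe and metabolite validation errors are raised", {
  m <- toy_with_uptakes(toy_cerevisiae(), 10, 4)
  f <- fba(m)
  expect_error(verify_fd(m, "glc_e", probe = 0), "probe")
  expect_error(shadow_price(f, "nope_c"), "unknown metabolite")
  expect_error(gamma_red(f, "m"), "not found")
})

test_that("per-compartment table reports the cytosolic pair for the toys", {
  f <- fba(toy_with_uptakes(toy_stipitis(), 10, 3))
  tab <- gamma_red_table(f)
  expect_true("c" %in% tab$compartment)
  expect_true(all(tab$classification %in% c("excess", "limiting", "neutral")))
})
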