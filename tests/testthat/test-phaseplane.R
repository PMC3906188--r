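# Phase planes: line of optimality, growth monotonicity, ethanol geometry
# and availability-pattern summaries.

sc_grid <- NULL
get_sc_grid <- function() {
  if (is.null(sc_grid)) sc_grid <<- phpp_scan(toy_cerevisiae(), steps = 12)
  sc_grid
}
ss_grid <- NULL
get_ss_grid <- function() {
  if (is.null(ss_grid)) ss_grid <<- phpp_scan(toy_stipitis(), steps = 12)
  ss_grid
}

test_that("line of optimality starts at zero and carries no ethanol", {
  sc <- toy_cerevisiae()
  loo <- line_of_optimality(sc, c(0, 5, 10))
  # zero glucose cannot pay the maintenance demand: the line is undefined
  expect_true(is.na(loo$o2[1]))
  expect_gt(loo$o2[3], loo$o2[2])
  for (i in 2:3) {
    m <- toy_with_uptakes(sc, loo$glc[i], loo$o2[i])
    f <- remove_loops(m, fba(m, degeneracy = FALSE))
    expect_lte(f$fluxes[["EX_etoh"]], 1e-6)
  }
})

test_that("growth is monotone in each uptake up to the line of optimality", {
  g <- get_sc_grid()
  for (i in seq_along(g$glc_axis)) {
    loo_i <- g$loo$o2[i]
    if (is.na(loo_i)) next
    below <- which(g$o2_axis <= loo_i & g$feasible[i, ])
    if (length(below) > 1)
      expect_true(all(diff(g$growth[i, below]) >= -1e-8))
    # beyond the line growth never exceeds the on-line (unbounded-oxygen) value
    above <- which(g$o2_axis > loo_i & g$feasible[i, ])
    if (length(above))
      expect_true(all(g$growth[i, above] <= g$loo$growth[i] + 1e-8))
  }
  # monotone in glucose at fixed oxygen
  for (j in seq_along(g$o2_axis)) {
    fe <- which(g$feasible[, j])
    if (length(fe) > 1)
      expect_true(all(diff(g$growth[fe, j]) >= -1e-8))
  }
})

test_that("ethanol is secreted strictly left of the line in the overflow toy", {
  g <- get_sc_grid()
  sel <- g$feasible & g$o2_limited
  expect_gt(sum(sel), 0)
  expect_true(all(g$ethanol[sel] > 0))
})

test_that("availability patterns separate the two toys", {
  p_sc <- availability_pattern(get_sc_grid())
  expect_true(p_sc$all_excess_o2_limited)
  expect_false(p_sc$subset_excess)
  p_ss <- availability_pattern(get_ss_grid())
  expect_true(p_ss$subset_excess)
  expect_false(p_ss$all_excess_o2_limited)
})

test_that("the recycling toy is limiting near its line and excess only at low oxygen", {
  g <- get_ss_grid()
  df <- as.data.frame(g)
  df <- df[df$feasible & df$o2_limited, ]
  exc <- df[df$classification == "excess", ]
  non <- df[df$classification != "excess", ]
  # excess points sit at lower oxygen than the rest, column by column
  for (glc in unique(exc$glc)) {
    e <- exc$o2[exc$glc == glc]; n <- non$o2[non$glc == glc]
    if (length(e) && length(n)) expect_lt(max(e), min(n))
  }
  # at least one strictly limiting point exists left of the line (the
  # limiting band hugs the line, inside the one-step exclusion zone)
  dfl <- as.data.frame(g)
  dfl$loo <- g$loo$o2[match(dfl$glc, g$loo$glc)]
  dfl <- dfl[dfl$feasible & !is.na(dfl$loo) & dfl$o2 < dfl$loo - 1e-9, ]
  expect_gt(sum(dfl$classification == "limiting"), 0)
})

test_that("pattern summaries are stable under grid refinement", {
  coarse <- availability_pattern(phpp_scan(toy_cerevisiae(), steps = 8))
  fine <- availability_pattern(get_sc_grid())
  expect_identical(coarse$all_excess_o2_limited, fine$all_excess_o2_limited)
  coarse_ss <- availability_pattern(phpp_scan(toy_stipitis(), steps = 8))
  fine_ss <- availability_pattern(get_ss_grid())
  expect_identical(coarse_ss$subset_excess, fine_ss$subset_excess)
})

test_that("degenerate ranges and missing exchanges are rejected", {
  expect_error(phpp_scan(toy_cerevisiae(), steps = 1), "steps")
  expect_error(phpp_scan(toy_cerevisiae(), glc_range = c(3, 3)),
               "non-degenerate")
  expect_error(phpp_scan(cycle_model()), "glucose")
  g <- get_sc_grid()
  g$feasible[] <- FALSE
  expect_error(availability_pattern(g), "no feasible")
})
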