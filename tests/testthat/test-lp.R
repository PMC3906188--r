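# LP engine: optima against brute-force vertex enumeration, duals against
# central finite differences, and an external HiGHS cross-check.

test_that("simplex optimum matches vertex enumeration on random bounded LPs", {
  set.seed(7)
  for (trial in 1:25) {
    m <- sample(2:4, 1); n <- m + sample(1:4, 1)
    A <- matrix(round(rnorm(m * n), 2), m, n)
    lb <- round(runif(n, -4, 0), 2); ub <- lb + round(runif(n, 0.5, 6), 2)
    x0 <- lb + runif(n) * (ub - lb)
    b <- as.numeric(A %*% x0)            # feasible by construction
    obj <- round(rnorm(n), 2)
    got <- redoxplane:::lp_solve_bounded(A, b, obj, lb, ub)
    want <- vertex_lp(A, b, obj, lb, ub)
    expect_identical(got$status, "optimal")
    expect_equal(got$obj, want$obj, tolerance = 1e-7)
    expect_lt(max(abs(A %*% got$x - b)), 1e-6)
    expect_true(all(got$x >= lb - 1e-8 & got$x <= ub + 1e-8))
  }
})

test_that("equality duals equal dZ*/db by central finite differences", {
  set.seed(11)
  checked <- 0
  for (trial in 1:10) {
    m <- sample(2:4, 1); n <- m + sample(2:5, 1)
    A <- matrix(round(rnorm(m * n), 2), m, n)
    lb <- round(runif(n, -4, 0), 2); ub <- lb + round(runif(n, 1, 6), 2)
    b <- as.numeric(A %*% (lb + runif(n) * (ub - lb)))
    obj <- round(rnorm(n), 2)
    r <- redoxplane:::lp_solve_bounded(A, b, obj, lb, ub)
    if (r$status != "optimal") next
    h <- 1e-5
    for (i in seq_len(m)) {
      bp <- b; bp[i] <- bp[i] + h
      bm <- b; bm[i] <- bm[i] - h
      rp <- redoxplane:::lp_solve_bounded(A, bp, obj, lb, ub)
      rm <- redoxplane:::lp_solve_bounded(A, bm, obj, lb, ub)
      if (rp$status != "optimal" || rm$status != "optimal") next
      fwd <- (rp$obj - r$obj) / h
      bwd <- (r$obj - rm$obj) / h
      if (abs(fwd - bwd) > 1e-6) next     # kink: dual not unique, skip
      expect_equal(r$y[i], (rp$obj - rm$obj) / (2 * h), tolerance = 1e-4)
      checked <- checked + 1
    }
  }
  expect_gt(checked, 10)
})

test_that("toy FBA objectives agree with an external HiGHS solve", {
  for (model in list(toy_cerevisiae(), toy_stipitis())) {
    m <- toy_with_uptakes(model, 10, 4)
    f <- fba(m, degeneracy = FALSE)
    ext <- scipy_lp_obj(m$S, rep(0, nrow(m$S)), m$obj, m$lb, m$ub)
    expect_false(is.null(ext))
    expect_equal(ext$status, 0L)
    expect_equal(f$objective, ext$obj, tolerance = 1e-7)
  }
})

test_that("infeasible and unbounded problems are reported as such", {
  A <- matrix(c(1, 1), 1, 2)
  r <- redoxplane:::lp_solve_bounded(A, 10, c(1, 0), c(0, 0), c(1, 1))
  expect_identical(r$status, "infeasible")
  r2 <- redoxplane:::lp_solve_bounded(A, 0, c(1, -1), c(-1e30, -1e30),
                                      c(1e30, 1e30))
  expect_identical(r2$status, "unbounded")
})

test_that("FBA optimum scales linearly with uptake bounds (LP homogeneity)", {
  m <- cycle_model()
  f1 <- fba(m, degeneracy = FALSE)
  m2 <- set_uptake(m, "EX_s", 10)       # doubles the only uptake bound
  f2 <- fba(m2, degeneracy = FALSE)
  expect_equal(f2$objective, 2 * f1$objective, tolerance = 1e-9)
})
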