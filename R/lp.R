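## Bounded-variable two-phase primal simplex.
##
## Solves   max/min  c'x   s.t.  A x = b,  lb <= x <= ub
## and returns, besides the optimal vertex, the dual vector y of the equality
## rows (dZ*/db for the maximisation) and per-column reduced costs. This is
## the engine behind every flux-balance solve in the package; metabolite
## shadow prices are exactly the equality duals y.
##
## Written for the dense, small-to-medium stoichiometric matrices this package
## targets; the basis is refactorised from scratch every pivot (solve() on an
## m x m matrix), trading speed for transparency and numerical robustness.
## Bland's anti-cycling rule is used throughout, so termination is guaranteed.

#' Solve a bounded-variable linear program
#'
#' @param A constraint matrix (m x n), equalities \code{A x = b}.
#' @param b right-hand side (length m).
#' @param obj objective coefficients (length n).
#' @param lb,ub finite variable bounds, \code{lb <= ub} element-wise.
#' @param maximize maximise (default) or minimise.
#' @param tol pivot / feasibility tolerance.
#' @param max_iter iteration cap across both phases.
#' @return list with \code{status} ("optimal", "infeasible", "unbounded",
#'   "iteration_limit"), \code{x}, \code{obj}, \code{y} (equality duals, signed
#'   as dZ*/db of the maximisation), \code{dj} (reduced costs) and
#'   \code{iterations}.
#' @keywords internal
lp_solve_bounded <- function(A, b, obj, lb, ub, maximize = TRUE,
                             tol = 1e-9, max_iter = 20000L) {
  A <- as.matrix(A)
  m <- nrow(A); n <- ncol(A)
  stopifnot(length(b) == m, length(obj) == n, length(lb) == n, length(ub) == n)
  if (any(lb > ub + 1e-12))
    return(list(status = "infeasible", x = NULL, obj = NA_real_,
                y = NULL, dj = NULL, iterations = 0L))
  lb <- pmax(lb, -1e30); ub <- pmin(ub, 1e30)
  sense <- if (maximize) 1 else -1
  c_full <- sense * obj

  ## augment with m artificial columns (identity, sign-adjusted below)
  nt <- n + m
  Af <- cbind(A, diag(m))
  lbf <- c(lb, rep(0, m))
  ubf <- c(ub, rep(Inf, m))

  ## nonbasic structural variables start at the bound nearest zero
  at_ub <- logical(nt)
  x <- numeric(nt)
  x[seq_len(n)] <- ifelse(abs(lb) <= abs(ub), lb, ub)
  at_ub[seq_len(n)] <- abs(lb) > abs(ub)
  r <- b - A %*% x[seq_len(n)]
  sgn <- ifelse(r >= 0, 1, -1)
  Af[, n + seq_len(m)] <- diag(as.numeric(sgn), m)
  x[n + seq_len(m)] <- abs(r)
  basis <- n + seq_len(m)

  phase1_c <- c(rep(0, n), rep(-1, m))   # maximise -(sum of artificials)

  run_phase <- function(cvec, basis, x, at_ub, iter0, huge_unbounded = FALSE) {
    iter <- iter0
    repeat {
      if (iter >= max_iter)
        return(list(status = "iteration_limit", basis = basis, x = x,
                    at_ub = at_ub, y = NULL, iter = iter))
      B <- Af[, basis, drop = FALSE]
      y <- tryCatch(solve(t(B), cvec[basis]), error = function(e) NULL)
      if (is.null(y))
        return(list(status = "singular", basis = basis, x = x,
                    at_ub = at_ub, y = NULL, iter = iter))
      nonbasic <- setdiff(seq_len(nt), basis)
      dj <- cvec[nonbasic] - as.numeric(crossprod(y, Af[, nonbasic, drop = FALSE]))
      ## eligible entering columns (Bland: smallest index)
      up_ok <- dj > tol & !at_ub[nonbasic] & (ubf[nonbasic] > lbf[nonbasic])
      dn_ok <- dj < -tol & at_ub[nonbasic]
      elig <- nonbasic[up_ok | dn_ok]
      if (!length(elig))
        return(list(status = "optimal", basis = basis, x = x,
                    at_ub = at_ub, y = y, iter = iter))
      j <- min(elig)
      dirn <- if (at_ub[j]) -1 else 1      # move off its current bound
      d <- solve(B, Af[, j])               # basic response: xB -= t*dirn*d
      ## ratio test over basic variables + entering's own opposite bound
      lim_t <- ubf[j] - lbf[j]               # bound-flip limit
      lim_k <- 0L                            # 0 = bound flip
      lim_to_ub <- FALSE
      cand <- list()
      for (k in seq_len(m)) {
        dk <- dirn * d[k]
        bk <- basis[k]
        if (dk > tol) {
          cand[[length(cand) + 1L]] <- c(k, (x[bk] - lbf[bk]) / dk, 0)
        } else if (dk < -tol && is.finite(ubf[bk])) {
          cand[[length(cand) + 1L]] <- c(k, (ubf[bk] - x[bk]) / (-dk), 1)
        }
      }
      if (length(cand)) {
        cm <- do.call(rbind, cand)
        cm[, 2] <- pmax(cm[, 2], 0)
        best <- min(cm[, 2])
        if (best < lim_t - 1e-12) {
          ties <- cm[cm[, 2] <= best + 1e-12, , drop = FALSE]
          pick <- ties[which.min(basis[ties[, 1]]), ]   # Bland on leaving var
          lim_t <- pick[2]; lim_k <- as.integer(pick[1]); lim_to_ub <- pick[3] == 1
        }
      }
      t_max <- lim_t
      leave <- lim_k; leave_to_ub <- lim_to_ub
      if (huge_unbounded && t_max > 1e20) t_max <- Inf   # bounds standing in for infinity
      if (!is.finite(t_max))
        return(list(status = "unbounded", basis = basis, x = x,
                    at_ub = at_ub, y = y, iter = iter))
      t_max <- max(t_max, 0)
      ## update primal values
      x[j] <- x[j] + dirn * t_max
      x[basis] <- x[basis] - t_max * dirn * d
      if (leave == 0L) {
        at_ub[j] <- !at_ub[j]              # bound flip, basis unchanged
      } else {
        lv <- basis[leave]
        x[lv] <- if (leave_to_ub) ubf[lv] else lbf[lv]
        at_ub[lv] <- leave_to_ub
        basis[leave] <- j
      }
      iter <- iter + 1L
    }
  }

  ph1 <- run_phase(phase1_c, basis, x, at_ub, 0L)
  if (ph1$status %in% c("iteration_limit", "singular"))
    return(list(status = ph1$status, x = NULL, obj = NA_real_, y = NULL,
                dj = NULL, iterations = ph1$iter))
  art_val <- sum(ph1$x[n + seq_len(m)])
  if (ph1$status != "optimal" || art_val > 1e-7)
    return(list(status = "infeasible", x = NULL, obj = NA_real_, y = NULL,
                dj = NULL, iterations = ph1$iter))
  ## pin artificials to zero for phase 2
  ubf[n + seq_len(m)] <- 0
  x <- ph1$x; x[n + seq_len(m)] <- pmin(x[n + seq_len(m)], 0)
  ph2_c <- c(c_full, rep(0, m))
  ph2 <- run_phase(ph2_c, ph1$basis, x, ph1$at_ub, ph1$iter, huge_unbounded = TRUE)
  if (ph2$status == "unbounded")
    return(list(status = "unbounded", x = NULL, obj = NA_real_, y = NULL,
                dj = NULL, iterations = ph2$iter))
  if (ph2$status != "optimal")
    return(list(status = ph2$status, x = NULL, obj = NA_real_, y = NULL,
                dj = NULL, iterations = ph2$iter))
  xs <- ph2$x[seq_len(n)]
  if (abs(sum(obj * xs)) > 1e25)           # optimum at a stand-in-infinity bound
    return(list(status = "unbounded", x = NULL, obj = NA_real_, y = NULL,
                dj = NULL, iterations = ph2$iter))
  y <- sense * as.numeric(ph2$y)           # duals of the stated (max) problem
  dj_full <- sense * (c_full - as.numeric(crossprod(ph2$y, Af[, seq_len(n), drop = FALSE])))
  list(status = "optimal", x = xs,
       obj = sum(obj * xs),
       y = y, dj = dj_full, iterations = ph2$iter)
}
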