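#' Solve a bounded linear program
#'
#' Solves \deqn{\max_v\ c^T v \quad \text{s.t.}\quad A v = b,\; l \le v \le u}
#' (or the minimization) with a dense two-phase primal simplex that keeps
#' nonbasic variables at either of their bounds. This is the linear-algebra
#' core behind FBA and FVA, where \eqn{A} is the stoichiometric matrix and
#' \eqn{b = 0} expresses steady-state mass balance. Designed for the dense,
#' well-scaled systems metabolic models produce; all lower bounds must be
#' finite (flux bounds conventionally are), upper bounds may be `Inf`.
#'
#' @param obj objective coefficient vector, length `n`.
#' @param A constraint matrix, `m x n`.
#' @param b right-hand side, length `m`.
#' @param lb,ub variable bounds, length `n`; `lb` finite, `ub` may be `Inf`.
#' @param maximize maximize (default) or minimize.
#' @param tol feasibility / reduced-cost tolerance.
#' @param max_iter simplex iteration cap per phase.
#' @return A list with `status` (`"optimal"`, `"infeasible"`, `"unbounded"`),
#'   `objective` and `x` (a solution vector when optimal, otherwise `NULL`).
#' @export
solve_lp <- function(obj, A, b, lb, ub, maximize = TRUE,
                     tol = 1e-9, max_iter = 20000L) {
  A <- as.matrix(A)
  m <- nrow(A); n <- ncol(A)
  stopifnot(length(obj) == n, length(b) == m, length(lb) == n, length(ub) == n)
  if (any(!is.finite(lb))) stop("solve_lp requires finite lower bounds")
  if (any(lb > ub)) stop("lb > ub in LP")
  cmin <- if (maximize) -obj else obj

  # Shift to x = v - lb in [0, U]; flip rows so the RHS is non-negative,
  # making the identity columns of the artificials a feasible basis.
  b2 <- b - as.vector(A %*% lb)
  U <- ub - lb
  flip <- b2 < 0
  A2 <- A
  if (any(flip)) {
    A2[flip, ] <- -A2[flip, , drop = FALSE]
    b2[flip] <- -b2[flip]
  }
  Aall <- cbind(A2, diag(1, m))
  Uall <- c(U, rep(Inf, m))
  ntot <- n + m

  basis <- (n + 1L):ntot
  at_upper <- rep(FALSE, ntot)

  run_phase <- function(cost, basis, at_upper) {
    iter <- 0L
    bland_after <- 500L + 20L * ntot
    repeat {
      iter <- iter + 1L
      if (iter > max_iter) {
        stop("simplex iteration limit reached (", max_iter, ")")
      }
      nb <- setdiff(seq_len(ntot), basis)
      B <- Aall[, basis, drop = FALSE]
      xNval <- ifelse(at_upper[nb], Uall[nb], 0)
      xB <- tryCatch(solve(B, b2 - as.vector(Aall[, nb, drop = FALSE] %*% xNval)),
                     error = function(e) stop("singular simplex basis"))
      y <- solve(t(B), cost[basis])
      d <- cost[nb] - as.vector(crossprod(Aall[, nb, drop = FALSE], y))
      # Improving directions for a minimization: increase an at-lower variable
      # with negative reduced cost, or decrease an at-upper one with positive.
      viol <- ifelse(at_upper[nb], d, -d)
      cand <- which(viol > tol & Uall[nb] > 0)
      if (!length(cand)) {
        xfull <- numeric(ntot)
        xfull[nb] <- xNval
        xfull[basis] <- xB
        return(list(status = "optimal", x = xfull, basis = basis,
                    at_upper = at_upper))
      }
      j <- if (iter > bland_after) cand[which.min(nb[cand])]
           else cand[which.max(viol[cand])]
      e <- nb[j]
      dirsign <- if (at_upper[e]) -1 else 1
      w <- solve(B, Aall[, e])
      # xB moves by -dirsign * w * t as the entering variable moves by t.
      ti <- rep(Inf, m)
      hit_upper <- rep(FALSE, m)
      for (i in seq_len(m)) {
        wi <- dirsign * w[i]
        if (wi > tol) {
          ti[i] <- max(xB[i], 0) / wi
        } else if (wi < -tol) {
          ub_i <- Uall[basis[i]]
          if (is.finite(ub_i)) {
            ti[i] <- max(ub_i - xB[i], 0) / (-wi)
            hit_upper[i] <- TRUE
          }
        }
      }
      t_basic <- min(ti)
      t_own <- Uall[e]
      if (!is.finite(t_basic) && !is.finite(t_own)) {
        return(list(status = "unbounded"))
      }
      if (is.finite(t_own) && t_own <= t_basic) {
        at_upper[e] <- !at_upper[e]      # bound flip, basis unchanged
        next
      }
      ties <- which(ti <= t_basic + 1e-9)
      r <- if (iter > bland_after) ties[which.min(basis[ties])]
           else ties[which.max(abs(w[ties]))]
      leaving <- basis[r]
      basis[r] <- e
      at_upper[leaving] <- hit_upper[r]
      at_upper[e] <- FALSE
    }
  }

  # Phase 1: minimize the sum of artificials.
  p1 <- run_phase(c(rep(0, n), rep(1, m)), basis, at_upper)
  if (p1$status != "optimal" || sum(p1$x[(n + 1L):ntot]) > 1e-7) {
    return(list(status = "infeasible", objective = NA_real_, x = NULL))
  }
  # Freeze artificials at zero for phase 2.
  Uall[(n + 1L):ntot] <- 0

  p2 <- run_phase(c(cmin, rep(0, m)), p1$basis, p1$at_upper)
  if (p2$status == "unbounded") {
    return(list(status = "unbounded", objective = if (maximize) Inf else -Inf,
                x = NULL))
  }
  x <- p2$x[seq_len(n)] + lb
  x <- pmin(pmax(x, lb), ub)   # shave solver-tolerance excursions
  list(status = "optimal", objective = sum(obj * x), x = x)
}
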