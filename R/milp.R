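# Branch-and-bound mixed-integer layer over the bounded simplex, plus a thin
# quadratic-program wrapper around quadprog. Sized for the relaxation
# problems this package poses (a handful of binary indicators).

#' Solve a mixed-binary linear program
#'
#' Minimizes (or maximizes) `obj' x` subject to `A x = rhs`,
#' `lb <= x <= ub`, with the variables indexed by `bin_idx` restricted to
#' \{0, 1\}. Solved by LP-based branch and bound (best-bound search, most
#' fractional branching).
#'
#' @inheritParams lp_solve
#' @param bin_idx integer indices of binary variables.
#' @param gap_tol relative optimality gap at which the search stops.
#' @param time_limit wall-clock budget in seconds.
#' @param int_tol integrality tolerance.
#' @return list with `status` (`"optimal"`, `"infeasible"`, or `"time_limit"`
#'   when the budget expired before proving optimality), `x`, `objective`,
#'   and `nodes` (number of branch-and-bound nodes solved).
#' @export
milp_solve <- function(obj, A, rhs, lb, ub, bin_idx, sense = c("min", "max"),
                       gap_tol = 1e-6, time_limit = 45, int_tol = 1e-6) {
  sense <- match.arg(sense)
  cc <- if (sense == "max") -obj else obj
  n <- length(obj)
  stopifnot(all(bin_idx >= 1), all(bin_idx <= n))
  lb <- as.numeric(lb); ub <- as.numeric(ub)
  lb[bin_idx] <- pmax(lb[bin_idx], 0)
  ub[bin_idx] <- pmin(ub[bin_idx], 1)

  t0 <- proc.time()[["elapsed"]]
  inc_x <- NULL
  inc_obj <- Inf
  nodes_solved <- 0L
  timed_out <- FALSE
  # open nodes: list of (lb, ub, bound) kept sorted by parent LP bound
  open <- list(list(lb = lb, ub = ub, bound = -Inf))

  while (length(open) > 0L) {
    if (proc.time()[["elapsed"]] - t0 > time_limit) { timed_out <- TRUE; break }
    bounds <- vapply(open, function(nd) nd$bound, numeric(1))
    pick <- which.min(bounds)
    node <- open[[pick]]
    open[[pick]] <- NULL

    if (node$bound >= inc_obj - 1e-9) next
    # optimality-gap stop
    if (is.finite(inc_obj)) {
      best_bound <- min(node$bound, if (length(open)) min(vapply(open, `[[`, numeric(1), "bound")) else Inf)
      if ((inc_obj - best_bound) <= gap_tol * max(1, abs(inc_obj))) break
    }

    rel <- lp_solve(cc, A, rhs, node$lb, node$ub, "min")
    nodes_solved <- nodes_solved + 1L
    if (rel$status != "optimal") next
    if (rel$objective >= inc_obj - 1e-9) next

    yv <- rel$x[bin_idx]
    frac <- abs(yv - round(yv))
    if (all(frac <= int_tol)) {
      inc_obj <- rel$objective
      inc_x <- rel$x
      inc_x[bin_idx] <- round(yv)
      next
    }
    jb <- bin_idx[which.max(frac)]
    for (val in c(0, 1)) {
      lb2 <- node$lb; ub2 <- node$ub
      lb2[jb] <- val; ub2[jb] <- val
      open[[length(open) + 1L]] <- list(lb = lb2, ub = ub2, bound = rel$objective)
    }
  }

  if (is.null(inc_x)) {
    status <- if (timed_out) "time_limit" else "infeasible"
    return(list(status = status, x = NULL, objective = NA_real_,
                nodes = nodes_solved))
  }
  val <- if (sense == "max") -inc_obj else inc_obj
  list(status = if (timed_out) "time_limit" else "optimal",
       x = inc_x, objective = val, nodes = nodes_solved)
}

#' Solve a convex quadratic program over a bounded polytope
#'
#' Minimizes `0.5 * x' diag(qdiag) x + obj' x` subject to `A x = rhs` and
#' `lb <= x <= ub`, via [quadprog::solve.QP()]. Zero entries of `qdiag` are
#' lifted to a small ridge so the Hessian is positive definite.
#'
#' @inheritParams lp_solve
#' @param qdiag non-negative diagonal of the quadratic term.
#' @param ridge curvature assigned to zero-weight variables.
#' @return list with `status`, `x`, `objective` (the quadratic objective
#'   without the ridge contribution).
#' @export
qp_solve <- function(qdiag, obj, A, rhs, lb, ub, ridge = 1e-8) {
  n <- length(qdiag)
  A <- as.matrix(A)
  d <- pmax(qdiag, ridge)
  Dmat <- diag(d, n)
  dvec <- -obj
  Amat <- cbind(t(A), diag(1, n), -diag(1, n))
  bvec <- c(rhs, lb, -ub)
  res <- tryCatch(
    quadprog::solve.QP(Dmat, dvec, Amat, bvec, meq = nrow(A)),
    error = function(e) e)
  if (inherits(res, "error")) {
    # quadprog signals infeasible / inconsistent constraints via error
    return(list(status = "infeasible", x = NULL, objective = NA_real_,
                message = conditionMessage(res)))
  }
  x <- pmin(pmax(res$solution, lb), ub)
  list(status = "optimal", x = x,
       objective = 0.5 * sum(qdiag * x^2) + sum(obj * x))
}
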