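# Dense two-phase bounded-variable primal simplex.
#
# Solves   min/max  c'x   s.t.  A x = b,  lb <= x <= ub
# with all bounds finite (the package encodes "unbounded" directions as the
# configurable +-1000 proxy, so every LP it poses is a bounded polytope).
# Problem sizes here are tiny (tens of variables), so the basis system is
# re-solved densely at every pivot; Dantzig pricing with a Bland fallback
# guards against cycling.

#' Solve a linear program over a bounded flux polytope
#'
#' Minimizes (or maximizes) `obj' x` subject to `A x = rhs` and
#' `lb <= x <= ub`. All bounds must be finite.
#'
#' @param obj numeric objective vector (length n).
#' @param A dense constraint matrix (m x n); may have zero rows.
#' @param rhs right-hand side vector (length m).
#' @param lb,ub finite variable bounds (length n).
#' @param sense `"min"` or `"max"`.
#' @param tol pivot tolerance.
#' @return A list with `status` (`"optimal"` or `"infeasible"`), `x`
#'   (primal solution, `NULL` when infeasible) and `objective`.
#' @export
lp_solve <- function(obj, A, rhs, lb, ub, sense = c("min", "max"),
                     tol = 1e-9) {
  sense <- match.arg(sense)
  A <- as.matrix(A)
  n <- length(obj)
  m <- nrow(A)
  stopifnot(ncol(A) == n, length(rhs) == m, length(lb) == n, length(ub) == n)
  if (any(!is.finite(lb)) || any(!is.finite(ub)))
    stop("lp_solve requires finite variable bounds")
  if (any(lb > ub + 1e-12))
    return(list(status = "infeasible", x = NULL, objective = NA_real_))
  cc <- if (sense == "max") -obj else obj

  if (m == 0L) {
    # bounds-only problem: each variable sits at the bound favoured by cc
    x <- ifelse(cc >= 0, lb, ub)
    val <- sum(cc * x)
    return(list(status = "optimal", x = x,
                objective = if (sense == "max") -val else val))
  }

  res <- .simplex_bounded(cc, A, rhs, lb, ub, tol)
  if (res$status != "optimal")
    return(list(status = res$status, x = NULL, objective = NA_real_))
  val <- sum(cc * res$x)
  list(status = "optimal", x = res$x,
       objective = if (sense == "max") -val else val)
}

#' Test feasibility of a bounded linear system
#'
#' Phase-1 feasibility check for `A x = rhs`, `lb <= x <= ub`.
#'
#' @inheritParams lp_solve
#' @param feas_tol residual tolerance for declaring feasibility.
#' @return `TRUE`/`FALSE`, with attribute `"x"` holding a feasible point when
#'   one exists.
#' @export
lp_feasible <- function(A, rhs, lb, ub, feas_tol = 1e-7) {
  res <- lp_solve(rep(0, length(lb)), A, rhs, lb, ub)
  ok <- identical(res$status, "optimal")
  out <- ok
  if (ok) attr(out, "x") <- res$x
  out
}

# Two-phase driver. Returns list(status, x).
.simplex_bounded <- function(cc, A, b, lb, ub, tol) {
  n <- length(cc)
  m <- nrow(A)

  # initial nonbasic point: each structural at the bound of least magnitude
  x0 <- ifelse(abs(lb) <= abs(ub), lb, ub)
  at_upper0 <- abs(lb) > abs(ub)
  r <- b - as.vector(A %*% x0)

  # artificials: one per row, signed so the start is feasible for phase 1
  sg <- ifelse(r >= 0, 1, -1)
  Afull <- cbind(A, diag(sg, m))
  big <- max(1, abs(r)) * 2
  lb_f <- c(lb, rep(0, m))
  ub_f <- c(ub, rep(big, m))
  c1 <- c(rep(0, n), rep(1, m))
  basis <- n + seq_len(m)
  at_upper <- c(at_upper0, rep(FALSE, m))

  ph1 <- .simplex_core(c1, Afull, b, lb_f, ub_f, basis, at_upper, tol)
  if (ph1$status != "optimal") return(list(status = "infeasible", x = NULL))
  if (ph1$objective > 1e-7 * max(1, max(abs(b))))
    return(list(status = "infeasible", x = NULL))

  # freeze artificials at zero and optimize the real objective
  ub_f[n + seq_len(m)] <- 0
  lb_f[n + seq_len(m)] <- 0
  c2 <- c(cc, rep(0, m))
  ph2 <- .simplex_core(c2, Afull, b, lb_f, ub_f, ph1$basis, ph1$at_upper, tol)
  if (ph2$status != "optimal") return(list(status = "infeasible", x = NULL))
  x <- ph2$x[seq_len(n)]
  # clamp round-off back into bounds
  x <- pmin(pmax(x, lb), ub)
  list(status = "optimal", x = x)
}

# Core bounded-variable simplex. basis: m indices; at_upper: logical per
# variable (meaningful for nonbasic). Returns status, x, basis, at_upper,
# objective.
.simplex_core <- function(cc, A, b, lb, ub, basis, at_upper, tol) {
  n <- ncol(A)
  m <- nrow(A)
  nonbasic <- setdiff(seq_len(n), basis)
  max_iter <- 200L * (n + m) + 200L
  bland_after <- 20L * (n + m) + 50L

  for (iter in seq_len(max_iter)) {
    B <- A[, basis, drop = FALSE]
    xN <- ifelse(at_upper[nonbasic], ub[nonbasic], lb[nonbasic])
    rhsB <- b - A[, nonbasic, drop = FALSE] %*% xN
    xB <- tryCatch(solve(B, rhsB), error = function(e) NULL)
    if (is.null(xB)) return(list(status = "singular", x = NULL))
    xB <- as.vector(xB)

    y <- as.vector(solve(t(B), cc[basis]))
    dN <- cc[nonbasic] - as.vector(crossprod(A[, nonbasic, drop = FALSE], y))

    up <- at_upper[nonbasic]
    elig_lo <- !up & dN < -tol   # at lower bound, profitable to increase
    elig_hi <- up & dN > tol     # at upper bound, profitable to decrease
    elig <- elig_lo | elig_hi
    if (!any(elig)) {
      x <- numeric(n)
      x[basis] <- xB
      x[nonbasic] <- xN
      return(list(status = "optimal", x = x, basis = basis,
                  at_upper = at_upper, objective = sum(cc * x)))
    }

    if (iter > bland_after) {
      j_pos <- which(elig)[1L]                       # Bland: lowest index
    } else {
      scores <- abs(dN)
      scores[!elig] <- -Inf
      j_pos <- which.max(scores)
    }
    j <- nonbasic[j_pos]
    sigma <- if (at_upper[j]) -1 else 1              # direction of change

    w <- as.vector(solve(B, A[, j]))
    # step limits: basic variables hitting a bound, or the entering variable
    # travelling bound to bound
    ratios <- rep(Inf, m)
    to_upper <- logical(m)
    for (i in seq_len(m)) {
      d <- sigma * w[i]
      if (d > tol) {
        ratios[i] <- (xB[i] - lb[basis[i]]) / d
      } else if (d < -tol) {
        ratios[i] <- (ub[basis[i]] - xB[i]) / (-d)
        to_upper[i] <- TRUE
      }
    }
    ratios[ratios < 0] <- 0                          # degeneracy guard
    span <- ub[j] - lb[j]
    min_ratio <- min(ratios)
    if (span <= min_ratio + 1e-12) {                 # bound-to-bound flip
      t_max <- span
      leave_i <- 0L
      leave_to_upper <- FALSE
    } else {
      t_max <- max(min_ratio, 0)
      hit <- which(ratios <= min_ratio + 1e-12)
      leave_i <- hit[which.min(basis[hit])]          # Bland tie-break
      leave_to_upper <- to_upper[leave_i]
    }

    if (leave_i == 0L) {
      # entering variable travels bound to bound
      at_upper[j] <- !at_upper[j]
    } else {
      out <- basis[leave_i]
      at_upper[out] <- leave_to_upper
      basis[leave_i] <- j
      nonbasic <- setdiff(seq_len(n), basis)
    }
  }
  list(status = "iteration_limit", x = NULL)
}
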