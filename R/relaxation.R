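# Metabolite-node relaxation: decide parsimoniously which unmeasured
# metabolites must deviate from steady state for the closed model to be
# feasible, then fix relaxation magnitudes.
#
# Five formulations are provided, all parsimonious in slightly different
# senses:
#   case 1 (MILP): minimize the number of relaxed nodes (the default; this
#     is also the most conservative on degrees of freedom),
#   case 2 (LP):   minimize the summed magnitude of sink fluxes,
#   case 3 (LP):   case 2 plus the summed magnitude of intracellular fluxes,
#   case 4 (QP):   minimize the summed squared sink fluxes,
#   case 5 (QP):   case 4 plus the summed squared intracellular fluxes.
# Cases 1-3 are re-solved under integer cuts to enumerate alternative
# optima; the per-iteration supports are tallied and a final
# frequency-weighted optimization picks the retained node set. Cases 4-5
# are strictly convex in the sink fluxes and give a single support.

#' Add relaxation sinks for every unmeasured metabolite
#'
#' Installs, for each metabolite without an accumulation reaction, an "up"
#' sink (`{met: -1}`, flux >= 0 = accumulation out of the network) and a
#' "down" sink (`{met: +1}`, flux >= 0 = depletion of a pool into the
#' network). Measured-significant metabolites receive no sinks.
#'
#' @param model an `unsteady_model` from [build_ufba_model()] or
#'   [build_fba_control()].
#' @param case relaxation formulation, 1-5 (see module description).
#' @param iterations number of integer-cut re-solves used to tally
#'   alternative optima (the study default is 100).
#' @param gap_tol relative MILP gap tolerance per iteration.
#' @param time_limit per-iteration time limit in seconds.
#' @param exo_preference preferentially relax extracellular nodes in the
#'   final weighted optimization.
#' @param big_m indicator coupling constant; defaults to the global
#'   flux-bound proxy.
#' @return a `relaxation_problem`.
#' @export
add_relaxation_sinks <- function(model, case = 1, iterations = 100,
                                 gap_tol = 1e-6, time_limit = 45,
                                 exo_preference = FALSE,
                                 big_m = DEFAULT_BOUND) {
  stopifnot(inherits(model, "unsteady_model"))
  if (!case %in% 1:5) stop("case must be in 1..5")
  unmeasured <- setdiff(model$metabolites$id, model$measured)
  up <- character(); down <- character()
  for (met in unmeasured) {
    uid <- paste0(SINK_UP_PREFIX, met)
    did <- paste0(SINK_DOWN_PREFIX, met)
    model <- add_reaction(model, uid, stats::setNames(-1, met), 0, big_m,
                          name = paste("up sink (accumulation) for", met))
    model <- add_reaction(model, did, stats::setNames(+1, met), 0, big_m,
                          name = paste("down sink (depletion) for", met))
    up[met] <- uid; down[met] <- did
  }
  model$relaxation_sinks <- list(up = up, down = down)
  n_intracellular <- sum(!model$reactions$id %in%
                           c(up, down, unname(model$accumulation)))
  structure(list(model = model,
                 unmeasured = unmeasured,
                 up = up, down = down,
                 m = length(unmeasured),
                 n = n_intracellular,
                 case = case,
                 iterations = iterations,
                 gap_tol = gap_tol,
                 time_limit = time_limit,
                 exo_preference = exo_preference,
                 big_m = big_m),
            class = "relaxation_problem")
}

# Shared constraint-system builder. Variables are laid out as
#   [fluxes (incl. sinks) | y (binaries, m) | coupling slacks | extras]
# with equality rows: S v = 0, then u_j + w_j - M y_j + s_j = 0 per node,
# optionally u_j + w_j - eps y_j - t_j = 0 (forces y_j = 1 iff the node
# carries flux; used when cuts must exclude LP/QP supports), then any
# integer-cut rows.
.relax_system <- function(problem, force_support = FALSE, cuts = list()) {
  lpv <- model_lp(problem$model)
  n_flux <- length(lpv$rxns)
  m <- problem$m
  M <- problem$big_m
  eps_y <- 1e-6

  up_idx <- match(problem$up, lpv$rxns)
  dn_idx <- match(problem$down, lpv$rxns)

  n_slack <- m
  n_extra <- if (force_support) m else 0L
  n_cut <- length(cuts)
  n_var <- n_flux + m + n_slack + n_extra + n_cut
  y_idx <- n_flux + seq_len(m)
  s_idx <- n_flux + m + seq_len(m)
  t_idx <- if (force_support) n_flux + 2L * m + seq_len(m) else integer()
  cut_slack_idx <- n_flux + 2L * m + n_extra + seq_len(n_cut)

  n_met <- length(lpv$mets)
  n_row <- n_met + m + n_extra + n_cut
  A <- matrix(0, n_row, n_var)
  A[seq_len(n_met), seq_len(n_flux)] <- lpv$S
  rhs <- numeric(n_row)

  for (j in seq_len(m)) {
    r <- n_met + j
    A[r, up_idx[j]] <- 1
    A[r, dn_idx[j]] <- 1
    A[r, y_idx[j]] <- -M
    A[r, s_idx[j]] <- 1
  }
  if (force_support) {
    for (j in seq_len(m)) {
      r <- n_met + m + j
      A[r, up_idx[j]] <- 1
      A[r, dn_idx[j]] <- 1
      A[r, y_idx[j]] <- -eps_y
      A[r, t_idx[j]] <- -1
    }
  }
  for (k in seq_along(cuts)) {
    r <- n_met + m + n_extra + k
    sel <- cuts[[k]]              # logical length m: support to exclude
    A[r, y_idx] <- ifelse(sel, 1, -1)
    A[r, cut_slack_idx[k]] <- 1
    rhs[r] <- sum(sel) - 1
  }

  lb <- c(lpv$lb, rep(0, m), rep(0, n_slack),
          rep(0, n_extra), rep(0, n_cut))
  ub <- c(lpv$ub, rep(1, m), rep(2 * M, n_slack),
          rep(2 * M, n_extra), rep(m + 1, n_cut))

  list(A = A, rhs = rhs, lb = lb, ub = ub,
       n_flux = n_flux, y_idx = y_idx,
       up_idx = up_idx, dn_idx = dn_idx, n_var = n_var)
}

# objective over the flux variables for cases 2/3 (|d|, optionally + |v|).
# |v| terms add auxiliary variables t_i >= |v_i| via two inequality rows
# each; returns an augmented system.
.relax_flux_objective <- function(problem, sys) {
  cc <- numeric(sys$n_var)
  cc[sys$up_idx] <- 1
  cc[sys$dn_idx] <- 1
  if (problem$case %in% c(3, 5)) {
    internal <- setdiff(seq_len(sys$n_flux), c(sys$up_idx, sys$dn_idx,
                                               match(problem$model$accumulation,
                                                     problem$model$reactions$id)))
  } else internal <- integer()
  list(cc = cc, internal = internal)
}

#' Solve the relaxation problem, tallying alternative optima
#'
#' Runs the configured formulation repeatedly under integer cuts that
#' exclude previously found supports, up to `iterations` times, stopping
#' early when the cut-augmented problem becomes infeasible or the objective
#' degrades beyond the first optimum. Cases 4-5 (strictly convex QP in the
#' sink fluxes) return a single support.
#'
#' @param problem a `relaxation_problem` from [add_relaxation_sinks()].
#' @return a `relaxation_result` with per-iteration supports, tallies and
#'   objective values (pre-finalization).
#' @export
solve_relaxation <- function(problem) {
  stopifnot(inherits(problem, "relaxation_problem"))
  # base feasibility with all sinks open: if even this fails, the measured
  # rates contradict the stoichiometry
  lpv <- model_lp(problem$model)
  if (!lp_feasible(lpv$S, rep(0, length(lpv$mets)), lpv$lb, lpv$ub))
    stop("data inconsistent with stoichiometry: model infeasible even with all relaxation sinks open")
  if (problem$m == 0L) {
    return(structure(list(iterations = list(), tally = numeric(),
                          n_iterations = 0L, case = problem$case,
                          objectives = numeric()),
                     class = "relaxation_result"))
  }

  if (problem$case %in% c(4, 5)) {
    sol <- .relax_qp(problem)
    tally <- stats::setNames(as.numeric(sol$relaxed), problem$unmeasured)
    return(structure(list(iterations = list(sol), tally = tally,
                          n_iterations = 1L, case = problem$case,
                          objectives = sol$objective),
                     class = "relaxation_result"))
  }

  force_support <- problem$case %in% c(2, 3)
  cuts <- list()
  iters <- list()
  objectives <- numeric()
  obj0 <- NULL

  for (it in seq_len(problem$iterations)) {
    sys <- .relax_system(problem, force_support = force_support, cuts = cuts)
    if (problem$case == 1) {
      cc <- numeric(sys$n_var)
      cc[sys$y_idx] <- 1
    } else {
      fo <- .relax_flux_objective(problem, sys)
      cc <- fo$cc
      if (length(fo$internal) > 0) {
        aug <- .augment_abs(sys, fo$internal)
        sys <- aug$sys
        cc <- c(cc, numeric(sys$n_var - length(cc)))
        cc[aug$t_idx] <- 1
      }
    }
    res <- milp_solve(cc, sys$A, sys$rhs, sys$lb, sys$ub, sys$y_idx,
                      gap_tol = problem$gap_tol,
                      time_limit = problem$time_limit)
    if (res$status != "optimal") break
    if (is.null(obj0)) obj0 <- res$objective
    tol_deg <- if (problem$case == 1) 0.5 else
      1e-6 * max(1, abs(obj0)) + 1e-9
    if (res$objective > obj0 + tol_deg) break

    ysel <- res$x[sys$y_idx] > 0.5
    dup <- res$x[sys$up_idx]
    ddn <- res$x[sys$dn_idx]
    support <- problem$unmeasured[ysel]
    dirs <- ifelse(dup[ysel] > 1e-9 & ddn[ysel] > 1e-9, "both",
                   ifelse(dup[ysel] > 1e-9, "up", "down"))
    iters[[length(iters) + 1L]] <- list(
      support = support,
      directions = stats::setNames(dirs, support),
      d_up = stats::setNames(dup[ysel], support),
      d_down = stats::setNames(ddn[ysel], support),
      objective = res$objective,
      relaxed = ysel)
    objectives <- c(objectives, res$objective)
    cuts[[length(cuts) + 1L]] <- ysel
  }

  if (length(iters) == 0L)
    stop("relaxation found no feasible support (solver fault)")
  tally <- Reduce(`+`, lapply(iters, function(x) as.numeric(x$relaxed)))
  tally <- stats::setNames(tally, problem$unmeasured)
  structure(list(iterations = iters, tally = tally,
                 n_iterations = length(iters), case = problem$case,
                 objectives = objectives),
            class = "relaxation_result")
}

# QP cases: minimize sum d^2 (+ sum v^2 for case 5) over S v = 0 and bounds
.relax_qp <- function(problem) {
  lpv <- model_lp(problem$model)
  n <- length(lpv$rxns)
  up_idx <- match(problem$up, lpv$rxns)
  dn_idx <- match(problem$down, lpv$rxns)
  qdiag <- numeric(n)
  qdiag[c(up_idx, dn_idx)] <- 1
  if (problem$case == 5) {
    internal <- setdiff(seq_len(n),
                        c(up_idx, dn_idx,
                          match(problem$model$accumulation, lpv$rxns)))
    qdiag[internal] <- 1
  }
  res <- qp_solve(qdiag, numeric(n), lpv$S, rep(0, length(lpv$mets)),
                  lpv$lb, lpv$ub)
  if (res$status != "optimal")
    stop("QP relaxation failed (case ", problem$case, "): ", res$message)
  dup <- res$x[up_idx]; ddn <- res$x[dn_idx]
  relaxed <- (dup + ddn) > 1e-9
  support <- problem$unmeasured[relaxed]
  dirs <- ifelse(dup[relaxed] > 1e-9 & ddn[relaxed] > 1e-9, "both",
                 ifelse(dup[relaxed] > 1e-9, "up", "down"))
  list(support = support,
       directions = stats::setNames(dirs, support),
       d_up = stats::setNames(dup[relaxed], support),
       d_down = stats::setNames(ddn[relaxed], support),
       objective = res$objective, relaxed = relaxed)
}

# add auxiliary t_i >= |v_i| rows/vars for flux-magnitude objectives
.augment_abs <- function(sys, internal) {
  n_int <- length(internal)
  n_old <- ncol(sys$A)
  # new vars: t_i, then 2 slack per row pair
  n_new <- n_int * 3L
  A <- cbind(sys$A, matrix(0, nrow(sys$A), n_new))
  A2 <- matrix(0, 2L * n_int, ncol(A))
  t_idx <- n_old + seq_len(n_int)
  sl1 <- n_old + n_int + seq_len(n_int)
  sl2 <- n_old + 2L * n_int + seq_len(n_int)
  for (i in seq_len(n_int)) {
    #  v_i - t_i + s1 = 0  (t >= v)
    A2[2L * i - 1L, internal[i]] <- 1
    A2[2L * i - 1L, t_idx[i]] <- -1
    A2[2L * i - 1L, sl1[i]] <- 1
    # -v_i - t_i + s2 = 0  (t >= -v)
    A2[2L * i, internal[i]] <- -1
    A2[2L * i, t_idx[i]] <- -1
    A2[2L * i, sl2[i]] <- 1
  }
  sys$A <- rbind(A, A2)
  sys$rhs <- c(sys$rhs, numeric(2L * n_int))
  big <- 4 * DEFAULT_BOUND
  sys$lb <- c(sys$lb, rep(0, n_new))
  sys$ub <- c(sys$ub, rep(c(DEFAULT_BOUND, big, big), each = n_int))
  sys$n_var <- ncol(sys$A)
  list(sys = sys, t_idx = t_idx)
}

#' Finalize the relaxation: frequency-weighted node selection
#'
#' Runs one last node-selection optimization with per-node cost
#' `c_j = 1 - f_j + eps` where `f_j` is the tally frequency of node `j`
#' across iterations (`eps = 1e-3`, so zero-frequency nodes still carry
#' positive cost and cardinality dominates). With `exo_preference`,
#' extracellular node costs are additionally halved. The selected nodes'
#' sinks are retained; all other sinks are deleted from the model.
#'
#' @param problem a `relaxation_problem`.
#' @param result a `relaxation_result` from [solve_relaxation()].
#' @param eps cost floor added to every node.
#' @return the `relaxation_result` augmented with `final_set` (named
#'   direction vector), `final_d_up`/`final_d_down`, and `model` (sinks
#'   pruned to the final set).
#' @export
finalize_relaxation <- function(problem, result, eps = 1e-3) {
  stopifnot(inherits(problem, "relaxation_problem"),
            inherits(result, "relaxation_result"))
  if (problem$m == 0L || result$n_iterations == 0L) {
    result$final_set <- stats::setNames(character(), character())
    result$model <- problem$model
    return(result)
  }
  f <- result$tally / result$n_iterations
  cost <- 1 - f + eps
  if (problem$exo_preference) {
    exo <- is_extracellular(problem$model, problem$unmeasured)
    cost[exo] <- cost[exo] * 0.5
  }
  sys <- .relax_system(problem, force_support = TRUE)
  cc <- numeric(sys$n_var)
  cc[sys$y_idx] <- cost
  res <- milp_solve(cc, sys$A, sys$rhs, sys$lb, sys$ub, sys$y_idx,
                    gap_tol = problem$gap_tol,
                    time_limit = problem$time_limit)
  if (res$status != "optimal")
    stop("final relaxation optimization infeasible (solver-tolerance fault)")
  ysel <- res$x[sys$y_idx] > 0.5
  support <- problem$unmeasured[ysel]

  # prune sinks: keep only the final nodes' sinks (both directions)
  drop_mets <- setdiff(problem$unmeasured, support)
  model <- remove_reactions(problem$model,
                            c(problem$up[drop_mets], problem$down[drop_mets]))
  model$relaxation_sinks <- list(up = problem$up[support],
                                 down = problem$down[support])

  # directions from the sink-flux-minimizing point (the MILP vertex may
  # carry futile up+down circulation)
  if (length(support) > 0) {
    lpv <- model_lp(model)
    cc <- as.numeric(lpv$rxns %in% c(problem$up[support], problem$down[support]))
    minp <- lp_solve(cc, lpv$S, rep(0, length(lpv$mets)), lpv$lb, lpv$ub, "min")
    if (minp$status != "optimal")
      stop("final relaxation set infeasible (solver-tolerance fault)")
    dup <- minp$x[match(problem$up[support], lpv$rxns)]
    ddn <- minp$x[match(problem$down[support], lpv$rxns)]
  } else dup <- ddn <- numeric()
  dirs <- ifelse(dup > 1e-9 & ddn > 1e-9, "both",
                 ifelse(dup > 1e-9, "up", "down"))
  result$final_set <- stats::setNames(dirs, support)
  result$final_d_up <- stats::setNames(dup, support)
  result$final_d_down <- stats::setNames(ddn, support)
  result$model <- model
  result
}

#' Fix relaxation magnitudes by sink-flux minimization
#'
#' Minimizes the total flux through the retained sink reactions subject to
#' all model constraints, then caps each retained sink at `scale` times its
#' minimized flux (`[0, scale * d*]`). A scale of 1 leaves the model
#' feasible but maximally tight; the study default 1.5 avoids
#' over-constraining.
#'
#' @param model an `unsteady_model` whose `relaxation_sinks` are the
#'   retained final set (from [finalize_relaxation()]).
#' @param scale multiplier >= 1 applied to each minimized sink flux.
#' @return the model with scaled sink bounds; feasibility is re-asserted.
#' @export
fix_relaxation_magnitudes <- function(model, scale = 1.5) {
  stopifnot(inherits(model, "unsteady_model"))
  if (scale < 1) stop("scale must be >= 1")
  sinks <- c(model$relaxation_sinks$up, model$relaxation_sinks$down)
  if (length(sinks) == 0L) return(model)
  lpv <- model_lp(model)
  cc <- as.numeric(lpv$rxns %in% sinks)
  res <- lp_solve(cc, lpv$S, rep(0, length(lpv$mets)), lpv$lb, lpv$ub, "min")
  if (res$status != "optimal")
    stop("sink-minimization LP infeasible; relaxation set inconsistent")
  for (rid in sinks) {
    dstar <- res$x[match(rid, lpv$rxns)]
    if (dstar < 1e-9) dstar <- 0
    model <- set_bounds(model, rid, 0, scale * dstar)
  }
  lpv2 <- model_lp(model)
  if (!lp_feasible(lpv2$S, rep(0, length(lpv2$mets)), lpv2$lb, lpv2$ub))
    stop("model infeasible after scaling sink bounds (numerical fault)")
  model
}

#' Run the full relaxation pipeline
#'
#' Convenience wrapper: [add_relaxation_sinks()] then [solve_relaxation()],
#' [finalize_relaxation()] and [fix_relaxation_magnitudes()].
#'
#' @inheritParams add_relaxation_sinks
#' @param scale sink-bound scaling (default 1.5).
#' @return list with `model` (relaxed, scaled, ready for analysis) and
#'   `result` (the `relaxation_result`).
#' @export
relax_model <- function(model, case = 1, iterations = 100, gap_tol = 1e-6,
                        time_limit = 45, exo_preference = FALSE,
                        scale = 1.5, big_m = DEFAULT_BOUND) {
  problem <- add_relaxation_sinks(model, case = case, iterations = iterations,
                                  gap_tol = gap_tol, time_limit = time_limit,
                                  exo_preference = exo_preference,
                                  big_m = big_m)
  result <- solve_relaxation(problem)
  result <- finalize_relaxation(problem, result)
  relaxed <- fix_relaxation_magnitudes(result$model, scale = scale)
  list(model = relaxed, result = result)
}
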