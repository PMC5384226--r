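# Synthetic fixtures: named toy metabolic networks with known flux states,
# ground-truth time-course simulation, and random networks for
# oracle-equivalence testing. Concentration dynamics are piecewise linear by
# construction, C(t) = C0 + (S v_state) (t - t_start) accumulated over
# states, matching the workflow's own linearization assumption; replicate
# noise is multiplicative Gaussian (SD proportional to concentration),
# reflecting metabolomics error structure.

#' Construct a named toy metabolic network
#'
#' Topologies:
#' \describe{
#'   \item{chain}{linear pathway M1 -> ... -> M(k+1) with exchanges at both
#'     ends; `size` = number of internal reactions.}
#'   \item{branched}{uptake, a split into two parallel routes, a merge and
#'     secretion — one interior degree of freedom.}
#'   \item{pool_depletion}{a large intracellular pool (M_c) feeding secreted
#'     products through a reversible dehydrogenase-like reaction (MDH) —
#'     the motif where steady-state FBA predicts the reverse flux direction
#'     of the pool-informed model. Includes an independently measured
#'     calibration path (T_D) and an unmeasured secreted product (L_e).}
#'   \item{cofactor_rescue}{gene-labelled biosynthesis and growth
#'     consumption of a cofactor whose stored pool can rescue a
#'     biosynthesis knockout when its depletion is measured.}
#'   \item{twin_pathway}{two symmetric routes between a depleting source
#'     and an accumulating product — the alternative-optima motif.}
#' }
#'
#' @param kind one of `"chain"`, `"branched"`, `"pool_depletion"`,
#'   `"cofactor_rescue"`, `"twin_pathway"`.
#' @param size chain length (chain only; 2..20).
#' @return a `stoichiometric_model`.
#' @export
make_toy_network <- function(kind = c("chain", "branched", "pool_depletion",
                                      "cofactor_rescue", "twin_pathway"),
                             size = 3) {
  kind <- tryCatch(match.arg(kind),
                   error = function(e) stop("unknown toy network kind: ",
                                            kind[1]))
  switch(kind,
         chain = .toy_chain(size),
         branched = .toy_branched(),
         pool_depletion = .toy_pool_depletion(),
         cofactor_rescue = .toy_cofactor_rescue(),
         twin_pathway = .toy_twin_pathway())
}

.toy_chain <- function(size) {
  stopifnot(size >= 2, size <= 20)
  m <- new_model("chain")
  ids <- paste0("M", seq_len(size + 1))
  comp <- c("e", rep("c", size - 1), "e")
  for (i in seq_along(ids)) m <- add_metabolite(m, ids[i], compartment = comp[i])
  for (i in seq_len(size))
    m <- add_reaction(m, paste0("R", i),
                      stats::setNames(c(-1, 1), ids[c(i, i + 1)]), 0, DEFAULT_BOUND)
  m <- add_reaction(m, paste0("EX_", ids[1]), stats::setNames(-1, ids[1]),
                    -DEFAULT_BOUND, DEFAULT_BOUND)
  m <- add_reaction(m, paste0("EX_", ids[size + 1]),
                    stats::setNames(-1, ids[size + 1]),
                    -DEFAULT_BOUND, DEFAULT_BOUND)
  m
}

.toy_branched <- function() {
  m <- new_model("branched")
  for (sp in list(c("A_e", "e"), c("A_c", "c"), c("B_c", "c"), c("C_c", "c"),
                  c("D_c", "c"), c("E_c", "c"), c("F_e", "e")))
    m <- add_metabolite(m, sp[1], compartment = sp[2])
  rx <- list(T_in = c(A_e = -1, A_c = 1), R_AB = c(A_c = -1, B_c = 1),
             R_BC = c(B_c = -1, C_c = 1), R_BD = c(B_c = -1, D_c = 1),
             R_CE = c(C_c = -1, E_c = 1), R_DE = c(D_c = -1, E_c = 1),
             T_out = c(E_c = -1, F_e = 1))
  for (id in names(rx)) m <- add_reaction(m, id, rx[[id]], 0, DEFAULT_BOUND)
  m <- add_reaction(m, "EX_A_e", c(A_e = -1), -DEFAULT_BOUND, DEFAULT_BOUND)
  m <- add_reaction(m, "EX_F_e", c(F_e = -1), -DEFAULT_BOUND, DEFAULT_BOUND)
  m
}

.toy_pool_depletion <- function() {
  m <- new_model("pool_depletion")
  mets <- list(c("C_e", "e"), c("O_c", "c"), c("M_c", "c"), c("M_e", "e"),
               c("A_c", "c"), c("G_e", "e"), c("L_c", "c"), c("L_e", "e"),
               c("D_e", "e"), c("W_e", "e"))
  for (sp in mets) m <- add_metabolite(m, sp[1], compartment = sp[2])
  m <- add_reaction(m, "T_C", c(C_e = -1, O_c = 1), 0, DEFAULT_BOUND)
  m <- add_reaction(m, "MDH", c(O_c = -1, M_c = 1), -DEFAULT_BOUND, DEFAULT_BOUND)
  m <- add_reaction(m, "T_M", c(M_c = -1, M_e = 1), 0, DEFAULT_BOUND)
  m <- add_reaction(m, "R_OL", c(O_c = -1, L_c = 1), 0, DEFAULT_BOUND)
  m <- add_reaction(m, "T_L", c(L_c = -1, L_e = 1), 0, DEFAULT_BOUND)
  m <- add_reaction(m, "R_OA", c(O_c = -1, A_c = 1), 0, DEFAULT_BOUND)
  m <- add_reaction(m, "R_AG", c(A_c = -1, G_e = 1), 0, DEFAULT_BOUND)
  m <- add_reaction(m, "T_D", c(D_e = -1, W_e = 1), 0, DEFAULT_BOUND)
  # additional independently measured calibration paths; their flux values
  # sit between the free means and corner values of the main pathway fluxes
  # so constraint-tightness changes are visible in rank statistics
  for (i in 2:4) {
    di <- paste0("D", i, "_e"); wi <- paste0("W", i, "_e")
    m <- add_metabolite(m, di, compartment = "e")
    m <- add_metabolite(m, wi, compartment = "e")
    m <- add_reaction(m, paste0("T_D", i),
                      stats::setNames(c(-1, 1), c(di, wi)), 0, DEFAULT_BOUND)
  }
  for (met in c("C_e", "M_e", "G_e", "L_e", "D_e", "W_e",
                "D2_e", "W2_e", "D3_e", "W3_e", "D4_e", "W4_e"))
    m <- add_reaction(m, paste0("EX_", met), stats::setNames(-1, met),
                      -DEFAULT_BOUND, DEFAULT_BOUND)
  m
}

.toy_cofactor_rescue <- function() {
  m <- new_model("cofactor_rescue")
  m <- add_metabolite(m, "S_e", compartment = "e")
  m <- add_metabolite(m, "P_c", compartment = "c")
  m <- add_metabolite(m, "N_c", compartment = "c")
  m <- add_reaction(m, "T_S", c(S_e = -1, P_c = 1), 0, DEFAULT_BOUND,
                    gene_rule = "gT1 or gT2")
  m <- add_reaction(m, "BIOSYN", c(P_c = -1, N_c = 1), 0, DEFAULT_BOUND,
                    gene_rule = "gB")
  m <- add_reaction(m, "GROWTH", c(P_c = -1, N_c = -0.1), 0, DEFAULT_BOUND,
                    objective_coefficient = 1)
  m <- add_reaction(m, "EX_S_e", c(S_e = -1), -DEFAULT_BOUND, 0)
  m
}

.toy_twin_pathway <- function() {
  m <- new_model("twin_pathway")
  for (sp in list(c("A_c", "c"), c("X1_c", "c"), c("X2_c", "c"), c("B_c", "c")))
    m <- add_metabolite(m, sp[1], compartment = sp[2])
  m <- add_reaction(m, "R_A1", c(A_c = -1, X1_c = 1), 0, DEFAULT_BOUND)
  m <- add_reaction(m, "R_A2", c(A_c = -1, X2_c = 1), 0, DEFAULT_BOUND)
  m <- add_reaction(m, "R_1B", c(X1_c = -1, B_c = 1), 0, DEFAULT_BOUND)
  m <- add_reaction(m, "R_2B", c(X2_c = -1, B_c = 1), 0, DEFAULT_BOUND)
  m
}

#' Construct a synthetic scenario with ground-truth flux states
#'
#' Bundles a toy network with its study conditions: per-state true internal
#' flux vectors (exchanges carry zero flux — the system is a closed bag),
#' the set of metabolites the assay measures, state boundaries and noise
#' parameters. The per-kind measured sets and flux values are the fixture's
#' defining conditions, not tuning knobs.
#'
#' @inheritParams make_toy_network
#' @param n_states number of metabolic states simulated (1 or 2).
#' @param replicates replicate count (default 5).
#' @param n_points time points per state (default 10).
#' @param noise_sd relative (multiplicative) Gaussian noise SD (default
#'   0.05).
#' @param missing_fraction fraction of measurements masked missing.
#' @param measured override of the measured metabolite set.
#' @param state_duration hours per state (default 10).
#' @param seed RNG seed.
#' @return a `synthetic_scenario`.
#' @export
make_scenario <- function(kind, n_states = 1, replicates = 5, n_points = 10,
                          noise_sd = 0.05, missing_fraction = 0,
                          measured = NULL, state_duration = 10, seed = 1) {
  model <- make_toy_network(kind)
  truth <- .scenario_truth(kind, model, n_states)
  if (is.null(measured)) measured <- truth$measured
  stopifnot(noise_sd >= 0, missing_fraction >= 0, missing_fraction < 1)
  structure(list(kind = kind, model = model,
                 v_states = truth$v_states,
                 measured = measured,
                 unsteady_unmeasured = truth$unsteady_unmeasured,
                 ci_halfwidth = truth$ci_halfwidth,
                 n_states = n_states, replicates = replicates,
                 n_points = n_points, noise_sd = noise_sd,
                 missing_fraction = missing_fraction,
                 state_duration = state_duration, seed = seed),
            class = "synthetic_scenario")
}

# per-kind true internal flux vectors and study measured sets
.scenario_truth <- function(kind, model, n_states) {
  rxns <- model$reactions$id
  zero <- stats::setNames(numeric(length(rxns)), rxns)
  v_of <- function(...) { v <- zero; vals <- c(...); v[names(vals)] <- vals; v }
  if (kind == "chain") {
    n_int <- sum(!startsWith(rxns, "EX_"))
    v1 <- v_of(stats::setNames(rep(2, n_int), paste0("R", seq_len(n_int))))
    v2 <- v_of(stats::setNames(rep(0.5, n_int), paste0("R", seq_len(n_int))))
    mets <- model$metabolites$id
    list(v_states = if (n_states == 1) list(v1) else list(v1, v2),
         measured = mets[is_extracellular(model, mets)],
         ci_halfwidth = NULL,
         unsteady_unmeasured = character())
  } else if (kind == "branched") {
    v1 <- v_of(c(T_in = 2, R_AB = 2, R_BC = 1.2, R_BD = 0.8, R_CE = 1.2,
                 R_DE = 0.8, T_out = 2))
    v2 <- v_of(c(T_in = 0.5, R_AB = 0.5, R_BC = 0.3, R_BD = 0.2, R_CE = 0.3,
                 R_DE = 0.2, T_out = 0.5))
    list(v_states = if (n_states == 1) list(v1) else list(v1, v2),
         measured = c("A_e", "F_e"),
         ci_halfwidth = c(A_e = 0.05, F_e = 0.05),
         unsteady_unmeasured = character())
  } else if (kind == "pool_depletion") {
    calib <- c(T_D = 1.95, T_D2 = 1.02, T_D3 = 0.52, T_D4 = 5.35)
    v1 <- v_of(c(T_C = 2, MDH = -4, T_M = 1, R_OL = 5.5, T_L = 5.5,
                 R_OA = 0.5, R_AG = 0.5), calib)
    # state 2: pool exhausted, forward dehydrogenase flux
    v2 <- v_of(c(T_C = 2, MDH = 1, T_M = 1, R_OL = 0.5, T_L = 0.5,
                 R_OA = 0.5, R_AG = 0.5), calib)
    calib_mets <- c("D_e", "W_e", "D2_e", "W2_e", "D3_e", "W3_e",
                    "D4_e", "W4_e")
    list(v_states = if (n_states == 1) list(v1) else list(v1, v2),
         measured = c("C_e", "M_c", "M_e", "G_e", calib_mets),
         ci_halfwidth = c(stats::setNames(rep(0.1, 4),
                                          c("C_e", "M_c", "M_e", "G_e")),
                          stats::setNames(rep(0.01, length(calib_mets)),
                                          calib_mets)),
         unsteady_unmeasured = c(L_e = "up"))
  } else if (kind == "cofactor_rescue") {
    # growth consumes the precursor and the cofactor; the cofactor pool
    # depletes at 0.5 while biosynthesis covers the rest
    vg <- (10 + 0.5) / 1.1
    v1 <- v_of(c(T_S = 10, GROWTH = vg, BIOSYN = 0.1 * vg - 0.5))
    list(v_states = list(v1),
         measured = c("S_e", "N_c"),
         ci_halfwidth = c(S_e = 0.2, N_c = 0.02),
         unsteady_unmeasured = character())
  } else if (kind == "twin_pathway") {
    # source drains at 2, product gains 1: one twin intermediate must
    # accumulate — two symmetric minimal relaxations
    v1 <- v_of(c(R_A1 = 1, R_A2 = 1, R_1B = 1, R_2B = 0))
    list(v_states = list(v1),
         measured = c("A_c", "B_c"),
         ci_halfwidth = c(A_c = 0.05, B_c = 0.05),
         unsteady_unmeasured = c(X2_c = "up"))
  } else stop("unknown kind")
}

#' Nominal rate table of a scenario
#'
#' The fixture's defining rate intervals: true rates of change `S v` for
#' the measured metabolites of a state, with the per-metabolite nominal
#' confidence half-widths the scenario declares. Used for analyses that
#' isolate a model-construction parameter (e.g. sink-bound scaling) from
#' regression noise.
#'
#' @param scenario a `synthetic_scenario`.
#' @param state state index.
#' @return data.frame in the format of [estimate_rates()].
#' @export
true_rates <- function(scenario, state = 1) {
  S <- s_matrix(scenario$model)
  v <- scenario$v_states[[state]]
  b <- as.vector(S %*% v[colnames(S)])
  names(b) <- rownames(S)
  hw <- scenario$ci_halfwidth
  if (is.null(hw)) hw <- stats::setNames(rep(0.05, length(scenario$measured)),
                                         scenario$measured)
  comp <- stats::setNames(scenario$model$metabolites$compartment,
                          scenario$model$metabolites$id)
  mets <- scenario$measured
  data.frame(metabolite_id = mets, compartment = comp[mets],
             state = state, slope = b[mets],
             b1 = b[mets] - hw[mets], b2 = b[mets] + hw[mets],
             significant = abs(b[mets]) > hw[mets],
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Simulate a ground-truth time course from a scenario
#'
#' Noiseless trajectories follow the piecewise-linear invariant
#' `C(t) = C0 + (S v_state)(t - t_start)` accumulated over states; then
#' multiplicative Gaussian replicate noise, then missingness, then the
#' measured-metabolite mask. Initial concentrations are chosen high enough
#' that no trajectory goes negative.
#'
#' @param scenario a `synthetic_scenario`.
#' @return list with `data` (a `timecourse_dataset` over measured
#'   metabolites), `truth_rates` (metabolite x state matrix of true rates
#'   `S v`), `windows` (true state windows), `times`, and the scenario.
#' @export
simulate_timecourse <- function(scenario) {
  stopifnot(inherits(scenario, "synthetic_scenario"))
  if (scenario$noise_sd < 0) stop("noise SD must be >= 0")
  model <- scenario$model
  S <- s_matrix(model)
  rates <- vapply(scenario$v_states, function(v)
    as.vector(S %*% v[colnames(S)]), numeric(nrow(S)))
  rownames(rates) <- rownames(S)

  n_states <- length(scenario$v_states)
  dur <- scenario$state_duration
  times_by_state <- lapply(seq_len(n_states), function(s)
    seq((s - 1) * dur, s * dur, length.out = scenario$n_points + (s > 1)))
  # drop duplicated boundary point from later states
  if (n_states > 1)
    for (s in 2:n_states)
      times_by_state[[s]] <- times_by_state[[s]][-1]

  all_times <- unlist(times_by_state)
  conc0_need <- numeric(nrow(S))
  traj <- matrix(0, nrow(S), length(all_times),
                 dimnames = list(rownames(S), NULL))
  tix <- 0L
  base <- numeric(nrow(S))
  t_prev <- 0
  for (s in seq_len(n_states)) {
    for (tt in times_by_state[[s]]) {
      tix <- tix + 1L
      traj[, tix] <- base + rates[, s] * (tt - t_prev)
    }
    base <- base + rates[, s] * dur
    t_prev <- t_prev + dur
  }
  C0 <- pmax(5, -apply(traj, 1, min) + 5)
  traj <- traj + C0

  set.seed(scenario$seed)
  rows <- list()
  comp <- stats::setNames(model$metabolites$compartment, model$metabolites$id)
  for (met in scenario$measured) {
    for (r in seq_len(scenario$replicates)) {
      noise <- stats::rnorm(length(all_times), 0, scenario$noise_sd)
      conc <- traj[met, ] * (1 + noise)
      rows[[length(rows) + 1L]] <- data.frame(
        metabolite_id = met, compartment = comp[[met]],
        time = all_times, replicate = r, concentration = conc,
        missing = FALSE, stringsAsFactors = FALSE)
    }
  }
  d <- do.call(rbind, rows)
  if (scenario$missing_fraction > 0) {
    nmiss <- floor(nrow(d) * scenario$missing_fraction)
    idx <- sample.int(nrow(d), nmiss)
    d$missing[idx] <- TRUE
    d$concentration[idx] <- NA_real_
    # keep at least one observation per metabolite
    for (met in unique(d$metabolite_id)) {
      sel <- d$metabolite_id == met
      if (all(d$missing[sel])) {
        first <- which(sel)[1L]
        d$missing[first] <- FALSE
        d$concentration[first] <- traj[met, 1L]
      }
    }
  }
  windows <- lapply(seq_len(n_states), function(s)
    .state_window(s, times_by_state[[s]]))
  list(data = timecourse_dataset(d),
       truth_rates = rates,
       windows = windows,
       times = all_times,
       scenario = scenario)
}

#' Random toy network + measurements for oracle testing
#'
#' Generates a random acyclic internal network over `n_mets` metabolites
#' (reactions point from lower to higher index, with occasional two-substrate
#' reactions), picks a random measured subset with random significant rate
#' intervals, and returns the built closed unsteady model. Instances whose
#' base relaxation problem is infeasible even with all sinks open are
#' resampled from the seed stream.
#'
#' @param n_mets number of metabolites (<= 14).
#' @param n_rxns number of internal reactions (<= 20).
#' @param n_measured number of measured-significant metabolites.
#' @param seed RNG seed.
#' @return list with `model` (the unsteady model), `rates`, and the source
#'   `network`.
#' @export
make_random_instance <- function(n_mets = 8, n_rxns = 10, n_measured = 3,
                                 seed = 1) {
  stopifnot(n_mets <= 14, n_rxns <= 20)
  set.seed(seed)
  for (attempt in 1:50) {
    m <- new_model(sprintf("rand_%d", seed))
    ids <- paste0("X", seq_len(n_mets))
    for (i in seq_len(n_mets))
      m <- add_metabolite(m, ids[i],
                          compartment = if (stats::runif(1) < 0.25) "e" else "c")
    ok <- TRUE
    for (r in seq_len(n_rxns)) {
      from <- sample.int(n_mets - 1L, 1L)
      to <- sample((from + 1L):n_mets, 1L)
      st <- stats::setNames(c(-1, 1), ids[c(from, to)])
      if (stats::runif(1) < 0.25 && from > 1L) {
        extra <- sample.int(from - 1L, 1L)   # second substrate, keeps DAG order
        if (!ids[extra] %in% names(st)) st <- c(st, stats::setNames(-1, ids[extra]))
      }
      rev <- stats::runif(1) < 0.3
      m <- add_reaction(m, paste0("R", r), st,
                        lower_bound = if (rev) -DEFAULT_BOUND else 0,
                        upper_bound = DEFAULT_BOUND)
    }
    measured <- sample(ids, n_measured)
    slope <- round(stats::runif(n_measured, -3, 3), 2)
    slope[slope == 0] <- 1
    hw <- 0.05
    rates <- data.frame(metabolite_id = measured, compartment = "c",
                        state = 1L, slope = slope,
                        b1 = slope - hw, b2 = slope + hw,
                        significant = TRUE, stringsAsFactors = FALSE)
    um <- build_ufba_model(m, rates)
    prob <- add_relaxation_sinks(um, iterations = 1)
    lpv <- model_lp(prob$model)
    if (lp_feasible(lpv$S, rep(0, length(lpv$mets)), lpv$lb, lpv$ub))
      return(list(model = um, rates = rates, network = m))
    # otherwise fall through and resample
  }
  stop("could not generate a feasible random instance for seed ", seed)
}

#' Exhaustive minimal-relaxation oracle
#'
#' Enumerates subsets of unmeasured metabolites by increasing cardinality,
#' opening both sinks for the subset only, and tests LP feasibility —
#' independent of the MILP path. Returns the minimal cardinality and all
#' minimal feasible supports.
#'
#' @param model an `unsteady_model`.
#' @param max_card cap on enumerated cardinality.
#' @param big_m sink capacity.
#' @return list with `cardinality` and `supports` (list of metabolite-id
#'   vectors); `cardinality` is `NA` if no subset up to `max_card` works.
#' @export
relaxation_oracle <- function(model, max_card = 4, big_m = DEFAULT_BOUND) {
  prob <- add_relaxation_sinks(model, iterations = 1, big_m = big_m)
  lpv <- model_lp(prob$model)
  zero <- rep(0, length(lpv$mets))
  up_idx <- match(prob$up, lpv$rxns)
  dn_idx <- match(prob$down, lpv$rxns)
  test_subset <- function(sel) {
    ub <- lpv$ub
    off <- c(up_idx[!sel], dn_idx[!sel])
    ub[off] <- 0
    lp_feasible(lpv$S, zero, lpv$lb, ub)
  }
  m <- prob$m
  for (k in 0:min(max_card, m)) {
    supports <- list()
    combs <- utils::combn(m, k, simplify = FALSE)
    for (cb in combs) {
      sel <- logical(m); sel[cb] <- TRUE
      if (test_subset(sel))
        supports[[length(supports) + 1L]] <- prob$unmeasured[sel]
    }
    if (length(supports) > 0)
      return(list(cardinality = k, supports = supports))
  }
  list(cardinality = NA_integer_, supports = list())
}
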