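# Conversion of a stoichiometric model plus per-state rate estimates into a
# closed-system unsteady model, and the matched steady-state FBA control.
#
# Unsteady mass balances are realized as single-metabolite accumulation
# pseudo-reactions rather than a nonzero right-hand side: for metabolite i
# with measured rate interval [b1, b2], a reaction {i: -1} with flux bounds
# [b1, b2] is added, so positive flux = accumulation and the network stays in
# standard S v = 0 form for every downstream LP/MILP/sampler. The
# accumulation flux *is* the rate-of-change b of the mass balance.

ACC_PREFIX <- "ACC_"
EFFLUX_PREFIX <- "EFF_"
SINK_UP_PREFIX <- "UP_"
SINK_DOWN_PREFIX <- "DN_"

#' Build an unsteady-state (uFBA) model for one metabolic state
#'
#' Removes all exchange reactions (closed system), then encodes each
#' significant measured rate of change as an accumulation pseudo-reaction
#' bounded by the rate's 95% confidence interval `[b1, b2]`. Extracellular
#' and intracellular metabolites are treated identically. Non-significant
#' measured metabolites are treated exactly as unmeasured ones (held at
#' steady state). Optional growth-rate bounds are applied to the objective
#' (biomass) reaction, and declared metabolite reserves get sink reactions.
#'
#' @param model a valid `stoichiometric_model`.
#' @param rates data.frame of rate estimates (from [estimate_rates()]):
#'   columns `metabolite_id`, `b1`, `b2`, `significant`, optionally `state`.
#'   Ids must be model metabolite ids (apply any assay-to-model mapping and
#'   compartment assignment beforehand).
#' @param growth_rate optional numeric length-2 `(lower, upper)` bounds for
#'   the biomass reaction.
#' @param reserves optional character vector of metabolite ids with internal
#'   reserves (e.g. glycogen stores); each gets a reversible sink.
#' @return an `unsteady_model` (subclass of `stoichiometric_model`).
#' @export
build_ufba_model <- function(model, rates, growth_rate = NULL,
                             reserves = NULL) {
  .build_state_model(model, rates, growth_rate, reserves, mode = "ufba")
}

#' Build the steady-state FBA control model
#'
#' Same workflow as [build_ufba_model()] but only the exometabolomics data
#' is integrated: significant rates of *extracellular* metabolites become
#' accumulation bounds, all intracellular metabolites are held at steady
#' state, and every extracellular metabolite without a measurement receives
#' a free efflux reaction (bounds `[0, 1000]`) permitting secretion out of
#' the system but no uptake — the standard FBA practice the control is meant
#' to represent.
#'
#' @inheritParams build_ufba_model
#' @export
build_fba_control <- function(model, rates, growth_rate = NULL,
                              reserves = NULL) {
  .build_state_model(model, rates, growth_rate, reserves, mode = "fba")
}

.build_state_model <- function(model, rates, growth_rate, reserves, mode) {
  validate_model(model)
  if (nrow(rates) > 0) {
    unknown <- setdiff(rates$metabolite_id, model$metabolites$id)
    if (length(unknown) > 0)
      stop("rate estimate for unknown metabolite(s): ",
           paste(unknown, collapse = ", "))
    if (anyDuplicated(rates$metabolite_id))
      stop("multiple rate estimates for metabolite ",
           rates$metabolite_id[duplicated(rates$metabolite_id)][1L],
           " in one state")
  }

  m <- remove_reactions(model, find_exchange_reactions(model))
  exo <- is_extracellular(model)

  sig <- rates[rates$significant, , drop = FALSE]
  if (mode == "fba" && nrow(sig) > 0)
    sig <- sig[exo[sig$metabolite_id], , drop = FALSE]

  acc <- character()
  for (i in seq_len(nrow(sig))) {
    met <- sig$metabolite_id[i]
    rid <- paste0(ACC_PREFIX, met)
    m <- add_reaction(m, rid, stats::setNames(-1, met),
                      lower_bound = sig$b1[i], upper_bound = sig$b2[i],
                      name = paste("accumulation of", met))
    acc[met] <- rid
  }

  if (mode == "fba") {
    free_exo <- model$metabolites$id[exo & !model$metabolites$id %in% names(acc)]
    for (met in free_exo) {
      m <- add_reaction(m, paste0(EFFLUX_PREFIX, met),
                        stats::setNames(-1, met),
                        lower_bound = 0, upper_bound = DEFAULT_BOUND,
                        name = paste("free efflux of", met))
    }
  }

  if (!is.null(reserves)) {
    for (met in reserves) {
      if (!met %in% model$metabolites$id)
        stop("reserve declared for unknown metabolite ", met)
      m <- add_reaction(m, paste0("SK_", met), stats::setNames(-1, met),
                        lower_bound = -DEFAULT_BOUND,
                        upper_bound = DEFAULT_BOUND,
                        name = paste("reserve sink for", met))
    }
  }

  if (!is.null(growth_rate)) {
    biomass <- objective_reaction(m)
    if (is.na(biomass))
      stop("growth-rate bounds supplied but the model has no objective reaction")
    m <- set_bounds(m, biomass, growth_rate[1L], growth_rate[2L])
  }

  m$mode <- mode
  m$state <- if ("state" %in% names(rates) && nrow(rates) > 0)
    rates$state[1L] else NA_integer_
  m$measured <- names(acc)
  m$accumulation <- acc
  m$relaxation_sinks <- list()
  m$growth_rate <- growth_rate
  class(m) <- c("unsteady_model", class(model))
  m
}

#' @export
print.unsteady_model <- function(x, ...) {
  cat(sprintf("unsteady_model (%s, state %s): %d metabolites, %d reactions, %d measured-significant\n",
              x$mode, x$state, nrow(x$metabolites), nrow(x$reactions),
              length(x$measured)))
  invisible(x)
}

# LP view of a model: S matrix plus bound vectors, in reaction order
model_lp <- function(model) {
  S <- s_matrix(model)
  list(S = S,
       lb = model$reactions$lower_bound,
       ub = model$reactions$upper_bound,
       rxns = model$reactions$id,
       mets = model$metabolites$id)
}

#' Degrees of freedom of a model's flux space
#'
#' Number of reactions minus the rank of S: the dimension of the null space
#' a flux state can move in. Adding an accumulation reaction or retaining a
#' relaxation sink raises it by one (per the degrees-of-freedom bookkeeping
#' of the unsteady formulation) provided the new column is independent.
#'
#' @param model a `stoichiometric_model`.
#' @return integer.
#' @export
model_dof <- function(model) {
  S <- s_matrix(model)
  if (ncol(S) == 0) return(0L)
  ncol(S) - qr(S)$rank
}
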