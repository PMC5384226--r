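# Interrogation of built models: FBA optimization, flux variability
# analysis, artificial-centering hit-and-run sampling of the flux polytope,
# uFBA-vs-FBA comparison statistics, internal-loop detection and single-gene
# essentiality.

#' Optimize a flux objective (FBA solve)
#'
#' @param model a `stoichiometric_model`.
#' @param objective reaction id to optimize; default the model's objective
#'   reaction.
#' @param sense `"max"` or `"min"`.
#' @return list with `status` (`"optimal"` or `"infeasible"` — infeasibility
#'   is a result, not an exception), `objective` value and named `fluxes`.
#' @export
optimize_model <- function(model, objective = NULL, sense = c("max", "min")) {
  sense <- match.arg(sense)
  if (is.null(objective)) objective <- objective_reaction(model)
  if (is.na(objective) || !objective %in% model$reactions$id)
    stop("objective reaction not found in model")
  lpv <- model_lp(model)
  cc <- as.numeric(lpv$rxns == objective)
  res <- lp_solve(cc, lpv$S, rep(0, length(lpv$mets)), lpv$lb, lpv$ub, sense)
  if (res$status != "optimal")
    return(list(status = res$status, objective = NA_real_, fluxes = NULL))
  list(status = "optimal", objective = res$objective,
       fluxes = stats::setNames(res$x, lpv$rxns))
}

#' Flux variability analysis
#'
#' Two LP solves per reaction; `range = max - min >= 0`.
#'
#' @param model a feasible `stoichiometric_model`.
#' @param reactions reaction ids to analyze (default all).
#' @return data.frame with `reaction`, `min`, `max`, `range`.
#' @export
fva <- function(model, reactions = model$reactions$id) {
  lpv <- model_lp(model)
  zero <- rep(0, length(lpv$mets))
  out <- lapply(reactions, function(rid) {
    cc <- as.numeric(lpv$rxns == rid)
    lo <- lp_solve(cc, lpv$S, zero, lpv$lb, lpv$ub, "min")
    hi <- lp_solve(cc, lpv$S, zero, lpv$lb, lpv$ub, "max")
    if (lo$status != "optimal" || hi$status != "optimal")
      stop("FVA on an infeasible model")
    data.frame(reaction = rid, min = lo$objective, max = hi$objective,
               range = hi$objective - lo$objective,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Sample a bounded flux polytope by artificial-centering hit-and-run
#'
#' Warmup points are the FVA optima (two per coordinate); directions are
#' drawn as (random stored point - running center), so every move stays in
#' the null space of `S` exactly and only the box bounds limit the step.
#' Points are periodically re-projected onto the null space to cancel
#' round-off drift. Sampling restarts with doubled thinning until the
#' mixed-fraction diagnostic falls to the threshold or `max_rounds` is hit.
#'
#' @param S equality-constraint matrix (rows can be zero).
#' @param lb,ub finite bounds.
#' @param n_samples number of samples to store.
#' @param seed RNG seed for reproducibility.
#' @param thinning initial steps per stored sample.
#' @param mixed_fraction_threshold convergence threshold (study value 0.54).
#' @param max_rounds maximum thinning doublings.
#' @return list with `samples` (n_samples x n matrix), `mixed_fraction`,
#'   `converged`, `thinning`.
#' @export
sample_polytope <- function(S, lb, ub, n_samples = 1000, seed = 1,
                            thinning = 2, mixed_fraction_threshold = 0.54,
                            max_rounds = 6) {
  S <- as.matrix(S)
  n <- length(lb)
  if (any(!is.finite(lb)) || any(!is.finite(ub)))
    stop("polytope must be bounded in every direction; close open bounds first")
  zero <- rep(0, nrow(S))

  # warmup: FVA vertices
  warm <- matrix(NA_real_, 2L * n, n)
  for (j in seq_len(n)) {
    cc <- numeric(n); cc[j] <- 1
    lo <- lp_solve(cc, S, zero, lb, ub, "min")
    hi <- lp_solve(cc, S, zero, lb, ub, "max")
    if (lo$status != "optimal" || hi$status != "optimal")
      stop("polytope is infeasible")
    warm[2L * j - 1L, ] <- lo$x
    warm[2L * j, ] <- hi$x
  }
  spread <- apply(warm, 2, function(v) diff(range(v)))
  if (all(spread < 1e-9)) {
    # fully determined polytope: a single point
    pt <- warm[1L, ]
    return(list(samples = matrix(rep(pt, n_samples), n_samples, n,
                                 byrow = TRUE,
                                 dimnames = list(NULL, colnames(S))),
                mixed_fraction = 0.5, converged = TRUE, thinning = thinning))
  }

  # null-space projector for drift correction
  proj <- NULL
  if (nrow(S) > 0) {
    sv <- svd(t(S))
    pos <- sv$d > max(dim(S)) * max(sv$d, 0) * 1e-12
    if (any(pos)) {
      U <- sv$u[, pos, drop = FALSE]
      proj <- function(x) x - U %*% crossprod(U, x)
    }
  }

  set.seed(seed)
  round_thin <- thinning
  for (round_i in seq_len(max_rounds)) {
    cap <- nrow(warm) + n_samples * round_thin + 64L
    pts <- matrix(NA_real_, cap, n)
    pts[seq_len(nrow(warm)), ] <- warm
    total_pts <- nrow(warm)
    center <- colMeans(warm)
    x <- pmin(pmax(center, lb), ub)
    samples <- matrix(NA_real_, n_samples, n)
    n_stored <- 0L
    step_i <- 0L
    while (n_stored < n_samples) {
      step_i <- step_i + 1L
      p <- pts[sample.int(total_pts, 1L), ]
      u <- p - center
      # re-project the direction: normalization would otherwise amplify
      # round-off that has leaked out of the null space
      if (!is.null(proj)) u <- as.vector(proj(u))
      nu <- sqrt(sum(u^2))
      if (nu < 1e-9) next
      u <- u / nu
      # step limits from the box
      tmax <- Inf; tmin <- -Inf
      for (j in seq_len(n)) {
        if (u[j] > 1e-12) {
          tmax <- min(tmax, (ub[j] - x[j]) / u[j])
          tmin <- max(tmin, (lb[j] - x[j]) / u[j])
        } else if (u[j] < -1e-12) {
          tmax <- min(tmax, (lb[j] - x[j]) / u[j])
          tmin <- max(tmin, (ub[j] - x[j]) / u[j])
        }
      }
      if (!is.finite(tmax) || !is.finite(tmin) || tmax < tmin) next
      tt <- stats::runif(1, tmin, tmax)
      x <- x + tt * u
      if (step_i %% 50L == 0L && !is.null(proj)) x <- as.vector(proj(x))
      x <- pmin(pmax(x, lb), ub)
      # artificial centering: the new point joins the point set
      if (total_pts < cap) {
        total_pts <- total_pts + 1L
        pts[total_pts, ] <- x
      }
      center <- center + (x - center) / total_pts
      if (step_i %% round_thin == 0L) {
        n_stored <- n_stored + 1L
        samples[n_stored, ] <- x
      }
    }
    mf <- .mixed_fraction(samples)
    if (mf <= mixed_fraction_threshold || round_i == max_rounds) {
      colnames(samples) <- colnames(S)
      return(list(samples = samples, mixed_fraction = mf,
                  converged = mf <= mixed_fraction_threshold,
                  thinning = round_thin))
    }
    round_thin <- round_thin * 2L
  }
}

# fraction of (sample, reaction) pairs that stay on the same side of the
# per-reaction median between the first and second half of the chain;
# 1 = unmixed, 0.5 = perfectly mixed
.mixed_fraction <- function(samples) {
  k <- nrow(samples)
  half <- floor(k / 2)
  med <- apply(samples, 2, stats::median)
  sds <- apply(samples, 2, stats::sd)
  live <- sds > 1e-9
  if (!any(live)) return(0.5)
  a <- sweep(samples[seq_len(half), live, drop = FALSE], 2, med[live]) > 0
  b <- sweep(samples[half + seq_len(half), live, drop = FALSE], 2, med[live]) > 0
  mean(a == b)
}

#' Sample feasible flux states of a model
#'
#' @param model a feasible, bounded `stoichiometric_model`.
#' @inheritParams sample_polytope
#' @return a `flux_sample_set`: `samples` matrix (samples x reactions, named
#'   columns), `reactions`, `mixed_fraction`, `converged`, sampler
#'   parameters.
#' @export
sample_fluxes <- function(model, n_samples = 1000, seed = 1,
                          thinning = 2, mixed_fraction_threshold = 0.54,
                          max_rounds = 6) {
  lpv <- model_lp(model)
  colnames(lpv$S) <- lpv$rxns
  res <- sample_polytope(lpv$S, lpv$lb, lpv$ub, n_samples = n_samples,
                         seed = seed, thinning = thinning,
                         mixed_fraction_threshold = mixed_fraction_threshold,
                         max_rounds = max_rounds)
  colnames(res$samples) <- lpv$rxns
  structure(list(samples = res$samples, reactions = lpv$rxns,
                 mixed_fraction = res$mixed_fraction,
                 converged = res$converged,
                 params = list(n_samples = n_samples, seed = seed,
                               thinning = res$thinning,
                               threshold = mixed_fraction_threshold)),
            class = "flux_sample_set")
}

#' @export
print.flux_sample_set <- function(x, ...) {
  cat(sprintf("flux_sample_set: %d samples x %d reactions, mixed fraction %.3f (%s)\n",
              nrow(x$samples), length(x$reactions), x$mixed_fraction,
              if (x$converged) "converged" else "NOT converged"))
  invisible(x)
}

#' Verify stored samples against model constraints
#'
#' Every sample must satisfy `S v = 0` (accumulation fluxes are the
#' rate-of-change vector b) and the flux bounds within `tol`.
#'
#' @param model the sampled model.
#' @param sample_set a `flux_sample_set`.
#' @param tol violation tolerance (1e-6).
#' @return maximum violation (invisibly); errors if above `tol`.
#' @export
check_samples <- function(model, sample_set, tol = 1e-6) {
  lpv <- model_lp(model)
  X <- sample_set$samples[, lpv$rxns, drop = FALSE]
  resid <- max(abs(lpv$S %*% t(X)))
  bviol <- max(c(sweep(X, 2, lpv$lb, `-`) * -1, sweep(X, 2, lpv$ub, `-`)), 0)
  v <- max(resid, bviol)
  if (v > tol) stop("stored flux sample violates constraints by ", v)
  invisible(v)
}

#' Reactions able to carry flux in the fully closed network (type-3 loops)
#'
#' Closes every exchange, accumulation and sink reaction to zero and then
#' maximizes/minimizes each remaining reaction; any reaction that can still
#' carry flux belongs to an internal (thermodynamically infeasible) cycle
#' and is excluded from flux comparisons.
#'
#' @param model a `stoichiometric_model`.
#' @return character vector of loop-member reaction ids.
#' @export
exclude_loop_reactions <- function(model) {
  boundary <- find_exchange_reactions(model)
  if (inherits(model, "unsteady_model")) {
    boundary <- union(boundary, unname(model$accumulation))
    boundary <- union(boundary, unname(unlist(model$relaxation_sinks)))
  }
  closed <- model
  for (rid in intersect(boundary, model$reactions$id))
    closed <- set_bounds(closed, rid, 0, 0)
  lpv <- model_lp(closed)
  zero <- rep(0, length(lpv$mets))
  internal <- setdiff(model$reactions$id, boundary)
  loops <- character()
  for (rid in internal) {
    cc <- as.numeric(lpv$rxns == rid)
    hi <- lp_solve(cc, lpv$S, zero, lpv$lb, lpv$ub, "max")
    lo <- lp_solve(cc, lpv$S, zero, lpv$lb, lpv$ub, "min")
    if (hi$status == "optimal" && lo$status == "optimal" &&
        (hi$objective > 1e-6 || lo$objective < -1e-6))
      loops <- c(loops, rid)
  }
  loops
}

#' Compare two sampled flux states (uFBA vs FBA machinery)
#'
#' For every reaction present in both models and not in a type-3 loop of
#' either, computes the overlap coefficient of the two empirical flux
#' distributions on a shared equal-width binning (Freedman-Diaconis on the
#' pooled samples, at least 20 bins); a reaction is significantly different
#' when the distributions overlap by less than 5%. A distribution of
#' Spearman correlations is computed by pairing independently shuffled
#' sample vectors, one pairing per stored sample.
#'
#' @param a,b `flux_sample_set`s (should be converged).
#' @param model_a,model_b the sampled models (used for loop exclusion).
#' @param overlap_threshold significance threshold on the overlap (0.05).
#' @param seed seed for the Spearman pairing shuffles.
#' @return a `flux_comparison`: per-reaction data.frame (`reaction`,
#'   `overlap`, `significant`), `spearman` vector, `reactions` compared.
#' @export
compare_flux_states <- function(a, b, model_a, model_b,
                                overlap_threshold = 0.05, seed = 1) {
  shared <- intersect(a$reactions, b$reactions)
  loops <- union(exclude_loop_reactions(model_a),
                 exclude_loop_reactions(model_b))
  shared <- setdiff(shared, loops)
  if (length(shared) == 0) stop("no shared non-loop reactions to compare")

  per <- do.call(rbind, lapply(shared, function(rid) {
    ov <- .overlap_coefficient(a$samples[, rid], b$samples[, rid])
    data.frame(reaction = rid, overlap = ov,
               significant = ov < overlap_threshold,
               stringsAsFactors = FALSE)
  }))
  rownames(per) <- NULL

  set.seed(seed)
  na <- nrow(a$samples); nb <- nrow(b$samples)
  k <- min(na, nb)
  pa <- sample.int(na, k)
  pb <- sample.int(nb, k)
  rho <- vapply(seq_len(k), function(i) {
    suppressWarnings(stats::cor(a$samples[pa[i], shared],
                                b$samples[pb[i], shared],
                                method = "spearman"))
  }, numeric(1))
  structure(list(per_reaction = per, spearman = rho, reactions = shared,
                 loops_excluded = loops),
            class = "flux_comparison")
}

# overlap coefficient of two empirical distributions on shared
# Freedman-Diaconis bins (min 20)
.overlap_coefficient <- function(x, y, min_bins = 20) {
  pooled <- c(x, y)
  rng <- range(pooled)
  if (diff(rng) < 1e-12) return(1)   # identical constants overlap fully
  iqr <- stats::IQR(pooled)
  bw <- if (iqr > 0) 2 * iqr / length(pooled)^(1 / 3) else diff(rng) / min_bins
  nb <- max(min_bins, ceiling(diff(rng) / bw))
  brks <- seq(rng[1], rng[2], length.out = nb + 1)
  px <- tabulate(findInterval(x, brks, rightmost.closed = TRUE,
                              all.inside = TRUE), nb) / length(x)
  py <- tabulate(findInterval(y, brks, rightmost.closed = TRUE,
                              all.inside = TRUE), nb) / length(y)
  sum(pmin(px, py))
}

#' Single-gene essentiality simulation
#'
#' For each gene, its gene rules are evaluated with the gene knocked out;
#' reactions whose rule evaluates false are disabled, growth is
#' re-optimized, and the gene is essential when the optimum falls below
#' `threshold_fraction` of the reference growth rate (study threshold: 1%
#' of the experimentally determined growth rate).
#'
#' For unsteady models, bounds that conflict with the zero flux vector
#' being feasible (accumulation intervals excluding 0) are widened to
#' include 0, and metabolic exchange out of the system is opened, matching
#' the essentiality protocol for uFBA models.
#'
#' @param model a `stoichiometric_model` with gene rules.
#' @param growth_reaction biomass reaction id; default the objective.
#' @param threshold_fraction essential iff knockout growth falls below this
#'   fraction of `reference_growth` (default 0.01).
#' @param reference_growth reference growth rate (> 0); default the
#'   wild-type optimum of the prepared model.
#' @param genes genes to test (default all model genes).
#' @return data.frame with `gene`, `growth`, `essential`.
#' @export
gene_essentiality <- function(model, growth_reaction = NULL,
                              threshold_fraction = 0.01,
                              reference_growth = NULL,
                              genes = model$genes) {
  if (is.null(growth_reaction)) growth_reaction <- objective_reaction(model)
  if (is.na(growth_reaction) || !growth_reaction %in% model$reactions$id)
    stop("growth reaction not found in model")
  prep <- .prepare_for_knockouts(model)
  if (is.null(reference_growth)) {
    wt <- optimize_model(prep, growth_reaction, "max")
    if (wt$status != "optimal" || wt$objective <= 0)
      stop("reference growth not positive; supply reference_growth")
    reference_growth <- wt$objective
  }
  if (reference_growth <= 0) stop("reference growth must be > 0")
  out <- do.call(rbind, lapply(genes, function(g) {
    km <- prep
    rules <- km$reactions$gene_rule
    off <- which(!is.na(rules) &
                   vapply(rules, function(r) !eval_gene_rule(r, g), logical(1)))
    for (i in off) km <- set_bounds(km, km$reactions$id[i], 0, 0)
    sol <- optimize_model(km, growth_reaction, "max")
    gr <- if (sol$status == "optimal") sol$objective else 0
    data.frame(gene = g, growth = gr,
               essential = gr < threshold_fraction * reference_growth,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

# uFBA essentiality protocol: make the zero vector admissible and allow
# exchange out of the system
.prepare_for_knockouts <- function(model) {
  if (!inherits(model, "unsteady_model")) return(model)
  for (rid in model$reactions$id) {
    i <- match(rid, model$reactions$id)
    lo <- model$reactions$lower_bound[i]
    hi <- model$reactions$upper_bound[i]
    if (lo > 0) model <- set_bounds(model, rid, 0, hi)
    if (hi < 0) model <- set_bounds(model, rid, lo, 0)
  }
  # open efflux for extracellular metabolites lacking one
  exo_mets <- model$metabolites$id[is_extracellular(model)]
  have <- names(model$accumulation)
  for (met in setdiff(exo_mets, have)) {
    rid <- paste0(EFFLUX_PREFIX, met)
    if (!rid %in% model$reactions$id)
      model <- add_reaction(model, rid, stats::setNames(-1, met), 0,
                            DEFAULT_BOUND,
                            name = paste("knockout efflux for", met))
  }
  model
}
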