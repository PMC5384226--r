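# Time-course metabolomics preparation: imputation of missing values,
# PCA-based discretization of trajectories into linearized metabolic states,
# and per-state rate-of-change estimation by ordinary least squares.

#' Construct a time-course metabolomics dataset
#'
#' @param measurements data.frame with columns `metabolite_id`,
#'   `compartment`, `time` (hours), `replicate` (integer), `concentration`
#'   (mmol/L or mmol/gDW), and optionally `missing` (logical). `NA`
#'   concentrations are treated as missing.
#' @param units concentration units, `"mmol/L"` or `"mmol/gDW"`.
#' @param mapping optional named character vector translating assay
#'   metabolite ids to model metabolite ids.
#' @return a `timecourse_dataset` (a data.frame with attributes).
#' @export
timecourse_dataset <- function(measurements, units = "mmol/L",
                               mapping = NULL) {
  req <- c("metabolite_id", "compartment", "time", "replicate", "concentration")
  miss_cols <- setdiff(req, names(measurements))
  if (length(miss_cols) > 0)
    stop("time-course table lacks column(s): ", paste(miss_cols, collapse = ", "))
  d <- measurements[, req, drop = FALSE]
  if (!"missing" %in% names(measurements)) {
    d$missing <- is.na(d$concentration)
  } else {
    d$missing <- as.logical(measurements$missing) | is.na(d$concentration)
  }
  if (any(d$time < 0)) stop("negative time values")
  if (length(unique(d$time)) < 2) stop("need at least 2 distinct time points")
  key <- paste(d$metabolite_id, d$time, d$replicate)
  if (anyDuplicated(key))
    stop("duplicate (metabolite, time, replicate) keys: ",
         key[duplicated(key)][1L])
  bad <- !d$missing & !is.finite(d$concentration)
  if (any(bad)) stop("non-finite concentration for ", d$metabolite_id[bad][1L])
  structure(d, units = units, mapping = mapping,
            class = c("timecourse_dataset", "data.frame"))
}

#' Read a time-course CSV file
#'
#' Expected columns: `metabolite_id`, `compartment`, `time`, `replicate`,
#' `concentration`, optional `missing`. Time is converted to hours at
#' ingest so all downstream rates are per hour.
#'
#' @param path CSV path.
#' @param time_units units of the `time` column, `"hours"` or `"days"`.
#' @inheritParams timecourse_dataset
#' @export
read_timecourse_csv <- function(path, units = "mmol/L",
                                time_units = c("hours", "days")) {
  time_units <- match.arg(time_units)
  d <- tryCatch(utils::read.csv(path, stringsAsFactors = FALSE),
                error = function(e) stop("cannot read time-course CSV ", path,
                                         ": ", conditionMessage(e)))
  req <- c("metabolite_id", "compartment", "time", "replicate", "concentration")
  miss_cols <- setdiff(req, names(d))
  if (length(miss_cols) > 0)
    stop("time-course CSV ", path, " lacks column(s): ",
         paste(miss_cols, collapse = ", "))
  if (time_units == "days") d$time <- d$time * 24
  timecourse_dataset(d, units = units)
}

# metabolites x (time, replicate) concentration matrix; NA = missing
.tc_matrix <- function(data) {
  cells <- unique(data[, c("time", "replicate")])
  cells <- cells[order(cells$time, cells$replicate), ]
  mets <- unique(data$metabolite_id)
  M <- matrix(NA_real_, length(mets), nrow(cells),
              dimnames = list(mets, paste(cells$time, cells$replicate, sep = "@")))
  idx_col <- match(paste(data$time, data$replicate, sep = "@"), colnames(M))
  idx_row <- match(data$metabolite_id, mets)
  vals <- ifelse(data$missing, NA_real_, data$concentration)
  M[cbind(idx_row, idx_col)] <- vals
  list(M = M, cells = cells)
}

#' Impute missing concentrations by weighted k-nearest neighbours
#'
#' Each missing entry is replaced by the inverse-distance-weighted average of
#' the `k` nearest metabolite profiles that observe that coordinate.
#' Nearness is root-mean-square Euclidean distance over the coordinates the
#' two profiles co-observe. Non-missing entries are untouched, so the
#' operation is idempotent on its own output.
#'
#' @param data a `timecourse_dataset`.
#' @param k number of neighbours (default 5).
#' @return the dataset with all `missing` entries filled in.
#' @export
impute_missing <- function(data, k = 5) {
  stopifnot(inherits(data, "timecourse_dataset"), k >= 1)
  if (!any(data$missing)) return(data)
  tm <- .tc_matrix(data)
  M <- tm$M
  n_obs <- rowSums(!is.na(M))
  if (any(n_obs == 0))
    stop("metabolite with no observed values: ",
         rownames(M)[n_obs == 0][1L])
  filled <- M
  for (g in which(apply(M, 1, anyNA))) {
    for (jcol in which(is.na(M[g, ]))) {
      cand <- which(!is.na(M[, jcol]))
      cand <- setdiff(cand, g)
      if (length(cand) == 0)
        stop("no neighbour observes coordinate ", colnames(M)[jcol])
      dist_g <- vapply(cand, function(h) {
        co <- !is.na(M[g, ]) & !is.na(M[h, ])
        if (!any(co)) return(Inf)
        sqrt(mean((M[g, co] - M[h, co])^2))
      }, numeric(1))
      ord <- order(dist_g)
      nn <- cand[ord][seq_len(min(k, length(cand)))]
      dd <- dist_g[ord][seq_len(min(k, length(cand)))]
      if (all(!is.finite(dd)))
        stop("metabolite ", rownames(M)[g],
             " shares no observed coordinates with any neighbour")
      w <- 1 / (dd + 1e-12)
      w[!is.finite(w)] <- 0
      filled[g, jcol] <- sum(w * M[nn, jcol]) / sum(w)
    }
  }
  out <- as.data.frame(data)
  key_col <- match(paste(out$time, out$replicate, sep = "@"), colnames(M))
  key_row <- match(out$metabolite_id, rownames(M))
  vals <- filled[cbind(key_row, key_col)]
  out$concentration[out$missing] <- vals[out$missing]
  out$missing <- FALSE
  timecourse_dataset(out, units = attr(data, "units"),
                     mapping = attr(data, "mapping"))
}

#' Discretize a time course into linearized metabolic states
#'
#' Replicate-averaged metabolite profiles are standardized to Z-scores
#' across time (zero-variance metabolites are dropped from the PCA), PCA is
#' applied over time points, and the first-principal-component score
#' trajectory is segmented by exhaustive dynamic-programming segmented
#' regression minimizing total within-segment SSE. The number of segments is
#' the supplied `n_states`, or else chosen by an elbow rule (smallest k
#' capturing 95% of the achievable SSE reduction).
#'
#' @param data a `timecourse_dataset` (no missing values; run
#'   [impute_missing()] first).
#' @param n_states optional fixed number of states.
#' @param min_points minimum time points per state window (default 3).
#' @return list of `metabolic_state_window` objects, each with `index`,
#'   `t_start`, `t_end`, `times`.
#' @export
discretize_states <- function(data, n_states = NULL, min_points = 3) {
  stopifnot(inherits(data, "timecourse_dataset"))
  if (any(data$missing))
    stop("dataset has missing values; impute first")
  avg <- stats::aggregate(concentration ~ metabolite_id + time,
                          data = as.data.frame(data), FUN = mean)
  times <- sort(unique(avg$time))
  Tn <- length(times)
  if (Tn < 3) stop("need at least 3 time points to discretize")
  if (!is.null(n_states)) {
    if (Tn < min_points * n_states)
      stop("fewer than ", min_points, " time points per requested state")
  }
  X <- matrix(NA_real_, Tn, length(unique(avg$metabolite_id)),
              dimnames = list(NULL, unique(avg$metabolite_id)))
  for (i in seq_len(nrow(avg)))
    X[match(avg$time[i], times), avg$metabolite_id[i]] <- avg$concentration[i]
  sds <- apply(X, 2, stats::sd)
  keep <- is.finite(sds) & sds > 1e-12 & colSums(is.na(X)) == 0
  if (!any(keep)) {
    # nothing varies: one state spanning everything
    return(list(.state_window(1L, times)))
  }
  Z <- scale(X[, keep, drop = FALSE])
  pc1 <- stats::prcomp(Z, center = FALSE, scale. = FALSE)$x[, 1]

  sse <- .segment_sse_table(times, pc1, min_points)
  kmax <- min(floor(Tn / min_points), Tn - 1L)
  kmax <- max(kmax, 1L)
  fits <- .segment_dp(sse, Tn, kmax)
  if (!is.null(n_states)) {
    k <- n_states
    if (k > kmax || !is.finite(fits$cost[k]))
      stop("cannot form ", k, " windows of >= ", min_points, " points")
  } else {
    costs <- fits$cost[seq_len(kmax)]
    best <- min(costs, na.rm = TRUE)
    total_gain <- costs[1] - best
    if (total_gain <= 1e-9 * max(1, costs[1])) {
      k <- 1L
    } else {
      k <- which((costs - best) <= 0.05 * total_gain)[1L]
    }
  }
  bounds <- .segment_backtrack(fits$choice, Tn, k)
  lapply(seq_len(k), function(i) {
    idx <- seq(bounds[i] + 1L, bounds[i + 1L])
    .state_window(i, times[idx])
  })
}

.state_window <- function(index, times) {
  structure(list(index = as.integer(index), t_start = min(times),
                 t_end = max(times), times = times),
            class = "metabolic_state_window")
}

#' @export
print.metabolic_state_window <- function(x, ...) {
  cat(sprintf("state %d: t = [%g, %g] h, %d time points\n",
              x$index, x$t_start, x$t_end, length(x$times)))
  invisible(x)
}

# SSE of a linear fit on points i..j (1-based), Inf when segment too short
.segment_sse_table <- function(tt, ss, min_points) {
  Tn <- length(tt)
  sse <- matrix(Inf, Tn, Tn)
  for (i in seq_len(Tn)) {
    for (j in seq_len(Tn)) {
      if (j - i + 1L < min_points) next
      x <- tt[i:j]; y <- ss[i:j]
      fit <- stats::lm.fit(cbind(1, x), y)
      sse[i, j] <- sum(fit$residuals^2)
    }
  }
  sse
}

# dynamic program over contiguous segmentations
.segment_dp <- function(sse, Tn, kmax) {
  cost <- matrix(Inf, kmax, Tn)    # cost[k, j]: best SSE of k segments over 1..j
  choice <- array(0L, c(kmax, Tn))
  cost[1, ] <- sse[1, ]
  if (kmax >= 2) {
    for (k in 2:kmax) {
      for (j in seq_len(Tn)) {
        best <- Inf; arg <- 0L
        for (i in seq_len(j - 1L)) {
          v <- cost[k - 1L, i] + sse[i + 1L, j]
          if (v < best) { best <- v; arg <- i }
        }
        cost[k, j] <- best
        choice[k, j] <- arg
      }
    }
  }
  list(cost = cost[, Tn], choice = choice)
}

.segment_backtrack <- function(choice, Tn, k) {
  bounds <- integer(k + 1L)
  bounds[k + 1L] <- Tn
  j <- Tn
  if (k >= 2L) {
    for (kk in k:2L) {
      j <- choice[kk, j]
      bounds[kk] <- j
    }
  }
  bounds[1L] <- 0L
  bounds
}

#' Estimate per-metabolite rates of change within a state window
#'
#' Ordinary-least-squares slope of concentration versus time, pooling
#' replicate measurements as independent observations, with a two-sided
#' `(1 - alpha)` confidence interval from the t distribution. A metabolite
#' is significant when its confidence interval excludes zero; otherwise it
#' is deemed at steady state.
#'
#' @param data a `timecourse_dataset` without missing values.
#' @param window a `metabolic_state_window` from [discretize_states()].
#' @param alpha significance level (default 0.05, i.e. 95% CI).
#' @return data.frame of `RateEstimate`s: `metabolite_id`, `compartment`,
#'   `state`, `slope`, `b1`, `b2`, `significant`. Units: concentration
#'   units per hour.
#' @export
estimate_rates <- function(data, window, alpha = 0.05) {
  stopifnot(inherits(data, "timecourse_dataset"),
            inherits(window, "metabolic_state_window"))
  d <- as.data.frame(data)
  d <- d[!d$missing & d$time %in% window$times, , drop = FALSE]
  if (length(unique(d$time)) < 3)
    stop("window holds fewer than 3 time points")
  out <- do.call(rbind, lapply(split(d, d$metabolite_id), function(g) {
    if (stats::var(g$time) < 1e-12)
      stop("zero time-variance within window for ", g$metabolite_id[1L])
    fit <- stats::lm(concentration ~ time, data = g)
    slope <- unname(stats::coef(fit)[2L])
    # a perfect (noiseless) fit is legitimate here; silence the summary
    # warning about it
    se <- suppressWarnings(summary(fit)$coefficients[2L, 2L])
    df <- fit$df.residual
    tq <- stats::qt(1 - alpha / 2, df)
    half <- if (is.finite(se)) tq * se else 0
    if (is.na(half)) half <- 0
    b1 <- slope - half
    b2 <- slope + half
    data.frame(metabolite_id = g$metabolite_id[1L],
               compartment = g$compartment[1L],
               state = window$index,
               slope = slope, b1 = b1, b2 = b2,
               significant = !(b1 <= 0 && b2 >= 0),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Split pooled metabolite measurements by fixed ratios
#'
#' Assays sometimes report unresolved pools (e.g. 3PG/2PG, pentoses,
#' Leu/Ile). This splits a pooled id into individual metabolite records
#' using a user-supplied ratio table; no ratios are hard-coded.
#'
#' @param data a `timecourse_dataset`.
#' @param ratios data.frame with columns `pool_id`, `metabolite_id`,
#'   `ratio`; ratios for a pool must sum to 1.
#' @export
split_pooled <- function(data, ratios) {
  stopifnot(all(c("pool_id", "metabolite_id", "ratio") %in% names(ratios)))
  for (p in unique(ratios$pool_id)) {
    rsum <- sum(ratios$ratio[ratios$pool_id == p])
    if (abs(rsum - 1) > 1e-8)
      stop("split ratios for pool ", p, " sum to ", rsum, ", not 1")
  }
  d <- as.data.frame(data)
  keep <- d[!d$metabolite_id %in% ratios$pool_id, , drop = FALSE]
  extra <- do.call(rbind, lapply(seq_len(nrow(ratios)), function(i) {
    r <- ratios[i, ]
    src <- d[d$metabolite_id == r$pool_id, , drop = FALSE]
    if (nrow(src) == 0) return(NULL)
    src$metabolite_id <- r$metabolite_id
    src$concentration <- src$concentration * r$ratio
    src
  }))
  timecourse_dataset(rbind(keep, extra), units = attr(data, "units"),
                     mapping = attr(data, "mapping"))
}
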