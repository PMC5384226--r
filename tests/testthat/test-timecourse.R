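test_that("kNN imputation matches a brute-force oracle on a small dataset", {
  # 6 metabolite profiles over 5 time points, one hole in m1 at t = 2
  profs <- list(m1 = c(1.0, 2.0, NA, 4.0, 5.0),
                m2 = c(1.1, 2.1, 3.1, 4.1, 5.1),
                m3 = c(0.9, 1.8, 2.9, 3.9, 5.2),
                m4 = c(5.0, 4.0, 3.0, 2.0, 1.0),
                m5 = c(1.0, 2.2, 3.3, 4.4, 5.6),
                m6 = c(2.0, 2.0, 2.0, 2.0, 2.0))
  d <- do.call(rbind, lapply(names(profs), function(g)
    data.frame(metabolite_id = g, compartment = "c", time = 0:4,
               replicate = 1, concentration = profs[[g]])))
  tc <- timecourse_dataset(d)
  out <- impute_missing(tc, k = 3)

  # oracle: RMS distance over co-observed coordinates, inverse-distance
  # weights, 3 nearest neighbours observed at the hole
  co <- c(1, 2, 4, 5)
  dists <- vapply(profs[-1], function(p)
    sqrt(mean((profs$m1[co] - p[co])^2)), numeric(1))
  nn <- names(sort(dists))[1:3]
  w <- 1 / (sort(dists)[1:3] + 1e-12)
  expected <- sum(w * vapply(profs[nn], `[`, numeric(1), 3)) / sum(w)

  got <- out$concentration[out$metabolite_id == "m1" & out$time == 2]
  expect_equal(got, expected, tolerance = 1e-12)
  # non-missing entries untouched
  expect_equal(out$concentration[out$metabolite_id == "m2"], profs$m2)
})

test_that("imputation is an identity without holes and idempotent on its output", {
  sc <- make_scenario("branched", noise_sd = 0.02, seed = 3)
  sim <- simulate_timecourse(sc)
  expect_identical(impute_missing(sim$data), sim$data)

  sc2 <- make_scenario("branched", noise_sd = 0.02, missing_fraction = 0.2,
                       seed = 4)
  sim2 <- simulate_timecourse(sc2)
  once <- impute_missing(sim2$data)
  expect_false(any(once$missing))
  expect_identical(impute_missing(once), once)
})

test_that("constant neighbours impute the constant and orphans error", {
  d <- rbind(
    data.frame(metabolite_id = "t", compartment = "c", time = 0:2,
               replicate = 1, concentration = c(4.0, NA, 4.0)),
    do.call(rbind, lapply(1:5, function(i)
      data.frame(metabolite_id = paste0("n", i), compartment = "c",
                 time = 0:2, replicate = 1,
                 concentration = c(4 + i / 10, 4.0, 4 - i / 10)))))
  out <- impute_missing(timecourse_dataset(d), k = 5)
  expect_equal(out$concentration[out$metabolite_id == "t" & out$time == 1], 4.0)

  d2 <- data.frame(metabolite_id = rep(c("a", "b"), each = 2),
                   compartment = "c", time = rep(0:1, 2), replicate = 1,
                   concentration = c(NA, NA, 1, 2))
  expect_error(impute_missing(timecourse_dataset(d2)), "a")
})

test_that("rate estimation matches the textbook OLS/t-interval formulas", {
  # perfect line: slope exact, zero-width interval, significant
  d <- tc_table("m", 0:2, function(g, t, r) 2 * t)
  w <- structure(list(index = 1L, t_start = 0, t_end = 2, times = 0:2),
                 class = "metabolic_state_window")
  r <- estimate_rates(timecourse_dataset(d), w)
  expect_equal(r$slope, 2)
  expect_equal(r$b1, 2)
  expect_equal(r$b2, 2)
  expect_true(r$significant)

  # flat profile: slope 0, interval spans 0, not significant
  d2 <- tc_table("m", 0:3, function(g, t, r) rep(5, length(t)), replicates = 2)
  w2 <- structure(list(index = 1L, t_start = 0, t_end = 3, times = 0:3),
                  class = "metabolic_state_window")
  r2 <- estimate_rates(timecourse_dataset(d2), w2)
  expect_equal(r2$slope, 0)
  expect_false(r2$significant)

  # noisy line vs closed-form: beta = Sxy/Sxx, CI = beta +- t * s/sqrt(Sxx)
  set.seed(9)
  tt <- 0:9
  y <- 3 + 1 * tt + rnorm(10, 0, 0.1)
  d3 <- data.frame(metabolite_id = "m", compartment = "c", time = tt,
                   replicate = 1, concentration = y)
  w3 <- structure(list(index = 1L, t_start = 0, t_end = 9, times = tt),
                  class = "metabolic_state_window")
  r3 <- estimate_rates(timecourse_dataset(d3), w3)
  Sxx <- sum((tt - mean(tt))^2)
  beta <- sum((tt - mean(tt)) * (y - mean(y))) / Sxx
  res <- y - (mean(y) - beta * mean(tt)) - beta * tt
  s <- sqrt(sum(res^2) / (10 - 2))
  half <- qt(0.975, 8) * s / sqrt(Sxx)
  expect_equal(r3$slope, beta, tolerance = 1e-10)
  expect_equal(r3$b1, beta - half, tolerance = 1e-10)
  expect_equal(r3$b2, beta + half, tolerance = 1e-10)

  expect_error(estimate_rates(timecourse_dataset(d3),
                              structure(list(index = 1L, t_start = 0,
                                             t_end = 0, times = c(0, 0, 0)),
                                        class = "metabolic_state_window")),
               "time")
})

test_that("state discretization finds the single- and two-phase structure", {
  # all metabolites linear: one window spanning everything
  d <- tc_table(c("a", "b"), 0:8, function(g, t, r)
    if (g == "a") 1 + 2 * t else 10 - t)
  tc <- timecourse_dataset(d)
  ws <- discretize_states(tc)
  expect_length(ws, 1)
  expect_equal(ws[[1]]$times, 0:8)

  # slopes switch sign at t = 9 (between sample points) for half the
  # metabolites: 2 windows splitting there; the kink sits strictly inside
  # one segment so the optimal split is unique
  tt <- seq(0, 20, by = 2)
  d2 <- tc_table(c("a", "b", "c", "d"), tt, function(g, t, r) {
    if (g %in% c("a", "b")) 20 + pmin(t, 9) - 2 * pmax(t - 9, 0)
    else 5 + 0.5 * t
  })
  ws2 <- discretize_states(timecourse_dataset(d2))
  expect_length(ws2, 2)
  expect_equal(ws2[[1]]$t_end, 10, tolerance = 2)

  # windows partition the time points
  got <- sort(unlist(lapply(ws2, `[[`, "times")))
  expect_equal(got, tt)

  # invariant under uniform time translation
  d3 <- d2
  d3$time <- d3$time + 7
  ws3 <- discretize_states(timecourse_dataset(d3))
  expect_equal(vapply(ws3, function(w) length(w$times), integer(1)),
               vapply(ws2, function(w) length(w$times), integer(1)))

  expect_error(discretize_states(tc, n_states = 4), "windows|points")
})

test_that("pooled metabolite splitting applies user ratios and checks sums", {
  d <- tc_table("pool_xy", 0:3, function(g, t, r) 10 + t)
  tc <- timecourse_dataset(d)
  ratios <- data.frame(pool_id = "pool_xy",
                       metabolite_id = c("x", "y"), ratio = c(0.7, 0.3))
  out <- split_pooled(tc, ratios)
  expect_setequal(unique(out$metabolite_id), c("x", "y"))
  expect_equal(out$concentration[out$metabolite_id == "x" & out$time == 0],
               7)
  bad <- data.frame(pool_id = "pool_xy", metabolite_id = c("x", "y"),
                    ratio = c(0.7, 0.4))
  expect_error(split_pooled(tc, bad), "sum")
})
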