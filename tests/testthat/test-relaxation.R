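test_that("sink installation covers exactly the unmeasured metabolites", {
  sc <- make_scenario("pool_depletion")
  um <- build_ufba_model(sc$model, true_rates(sc))
  prob <- add_relaxation_sinks(um)
  unmeasured <- setdiff(um$metabolites$id, um$measured)
  expect_equal(prob$m, length(unmeasured))
  expect_setequal(names(prob$up), unmeasured)
  # up sink consumes (accumulation), down sink produces (depletion)
  for (met in unmeasured) {
    expect_equal(prob$model$stoichiometry[[prob$up[met]]],
                 setNames(-1, met))
    expect_equal(prob$model$stoichiometry[[prob$down[met]]],
                 setNames(1, met))
  }
  # 10-metabolite model with 4 measured-significant: 6 sink pairs
  m <- three_exchange_model()   # 6 metabolites
  um2 <- build_ufba_model(m, rbind(rate_row("A_e", -1, compartment = "e"),
                                   rate_row("B_c", 0.5)))
  p2 <- add_relaxation_sinks(um2)
  expect_equal(p2$m, 4)
  expect_equal(sum(startsWith(p2$model$reactions$id, "UP_")), 4)
  expect_equal(sum(startsWith(p2$model$reactions$id, "DN_")), 4)
})

test_that("a consistent closed model needs no relaxation under any formulation", {
  m <- abc_chain_model()
  rates <- rbind(rate_row("A_c", -1, half = 0.1), rate_row("C_c", 1, half = 0.1))
  um <- build_ufba_model(m, rates)
  for (cs in 1:5) {
    prob <- add_relaxation_sinks(um, case = cs, iterations = 3)
    res <- solve_relaxation(prob)
    expect_length(res$iterations[[1]]$support, 0)
    # cases 3 and 5 also penalize intracellular flux, so only the pure
    # node-relaxation objectives are zero
    if (cs %in% c(1, 2, 4))
      expect_equal(res$objectives[1], 0, tolerance = 1e-6)
  }
})

test_that("minimum-cardinality relaxation matches exhaustive subset search on the chain", {
  # A depletes at 1, C measured but steady (non-significant, so treated as
  # unmeasured): the excess must surface at B or C
  m <- abc_chain_model()
  rates <- rbind(rate_row("A_c", -1, half = 0.05),
                 rate_row("C_c", 0, significant = FALSE))
  um <- build_ufba_model(m, rates)
  orc <- relaxation_oracle(um)
  expect_equal(orc$cardinality, 1)
  expect_setequal(vapply(orc$supports, paste, character(1)), c("B_c", "C_c"))

  prob <- add_relaxation_sinks(um, iterations = 8)
  res <- solve_relaxation(prob)
  expect_equal(length(res$iterations[[1]]$support), 1)
  for (it in res$iterations)
    expect_true(paste(it$support) %in% c("B_c", "C_c"))
  # both alternative optima are found and tallied
  expect_setequal(names(res$tally[res$tally > 0]), c("B_c", "C_c"))
  # direction: the excess accumulates
  res <- finalize_relaxation(prob, res)
  expect_equal(unname(res$final_set), "up")
})

test_that("symmetric twin pathways yield two equally tallied optima", {
  sc <- make_scenario("twin_pathway")
  um <- build_ufba_model(sc$model, true_rates(sc))
  prob <- add_relaxation_sinks(um, iterations = 10)
  res <- solve_relaxation(prob)
  expect_equal(res$n_iterations, 2)
  expect_equal(unname(res$tally[c("X1_c", "X2_c")]), c(1, 1))
  orc <- relaxation_oracle(um)
  expect_equal(orc$cardinality, 1)
  expect_setequal(vapply(orc$supports, paste, character(1)),
                  c("X1_c", "X2_c"))
})

test_that("integer cuts never repeat a support and iteration terminates", {
  set.seed(31)
  for (s in 1:5) {
    inst <- make_random_instance(n_mets = 7, n_rxns = 8, n_measured = 3,
                                 seed = 400 + s)
    prob <- add_relaxation_sinks(inst$model, iterations = 12)
    res <- solve_relaxation(prob)
    sup <- vapply(res$iterations, function(x)
      paste(sort(x$support), collapse = "+"), character(1))
    expect_equal(anyDuplicated(sup), 0L)
    expect_lte(res$n_iterations, 12)
  }
})

test_that("frequency weighting and extracellular preference drive the final choice", {
  sc <- make_scenario("twin_pathway")
  um <- build_ufba_model(sc$model, true_rates(sc))
  prob <- add_relaxation_sinks(um, iterations = 5)
  res <- solve_relaxation(prob)
  # degenerate tally: single iteration's solution is the final set
  res1 <- res; res1$iterations <- res$iterations[1]
  res1$n_iterations <- 1L
  res1$tally <- setNames(as.numeric(res$iterations[[1]]$relaxed),
                         prob$unmeasured)
  fin1 <- finalize_relaxation(prob, res1)
  expect_setequal(names(fin1$final_set), res$iterations[[1]]$support)

  # a node tallied 100/100 beats an equal-cardinality alternative at 40/100
  res2 <- res
  res2$n_iterations <- 100L
  res2$tally <- setNames(c(40, 100), c("X1_c", "X2_c"))
  fin2 <- finalize_relaxation(prob, res2)
  expect_equal(names(fin2$final_set), "X2_c")

  # extracellular preference picks the extracellular twin at equal tallies
  m <- new_model("exo_twin")
  m <- add_metabolite(m, "A_c", compartment = "c")
  m <- add_metabolite(m, "X1_c", compartment = "c")
  m <- add_metabolite(m, "X2_e", compartment = "e")
  m <- add_metabolite(m, "B_c", compartment = "c")
  m <- add_reaction(m, "R_A1", c(A_c = -1, X1_c = 1), 0, 1000)
  m <- add_reaction(m, "R_A2", c(A_c = -1, X2_e = 1), 0, 1000)
  m <- add_reaction(m, "R_1B", c(X1_c = -1, B_c = 1), 0, 1000)
  m <- add_reaction(m, "R_2B", c(X2_e = -1, B_c = 1), 0, 1000)
  um3 <- build_ufba_model(m, rbind(rate_row("A_c", -2), rate_row("B_c", 1)))
  prob3 <- add_relaxation_sinks(um3, iterations = 6, exo_preference = TRUE)
  res3 <- finalize_relaxation(prob3, solve_relaxation(prob3))
  expect_equal(names(res3$final_set), "X2_e")
})

test_that("magnitude fixing scales the minimized sink flux and stays feasible", {
  sc <- make_scenario("twin_pathway")
  um <- build_ufba_model(sc$model, true_rates(sc))
  for (scale in c(1, 1.5, 5)) {
    rel <- relax_model(um, iterations = 4, scale = scale)
    sinks <- c(rel$model$relaxation_sinks$up, rel$model$relaxation_sinks$down)
    ub <- rel$model$reactions$upper_bound[match(sinks, rel$model$reactions$id)]
    # minimal total sink flux is 0.9 (source CI low end minus product CI
    # high end); the active direction is scaled, the idle one closed
    expect_equal(sort(ub), sort(c(0, scale * 0.9)), tolerance = 1e-6)
    lpv <- ufbar:::model_lp(rel$model)
    expect_true(lp_feasible(lpv$S, rep(0, length(lpv$mets)), lpv$lb, lpv$ub))
  }
  rel <- relax_model(um, iterations = 2)
  expect_error(fix_relaxation_magnitudes(rel$model, scale = 0.5), "scale")
})

test_that("adding a steady measurement never shrinks the minimal relaxation", {
  for (s in 1:6) {
    inst <- make_random_instance(n_mets = 7, n_rxns = 8, n_measured = 2,
                                 seed = 500 + s)
    orc1 <- relaxation_oracle(inst$model, max_card = 5)
    um <- inst$model
    unmeasured <- setdiff(um$metabolites$id, um$measured)
    extra <- unmeasured[1]
    rates2 <- rbind(inst$rates, rate_row(extra, 0, half = 0,
                                         significant = TRUE))
    um2 <- build_ufba_model(inst$network, rates2)
    lpv <- ufbar:::model_lp(add_relaxation_sinks(um2)$model)
    if (!lp_feasible(lpv$S, rep(0, length(lpv$mets)), lpv$lb, lpv$ub))
      next   # pinning the node can make the instance outright inconsistent
    orc2 <- relaxation_oracle(um2, max_card = 5)
    expect_gte(orc2$cardinality, orc1$cardinality)
  }
})

test_that("the cardinality objective is never larger than the flux-magnitude support", {
  for (s in 1:4) {
    inst <- make_random_instance(n_mets = 7, n_rxns = 9, n_measured = 3,
                                 seed = 600 + s)
    p1 <- add_relaxation_sinks(inst$model, case = 1, iterations = 1)
    r1 <- solve_relaxation(p1)
    p2 <- add_relaxation_sinks(inst$model, case = 2, iterations = 1)
    r2 <- solve_relaxation(p2)
    expect_lte(length(r1$iterations[[1]]$support),
               length(r2$iterations[[1]]$support))
  }
})

test_that("quadratic relaxation splits symmetric twins evenly", {
  sc <- make_scenario("twin_pathway")
  um <- build_ufba_model(sc$model, true_rates(sc))
  prob <- add_relaxation_sinks(um, case = 4)
  res <- solve_relaxation(prob)
  d <- res$iterations[[1]]$d_up
  expect_setequal(names(d), c("X1_c", "X2_c"))
  expect_equal(unname(d["X1_c"]), unname(d["X2_c"]), tolerance = 1e-5)
  expect_equal(sum(d), 0.9, tolerance = 1e-5)
})

test_that("inconsistent measurements raise the stoichiometry error", {
  # single metabolite forced to deplete with nothing feeding it and no
  # unmeasured node to relax
  m <- abc_chain_model()
  rates <- rbind(rate_row("A_c", 1, half = 0.01),    # A accumulating
                 rate_row("B_c", 1, half = 0.01),
                 rate_row("C_c", 1, half = 0.01))    # everything accumulating
  um <- build_ufba_model(m, rates)
  prob <- add_relaxation_sinks(um)
  expect_error(solve_relaxation(prob), "inconsistent with stoichiometry")
})
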