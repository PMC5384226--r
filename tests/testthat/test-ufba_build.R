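test_that("uFBA construction closes the system and encodes rate intervals", {
  m <- three_exchange_model()
  # no significant rates: fully closed model, only zero flux feasible
  um <- build_ufba_model(m, rate_row("A_e", 0, significant = FALSE,
                                     compartment = "e"))
  expect_length(intersect(find_exchange_reactions(m), um$reactions$id), 0)
  expect_length(um$measured, 0)
  f <- fva(um)
  expect_true(all(abs(f$min) < 1e-9 & abs(f$max) < 1e-9))

  # a depleting intracellular pool gets strictly negative accumulation
  # bounds (rates ingested in per-hour units; -26.1 uM/day converts to
  # -26.1e-3/24 mmol/L/h)
  slope <- -26.1e-3 / 24
  um2 <- build_ufba_model(m, rate_row("B_c", slope, half = abs(slope) / 4))
  acc <- um2$accumulation[["B_c"]]
  i <- match(acc, um2$reactions$id)
  expect_lt(um2$reactions$upper_bound[i], 0)
  expect_equal(um2$reactions$lower_bound[i], slope - abs(slope) / 4)

  # extracellular and intracellular measurements are treated identically
  um3 <- build_ufba_model(m, rbind(rate_row("A_e", -1, compartment = "e"),
                                   rate_row("B_c", 0.5)))
  expect_setequal(um3$measured, c("A_e", "B_c"))
})

test_that("a measured depletion/accumulation pair pins the interior flux", {
  m <- abc_chain_model()
  rates <- rbind(rate_row("A_c", -1.5, half = 0), rate_row("C_c", 1.5, half = 0))
  um <- build_ufba_model(m, rates)
  f <- fva(um)
  expect_equal(f$min[f$reaction == "R_AB"], 1.5, tolerance = 1e-8)
  expect_equal(f$max[f$reaction == "R_AB"], 1.5, tolerance = 1e-8)
  opt <- optimize_model(um, "R_BC", "max")
  expect_equal(opt$objective, 1.5, tolerance = 1e-8)
})

test_that("rate-table validation rejects unknown and duplicated metabolites", {
  m <- abc_chain_model()
  expect_error(build_ufba_model(m, rate_row("Z_c", 1)), "unknown metabolite")
  expect_error(build_ufba_model(m, rbind(rate_row("A_c", 1),
                                         rate_row("A_c", 2))),
               "multiple rate estimates")
})

test_that("the FBA control frees efflux only for unmeasured extracellular metabolites", {
  m <- three_exchange_model()
  # no measurements: every extracellular metabolite gets efflux-only exchange
  ctl <- build_fba_control(m, rate_row("A_e", 0, significant = FALSE,
                                       compartment = "e"))
  eff <- grep("^EFF_", ctl$reactions$id, value = TRUE)
  expect_setequal(eff, paste0("EFF_", c("A_e", "B_e", "C_e")))
  i <- match(eff, ctl$reactions$id)
  expect_true(all(ctl$reactions$lower_bound[i] == 0))
  expect_true(all(ctl$reactions$upper_bound[i] > 0))

  # measured uptake only: that metabolite is interval-bounded, others
  # efflux-only; intracellular rates are dropped from the control
  ctl2 <- build_fba_control(m, rbind(rate_row("A_e", -2, compartment = "e"),
                                     rate_row("B_c", 1)))
  expect_setequal(ctl2$measured, "A_e")
  expect_setequal(grep("^EFF_", ctl2$reactions$id, value = TRUE),
                  paste0("EFF_", c("B_e", "C_e")))
})

test_that("the control can secrete an unmeasured metabolite the closed model forbids", {
  # the free-efflux failure mode: an unmeasured extracellular product can
  # leave the control system but not the closed unsteady model
  sc <- make_scenario("pool_depletion")
  rates <- true_rates(sc)
  um <- build_ufba_model(sc$model, rates)
  ctl <- build_fba_control(sc$model, rates)
  expect_false(any(grepl("L_e", um$reactions$id)))   # no outlet in uFBA
  expect_true("EFF_L_e" %in% ctl$reactions$id)
  f <- fva(ctl, "EFF_L_e")
  expect_gt(f$max, 0.1)        # the control is free to secrete the product
})

test_that("degrees of freedom grow with accumulation reactions as rank predicts", {
  # a fully closed mass-conserving network has a one-dimensional rank
  # deficiency (row sums of S cancel), so the first accumulation column
  # restores full row rank and each further one adds a degree of freedom:
  # DOF(k accumulations) = DOF(closed) + k - 1 for a connected network
  m <- abc_chain_model()
  closed <- remove_reactions(m, find_exchange_reactions(m))
  d0 <- model_dof(closed)
  um1 <- build_ufba_model(m, rate_row("A_c", -1))
  expect_equal(model_dof(um1), d0)
  um2 <- build_ufba_model(m, rbind(rate_row("A_c", -1), rate_row("C_c", 1)))
  expect_equal(model_dof(um2), d0 + 1)
  um3 <- build_ufba_model(m, rbind(rate_row("A_c", -1), rate_row("B_c", 0.2),
                                   rate_row("C_c", 0.8)))
  expect_equal(model_dof(um3), d0 + 2)
  # retained sinks contribute like accumulation columns
  prob <- add_relaxation_sinks(um2)
  expect_equal(model_dof(prob$model),
               model_dof(um2) + 2 * length(prob$unmeasured) - 0)
})

test_that("growth bounds and reserve sinks are applied when declared", {
  m <- make_toy_network("cofactor_rescue")
  rates <- rate_row("S_e", -10, half = 0.2, compartment = "e")
  um <- build_ufba_model(m, rates, growth_rate = c(5, 8),
                         reserves = "N_c")
  i <- match("GROWTH", um$reactions$id)
  expect_equal(um$reactions$lower_bound[i], 5)
  expect_equal(um$reactions$upper_bound[i], 8)
  expect_true("SK_N_c" %in% um$reactions$id)
  expect_error(build_ufba_model(abc_chain_model(), rate_row("A_c", -1),
                                growth_rate = c(0, 1)),
               "objective")
})
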