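test_that("FBA optimization respects bounds and reports infeasibility as a status", {
  m <- abc_chain_model()
  m <- set_bounds(m, "R_AB", 0, 10)
  rates <- rbind(rate_row("A_c", -10, half = 0), rate_row("C_c", 10, half = 0))
  um <- build_ufba_model(m, rates)
  opt <- optimize_model(um, "R_AB", "max")
  expect_equal(opt$objective, 10, tolerance = 1e-8)

  # forced depletion of A caps the achievable C accumulation at the rate
  um2 <- build_ufba_model(abc_chain_model(),
                          rbind(rate_row("A_c", -3, half = 0),
                                rate_row("C_c", 3, half = 0)))
  expect_equal(optimize_model(um2, "R_BC", "max")$objective, 3,
               tolerance = 1e-8)

  # contradictory rates: infeasible status, not an exception
  um3 <- build_ufba_model(abc_chain_model(),
                          rbind(rate_row("A_c", -1, half = 0),
                                rate_row("C_c", 5, half = 0)))
  expect_equal(optimize_model(um3, "R_AB", "max")$status, "infeasible")
})

test_that("FVA ranges follow bounds and blocked reactions", {
  m <- new_model()
  m <- add_metabolite(m, "A_c", compartment = "c")
  m <- add_metabolite(m, "B_c", compartment = "c")
  m <- add_reaction(m, "SRC", c(A_c = 1), 0, 10)
  m <- add_reaction(m, "R_AB", c(A_c = -1, B_c = 1), 0, 1000)
  m <- add_reaction(m, "SNK", c(B_c = -1), 0, 1000)
  m <- add_reaction(m, "DEAD", c(B_c = -1), 0, 0)
  f <- fva(m)
  expect_equal(f$range[f$reaction == "SRC"], 10)
  expect_equal(f$range[f$reaction == "R_AB"], 10)
  expect_equal(f$range[f$reaction == "DEAD"], 0)
  expect_true(all(f$range >= 0))
})

test_that("pool depletion widens some flux ranges and narrows most", {
  sc <- make_scenario("pool_depletion")
  rates <- true_rates(sc)
  rel_u <- relax_model(build_ufba_model(sc$model, rates),
                       iterations = 6, exo_preference = TRUE)
  ctl <- build_fba_control(sc$model, rates)
  f_u <- fva(rel_u$model)
  f_c <- fva(ctl)
  shared <- intersect(f_u$reaction, f_c$reaction)
  ru <- f_u$range[match(shared, f_u$reaction)]
  rc <- f_c$range[match(shared, f_c$reaction)]
  expect_gt(sum(ru > rc + 1e-6), 0)        # the pool grants flexibility
  # most ranges are equal or lower in the closed unsteady model
  expect_gt(sum(ru <= rc + 1e-6), sum(ru > rc + 1e-6))
})

test_that("hit-and-run sampling matches closed-form uniform moments", {
  # 1-D interval [0,1]: a source-sink pair pinning v1 = v2
  S <- matrix(c(1, -1), 1)
  for (seed in 1:5) {
    sm <- sample_polytope(S, c(0, 0), c(1, 1), n_samples = 600, seed = seed)
    se <- sd(sm$samples[, 1]) / sqrt(nrow(sm$samples))
    expect_lt(abs(mean(sm$samples[, 1]) - 0.5), 3 * se + 0.02)
    expect_lt(max(abs(S %*% t(sm$samples))), 1e-6)
  }

  # simplex v1 + v2 <= 1 via a shared precursor: marginal means 1/3
  S2 <- matrix(c(1, -1, -1), 1)
  for (seed in 1:5) {
    sm2 <- sample_polytope(S2, c(0, 0, 0), c(1, 1, 1), n_samples = 800,
                           seed = seed)
    for (j in 2:3) {
      se <- sd(sm2$samples[, j]) / sqrt(nrow(sm2$samples))
      expect_lt(abs(mean(sm2$samples[, j]) - 1 / 3), 3 * se + 0.02)
    }
  }

  # independent box dimensions: means at the box centers
  S3 <- matrix(0, 0, 2)
  sm3 <- sample_polytope(S3, c(-1, 2), c(1, 4), n_samples = 600, seed = 2)
  expect_lt(abs(mean(sm3$samples[, 1]) - 0), 0.1)
  expect_lt(abs(mean(sm3$samples[, 2]) - 3), 0.1)
})

test_that("a fully determined polytope yields identical samples and converges", {
  m <- abc_chain_model()
  rates <- rbind(rate_row("A_c", -2, half = 0), rate_row("C_c", 2, half = 0))
  um <- build_ufba_model(m, rates)
  sm <- sample_fluxes(um, n_samples = 50, seed = 1)
  expect_true(sm$converged)
  expect_equal(max(apply(sm$samples, 2, sd)), 0)
  expect_equal(unname(sm$samples[1, "R_AB"]), 2, tolerance = 1e-6)
  check_samples(um, sm)
})

test_that("flux comparison flags disjoint distributions and not self-comparisons", {
  sc <- make_scenario("branched")
  um <- relax_model(build_ufba_model(sc$model, true_rates(sc)),
                    iterations = 3)$model
  a <- sample_fluxes(um, n_samples = 400, seed = 1)
  b <- sample_fluxes(um, n_samples = 400, seed = 2)
  cmp <- compare_flux_states(a, b, um, um)
  expect_equal(sum(cmp$per_reaction$significant), 0)
  expect_gt(median(cmp$spearman), 0.7)

  # a model whose throughput sits in a disjoint range flags every pinned
  # reaction as significantly different
  mk_pinned <- function(level) {
    relax_model(build_ufba_model(
      make_toy_network("branched"),
      rbind(rate_row("A_e", -level, half = 0.05, compartment = "e"),
            rate_row("F_e", level, half = 0.05, compartment = "e"))),
      iterations = 3)$model
  }
  m2 <- mk_pinned(2)
  m3 <- mk_pinned(3)
  s2 <- sample_fluxes(m2, n_samples = 400, seed = 3)
  s3 <- sample_fluxes(m3, n_samples = 400, seed = 4)
  cmp2 <- compare_flux_states(s2, s3, m2, m3)
  r_ab <- cmp2$per_reaction[cmp2$per_reaction$reaction == "R_AB", ]
  expect_true(r_ab$significant)
  expect_equal(r_ab$overlap, 0)
})

test_that("internal cycles are detected and excluded", {
  # acyclic chain: no loops
  expect_length(exclude_loop_reactions(abc_chain_model()), 0)

  # two-reaction cycle
  m <- new_model()
  m <- add_metabolite(m, "A_c", compartment = "c")
  m <- add_metabolite(m, "B_c", compartment = "c")
  m <- add_reaction(m, "F", c(A_c = -1, B_c = 1), -1000, 1000)
  m <- add_reaction(m, "B", c(B_c = -1, A_c = 1), -1000, 1000)
  expect_setequal(exclude_loop_reactions(m), c("F", "B"))

  # 3-cycle plus a linear branch: exactly the cycle members
  m2 <- new_model()
  for (id in c("A_c", "B_c", "C_c", "D_c"))
    m2 <- add_metabolite(m2, id, compartment = "c")
  m2 <- add_reaction(m2, "C1", c(A_c = -1, B_c = 1), -1000, 1000)
  m2 <- add_reaction(m2, "C2", c(B_c = -1, C_c = 1), -1000, 1000)
  m2 <- add_reaction(m2, "C3", c(C_c = -1, A_c = 1), -1000, 1000)
  m2 <- add_reaction(m2, "LIN", c(A_c = -1, D_c = 1), 0, 1000)
  m2 <- add_reaction(m2, "EX_D", c(D_c = -1), 0, 1000)
  expect_setequal(exclude_loop_reactions(m2), c("C1", "C2", "C3"))
})

test_that("gene knockouts follow rule semantics and the growth threshold", {
  m <- make_toy_network("cofactor_rescue")
  rates <- rate_row("S_e", -10, half = 0.2, compartment = "e")
  um <- relax_model(build_ufba_model(m, rates), iterations = 3)$model
  ess <- gene_essentiality(um, "GROWTH", reference_growth = 9)
  # isozyme pair: knocking out one of an OR rule is non-essential
  expect_false(ess$essential[ess$gene == "gT1"])
  expect_false(ess$essential[ess$gene == "gT2"])
  # sole biosynthesis route without a measured pool: essential
  expect_true(ess$essential[ess$gene == "gB"])
  expect_error(gene_essentiality(um, "NOPE"), "growth reaction")
})

test_that("essentiality with an empty measured set equals plain FBA on the open model", {
  # reserve-fed network: growth draws the precursor from an internal store,
  # so openness does not hinge on an uptake exchange
  mk <- function() {
    m <- new_model("reservefed")
    m <- add_metabolite(m, "P_c", compartment = "c")
    m <- add_metabolite(m, "N_c", compartment = "c")
    m <- add_reaction(m, "BIOSYN", c(P_c = -1, N_c = 1), 0, 1000,
                      gene_rule = "gB")
    m <- add_reaction(m, "ALT", c(P_c = -1, N_c = 1), 0, 1000,
                      gene_rule = "gA1 and gA2")
    m <- add_reaction(m, "GROWTH", c(P_c = -1, N_c = -0.2), 0, 1000,
                      objective_coefficient = 1)
    m
  }
  open_model <- add_reaction(mk(), "SRC_P", c(P_c = -1), -10, 0)
  plain <- gene_essentiality(open_model, "GROWTH", reference_growth = 5)

  empty <- rate_row("P_c", 0, significant = FALSE)
  um <- build_ufba_model(mk(), empty, reserves = "P_c")
  um <- set_bounds(um, "SK_P_c", -10, 0)      # reserve capacity = open uptake
  ufba_calls <- gene_essentiality(um, "GROWTH", reference_growth = 5)
  expect_equal(ufba_calls$essential[match(plain$gene, ufba_calls$gene)],
               plain$essential)
})
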