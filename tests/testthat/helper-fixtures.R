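# Shared fixture builders for the test suite. Everything is constructed in
# code; no binary fixtures.

# A -> B -> C closed-system toy: A_c measured depleting at `rate`, C at the
# far end. Used for relaxation oracle cases.
abc_chain_model <- function() {
  m <- new_model("abc", compartments = c(c = "cytosol", e = "extracellular"))
  m <- add_metabolite(m, "A_c", compartment = "c")
  m <- add_metabolite(m, "B_c", compartment = "c")
  m <- add_metabolite(m, "C_c", compartment = "c")
  m <- add_reaction(m, "R_AB", c(A_c = -1, B_c = 1), 0, 1000)
  m <- add_reaction(m, "R_BC", c(B_c = -1, C_c = 1), 0, 1000)
  m
}

rate_row <- function(met, slope, half = 0.05, state = 1L,
                     significant = NA, compartment = "c") {
  if (is.na(significant)) significant <- abs(slope) > half
  data.frame(metabolite_id = met, compartment = compartment, state = state,
             slope = slope, b1 = slope - half, b2 = slope + half,
             significant = significant, stringsAsFactors = FALSE)
}

# small model with 3 true exchanges and 5 internal reactions
three_exchange_model <- function() {
  m <- new_model("threex")
  for (sp in list(c("A_e", "e"), c("B_e", "e"), c("C_e", "e"),
                  c("A_c", "c"), c("B_c", "c"), c("C_c", "c")))
    m <- add_metabolite(m, sp[1], compartment = sp[2])
  m <- add_reaction(m, "T_A", c(A_e = -1, A_c = 1))
  m <- add_reaction(m, "T_B", c(B_c = -1, B_e = 1))
  m <- add_reaction(m, "T_C", c(C_c = -1, C_e = 1))
  m <- add_reaction(m, "R_AB", c(A_c = -1, B_c = 1))
  m <- add_reaction(m, "R_AC", c(A_c = -1, C_c = 1))
  m <- add_reaction(m, "EX_A", c(A_e = -1))
  m <- add_reaction(m, "EX_B", c(B_e = -1))
  m <- add_reaction(m, "EX_C", c(C_e = -1))
  m
}

# simple time-course table builder
tc_table <- function(mets, times, fun, replicates = 1, compartment = "c") {
  do.call(rbind, lapply(mets, function(g)
    do.call(rbind, lapply(seq_len(replicates), function(r)
      data.frame(metabolite_id = g, compartment = compartment,
                 time = times, replicate = r,
                 concentration = fun(g, times, r),
                 stringsAsFactors = FALSE)))))
}
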