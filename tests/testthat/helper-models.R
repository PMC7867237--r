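# Small hand-built models shared across tests.

# linear chain: nutrient uptake (lb -5) -> conversion -> biomass sink
toy_chain_gem <- function(ex_lb = -5) {
  gem(list(
    list(id = "EX_a", lower_bound = ex_lb, upper_bound = 0,
         stoich = c(a = -1)),
    list(id = "R1", lower_bound = 0, upper_bound = 1000,
         stoich = c(a = -1, b = 1), gpr = "gA and gB"),
    list(id = "BIOMASS_toy", lower_bound = 0, upper_bound = 1000,
         stoich = c(b = -1), objective_coefficient = 1)
  ), model_id = "chain")
}

# two equivalent parallel routes from a to b (degenerate optimum)
toy_parallel_gem <- function() {
  gem(list(
    list(id = "EX_a", lower_bound = -5, upper_bound = 0,
         stoich = c(a = -1)),
    list(id = "P1", lower_bound = 0, upper_bound = 1000,
         stoich = c(a = -1, b = 1)),
    list(id = "P2", lower_bound = 0, upper_bound = 1000,
         stoich = c(a = -1, b = 1)),
    list(id = "BIOMASS_toy", lower_bound = 0, upper_bound = 1000,
         stoich = c(b = -1), objective_coefficient = 1)
  ), model_id = "parallel")
}

# two nutrients, one essential; exchanges open by default
toy_two_nutrient_gem <- function() {
  gem(list(
    list(id = "EX_glc", lower_bound = -1000, upper_bound = 1000,
         stoich = c(glc_e = -1)),
    list(id = "EX_gln", lower_bound = -1000, upper_bound = 1000,
         stoich = c(gln_e = -1)),
    list(id = "EX_lac", lower_bound = 0, upper_bound = 1000,
         stoich = c(lac_e = -1)),
    list(id = "T_glc", lower_bound = 0, upper_bound = 1000,
         stoich = c(glc_e = -1, glc_c = 1), gpr = "gT1 or gT2"),
    list(id = "T_gln", lower_bound = 0, upper_bound = 1000,
         stoich = c(gln_e = -1, gln_c = 1), gpr = "gT3"),
    list(id = "GLYC", lower_bound = 0, upper_bound = 1000,
         stoich = c(glc_c = -1, lac_e = 1), gpr = "gG1 and gG2"),
    list(id = "BIOMASS", lower_bound = 0, upper_bound = 1000,
         stoich = c(glc_c = -1, gln_c = -1), objective_coefficient = 1)
  ), model_id = "two_nutrient")
}
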