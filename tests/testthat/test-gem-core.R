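test_that("construction, exchange detection and the model report are consistent", {
  g <- toy_chain_gem()
  expect_s3_class(g, "gem")
  rep <- model_report(g)
  expect_equal(rep$n_reactions, 3L)
  expect_equal(rep$n_metabolites, 2L)
  expect_equal(rep$n_gpr_reactions, 1L)
  # EX_a and the single-metabolite biomass sink are both boundary reactions
  expect_equal(exchange_reactions(g), c("EX_a", "BIOMASS_toy"))
  expect_equal(rep$biomass_id, "BIOMASS_toy")

  g2 <- toy_two_nutrient_gem()
  expect_equal(exchange_reactions(g2), c("EX_glc", "EX_gln", "EX_lac"))
})

test_that("structural invariants are enforced at construction", {
  expect_error(gem(list(
    list(id = "R1", lower_bound = 5, upper_bound = -5, stoich = c(a = 1))
  )), "lower_bound > upper_bound")
  expect_error(gem(list(
    list(id = "R1", lower_bound = 0, upper_bound = 1, stoich = c(a = 1)),
    list(id = "R1", lower_bound = 0, upper_bound = 1, stoich = c(a = -1))
  )), "duplicate reaction")
  expect_error(gem(list(
    list(id = "R1", lower_bound = 0, upper_bound = 1, stoich = c(a = 1))
  ), metabolites = "b"), "undeclared metabolite")
})

test_that("biomass lookup uses the objective, then the id hint", {
  g <- toy_chain_gem()
  expect_equal(find_biomass_reaction(g), "BIOMASS_toy")

  no_obj <- gem(list(
    list(id = "EX_a", lower_bound = -5, upper_bound = 0, stoich = c(a = -1)),
    list(id = "biomass_rxn", lower_bound = 0, upper_bound = 10,
         stoich = c(a = -1))
  ))
  expect_equal(find_biomass_reaction(no_obj), "biomass_rxn")

  two_names <- gem(list(
    list(id = "biomass_1", lower_bound = 0, upper_bound = 10,
         stoich = c(a = -1)),
    list(id = "Biomass_2", lower_bound = 0, upper_bound = 10,
         stoich = c(a = 1))
  ))
  expect_error(find_biomass_reaction(two_names), "multiple reaction ids")
  expect_equal(find_biomass_reaction(two_names, hint = "biomass_1"),
               "biomass_1")
  expect_error(find_biomass_reaction(no_obj, hint = "nope"), "no reaction id")
})

test_that("exchange detection is invariant under reaction reordering", {
  g <- toy_two_nutrient_gem()
  perm <- c(4, 1, 7, 3, 6, 2, 5)
  reordered <- gem(lapply(perm, function(i) {
    col <- g$S[, i]
    list(id = g$reactions$id[i],
         lower_bound = g$reactions$lower_bound[i],
         upper_bound = g$reactions$upper_bound[i],
         gpr = g$reactions$gpr[i],
         objective_coefficient = g$reactions$objective_coefficient[i],
         stoich = col[col != 0])
  }), model_id = g$model_id)
  expect_setequal(exchange_reactions(reordered), exchange_reactions(g))
})

expect_same_model <- function(a, b) {
  expect_equal(a$reactions$id, b$reactions$id)
  expect_equal(a$reactions$lower_bound, b$reactions$lower_bound,
               tolerance = 1e-9)
  expect_equal(a$reactions$upper_bound, b$reactions$upper_bound,
               tolerance = 1e-9)
  expect_identical(a$reactions$gpr, b$reactions$gpr)
  expect_equal(a$reactions$objective_coefficient,
               b$reactions$objective_coefficient)
  expect_equal(sort(a$metabolites), sort(b$metabolites))
  expect_equal(as.matrix(a$S)[sort(a$metabolites), ],
               as.matrix(b$S)[sort(b$metabolites), ])
}

test_that("JSON and SBML round trips preserve the model", {
  g <- toy_two_nutrient_gem()
  jf <- withr::local_tempfile(fileext = ".json")
  sf <- withr::local_tempfile(fileext = ".xml")
  write_model(g, jf, format = "json")
  write_model(g, sf, format = "sbml")

  gj <- read_model(jf)
  gs <- read_model(sf)
  expect_same_model(gj, g)
  expect_same_model(gs, g)
  # GPR strings byte-for-byte
  expect_identical(gs$reactions$gpr, g$reactions$gpr)
  # the two serialisations agree with each other
  expect_same_model(gj, gs)
})

test_that("round trip preserves modified bounds and fractional stoichiometry", {
  g <- toy_two_nutrient_gem()
  g$reactions$lower_bound[2] <- -0.123456789
  g$reactions$upper_bound[4] <- 0.000314159
  validate_gem(g)
  for (fmt in c("json", "sbml")) {
    f <- withr::local_tempfile(fileext = if (fmt == "json") ".json" else ".xml")
    suppressWarnings(write_model(g, f, format = fmt))
    expect_same_model(read_model(f), g)
  }
})

test_that("reading malformed model files raises format errors", {
  bad_json <- withr::local_tempfile(fileext = ".json")
  writeLines('{"reactions": [{"id": "R1"}]}', bad_json)
  expect_error(read_json_model(bad_json), "no stoichiometry")

  bad_bounds <- withr::local_tempfile(fileext = ".json")
  writeLines(paste0('{"id":"x","metabolites":[{"id":"a"}],"reactions":',
                    '[{"id":"R1","metabolites":{"a":1},"lower_bound":5,',
                    '"upper_bound":-5}]}'), bad_bounds)
  expect_error(read_json_model(bad_bounds), "lower_bound > upper_bound")

  not_xml <- withr::local_tempfile(fileext = ".xml")
  writeLines("this is not sbml", not_xml)
  expect_error(read_sbml_model(not_xml), "not parseable")

  expect_error(read_model("/nonexistent/model.json"), "not found")
})

test_that("writing an objective-less model warns but succeeds", {
  g <- gem(list(
    list(id = "EX_a", lower_bound = -1, upper_bound = 0, stoich = c(a = -1)),
    list(id = "SINK_a", lower_bound = 0, upper_bound = 1, stoich = c(a = -1))
  ))
  f <- withr::local_tempfile(fileext = ".json")
  expect_warning(write_model(g, f, format = "json"), "empty objective")
  expect_equal(read_model(f)$reactions$id, g$reactions$id)
})
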