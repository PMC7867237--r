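ras_of <- function(...) {
  structure(list(condition = "c", ras = c(...), coverage = 1),
            class = "ras_profile")
}
mur_of <- function(...) {
  structure(list(condition = "c", mur = c(...)), class = "mur_profile")
}

test_that("RAS caps rewrite bounds symmetrically and never open a direction", {
  g <- gem(list(
    list(id = "REV", lower_bound = -1000, upper_bound = 1000,
         stoich = c(a = -1, b = 1), gpr = "g1"),
    list(id = "IRR", lower_bound = 0, upper_bound = 1000,
         stoich = c(b = -1, a = 1), gpr = "g2")
  ))
  out <- apply_ras_bounds(g, ras_of(REV = 10, IRR = 10), alpha = 0.001)
  expect_equal(out$reactions$lower_bound, c(-0.01, 0))
  expect_equal(out$reactions$upper_bound, c(0.01, 0.01))
  # the input model is untouched (value semantics)
  expect_equal(g$reactions$upper_bound, c(1000, 1000))
  expect_error(apply_ras_bounds(g, ras_of(REV = 1), alpha = 0), "positive")
  expect_error(apply_ras_bounds(g, ras_of(NOPE = 1), alpha = 1),
               "absent from the model")
})

test_that("zero RAS blocks or leaves a reaction according to policy", {
  g <- toy_chain_gem()
  blocked <- apply_ras_bounds(g, ras_of(R1 = 0), alpha = 0.5, "block")
  expect_equal(unlist(blocked$reactions[2, c("lower_bound", "upper_bound")]),
               c(lower_bound = 0, upper_bound = 0))
  left <- apply_ras_bounds(g, ras_of(R1 = 0), alpha = 0.5, "leave")
  expect_equal(left$reactions$upper_bound[2], 1000)
})

test_that("RAS caps only tighten: a cap beyond the original bound is inert", {
  g <- gem(list(list(id = "R", lower_bound = -2, upper_bound = 3,
                     stoich = c(a = 1), gpr = "g1")))
  out <- apply_ras_bounds(g, ras_of(R = 100), alpha = 1)  # cap 100 > bounds
  expect_equal(out$reactions$lower_bound, -2)
  expect_equal(out$reactions$upper_bound, 3)
})

test_that("MUR caps uptake only, leaving secretion and unmapped exchanges alone", {
  g <- toy_two_nutrient_gem()
  out <- apply_mur_bounds(g, mur_of(EX_gln = 4))
  i <- match("EX_gln", out$reactions$id)
  expect_equal(out$reactions$lower_bound[i], -4)
  expect_equal(out$reactions$upper_bound[i], 1000)  # secretion untouched
  # EX_glc unprofiled, policy leave -> default bounds
  expect_equal(out$reactions$lower_bound[match("EX_glc", out$reactions$id)],
               -1000)

  closed <- apply_mur_bounds(g, mur_of(EX_gln = 4), policy = "close")
  expect_equal(closed$reactions$lower_bound[
    match("EX_glc", closed$reactions$id)], 0)

  # zero availability forbids uptake entirely
  none <- apply_mur_bounds(g, mur_of(EX_gln = 0))
  expect_equal(none$reactions$lower_bound[i], 0)

  expect_error(apply_mur_bounds(g, mur_of(T_glc = 1)), "non-exchange")
})

test_that("variant composition validates its inputs and commutes", {
  g <- toy_two_nutrient_gem()
  ras <- compute_ras_profile(g, c(gT1 = 10, gT2 = 5, gT3 = 8, gG1 = 3,
                                  gG2 = 9))
  mur <- mur_of(EX_glc = 10, EX_gln = 4)
  cfg <- integration_config(alpha = 0.01, variant = "ras_mur")

  both <- build_condition_model(g, ras = ras, mur = mur, cfg = cfg)
  # manual composition in the opposite order gives the identical model
  other <- apply_ras_bounds(apply_mur_bounds(g, mur), ras, 0.01)
  expect_equal(both$reactions, other$reactions)

  expect_error(build_condition_model(g, ras = ras,
                                     cfg = cfg), "requires a MUR")
  expect_error(build_condition_model(
    g, ras = ras, mur = mur,
    cfg = integration_config(variant = "ras")), "does not take a MUR")
})

test_that("integration can only shrink the feasible box of every reaction", {
  set.seed(11)
  st <- make_fixture_study(fixture_spec(seed = 3))
  g <- st$gem
  for (alpha in c(1e-4, 1e-2, 1)) {
    for (cn in names(st$profiles)) {
      p <- st$profiles[[cn]]
      m <- build_condition_model(g, ras = p$ras, mur = p$mur,
                                 cfg = integration_config(alpha = alpha))
      expect_true(all(m$reactions$lower_bound >= g$reactions$lower_bound))
      expect_true(all(m$reactions$upper_bound <= g$reactions$upper_bound))
    }
  }
})

test_that("biomass vanishes in the zero-alpha limit", {
  st <- make_fixture_study(fixture_spec(seed = 2))
  p <- st$profiles[[1L]]
  m <- build_condition_model(st$gem, ras = p$ras, mur = p$mur,
                             cfg = integration_config(alpha = 1e-9))
  sol <- fba(m)
  expect_equal(sol$objective_value, 0, tolerance = 1e-4)
})
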