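test_that("fixture generation is fully deterministic per seed", {
  s <- fixture_spec(seed = 4)
  a <- make_fixture_study(s)
  b <- make_fixture_study(s)
  expect_equal(a$gem$reactions, b$gem$reactions)
  expect_identical(as.matrix(a$gem$S), as.matrix(b$gem$S))
  expect_identical(a$counts, b$counts)
  expect_equal(a$media, b$media)
  expect_equal(a$observations, b$observations)
  # a different seed produces a different study
  c <- make_fixture_study(fixture_spec(seed = 5))
  expect_false(identical(a$counts, c$counts))
})

test_that("generated models honour the requested shape and are growth-capable", {
  for (seed in 1:3) {
    spec <- fixture_spec(seed = seed, n_exchange = 2L)
    g <- make_toy_gem(spec)
    validate_gem(g)
    # one exchange per nutrient plus the byproduct outlet
    nut_ex <- grep("^EX_nut", exchange_reactions(g), value = TRUE)
    expect_length(nut_ex, 2L)
    # biomass drains at least two internal pools
    bio <- match("BIOMASS_toy", g$reactions$id)
    expect_gte(sum(g$S[, bio] != 0), 2L)
    sol <- fba(g)
    expect_equal(sol$status, "optimal")
    expect_gt(sol$objective_value, 0)
  }
})

test_that("expression counts are non-negative integers covering all GPR genes", {
  spec <- fixture_spec(seed = 6)
  g <- make_toy_gem(spec)
  counts <- make_expression_counts(spec, g)
  genes <- sort(unique(unlist(lapply(
    g$reactions$gpr[!is.na(g$reactions$gpr)],
    function(r) gpr_genes(parse_gpr(r))))))
  for (cn in names(counts)) {
    m <- counts[[cn]]
    expect_equal(sort(rownames(m)), genes)
    expect_equal(ncol(m), 3L)
    expect_true(all(m >= 0))
    expect_true(all(m == round(m)))
  }
  # conditions differ from one another
  expect_false(identical(counts[[1]], counts[[2]]))
})

test_that("media emulate the seven-condition two-nutrient design", {
  spec <- fixture_spec(seed = 1)
  media <- make_media(spec)
  conds <- unique(media$condition)
  expect_length(conds, 7L)
  expect_true(all(media$conc_initial_mM >= 0))
  b <- media[media$metabolite == "nutB", ]
  # zero-availability conditions for the essential nutrient exist
  expect_true(any(b$conc_initial_mM == 0))
  # requesting fewer conditions takes the head of the design
  expect_length(unique(make_media(fixture_spec(seed = 1,
                                               n_conditions = 3))$condition),
                3L)
})

test_that("noise-free observations are proportional to forward predictions", {
  spec <- fixture_spec(seed = 8, noise_cv = 0)
  st <- make_fixture_study(spec)
  flux <- vapply(names(st$profiles), function(cn) {
    p <- st$profiles[[cn]]
    m <- build_condition_model(st$gem, ras = p$ras, mur = p$mur,
                               cfg = integration_config(alpha = spec$true_alpha))
    fba(m)$objective_value
  }, numeric(1))
  obs <- st$observations$reciprocal_doubling_time
  grown <- !is.na(obs)
  expect_true(any(grown))
  ratio <- obs[grown] / flux[grown]
  expect_lt(diff(range(ratio)) / mean(ratio), 1e-9)
  # zero-flux conditions carry no observation
  expect_true(all(is.na(obs[flux <= 1e-6])))
})

test_that("fixture files round-trip through the pipeline readers", {
  dir <- withr::local_tempdir()
  st <- make_fixture_study(fixture_spec(seed = 9))
  write_fixture_files(st, dir)
  g <- read_model(file.path(dir, "model.json"))
  expect_equal(g$reactions$id, st$gem$reactions$id)
  gs <- read_model(file.path(dir, "model.xml"))
  expect_identical(gs$reactions$gpr, st$gem$reactions$gpr)
  media <- read_media_table(file.path(dir, "media.tsv"))
  expect_equal(nrow(media), nrow(st$media))
  cn <- names(st$counts)[1]
  m <- read_expression_table(file.path(dir, sprintf("expression_%s.tsv", cn)))
  expect_equal(unname(m), unname(st$counts[[cn]]))
})
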