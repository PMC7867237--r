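# Seeded synthetic fixtures: toy genome-scale models with GPRs, expression
# count tables, media tables, and forward-simulated growth observations.
#
# The generated study emulates the experimental design the package targets:
# a cell line cultured in seven media varying two nutrients (an abundant
# carbon source "nutA" and an essential amine source "nutB", the glucose /
# glutamine analogues), three count replicates per condition, spent-medium
# style availability data, and growth observables produced by the forward
# GEM-RAS-MUR model at a known alpha. Everything is deterministic per seed.

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Specification of a synthetic fixture study
#'
#' Defaults encode the emulated study design: seven conditions over two
#' varied nutrients (including zero-availability media for the essential
#' nutrient), three replicates, 5% multiplicative growth-measurement noise,
#' and a ground-truth `true_alpha` of 0.01 — placed in the rising region of
#' the biomass-versus-alpha curve for raw-count-scale expression, so
#' calibration is identifiable.
#'
#' @param seed integer seed driving every random choice.
#' @param n_exchange number of nutrient exchange reactions (>= 2; the first
#'   two are the varied nutrients, extras are fixed-availability).
#' @param n_internal_reactions number of random internal conversions added on
#'   top of the assimilation backbone.
#' @param genes_per_reaction integer range for genes in one GPR.
#' @param reversible_fraction fraction of random internal conversions made
#'   reversible.
#' @param n_conditions number of media conditions (<= 7 uses the canonical
#'   seven-condition design head-first).
#' @param noise_cv coefficient of variation of lognormal growth noise.
#' @param true_alpha positive ground-truth scale factor.
#' @return a `fixture_spec` list.
#' @export
fixture_spec <- function(seed = 1L, n_exchange = 3L,
                         n_internal_reactions = 4L,
                         genes_per_reaction = c(1L, 4L),
                         reversible_fraction = 0.3, n_conditions = 7L,
                         noise_cv = 0.05, true_alpha = 0.01) {
  stopifnot(n_exchange >= 2L, n_internal_reactions >= 0L,
            n_conditions >= 2L, noise_cv >= 0, true_alpha > 0,
            reversible_fraction >= 0, reversible_fraction <= 1)
  structure(list(seed = as.integer(seed), n_exchange = as.integer(n_exchange),
                 n_internal_reactions = as.integer(n_internal_reactions),
                 genes_per_reaction = as.integer(genes_per_reaction),
                 reversible_fraction = reversible_fraction,
                 n_conditions = as.integer(n_conditions),
                 noise_cv = noise_cv, true_alpha = true_alpha),
            class = "fixture_spec")
}

# random GPR over fresh gene ids; returns list(rule, n_genes_used)
random_gpr <- function(counter, lo, hi) {
  gid <- function(k) sprintf("g%03d", counter + k)
  form <- sample(c("single", "and", "or", "or_of_and"), 1L,
                 prob = c(0.3, 0.3, 0.2, 0.2))
  if (hi < 2L) form <- "single"
  switch(form,
    single = list(rule = gid(1L), used = 1L),
    and = list(rule = paste(gid(1L), "and", gid(2L)), used = 2L),
    or = list(rule = paste(gid(1L), "or", gid(2L)), used = 2L),
    or_of_and = if (hi >= 4L)
      list(rule = sprintf("(%s and %s) or (%s and %s)",
                          gid(1L), gid(2L), gid(3L), gid(4L)), used = 4L)
    else list(rule = paste(gid(1L), "or", gid(2L)), used = 2L))
}

#' Generate a toy genome-scale model
#'
#' The backbone is fixed: one exchange + assimilation reaction per nutrient,
#' a biomass reaction consuming the internal forms of the first two
#' nutrients (so the second nutrient is essential — its zero-availability
#' media cannot grow), and a secreted byproduct drained from the first
#' nutrient's pool. On top, `n_internal_reactions` random conversions are
#' added among the non-essential internal pools. Assimilation, byproduct and
#' conversion reactions carry random GPR rules (single genes, AND pairs,
#' OR-of-AND forms); exchanges and biomass carry none, as in genome-scale
#' reconstructions. Deterministic per `spec$seed`; regenerated with shifted
#' seeds (bounded retries) in the unlikely case the model cannot grow.
#'
#' @param spec a [fixture_spec()].
#' @return a [gem].
#' @export
make_toy_gem <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  for (attempt in 0:19) {
    g <- with_seed(spec$seed + 1000L * attempt, build_toy_gem(spec))
    sol <- fba(g)
    if (sol$status == "optimal" && sol$objective_value > 1e-6) return(g)
  }
  stop("fixture generation error: no growth-capable network within the ",
       "retry budget", call. = FALSE)
}

build_toy_gem <- function(spec) {
  nutrients <- c("nutA", "nutB",
                 if (spec$n_exchange > 2L)
                   sprintf("nut%s", LETTERS[3:spec$n_exchange]))
  pools <- sub("^nut", "Y", nutrients)  # internal forms YA, YB, ...
  lo <- spec$genes_per_reaction[1L]
  hi <- spec$genes_per_reaction[2L]
  gene_counter <- 0L
  rxns <- list()
  add <- function(r) rxns[[length(rxns) + 1L]] <<- r

  for (k in seq_along(nutrients)) {
    add(list(id = paste0("EX_", nutrients[k]),
             lower_bound = -1000, upper_bound = 1000,
             stoich = stats::setNames(-1, paste0("X", nutrients[k]))))
  }
  add(list(id = "EX_byp", lower_bound = 0, upper_bound = 1000,
           stoich = c(Xbyp = -1)))

  for (k in seq_along(nutrients)) {
    gp <- random_gpr(gene_counter, lo, hi)
    gene_counter <- gene_counter + gp$used
    add(list(id = paste0("T_", nutrients[k]),
             lower_bound = 0, upper_bound = 1000, gpr = gp$rule,
             stoich = stats::setNames(c(-1, 1),
                                      c(paste0("X", nutrients[k]), pools[k]))))
  }

  gp <- random_gpr(gene_counter, lo, hi)
  gene_counter <- gene_counter + gp$used
  add(list(id = "P_byp", lower_bound = 0, upper_bound = 1000, gpr = gp$rule,
           stoich = c(YA = -1, Xbyp = 1)))

  # random conversions among the non-essential pools (never producing YB,
  # which keeps nutB genuinely essential) and the byproduct precursor
  free_pools <- c(setdiff(pools, "YB"), "Xbyp")
  if (spec$n_internal_reactions > 0L) {
    for (k in seq_len(spec$n_internal_reactions)) {
      src <- sample(c(setdiff(pools, "YB")), 1L)
      dst <- sample(setdiff(free_pools, src), 1L)
      rev <- stats::runif(1) < spec$reversible_fraction
      gp <- random_gpr(gene_counter, lo, hi)
      gene_counter <- gene_counter + gp$used
      add(list(id = sprintf("C_%02d", k),
               lower_bound = if (rev) -1000 else 0, upper_bound = 1000,
               gpr = gp$rule,
               stoich = stats::setNames(c(-1, 1), c(src, dst))))
    }
  }

  add(list(id = "BIOMASS_toy", lower_bound = 0, upper_bound = 1000,
           stoich = c(YA = -1, YB = -1), objective_coefficient = 1))

  gem(rxns, model_id = sprintf("toy_seed%d", spec$seed))
}

#' Media tables for the synthetic conditions
#'
#' The canonical seven-condition design varies the two nutrients as
#' (A, B) = (10, 4), (2, 4), (10, 0), (2, 0), (25, 4), (2, 0.5), (2, 2) mM —
#' a grid including zero availability of the essential nutrient. Fewer
#' conditions take the head of this list; more extend it with seeded random
#' concentrations (essential nutrient kept positive). Extra nutrients beyond
#' the first two are fixed at 10 mM everywhere. All measurements are
#' availability-only (final concentration unknown) over a 48 h window.
#'
#' @param spec a [fixture_spec()].
#' @return data.frame with columns `condition`, `metabolite`, `exchange_id`,
#'   `conc_initial_mM`, `conc_final_mM` (`NA`), `t_hours`.
#' @export
make_media <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  base <- data.frame(
    a = c(10, 2, 10, 2, 25, 2, 2),
    b = c(4, 4, 0, 0, 4, 0.5, 2))
  design <- if (spec$n_conditions <= 7L) base[seq_len(spec$n_conditions), ]
  else rbind(base, with_seed(spec$seed + 77L, data.frame(
    a = round(stats::runif(spec$n_conditions - 7L, 1, 25), 1),
    b = round(stats::runif(spec$n_conditions - 7L, 0.5, 4), 1))))
  cond <- sprintf("A%gB%g", design$a, design$b)
  nutrients <- c("nutA", "nutB",
                 if (spec$n_exchange > 2L)
                   sprintf("nut%s", LETTERS[3:spec$n_exchange]))
  rows <- do.call(rbind, lapply(seq_along(cond), function(i) {
    conc <- c(design$a[i], design$b[i],
              rep(10, max(0L, spec$n_exchange - 2L)))
    data.frame(condition = cond[i], metabolite = nutrients,
               exchange_id = paste0("EX_", nutrients),
               conc_initial_mM = conc, conc_final_mM = NA_real_,
               t_hours = 48, stringsAsFactors = FALSE)
  }))
  rownames(rows) <- NULL
  rows
}

#' Expression count tables for the synthetic conditions
#'
#' Negative-binomial counts for every GPR gene of the model: per-gene
#' baseline means are lognormal (median 300, one log-sd), each condition
#' perturbs them by a mild lognormal factor (log-sd 0.2), and three
#' replicates are drawn with NB dispersion 0.1. Deterministic per
#' `spec$seed`.
#'
#' @param spec a [fixture_spec()].
#' @param g the [gem] from [make_toy_gem()].
#' @param conditions condition names; defaults to those of
#'   [make_media()].
#' @return named list (one element per condition) of integer gene x
#'   replicate matrices with gene-id rownames.
#' @export
make_expression_counts <- function(spec, g, conditions = NULL) {
  stopifnot(inherits(spec, "fixture_spec"))
  if (is.null(conditions)) conditions <- unique(make_media(spec)$condition)
  genes <- sort(unique(unlist(lapply(
    g$reactions$gpr[!is.na(g$reactions$gpr)],
    function(r) gpr_genes(parse_gpr(r))))))
  if (length(genes) == 0L)
    stop("model carries no GPR genes", call. = FALSE)
  with_seed(spec$seed + 1L, {
    base_mean <- stats::rlnorm(length(genes), meanlog = log(300), sdlog = 1)
    names(base_mean) <- genes
    out <- lapply(conditions, function(cn) {
      factor_c <- stats::rlnorm(length(genes), meanlog = 0, sdlog = 0.2)
      mu <- base_mean * factor_c
      m <- sapply(1:3, function(r)
        stats::rnbinom(length(genes), mu = mu, size = 10))
      dimnames(m) <- list(genes, paste0("rep", 1:3))
      m
    })
    names(out) <- conditions
    out
  })
}

#' Forward-simulate growth observations
#'
#' For each condition, builds the GEM-RAS-MUR model at the ground-truth
#' `true_alpha`, takes the FBA biomass optimum, scales it by a fixed positive
#' factor (0.005 reciprocal hours per flux unit) and multiplies by lognormal
#' noise of the requested coefficient of variation. Conditions whose forward
#' flux is (numerically) zero get no observation — cells that cannot grow
#' yield no doubling time.
#'
#' @param g the base [gem].
#' @param profiles named list per condition: `list(ras = , mur = )`.
#' @param true_alpha positive ground-truth alpha.
#' @param noise_cv coefficient of variation of the multiplicative noise.
#' @param seed integer seed.
#' @return data.frame `condition`, `reciprocal_doubling_time` (1/h, `NA`
#'   when absent).
#' @export
simulate_growth_observations <- function(g, profiles, true_alpha,
                                         noise_cv = 0.05, seed = 1L) {
  stopifnot(true_alpha > 0, noise_cv >= 0)
  flux <- vapply(profiles, function(p) {
    m <- build_condition_model(g, ras = p$ras, mur = p$mur,
                               cfg = integration_config(alpha = true_alpha))
    sol <- fba(m)
    if (sol$status != "optimal") 0 else sol$objective_value
  }, numeric(1))
  sdlog <- sqrt(log(1 + noise_cv^2))
  noise <- with_seed(seed + 2L,
                     stats::rlnorm(length(flux), meanlog = 0, sdlog = sdlog))
  obs <- ifelse(flux > 1e-6, 0.005 * flux * noise, NA_real_)
  data.frame(condition = names(profiles),
             reciprocal_doubling_time = obs,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Generate a complete synthetic study
#'
#' Convenience orchestrator: toy model, media, counts, per-condition RAS and
#' MUR profiles (raw-count mean aggregation — the scale at which the default
#' `true_alpha` is identifiable), and forward-simulated growth observations.
#'
#' @param spec a [fixture_spec()].
#' @return list with `spec`, `gem`, `media`, `counts`, `profiles` (named
#'   list of `list(ras, mur)`), `observations`.
#' @export
make_fixture_study <- function(spec = fixture_spec()) {
  g <- make_toy_gem(spec)
  media <- make_media(spec)
  conditions <- unique(media$condition)
  counts <- make_expression_counts(spec, g, conditions)
  profiles <- lapply(conditions, function(cn) {
    em <- aggregate_expression(counts[[cn]], normalization = "none",
                               combine = "mean")
    list(ras = compute_ras_profile(g, em, condition = cn),
         mur = build_mur_profile(cn, media[media$condition == cn, ], g))
  })
  names(profiles) <- conditions
  obs <- simulate_growth_observations(g, profiles, spec$true_alpha,
                                      spec$noise_cv, spec$seed)
  list(spec = spec, gem = g, media = media, counts = counts,
       profiles = profiles, observations = obs)
}

#' Write a synthetic study to files
#'
#' Writes the model (COBRA-JSON and SBML), one expression TSV per condition,
#' the media table and the observations YAML into `dir` — every input the
#' pipeline consumes, regenerable from a single seed.
#'
#' @param study result of [make_fixture_study()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_fixture_files <- function(study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_json_model(study$gem, file.path(dir, "model.json"))
  write_sbml_model(study$gem, file.path(dir, "model.xml"))
  utils::write.table(study$media, file.path(dir, "media.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  for (cn in names(study$counts)) {
    df <- data.frame(gene_id = rownames(study$counts[[cn]]),
                     study$counts[[cn]], check.names = FALSE)
    utils::write.table(df, file.path(dir, sprintf("expression_%s.tsv", cn)),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  obs <- stats::setNames(
    lapply(seq_len(nrow(study$observations)), function(i) {
      v <- study$observations$reciprocal_doubling_time[i]
      if (is.na(v)) NULL else v
    }), study$observations$condition)
  yaml::write_yaml(list(observations = obs),
                   file.path(dir, "observations.yaml"))
  invisible(dir)
}
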