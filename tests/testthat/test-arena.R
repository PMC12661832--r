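test_that("qPCR totals map onto the configured community-size range", {
  params <- arena_params()
  totals <- c(1.62e9, 7.5e10, 3.02e11)
  mk <- function(q) community_sample("s", "NB", c(a = 0.999, b = 0.001), q)
  lo <- scale_abundances(totals, mk(1.62e9), params)
  hi <- scale_abundances(totals, mk(3.02e11), params)
  # cohort min and max map exactly onto the 1000 / 5000 endpoints
  expect_equal(unname(lo["a"]), round(1000 * 0.999))
  expect_equal(unname(hi["a"]), round(5000 * 0.999))
  # the 0.1% species is floored at five individuals
  expect_identical(unname(lo["b"]), 5L)
  expect_identical(unname(hi["b"]), 5L)
  expect_warning(scale_abundances(c(2e10), mk(2e10), params), "midpoint")
  expect_error(
    scale_abundances(totals,
                     structure(list(sample_id = "s", group_label = "NB",
                                    members = c(a = 1, b = 0),
                                    qpcr_total = 2e10),
                               class = "community_sample"),
                     params),
    "zero abundance")
})

test_that("fair-share uptake bounds follow the stated rule", {
  params <- arena_params(vmax = 10)
  expect_equal(unname(compute_uptake_bounds(c(glc = 0), 10, 0.1, params)), 0)
  expect_equal(unname(compute_uptake_bounds(c(glc = 1e9), 10, 0.1, params)),
               10)
  # pool 10 mmol, 10 individuals, biomass 0.1 gDW, dt 1 h -> share 1 mmol,
  # specific rate 10 = exactly the cap
  expect_equal(unname(compute_uptake_bounds(c(glc = 10), 10, 0.1, params)),
               min(10, 10))
  b <- compute_uptake_bounds(c(glc = 1e9, o2 = 1e9), 1, 0.1, params)
  expect_equal(unname(b["o2"]), params$o2_mM)
  expect_error(compute_uptake_bounds(c(glc = -1), 1, 0.1, params),
               "non-negative")
})

test_that("emptying clears the exact cell count and pool share", {
  state <- list(individuals = data.frame(species = "a",
                                         cell = seq_len(5000),
                                         biomass = 1e-12),
                pools = c(glc = 8, ac = 2), n_cells = 10000)
  out <- withr::with_seed(1, apply_emptying(state, 0.25))
  expect_equal(attr(out, "emptied_cells"), 2500)
  expect_equal(out$pools, c(glc = 6, ac = 1.5))
  unchanged <- apply_emptying(state, 0)
  expect_identical(unchanged$individuals, state$individuals)
  expect_equal(unchanged$pools, state$pools)
  all_gone <- withr::with_seed(1, apply_emptying(state, 1))
  expect_identical(nrow(all_gone$individuals), 0L)
  expect_equal(unname(all_gone$pools), c(0, 0))
  expect_error(apply_emptying(state, 1.5), "fraction")
})

test_that("zero iterations and zero influx degenerate correctly", {
  models <- list(producer_A = toy_producer_model())
  counts <- c(producer_A = 10L)
  p0 <- small_arena(iterations = 0)
  sim <- run_simulation(models, counts, glc_only_diet(), p0, seed = 3)
  expect_identical(nrow(sim$records), 0L)
  expect_identical(nrow(sim$final_states[[1]]$individuals), 10L)
  expect_true(all(sim$final_states[[1]]$individuals$biomass ==
                    p0$ref_biomass))
  # nothing to eat: no growth, no exchange
  starved <- run_simulation(models, counts,
                            glc_only_diet(conc = 0), small_arena(), seed = 3)
  expect_identical(nrow(starved$records), 0L)
  expect_true(all(starved$final_states[[1]]$individuals$biomass ==
                    small_arena()$ref_biomass))
})

test_that("a strict consumer grows only when its feeder is present", {
  models <- list(producer_A = toy_producer_model(),
                 consumer_B = toy_consumer_model())
  params <- small_arena(iterations = 8)
  both <- run_simulation(models, c(producer_A = 20L, consumer_B = 20L),
                         glc_only_diet(), params, seed = 5)
  alone <- run_simulation(models["consumer_B"], c(consumer_B = 20L),
                          glc_only_diet(), params, seed = 5)
  bio_b <- function(sim) {
    ind <- sim$final_states[[1]]$individuals
    sum(ind$biomass[ind$species == "consumer_B"])
  }
  expect_gt(bio_b(both), 20 * params$ref_biomass)
  expect_equal(bio_b(alone), 20 * params$ref_biomass)
  # and the acetate hand-off is visible in the records
  tab <- extract_interactions(both$records)
  expect_true(any(tab$producer == "producer_A" &
                    tab$consumer == "consumer_B" & tab$metabolite == "ac"))
})

test_that("simulation is deterministic and respects grid capacity", {
  comm <- generate_community(community_config(n_species = 4), 2)
  diet <- generate_diet()
  params <- small_arena(iterations = 5, replicates = 2)
  counts <- suppressWarnings(scale_abundances(c(1e10), comm$sample, params))
  sim1 <- run_simulation(comm$models, counts, diet, params, seed = 9)
  sim2 <- run_simulation(comm$models, counts, diet, params, seed = 9)
  expect_identical(sim1$records, sim2$records)
  expect_identical(sim1$population, sim2$population)
  totals <- stats::aggregate(count ~ replicate + iteration,
                             sim1$population, sum)
  expect_true(all(totals$count <= params$grid_width * params$grid_height))
  expect_true(all(totals$count >= 0))
  # replicates differ (independent seeded streams)
  r1 <- sim1$records[sim1$records$replicate == 1, -which(names(sim1$records)
                                                         == "replicate")]
  r2 <- sim1$records[sim1$records$replicate == 2, -which(names(sim1$records)
                                                         == "replicate")]
  expect_false(identical(r1$flux, r2$flux))
})

test_that("mass accounting closes every iteration", {
  comm <- generate_community(community_config(n_species = 5), 4)
  diet <- generate_diet()
  params <- small_arena(iterations = 8)
  counts <- suppressWarnings(scale_abundances(c(1e10), comm$sample, params))
  sim <- run_simulation(comm$models, counts, diet, params, seed = 13)
  led <- sim$ledger
  resid <- with(led, end - (start + influx + produced - consumed - emptied))
  scale <- pmax(abs(led$start) + abs(led$influx) + abs(led$produced) +
                  abs(led$consumed) + abs(led$emptied), 1e-300)
  expect_lt(max(abs(resid) / scale), 1e-9)
  expect_true(all(sim$pools$amount >= -1e-15))
})

test_that("input validation catches missing models and over-capacity seeds", {
  models <- list(producer_A = toy_producer_model())
  expect_error(run_simulation(models, c(ghost = 5L), glc_only_diet(),
                              small_arena(), 1),
               "species without model")
  expect_error(run_simulation(models, c(producer_A = 10000L),
                              glc_only_diet(), small_arena(), 1),
               "capacity")
})
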