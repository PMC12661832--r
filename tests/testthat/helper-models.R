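# Fixture models built in code.

# linear chain: glucose uptake (cap set at solve time), conversion with
# biomass yield 0.5 per glucose -> growth = uptake / 2
toy_chain_model <- function() {
  gem("chain",
      list(metabolite("glc"), metabolite("bm")),
      list(reaction("EX_glc", c(glc = -1), -1000, 1000, is_exchange = TRUE),
           reaction("CONV", c(glc = -2, bm = 1), 0, 1000),
           reaction("BIOMASS", c(bm = -1), 0, 1000)),
      "BIOMASS")
}

# needs exactly glucose and ammonium; a third candidate is superfluous
toy_glc_nh4_model <- function() {
  gem("glc_nh4",
      list(metabolite("glc"), metabolite("nh4"), metabolite("xx"),
           metabolite("bm")),
      list(reaction("EX_glc", c(glc = -1), -1000, 1000, is_exchange = TRUE),
           reaction("EX_nh4", c(nh4 = -1), -1000, 1000, is_exchange = TRUE),
           reaction("EX_xx", c(xx = -1), -1000, 1000, is_exchange = TRUE),
           reaction("GROW", c(glc = -5, nh4 = -1, bm = 1), 0, 1000),
           reaction("BIOMASS", c(bm = -1), 0, 1000)),
      "BIOMASS")
}

# autotroph-like: biomass precursor made from nothing external
toy_selfsufficient_model <- function(ub = 0.5) {
  gem("selfsuff",
      list(metabolite("bm")),
      list(reaction("FIX", c(bm = 1), 0, ub),
           reaction("BIOMASS", c(bm = -1), 0, ub)),
      "BIOMASS")
}

# producer: glucose -> acetate exporter
toy_producer_model <- function() {
  gem("producer_A",
      list(metabolite("glc"), metabolite("ac"), metabolite("bm")),
      list(reaction("EX_glc", c(glc = -1), -1000, 1000, is_exchange = TRUE),
           reaction("EX_ac", c(ac = -1), -1000, 1000, is_exchange = TRUE),
           reaction("GROW", c(glc = -10, ac = 12, bm = 1), 0, 1000),
           reaction("BIOMASS", c(bm = -1), 0, 1000)),
      "BIOMASS")
}

# strict consumer: grows on acetate only
toy_consumer_model <- function() {
  gem("consumer_B",
      list(metabolite("ac"), metabolite("bm")),
      list(reaction("EX_ac", c(ac = -1), -1000, 1000, is_exchange = TRUE),
           reaction("GROW", c(ac = -8, bm = 1), 0, 1000),
           reaction("BIOMASS", c(bm = -1), 0, 1000)),
      "BIOMASS")
}

fixture_models <- function() {
  list(chain = toy_chain_model(),
       glc_nh4 = toy_glc_nh4_model(),
       producer = toy_producer_model(),
       consumer = toy_consumer_model())
}

# minimal diet containing only glucose (e.g. for producer/consumer pairs)
glc_only_diet <- function(conc = 20) {
  diet_spec(data.frame(metabolite = "glc", raw_concentration = conc,
                       absorption_fraction = 0))
}

small_arena <- function(...) {
  args <- list(grid_width = 12, grid_height = 12, iterations = 6,
               replicates = 1, community_size_range = c(20, 60),
               min_individuals_per_species = 5)
  ov <- list(...)
  args[names(ov)] <- ov
  do.call(arena_params, args)
}
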