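# Spatial individual-based dynamic-FBA simulator of the cecum.
#
# Individuals live on a rectangular grid (one per cell), each carrying a
# species model and a biomass. Every hourly iteration the diet influx is
# added and the metabolite pools are fully mixed across the grid (the
# luminal contents of the cecum are treated as well stirred); individuals
# then take up nutrients under fair-share rationing, grow by Euler update,
# divide when they double their seeding biomass, take one random-walk
# step, and every `empty_every` iterations a random fraction of grid cells
# is cleared (cecal emptying), removing both the individuals and the
# corresponding share of the mixed pools.

#' Arena simulation parameters
#'
#' Defaults encode the simulated cecal conditions: a 100 x 100 grid, 16
#' hourly iterations, 5 replicates, 25% emptying every 4th iteration,
#' ambient oxygen 1e-8 mM, pH 7 (recorded metadata; no kinetic effect),
#' community sizes rescaled into 1000-5000 individuals with at least 5 per
#' species.
#'
#' @param grid_width,grid_height grid dimensions (cells).
#' @param iterations number of hourly iterations.
#' @param replicates number of stochastic replicates.
#' @param empty_every emptying period (iterations).
#' @param empty_fraction fraction of grid cells cleared at each emptying.
#' @param o2_mM ambient oxygen concentration; also used as the fixed O2
#'   uptake cap (mmol/gDW/h), rendering the arena effectively anaerobic.
#' @param ph luminal pH, carried as metadata only.
#' @param community_size_range range onto which log qPCR totals are
#'   rescaled.
#' @param min_individuals_per_species floor on per-species individual
#'   counts.
#' @param cell_volume luminal volume represented by one grid cell (L);
#'   converts influx concentrations (mM) into pool amounts (mmol).
#' @param timestep iteration duration (h).
#' @param vmax default per-metabolite uptake cap (mmol/gDW/h).
#' @param ref_biomass seeding biomass of one individual (gDW); division
#'   triggers at twice this value.
#' @param preload_influx logical; pre-load one influx dose at t = 0 so the
#'   first hour is not universally starved.
#' @param o2_id metabolite id treated as oxygen.
#' @return list of class `arena_params`.
#' @export
arena_params <- function(grid_width = 100, grid_height = 100,
                         iterations = 16, replicates = 5,
                         empty_every = 4, empty_fraction = 0.25,
                         o2_mM = 1e-8, ph = 7,
                         community_size_range = c(1000, 5000),
                         min_individuals_per_species = 5,
                         cell_volume = 1e-12, timestep = 1,
                         vmax = 10, ref_biomass = 1e-12,
                         preload_influx = TRUE, o2_id = "o2") {
  if (empty_fraction < 0 || empty_fraction > 1) {
    stop("empty_fraction must lie in [0, 1]")
  }
  if (community_size_range[1L] > community_size_range[2L]) {
    stop("community_size_range must be increasing")
  }
  if (grid_width < 1 || grid_height < 1 || iterations < 0 || replicates < 1) {
    stop("grid dimensions and counts must be positive")
  }
  structure(as.list(environment()), class = "arena_params")
}

#' Rescale qPCR totals to individual counts
#'
#' The natural log of each sample's total 16S abundance is rescaled
#' linearly from the cohort's \[ln min, ln max\] onto
#' `community_size_range` (1000-5000 by default); per-species counts are
#' the rescaled total times relative abundance, floored at
#' `min_individuals_per_species`.
#'
#' @param qpcr_totals numeric vector of cohort totals (copies/g), used for
#'   the min/max anchors.
#' @param sample a [community_sample()].
#' @param params an [arena_params()].
#' @return named integer vector of per-species individual counts.
#' @export
scale_abundances <- function(qpcr_totals, sample, params = arena_params()) {
  if (any(qpcr_totals <= 0)) stop("qPCR totals must be positive")
  if (any(sample$members <= 0)) stop("zero abundance species in sample")
  lo <- log(min(qpcr_totals)); hi <- log(max(qpcr_totals))
  rng <- params$community_size_range
  if (hi - lo < .Machine$double.eps) {
    warning("single qPCR total: using midpoint of community_size_range")
    total <- mean(rng)
  } else {
    total <- rng[1L] + (log(sample$qpcr_total) - lo) / (hi - lo) *
      (rng[2L] - rng[1L])
  }
  counts <- pmax(params$min_individuals_per_species,
                 round(total * sample$members))
  stats::setNames(as.integer(counts), names(sample$members))
}

#' Fair-share uptake bounds for one individual
#'
#' Each metabolite's uptake bound is the smaller of the default cap `vmax`
#' and the individual's fair share of the mixed pool
#' (`pool / n_individuals`) converted to a specific rate by dividing by
#' `biomass * timestep`. Oxygen is capped at the fixed ambient-derived
#' value regardless of pools.
#'
#' @param pools named numeric vector of pool amounts (mmol).
#' @param n_individuals current number of individuals in the arena.
#' @param biomass this individual's biomass (gDW).
#' @param params an [arena_params()].
#' @return named numeric vector of maximal uptake rates (mmol/gDW/h).
#' @export
compute_uptake_bounds <- function(pools, n_individuals, biomass,
                                  params = arena_params()) {
  if (any(pools < 0)) stop("pools must be non-negative")
  share <- pools / max(1L, n_individuals)
  b <- pmin(params$vmax, share / (biomass * params$timestep))
  names(b) <- names(pools)
  if (params$o2_id %in% names(b)) b[params$o2_id] <- params$o2_mM
  b
}

#' Apply cecal emptying to an arena state
#'
#' Exactly `round(fraction * n_cells)` distinct cells are chosen uniformly;
#' their individuals are removed and the fully mixed pools are reduced by
#' the share residing in the emptied cells.
#'
#' @param state list with `individuals` (data.frame: species, cell,
#'   biomass) and `pools` (named numeric), plus `n_cells`.
#' @param fraction fraction of cells to clear, in \[0,1\].
#' @return the updated state; attribute `emptied_pool` records the amount
#'   of each metabolite removed.
#' @export
apply_emptying <- function(state, fraction) {
  if (fraction < 0 || fraction > 1) stop("fraction must lie in [0, 1]")
  n_cells <- state$n_cells
  n_remove <- round(fraction * n_cells)
  removed_share <- n_remove / n_cells
  cells <- if (n_remove > 0L) sample.int(n_cells, n_remove) else integer()
  keep <- !(state$individuals$cell %in% cells)
  state$individuals <- state$individuals[keep, , drop = FALSE]
  loss <- state$pools * removed_share
  state$pools <- state$pools - loss
  attr(state, "emptied_pool") <- loss
  attr(state, "emptied_cells") <- n_remove
  state
}

# neighbor cells (8-neighborhood, no wrap) of cell index (1-based,
# column-major: cell = (y - 1) * width + x)
neighbor_cells <- function(cell, width, height) {
  x <- (cell - 1L) %% width + 1L
  y <- (cell - 1L) %/% width + 1L
  nx <- x + c(-1L, 0L, 1L, -1L, 1L, -1L, 0L, 1L)
  ny <- y + c(-1L, -1L, -1L, 0L, 0L, 1L, 1L, 1L)
  ok <- nx >= 1L & nx <= width & ny >= 1L & ny <= height
  (ny[ok] - 1L) * width + nx[ok]
}

#' Run the spatial dynamic-FBA community simulation
#'
#' @param models named list of [gem()]s (names are species ids).
#' @param counts named integer vector of initial individuals per species
#'   (see [scale_abundances()]).
#' @param diet a [diet_spec()]; its influx concentrations are converted to
#'   per-hour pool doses via the cell volume and grid size.
#' @param params an [arena_params()].
#' @param seed integer seed; replicate r uses `seed + r`.
#' @return object of class `cecum_sim`: list with `records` (replicate,
#'   iteration, species, metabolite, flux mmol/gDW/h, amount mmol),
#'   `population` (per replicate/iteration/species counts and biomass, as
#'   acting at that hour), `pools` (per replicate/iteration pool amounts at
#'   the end of the hour; iteration 0 is the seeded state), `ledger`
#'   (per-metabolite mass accounting), `params`, `seed`, and `final_states`.
#' @export
run_simulation <- function(models, counts, diet, params = arena_params(),
                           seed = 1) {
  missing_models <- setdiff(names(counts), names(models))
  if (length(missing_models) > 0L) {
    stop("species without model: ", paste(missing_models, collapse = ", "))
  }
  n_cells <- params$grid_width * params$grid_height
  if (sum(counts) > n_cells) stop("initial community exceeds grid capacity")

  influx_conc <- stats::setNames(diet$influx_concentration, diet$metabolite)
  influx_dose <- influx_conc * params$cell_volume * n_cells
  met_ids <- sort(unique(c(names(influx_dose),
                           unlist(lapply(models, exchange_metabolites),
                                  use.names = FALSE))))
  dose <- stats::setNames(numeric(length(met_ids)), met_ids)
  dose[names(influx_dose)] <- influx_dose

  rec_all <- list(); pop_all <- list(); pool_all <- list(); led_all <- list()
  finals <- list()
  species_ids <- names(counts)

  for (r in seq_len(params$replicates)) {
    res <- with_seed(seed + r, {
      simulate_replicate(models, counts, dose, met_ids, params, n_cells)
    })
    add_rep <- function(df) { df$replicate <- rep(r, nrow(df)); df }
    res$records <- add_rep(res$records)
    res$population <- add_rep(res$population)
    res$pools <- add_rep(res$pools)
    res$ledger <- add_rep(res$ledger)
    rec_all[[r]] <- res$records
    pop_all[[r]] <- res$population
    pool_all[[r]] <- res$pools
    led_all[[r]] <- res$ledger
    finals[[r]] <- res$state
  }
  out <- list(records = do.call(rbind, rec_all),
              population = do.call(rbind, pop_all),
              pools = do.call(rbind, pool_all),
              ledger = do.call(rbind, led_all),
              params = params, seed = seed, species = species_ids,
              final_states = finals)
  class(out) <- "cecum_sim"
  out
}

simulate_replicate <- function(models, counts, dose, met_ids, params,
                               n_cells) {
  total0 <- sum(counts)
  species <- rep(names(counts), counts)
  cells <- sample.int(n_cells, total0)
  ind <- data.frame(species = species, cell = cells,
                    biomass = rep(params$ref_biomass, total0),
                    stringsAsFactors = FALSE)
  occupied <- logical(n_cells)
  occupied[cells] <- TRUE
  pools <- stats::setNames(numeric(length(met_ids)), met_ids)
  if (params$preload_influx) pools <- pools + dose

  ex_mets <- lapply(models, exchange_metabolites)   # EX rxn id -> met
  probs <- lapply(models, compile_fba)
  cache <- new.env(parent = emptyenv())
  recs <- list(); pops <- list(); poolrows <- list(); ledrows <- list()
  poolrows[[1L]] <- data.frame(iteration = 0L, metabolite = met_ids,
                               amount = as.numeric(pools),
                               stringsAsFactors = FALSE)

  n_iter <- params$iterations
  dt <- params$timestep
  for (it in seq_len(n_iter)) {
    pool_start <- pools
    pools <- pools + dose                      # influx, evenly mixed
    n_ind <- nrow(ind)
    prod_amt <- cons_amt <- stats::setNames(numeric(length(met_ids)), met_ids)
    # per species x metabolite accumulators
    amt <- matrix(0, length(models), length(met_ids),
                  dimnames = list(names(models), met_ids))
    bio_acted <- stats::setNames(numeric(length(models)), names(models))
    cnt <- table(factor(ind$species, levels = names(models)))

    if (n_ind > 0L) {
      order_idx <- sample.int(n_ind)
      for (i in order_idx) {
        sp <- ind$species[i]
        mets <- ex_mets[[sp]]
        bmass <- ind$biomass[i]
        ub <- compute_uptake_bounds(pools[mets], n_ind, bmass, params)
        names(ub) <- mets
        # fluxes depend on the model only through the bound vector
        key <- paste(sp, paste(signif(ub, 12), collapse = ","), sep = "|")
        sol <- cache[[key]]
        if (is.null(sol)) {
          sol <- solve_fba_compiled(probs[[sp]], ub)
          cache[[key]] <- sol
        }
        if (sol$status != "optimal") next      # idle individual
        vex <- sol$fluxes[names(mets)]         # EX reaction fluxes
        dmet <- vex * bmass * dt               # mmol; positive = export
        # guard against tolerance-level overdraw of a pool
        take <- -pmin(dmet, 0)
        over <- take > pools[mets]
        if (any(over)) {
          dmet[over] <- -pools[mets][over]
          take <- -pmin(dmet, 0)
        }
        pools[mets] <- pools[mets] + dmet
        amt[sp, mets] <- amt[sp, mets] + dmet
        bio_acted[sp] <- bio_acted[sp] + bmass
        ind$biomass[i] <- bmass +
          sol$objective_value * bmass * dt     # Euler growth
      }
    }

    # division: daughters take half the biomass, placed in a free neighbor
    if (nrow(ind) > 0L) {
      div_idx <- which(ind$biomass >= 2 * params$ref_biomass)
      if (length(div_idx) > 0L) div_idx <- div_idx[sample.int(length(div_idx))]
      for (i in div_idx) {
        nb <- neighbor_cells(ind$cell[i], params$grid_width,
                             params$grid_height)
        free <- nb[!occupied[nb]]
        if (length(free) == 0L) next
        target <- free[sample.int(length(free), 1L)]
        half <- ind$biomass[i] / 2
        ind$biomass[i] <- half
        ind <- rbind(ind, data.frame(species = ind$species[i], cell = target,
                                     biomass = half, stringsAsFactors = FALSE))
        occupied[target] <- TRUE
      }
    }

    # movement: one random-walk step into a free neighboring cell
    if (nrow(ind) > 0L) {
      for (i in sample.int(nrow(ind))) {
        nb <- neighbor_cells(ind$cell[i], params$grid_width,
                             params$grid_height)
        free <- nb[!occupied[nb]]
        if (length(free) == 0L) next
        target <- free[sample.int(length(free), 1L)]
        occupied[ind$cell[i]] <- FALSE
        ind$cell[i] <- target
        occupied[target] <- TRUE
      }
    }

    # emptying on schedule
    emptied <- stats::setNames(numeric(length(met_ids)), met_ids)
    if (params$empty_every > 0 && it %% params$empty_every == 0L) {
      state <- list(individuals = ind, pools = pools, n_cells = n_cells)
      state <- apply_emptying(state, params$empty_fraction)
      ind <- state$individuals
      pools <- state$pools
      emptied <- attr(state, "emptied_pool")
      occupied[] <- FALSE
      occupied[ind$cell] <- TRUE
    }

    nz <- which(amt != 0, arr.ind = TRUE)
    if (nrow(nz) > 0L) {
      sp_nz <- rownames(amt)[nz[, 1L]]
      recs[[it]] <- data.frame(
        iteration = it,
        species = sp_nz,
        metabolite = colnames(amt)[nz[, 2L]],
        flux = amt[nz] / (bio_acted[sp_nz] * dt),
        amount = amt[nz],
        stringsAsFactors = FALSE)
    }
    pops[[it]] <- data.frame(iteration = it,
                             species = names(models),
                             count = as.integer(cnt[names(models)]),
                             biomass = as.numeric(bio_acted),
                             stringsAsFactors = FALSE)
    poolrows[[it + 1L]] <- data.frame(iteration = it, metabolite = met_ids,
                                      amount = as.numeric(pools),
                                      stringsAsFactors = FALSE)
    produced <- colSums(pmax(amt, 0))
    consumed <- -colSums(pmin(amt, 0))
    ledrows[[it]] <- data.frame(
      iteration = it, metabolite = met_ids,
      start = as.numeric(pool_start), influx = as.numeric(dose),
      produced = as.numeric(produced), consumed = as.numeric(consumed),
      emptied = as.numeric(emptied), end = as.numeric(pools),
      stringsAsFactors = FALSE)
  }

  empty_rec <- data.frame(iteration = integer(), species = character(),
                          metabolite = character(), flux = numeric(),
                          amount = numeric(), stringsAsFactors = FALSE)
  list(records = if (length(recs) > 0L) do.call(rbind, recs) else empty_rec,
       population = do.call(rbind, pops) %||% data.frame(
         iteration = integer(), species = character(), count = integer(),
         biomass = numeric(), stringsAsFactors = FALSE),
       pools = do.call(rbind, poolrows),
       ledger = if (length(ledrows) > 0L) do.call(rbind, ledrows) else
         data.frame(iteration = integer(), metabolite = character(),
                    start = numeric(), influx = numeric(),
                    produced = numeric(), consumed = numeric(),
                    emptied = numeric(), end = numeric(),
                    stringsAsFactors = FALSE),
       state = list(individuals = ind, pools = pools, n_cells = n_cells))
}

#' @export
print.cecum_sim <- function(x, ...) {
  cat("<cecum_sim>", length(x$species), "species,",
      x$params$iterations, "iterations,",
      x$params$replicates, "replicates\n")
  cat("  grid:", x$params$grid_width, "x", x$params$grid_height,
      " seed:", x$seed, "\n")
  cat("  flux records:", nrow(x$records), "\n")
  invisible(x)
}

#' @export
summary.cecum_sim <- function(object, ...) {
  pop <- object$population
  last <- pop[pop$iteration == max(pop$iteration), ]
  agg <- stats::aggregate(count ~ species, last, mean)
  cat("Final mean population by species (over replicates):\n")
  print(agg, row.names = FALSE)
  if (nrow(object$records) > 0L) {
    net <- stats::aggregate(amount ~ metabolite, object$records, sum)
    net$amount <- net$amount / object$params$replicates
    cat("\nNet exchange per metabolite (mmol, mean over replicates):\n")
    print(net[order(-abs(net$amount)), ], row.names = FALSE)
  }
  invisible(object)
}

#' Plot population and pool trajectories of a simulation
#'
#' @param x a `cecum_sim`.
#' @param replicate which replicate to draw.
#' @param ... passed to [graphics::matplot()].
#' @export
plot.cecum_sim <- function(x, replicate = 1, ...) {
  pop <- x$population[x$population$replicate == replicate, ]
  if (nrow(pop) == 0L) return(invisible(x))
  w <- stats::reshape(pop[, c("iteration", "species", "count")],
                      idvar = "iteration", timevar = "species",
                      direction = "wide")
  old <- graphics::par(mfrow = c(1, 2), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(old))
  graphics::matplot(w$iteration, as.matrix(w[, -1L]), type = "l", lty = 1,
                    xlab = "iteration (h)", ylab = "individuals",
                    main = "population", ...)
  pl <- x$pools[x$pools$replicate == replicate,
                c("iteration", "metabolite", "amount")]
  wp <- stats::reshape(pl, idvar = "iteration", timevar = "metabolite",
                       direction = "wide")
  graphics::matplot(wp$iteration, as.matrix(wp[, -1L]), type = "l", lty = 1,
                    xlab = "iteration (h)", ylab = "pool (mmol)",
                    main = "metabolite pools", ...)
  invisible(x)
}
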