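# Synthetic toy communities with planted cross-feeding structure.
#
# The generator assembles small hand-checkable models from a closed motif
# library rather than random stoichiometry, so every growth optimum can be
# verified analytically and every intended producer -> consumer edge is
# recorded as ground truth. The keystone motif is a primary polysaccharide
# degrader (a *Bacteroides fragilis* analogue) that liberates sugars and
# succinate for the rest of the community; communities with it model the
# high-*Bacteroides* (HB-like) state, communities without it the
# no-*Bacteroides* (NB-like) state.

motif_names <- function() {
  c("degrader", "fermenter", "generalist", "butyrate_producer", "auxotroph")
}

# One conversion route: substrates/products per unit biomass, with EC and
# pathway annotation. Biomass precursor "bm" is the only internal
# metabolite; the biomass reaction drains it and its flux is the growth
# rate.
motif_routes <- function(motif) {
  switch(motif,
    degrader = list(
      R_starch = list(st = c(starch = -8, urea = -2, glc = 3, succ = 3, bm = 1),
                      ec = c("3.2.1.3", "3.5.1.5"),
                      pw = c("starch degradation", "urea utilization")),
      R_fiber = list(st = c(fiber = -8, urea = -2, glc = 2, succ = 2, bm = 1),
                     ec = c("3.2.1.4"),
                     pw = c("cellulose degradation"))),
    fermenter = list(
      R_ferm = list(st = c(glc = -10, urea = -2, lac = 15, bm = 1),
                    ec = c("1.1.1.27", "3.5.1.5"),
                    pw = c("glycolysis", "lactate fermentation"))),
    generalist = list(
      R_glc = list(st = c(glc = -10, urea = -2, ac = 12, bm = 1),
                   ec = c("2.7.2.1", "3.5.1.5"),
                   pw = c("glycolysis", "acetate fermentation")),
      R_mucin = list(st = c(mucin = -10, urea = -2, ac = 10, bm = 1),
                     ec = c("3.2.1.18"),
                     pw = c("mucin degradation", "acetate fermentation"))),
    butyrate_producer = list(
      R_but_ac = list(st = c(ac = -10, urea = -2, but = 4, bm = 1),
                      ec = c("2.8.3.8"),
                      pw = c("butyrate fermentation")),
      R_but_lac = list(st = c(lac = -10, urea = -2, but = 4, bm = 1),
                       ec = c("2.7.2.7"),
                       pw = c("butyrate fermentation")),
      R_but_glc = list(st = c(glc = -15, urea = -2, but = 5, bm = 1),
                       ec = c("2.7.2.7"),
                       pw = c("glycolysis", "butyrate fermentation"))),
    auxotroph = list(
      R_succ = list(st = c(succ = -6, urea = -2, ppa = 5, bm = 1),
                    ec = c("4.1.1.41"),
                    pw = c("propionate fermentation")),
      R_glc_aux = list(st = c(glc = -14, urea = -2, ppa = 4, bm = 1),
                       ec = c("2.7.2.1"),
                       pw = c("glycolysis", "propionate fermentation"))),
    stop("unknown motif: ", motif)
  )
}

# metabolites each motif exports / imports (used to plant edges)
motif_exports <- function(motif) {
  switch(motif,
         degrader = c("glc", "succ"),
         fermenter = "lac",
         generalist = "ac",
         butyrate_producer = "but",
         auxotroph = "ppa")
}

build_motif_model <- function(species_id, motif) {
  routes <- motif_routes(motif)
  ext <- unique(unlist(lapply(routes, function(r) {
    setdiff(names(r$st), "bm")
  })))
  mets <- c(lapply(ext, metabolite), list(metabolite("bm", "biomass precursor")))
  rxns <- list()
  for (m in ext) {
    rxns[[paste0("EX_", m)]] <-
      reaction(paste0("EX_", m), stats::setNames(-1, m),
               lower_bound = -1000, upper_bound = 1000, is_exchange = TRUE)
  }
  for (rn in names(routes)) {
    r <- routes[[rn]]
    rxns[[rn]] <- reaction(rn, r$st, 0, 1000,
                           ec_numbers = r$ec, pathways = r$pw)
  }
  rxns[["BIOMASS"]] <- reaction("BIOMASS", c(bm = -1), 0, 1000)
  g <- gem(species_id, mets, unname(rxns), "BIOMASS")
  attr(g, "motif") <- motif
  g
}

#' Planted cross-feeding ground truth
#'
#' @param edges data.frame with columns `producer`, `metabolite`,
#'   `consumer`.
#' @param keystone_species_id keystone species id, or `NA` when absent.
#' @param models list of member [gem()]s, used to check that each planted
#'   edge is realizable (metabolite producible by the producer and
#'   consumable by the consumer).
#' @return object of class `planted_truth`.
#' @export
planted_truth <- function(edges, keystone_species_id, models) {
  by_id <- stats::setNames(models, vapply(models, `[[`, "", "species_id"))
  for (i in seq_len(nrow(edges))) {
    p <- by_id[[edges$producer[i]]]
    c_ <- by_id[[edges$consumer[i]]]
    met <- edges$metabolite[i]
    producible <- any(vapply(p$reactions, function(r) {
      !r$is_exchange && isTRUE(r$stoichiometry[met] > 0)
    }, TRUE))
    consumable <- any(vapply(c_$reactions, function(r) {
      !r$is_exchange && isTRUE(r$stoichiometry[met] < 0)
    }, TRUE))
    if (!producible || !consumable) {
      stop("planted edge not realizable: ", edges$producer[i], " -> ",
           met, " -> ", edges$consumer[i])
    }
  }
  structure(list(edges = edges, keystone_species_id = keystone_species_id),
            class = "planted_truth")
}

#' Community generator configuration
#'
#' @param n_species number of member species (>= 2).
#' @param keystone logical; include the keystone primary-degrader taxon.
#' @param motif_mix character vector of non-keystone motifs cycled over the
#'   members (subset of `fermenter`, `generalist`, `butyrate_producer`,
#'   `auxotroph`).
#' @param qpcr_range range of total 16S copies per gram digesta from which
#'   the sample total is drawn log-uniformly; default spans the measured
#'   cohort spread.
#' @return list of class `community_config`.
#' @export
community_config <- function(n_species = 6, keystone = TRUE,
                             motif_mix = c("fermenter", "generalist",
                                           "butyrate_producer", "auxotroph"),
                             qpcr_range = c(1.62e9, 3.02e11)) {
  if (n_species < 2) stop("species count must be at least 2")
  bad <- setdiff(motif_mix, setdiff(motif_names(), "degrader"))
  if (length(bad) > 0L) stop("unknown motif in motif_mix: ",
                             paste(bad, collapse = ", "))
  structure(list(n_species = n_species, keystone = isTRUE(keystone),
                 motif_mix = motif_mix, qpcr_range = qpcr_range),
            class = "community_config")
}

#' Community sample metadata
#'
#' @param sample_id sample identifier.
#' @param group_label `"HB"` (keystone present) or `"NB"`.
#' @param members named numeric vector of relative abundances summing to 1.
#' @param qpcr_total total 16S copies per gram digesta.
#' @return object of class `community_sample`.
#' @export
community_sample <- function(sample_id, group_label, members, qpcr_total) {
  if (abs(sum(members) - 1) > 1e-9) stop("abundances must sum to 1")
  if (any(members <= 0)) stop("abundances must be positive")
  structure(list(sample_id = sample_id, group_label = group_label,
                 members = members, qpcr_total = qpcr_total),
            class = "community_sample")
}

#' Generate a toy community with planted cross-feeding structure
#'
#' Members are assembled from the closed motif library; the keystone
#' degrader (if enabled) is always the first member. Relative abundances
#' are drawn from a symmetric Dirichlet (keystone up-weighted), the sample
#' total from a log-uniform distribution over `qpcr_range`. Identical
#' (config, seed) pairs give identical output.
#'
#' @param config a [community_config()].
#' @param seed integer seed.
#' @param sample_id sample identifier (default derived from the seed).
#' @return list with `models` (list of [gem()]), `sample`
#'   ([community_sample()]) and `truth` ([planted_truth()]).
#' @export
generate_community <- function(config, seed, sample_id = NULL) {
  stopifnot(inherits(config, "community_config"))
  with_seed(seed, {
    n <- config$n_species
    motifs <- character(n)
    ids <- character(n)
    if (config$keystone) {
      motifs[1L] <- "degrader"
      ids[1L] <- "keystone_degrader"
    }
    others <- if (config$keystone) seq(2L, length.out = n - 1L) else seq_len(n)
    mix <- rep(config$motif_mix, length.out = length(others))
    counts <- stats::setNames(integer(length(motif_names())), motif_names())
    for (k in seq_along(others)) {
      m <- mix[k]
      counts[m] <- counts[m] + 1L
      motifs[others[k]] <- m
      ids[others[k]] <- paste0(m, "_", counts[m])
    }
    models <- Map(build_motif_model, ids, motifs)
    names(models) <- ids

    w <- stats::rgamma(n, shape = 5, rate = 1)
    if (config$keystone) w[1L] <- w[1L] * 2   # keystone is a dominant member
    ab <- w / sum(w)
    names(ab) <- ids
    qr <- config$qpcr_range
    qpcr <- exp(stats::runif(1, log(qr[1L]), log(qr[2L])))
    if (is.null(sample_id)) sample_id <- paste0("S", seed)
    grp <- if (config$keystone) "HB" else "NB"
    sample <- community_sample(sample_id, grp, ab, qpcr)

    truth <- planted_truth(plant_edges(ids, motifs),
                           if (config$keystone) ids[1L] else NA_character_,
                           models)
    list(models = models, sample = sample, truth = truth)
  })
}

# intended producer -> metabolite -> consumer edges given member motifs
plant_edges <- function(ids, motifs) {
  edges <- list()
  add <- function(p, m, c_) edges[[length(edges) + 1L]] <<-
    data.frame(producer = p, metabolite = m, consumer = c_,
               stringsAsFactors = FALSE)
  ferm <- ids[motifs == "fermenter"]
  gen <- ids[motifs == "generalist"]
  but <- ids[motifs == "butyrate_producer"]
  aux <- ids[motifs == "auxotroph"]
  key <- ids[motifs == "degrader"]
  if (length(key) == 1L) {
    # liberated glucose feeds every glucose-consuming motif
    for (f in c(ferm, gen, but, aux)) add(key, "glc", f)
    for (a in aux) add(key, "succ", a)
  }
  for (f in ferm) for (b in but) add(f, "lac", b)
  for (g in gen) for (b in but) add(g, "ac", b)
  if (length(edges) == 0L) {
    return(data.frame(producer = character(), metabolite = character(),
                      consumer = character(), stringsAsFactors = FALSE))
  }
  do.call(rbind, edges)
}

#' Generate a paired keystone-on / keystone-off cohort
#'
#' The two communities share the same non-keystone roster, abundance draw
#' and qPCR total; the NB-like sample simply lacks the keystone member and
#' renormalises the remaining abundances, giving a controlled contrast for
#' group-comparison tests.
#'
#' @param config a [community_config()] with `keystone = TRUE`.
#' @param seed integer seed.
#' @return list with elements `hb` and `nb`, each as returned by
#'   [generate_community()].
#' @export
generate_paired_cohort <- function(config, seed) {
  stopifnot(config$keystone)
  hb <- generate_community(config, seed, sample_id = paste0("HB", seed))
  key <- hb$truth$keystone_species_id
  keep <- setdiff(names(hb$models), key)
  ab <- hb$sample$members[keep]
  ab <- ab / sum(ab)
  nb_sample <- community_sample(paste0("NB", seed), "NB", ab,
                                hb$sample$qpcr_total)
  motifs <- vapply(hb$models[keep], function(m) attr(m, "motif"), "")
  nb_truth <- planted_truth(plant_edges(keep, motifs), NA_character_,
                            hb$models[keep])
  nb <- list(models = hb$models[keep], sample = nb_sample, truth = nb_truth)
  list(hb = hb, nb = nb)
}

#' Attach synthetic EC/pathway profiles with controlled overlap
#'
#' Replaces each model's EC annotations with generated sets whose pairwise
#' Jaccard similarity concentrates around `overlap`: a shared core of size
#' `2*overlap*t/(1+overlap)` plus species-specific unique ECs (sizes
#' jittered around the target). Used to exercise the EC-based metrics
#' (CMD, incidence, dissimilarity) at a known overlap level.
#'
#' @param models list of [gem()]s.
#' @param overlap target pairwise Jaccard similarity in \[0,1\].
#' @param seed integer seed.
#' @param set_size nominal EC set size per species.
#' @return the model list with rewritten EC annotations.
#' @export
generate_ec_profiles <- function(models, overlap, seed, set_size = 40) {
  if (overlap < 0 || overlap > 1) stop("overlap must lie in [0, 1]")
  with_seed(seed, {
    core_n <- round(2 * overlap * set_size / (1 + overlap))
    core <- if (core_n > 0) sprintf("2.7.1.%d", seq_len(core_n)) else character()
    out <- vector("list", length(models))
    for (i in seq_along(models)) {
      u_target <- set_size - core_n
      u <- if (overlap <= 0 || overlap >= 1) u_target else {
        max(0L, u_target + sample(-3:3, 1))
      }
      uniq <- if (u > 0) sprintf("3.%d.1.%d", i, seq_len(u)) else character()
      ecs <- c(core, uniq)
      m <- models[[i]]
      targets <- names(m$reactions)[!vapply(m$reactions, `[[`, TRUE,
                                            "is_exchange")]
      # spread the set round-robin over non-exchange reactions
      for (j in seq_along(targets)) {
        m$reactions[[targets[j]]]$ec_numbers <-
          ecs[seq(j, length(ecs), by = length(targets))]
      }
      out[[i]] <- m
    }
    names(out) <- names(models)
    out
  })
}

#' Write / read a sample sheet
#'
#' Long-format TSV: sample_id, group, qpcr_total, species, rel_abundance.
#'
#' @param samples list of [community_sample()] objects.
#' @param path file path.
#' @return the path ([write_samples()]) or a list of samples
#'   ([read_samples()]).
#' @export
write_samples <- function(samples, path) {
  rows <- lapply(samples, function(s) {
    data.frame(sample_id = s$sample_id, group = s$group_label,
               qpcr_total = s$qpcr_total,
               species = names(s$members),
               rel_abundance = as.numeric(s$members),
               stringsAsFactors = FALSE)
  })
  write_tsv(do.call(rbind, rows), path)
}

#' @rdname write_samples
#' @export
read_samples <- function(path) {
  df <- read_tsv(path)
  lapply(split(df, df$sample_id), function(d) {
    community_sample(d$sample_id[1L], d$group[1L],
                     stats::setNames(d$rel_abundance, d$species),
                     d$qpcr_total[1L])
  })
}
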