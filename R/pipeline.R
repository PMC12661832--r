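# End-to-end orchestration: synthetic cohort -> simulations -> interaction
# and community statistics -> group comparison -> report directory.

#' Pipeline configuration
#'
#' Defaults describe the simulated cecal study design: two groups of
#' samples (keystone-on HB-like, keystone-off NB-like), each simulated on
#' the arena and analysed with the cross-feeding and community-metabolism
#' statistics. Arena settings default to [arena_params()] (100 x 100 grid,
#' 16 h, 5 replicates); pass `arena` overrides to scale a run down.
#'
#' @param n_hb,n_nb samples per group.
#' @param n_species species per HB-like community (NB-like communities
#'   carry one fewer, lacking the keystone).
#' @param n_species_range optional integer range `c(lo, hi)`; when given,
#'   each sample draws its own species count uniformly from it
#'   (seed-derived), emulating the richness variation of real cohorts, and
#'   `n_species` is ignored.
#' @param motif_mix non-keystone motif cycle (see [community_config()]).
#' @param qpcr_range qPCR total range for the generator.
#' @param arena named list of [arena_params()] overrides.
#' @param flux_threshold interaction flux threshold (mmol/gDW/h).
#' @param min_partners,min_metabolites hub thresholds.
#' @param cliques_k number of cliques for [cluster_cliques()]; `NA` skips
#'   clique extraction when there are too few taxa.
#' @param alpha,fc_label_threshold group-comparison thresholds.
#' @param ec_overlap optional overlap in \[0,1\]; when set, species EC
#'   profiles are regenerated with [generate_ec_profiles()].
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(n_hb = 6, n_nb = 6, n_species = 6,
                            n_species_range = NULL,
                            motif_mix = c("fermenter", "generalist",
                                          "butyrate_producer", "auxotroph"),
                            qpcr_range = c(1.62e9, 3.02e11),
                            arena = list(),
                            flux_threshold = 1e-6,
                            min_partners = 10, min_metabolites = 12,
                            cliques_k = 8,
                            alpha = 0.05, fc_label_threshold = 0.7,
                            ec_overlap = NULL) {
  cfg <- as.list(environment())
  known <- names(formals(arena_params))
  bad <- setdiff(names(cfg$arena), known)
  if (length(bad) > 0L) {
    stop("unknown arena setting(s): ", paste(bad, collapse = ", "))
  }
  if (n_hb < 1 || n_nb < 1) stop("each group needs at least one sample")
  structure(cfg, class = "pipeline_config")
}

#' Validate a raw configuration list
#'
#' Checks a plain list (e.g. parsed from YAML) against the
#' [pipeline_config()] schema before any computation; unknown keys are an
#' error.
#'
#' @param config named list.
#' @return a validated `pipeline_config`.
#' @export
validate_config <- function(config) {
  if (inherits(config, "pipeline_config")) return(config)
  known <- names(formals(pipeline_config))
  bad <- setdiff(names(config), known)
  if (length(bad) > 0L) {
    stop("unknown config key(s): ", paste(bad, collapse = ", "))
  }
  do.call(pipeline_config, config)
}

#' Run the full in-silico cecum analysis pipeline
#'
#' Generates the synthetic cohort, simulates every sample, extracts
#' cross-feeding interactions and community metrics, and compares exchange
#' fluxes between groups. Rerunning with the same config and seed
#' reproduces every table exactly.
#'
#' @param config a [pipeline_config()] (or list accepted by
#'   [validate_config()]).
#' @param seed integer master seed; per-sample and per-replicate seeds are
#'   derived from it.
#' @param out_dir optional directory; when given, all result tables are
#'   written there as TSV together with a config echo (YAML) and a run-info
#'   file.
#' @return object of class `cecum_pipeline`: list with `samples`
#'   (metadata + per-sample CFC/MRO/CMD), `interactions` (per group),
#'   `hubs`, `shares`, `keystone_metabolites`, `comparison`, `mi`,
#'   `pcoa`, `cliques`, `flux_table`, `diet`, `config`, `seed`.
#' @export
run_pipeline <- function(config = pipeline_config(), seed = 1,
                         out_dir = NULL) {
  config <- validate_config(config)
  params <- do.call(arena_params, config$arena)
  diet <- generate_diet()

  stage <- function(name, sample_id, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed for sample '", sample_id,
           "': ", conditionMessage(e), call. = FALSE)
    })
  }

  sample_n <- function(sample_seed) {
    if (is.null(config$n_species_range)) return(config$n_species)
    r <- config$n_species_range
    with_seed(sample_seed + 5000, sample(seq(r[1L], r[2L]), 1L))
  }
  gens <- list()
  for (i in seq_len(config$n_hb)) {
    cfg_i <- community_config(n_species = sample_n(seed + i),
                              keystone = TRUE,
                              motif_mix = config$motif_mix,
                              qpcr_range = config$qpcr_range)
    gens[[paste0("HB", i)]] <-
      stage("generate", paste0("HB", i),
            generate_community(cfg_i, seed + i, sample_id = paste0("HB", i)))
  }
  for (i in seq_len(config$n_nb)) {
    cfg_i <- community_config(n_species = max(2, sample_n(seed + 1000 + i) - 1L),
                              keystone = FALSE,
                              motif_mix = config$motif_mix,
                              qpcr_range = config$qpcr_range)
    gens[[paste0("NB", i)]] <-
      stage("generate", paste0("NB", i),
            generate_community(cfg_i, seed + 1000 + i,
                               sample_id = paste0("NB", i)))
  }
  if (!is.null(config$ec_overlap)) {
    for (nm in names(gens)) {
      gens[[nm]]$models <- generate_ec_profiles(gens[[nm]]$models,
                                                config$ec_overlap,
                                                seed + 2000)
    }
  }

  qpcr_all <- vapply(gens, function(g) g$sample$qpcr_total, 0)
  diet_nutrients <- dietary_metabolites(diet)
  med_cache <- new.env(parent = emptyenv())
  minimal_media_for <- function(models) {
    out <- lapply(models, function(m) {
      key <- attr(m, "motif") %||% m$species_id
      mm <- med_cache[[key]]
      if (is.null(mm)) {
        mm <- minimal_medium(m, diet_nutrients)
        med_cache[[key]] <- mm
      }
      mm
    })
    names(out) <- vapply(models, `[[`, "", "species_id")
    out
  }

  sims <- list(); tabs <- list(); tabs_nd <- list(); fluxes <- list()
  meta_rows <- list()
  for (nm in names(gens)) {
    g <- gens[[nm]]
    counts <- stage("scale_abundances", nm,
                    scale_abundances(qpcr_all, g$sample, params))
    sim <- stage("simulate", nm,
                 run_simulation(g$models, counts, diet, params,
                                seed = seed + match(nm, names(gens)) * 100))
    sims[[nm]] <- sim
    tab <- stage("interactions", nm,
                 extract_interactions(sim$records, config$flux_threshold))
    tabs[[nm]] <- tab
    tabs_nd[[nm]] <- filter_nondietary(tab, diet)
    fluxes[[nm]] <- stage("aggregate_fluxes", nm,
                          aggregate_exchange_fluxes(sim$records,
                                                    sim$population))
    S <- length(g$sample$members)
    mro <- stage("mro", nm,
                 mro_score(unname(g$models), diet_nutrients,
                           minimal_media = minimal_media_for(g$models)))
    cmd <- stage("cmd", nm, cmd_score(unname(g$models)))
    meta_rows[[nm]] <- data.frame(
      sample_id = g$sample$sample_id, group = g$sample$group_label,
      n_species = S, qpcr_total = g$sample$qpcr_total,
      cfc = cross_feeding_coefficient(tabs_nd[[nm]], S),
      cfc_all = cross_feeding_coefficient(tab, S),
      mro = mro$mro, cmd = cmd$cmd, cmd_unadjusted = cmd$mean_distance,
      stringsAsFactors = FALSE)
  }
  samples_df <- do.call(rbind, meta_rows)
  rownames(samples_df) <- NULL

  groups <- samples_df$group
  hb_idx <- which(groups == "HB"); nb_idx <- which(groups == "NB")
  interactions <- list(HB = normalize_across_samples(tabs_nd[hb_idx]),
                       NB = normalize_across_samples(tabs_nd[nb_idx]))
  hubs <- lapply(interactions, identify_hubs,
                 min_partners = config$min_partners,
                 min_metabolites = config$min_metabolites)
  group_records <- function(idx) {
    do.call(rbind, lapply(sims[idx], `[[`, "records"))
  }
  shares <- list(HB = contribution_shares(group_records(hb_idx)),
                 NB = contribution_shares(group_records(nb_idx)))
  # keystone-metabolite filters operate on microbially produced metabolites
  nd <- function(sh) sh[!(sh$metabolite %in% dietary_metabolites(diet)), ,
                        drop = FALSE]
  keystone_mets <- tryCatch(
    select_keystone_metabolites(nd(shares$HB), nd(shares$NB),
                                "keystone_degrader"),
    error = function(e) character())

  # per-sample flux table over the union of exchanged metabolites
  all_mets <- sort(unique(unlist(lapply(fluxes, names))))
  flux_table <- t(vapply(fluxes, function(f) {
    v <- stats::setNames(numeric(length(all_mets)), all_mets)
    v[names(f)] <- f
    v
  }, numeric(length(all_mets))))
  rownames(flux_table) <- samples_df$sample_id

  comparison <- compare_groups(flux_table, groups, alpha = config$alpha,
                               fc_label_threshold = config$fc_label_threshold)

  all_models <- list()
  for (g in gens) for (m in g$models) {
    all_models[[m$species_id]] <- m
  }
  samples_list <- lapply(gens, `[[`, "sample")
  inc_bin <- build_incidence(samples_list, all_models, "binary", "reaction")
  inc_w <- build_incidence(samples_list, all_models, "weighted", "reaction")
  mi <- mi_matrix(inc_bin)
  ord <- list(jaccard = pcoa(dissimilarity(inc_bin, "jaccard")),
              bray_curtis = pcoa(dissimilarity(inc_w, "bray_curtis")))

  cliques <- lapply(interactions, function(tab) {
    n_taxa <- length(unique(c(tab$producer, tab$consumer)))
    k <- min(config$cliques_k, n_taxa)
    if (is.na(k) || n_taxa < 2L) return(NULL)
    cluster_cliques(tab, k = k)
  })

  out <- list(samples = samples_df, interactions = interactions,
              hubs = hubs, shares = shares,
              keystone_metabolites = keystone_mets,
              comparison = comparison, mi = mi, pcoa = ord,
              cliques = cliques, flux_table = flux_table,
              truths = lapply(gens, `[[`, "truth"),
              diet = diet, config = config, seed = seed)
  class(out) <- "cecum_pipeline"
  if (!is.null(out_dir)) write_report(out, out_dir)
  out
}

#' Write a pipeline report directory
#'
#' Emits every result table as TSV plus a YAML echo of the configuration
#' and seed. The package/R version stamp goes into a separate
#' `run_info.txt` so that the data tables themselves are byte-reproducible
#' across installations.
#'
#' @param result a `cecum_pipeline`.
#' @param out_dir output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_report <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(out_dir, f)
  write_tsv(result$samples, p("metrics.tsv"))
  for (g in names(result$interactions)) {
    write_tsv(result$interactions[[g]],
              p(paste0("interactions_", g, ".tsv")))
    write_tsv(result$hubs[[g]], p(paste0("hubs_", g, ".tsv")))
    write_tsv(result$shares[[g]], p(paste0("shares_", g, ".tsv")))
    cl <- result$cliques[[g]]
    if (!is.null(cl)) {
      write_tsv(data.frame(species = names(cl), clique = as.integer(cl),
                           stringsAsFactors = FALSE),
                p(paste0("cliques_", g, ".tsv")))
    }
  }
  write_tsv(result$comparison, p("comparison.tsv"))
  write_tsv(data.frame(metabolite = result$keystone_metabolites,
                       stringsAsFactors = FALSE),
            p("keystone_metabolites.tsv"))
  mi_df <- as.data.frame(result$mi)
  mi_df <- cbind(sample_id = rownames(result$mi), mi_df)
  write_tsv(mi_df, p("mi_matrix.tsv"))
  ft <- as.data.frame(result$flux_table)
  ft <- cbind(sample_id = rownames(result$flux_table), ft)
  write_tsv(ft, p("flux_table.tsv"))
  for (m in names(result$pcoa)) {
    co <- result$pcoa[[m]]$coordinates
    df <- cbind(data.frame(sample_id = rownames(co)), as.data.frame(co))
    write_tsv(df, p(paste0("pcoa_", m, ".tsv")))
  }
  cfg <- unclass(result$config)
  yaml::write_yaml(list(config = cfg, seed = result$seed), p("config.yaml"))
  writeLines(c(paste("cecosim version:",
                     as.character(utils::packageVersion("cecosim"))),
               paste("R version:", R.version.string)),
             p("run_info.txt"))
  invisible(out_dir)
}

#' @export
print.cecum_pipeline <- function(x, ...) {
  cat("<cecum_pipeline>", nrow(x$samples), "samples (",
      sum(x$samples$group == "HB"), "HB /",
      sum(x$samples$group == "NB"), "NB ), seed", x$seed, "\n")
  cat("  mean CFC:  HB", format(mean(x$samples$cfc[x$samples$group == "HB"]),
                                digits = 4),
      " NB", format(mean(x$samples$cfc[x$samples$group == "NB"]),
                    digits = 4), "\n")
  cat("  mean MRO:  HB", format(mean(x$samples$mro[x$samples$group == "HB"]),
                                digits = 4),
      " NB", format(mean(x$samples$mro[x$samples$group == "NB"]),
                    digits = 4), "\n")
  cat("  significant metabolites:", sum(x$comparison$significant), "of",
      nrow(x$comparison), "\n")
  invisible(x)
}

#' @export
summary.cecum_pipeline <- function(object, ...) {
  print(object)
  cat("\nPer-sample metrics:\n")
  print(object$samples, row.names = FALSE, digits = 4)
  cat("\nGroup comparison of exchange fluxes:\n")
  print(object$comparison, row.names = FALSE, digits = 3)
  invisible(object)
}
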