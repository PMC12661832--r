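# Cross-feeding interaction inference from exchange-flux records.
#
# A species is a producer of a metabolite when its run-aggregated export
# flux exceeds the threshold, a consumer when its aggregated import flux
# does; producer and consumer sets are merged on shared metabolites into
# (producer, consumer, metabolite) interaction rows with producer !=
# consumer.

#' Extract cross-feeding interactions from flux records
#'
#' Flux totals are aggregated over the whole run (all iterations, averaged
#' over replicates); totals at or below `flux_threshold` (in
#' mmol/gDW/h) are treated as numerical noise and dropped.
#'
#' @param records FluxRecord data.frame from [run_simulation()] (columns
#'   replicate, iteration, species, metabolite, flux).
#' @param flux_threshold minimum absolute aggregated flux.
#' @return data.frame of class `interaction_table`: producer, consumer,
#'   metabolite, production (aggregate flux of the producer), consumption
#'   (aggregate flux of the consumer).
#' @export
extract_interactions <- function(records, flux_threshold = 1e-6) {
  empty <- structure(
    data.frame(producer = character(), consumer = character(),
               metabolite = character(), production = numeric(),
               consumption = numeric(), stringsAsFactors = FALSE),
    class = c("interaction_table", "data.frame"))
  if (is.null(records) || nrow(records) == 0L) return(empty)
  n_rep <- length(unique(records$replicate))
  pos <- records
  pos$prod <- pmax(pos$flux, 0)
  pos$cons <- pmax(-pos$flux, 0)
  agg <- stats::aggregate(cbind(prod, cons) ~ species + metabolite, pos, sum)
  agg$prod <- agg$prod / n_rep
  agg$cons <- agg$cons / n_rep
  producers <- agg[agg$prod > flux_threshold,
                   c("species", "metabolite", "prod")]
  consumers <- agg[agg$cons > flux_threshold,
                   c("species", "metabolite", "cons")]
  if (nrow(producers) == 0L || nrow(consumers) == 0L) return(empty)
  m <- merge(producers, consumers, by = "metabolite",
             suffixes = c("_p", "_c"))
  m <- m[m$species_p != m$species_c, , drop = FALSE]
  out <- data.frame(producer = m$species_p, consumer = m$species_c,
                    metabolite = m$metabolite, production = m$prod,
                    consumption = m$cons, stringsAsFactors = FALSE)
  out <- out[order(out$producer, out$consumer, out$metabolite), ]
  rownames(out) <- NULL
  structure(out, class = c("interaction_table", "data.frame"))
}

#' Cross-feeding coefficient
#'
#' The number of realised ordered producer -> consumer species pairs
#' (sharing at least one exchanged metabolite) divided by all ordered
#' species pairs `S * (S - 1)`, so the coefficient lies in \[0, 1\].
#'
#' @param table an `interaction_table`.
#' @param n_species community size S (>= 2).
#' @return numeric scalar in \[0, 1\].
#' @export
cross_feeding_coefficient <- function(table, n_species) {
  if (n_species < 2) stop("community must contain at least 2 species")
  if (nrow(table) == 0L) return(0)
  pairs <- unique(paste(table$producer, table$consumer, sep = "\r"))
  length(pairs) / (n_species * (n_species - 1))
}

#' Pool per-sample interaction tables into a group table
#'
#' Counts of each (producer, consumer, metabolite) interaction are summed
#' over samples and normalised by the number of samples in which the
#' producer-consumer pair occurs.
#'
#' @param tables list of per-sample `interaction_table`s.
#' @return data.frame: producer, consumer, metabolite, weight (normalised
#'   count), n_samples_present (samples containing the pair).
#' @export
normalize_across_samples <- function(tables) {
  if (length(tables) == 0L) stop("at least one sample table required")
  rows <- do.call(rbind, lapply(seq_along(tables), function(i) {
    t <- tables[[i]]
    if (nrow(t) == 0L) return(NULL)
    data.frame(sample = i, producer = t$producer, consumer = t$consumer,
               metabolite = t$metabolite, stringsAsFactors = FALSE)
  }))
  if (is.null(rows)) {
    return(data.frame(producer = character(), consumer = character(),
                      metabolite = character(), weight = numeric(),
                      n_samples_present = integer(),
                      stringsAsFactors = FALSE))
  }
  key <- paste(rows$producer, rows$consumer, sep = "\r")
  pair_samples <- tapply(rows$sample, key, function(s) length(unique(s)))
  cnt <- stats::aggregate(
    list(count = rep(1L, nrow(rows))),
    by = list(producer = rows$producer, consumer = rows$consumer,
              metabolite = rows$metabolite), FUN = sum)
  k2 <- paste(cnt$producer, cnt$consumer, sep = "\r")
  cnt$n_samples_present <- as.integer(pair_samples[k2])
  cnt$weight <- cnt$count / cnt$n_samples_present
  out <- cnt[order(cnt$producer, cnt$consumer, cnt$metabolite),
             c("producer", "consumer", "metabolite", "weight",
               "n_samples_present")]
  rownames(out) <- NULL
  out
}

#' Identify metabolic hub taxa
#'
#' A hub exchanges at least `min_metabolites` distinct metabolites with at
#' least `min_partners` other taxa, counting both producer and consumer
#' roles.
#'
#' @param table an interaction table (per sample or group-pooled).
#' @param min_partners minimum number of distinct partner taxa.
#' @param min_metabolites minimum number of distinct exchanged metabolites.
#' @return data.frame: species, n_partners, n_metabolites, is_hub.
#' @export
identify_hubs <- function(table, min_partners = 10, min_metabolites = 12) {
  if (nrow(table) == 0L) {
    return(data.frame(species = character(), n_partners = integer(),
                      n_metabolites = integer(), is_hub = logical(),
                      stringsAsFactors = FALSE))
  }
  both <- rbind(
    data.frame(species = table$producer, partner = table$consumer,
               metabolite = table$metabolite, stringsAsFactors = FALSE),
    data.frame(species = table$consumer, partner = table$producer,
               metabolite = table$metabolite, stringsAsFactors = FALSE))
  sp <- sort(unique(both$species))
  n_partners <- vapply(sp, function(s) {
    length(unique(both$partner[both$species == s]))
  }, 0L)
  n_metabolites <- vapply(sp, function(s) {
    length(unique(both$metabolite[both$species == s]))
  }, 0L)
  data.frame(species = sp, n_partners = n_partners,
             n_metabolites = n_metabolites,
             is_hub = n_partners >= min_partners &
               n_metabolites >= min_metabolites,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Cluster taxa into interaction cliques
#'
#' Builds a per-taxon interaction profile (taxa x partners weight matrix)
#' from an interaction table, clusters it by complete-linkage agglomeration
#' on Euclidean distances, and cuts the tree into `k` groups. A fixed-k
#' tree cut replaces visual inspection of the clustered heatmap so clique
#' assignment is reproducible.
#'
#' @param table interaction table with `weight` column (see
#'   [normalize_across_samples()]) or per-sample table (unit weights).
#' @param k number of cliques to extract (default 8).
#' @return named integer vector of cluster labels per taxon; the `hclust`
#'   tree is attached as attribute `tree`.
#' @export
cluster_cliques <- function(table, k = 8) {
  if (nrow(table) == 0L) stop("empty interaction table")
  w <- if ("weight" %in% names(table)) table$weight else rep(1, nrow(table))
  taxa <- sort(unique(c(table$producer, table$consumer)))
  if (length(taxa) < 2L) stop("need at least 2 taxa to cluster")
  if (k > length(taxa)) stop("k exceeds the number of taxa")
  prof <- matrix(0, length(taxa), length(taxa),
                 dimnames = list(taxa, taxa))
  for (i in seq_len(nrow(table))) {
    prof[table$producer[i], table$consumer[i]] <-
      prof[table$producer[i], table$consumer[i]] + w[i]
    prof[table$consumer[i], table$producer[i]] <-
      prof[table$consumer[i], table$producer[i]] + w[i]
  }
  tree <- stats::hclust(stats::dist(prof, method = "euclidean"),
                        method = "complete")
  labels <- stats::cutree(tree, k = k)
  attr(labels, "tree") <- tree
  labels
}

#' Per-metabolite production and consumption shares
#'
#' Each species' share (percent) of a metabolite's total produced and
#' consumed amount over the run, optionally restricted to the top `top_n`
#' contributors above `min_share` percent (the defaults mirror a
#' top-3-at-5% display rule).
#'
#' @param records FluxRecord data.frame.
#' @param top_n keep at most this many species per metabolite per role
#'   (`Inf` keeps all).
#' @param min_share drop shares below this percentage (0 keeps all).
#' @return data.frame: metabolite, species, role
#'   ("producer"/"consumer"), amount (mmol), share (percent).
#' @export
contribution_shares <- function(records, top_n = Inf, min_share = 0) {
  empty <- data.frame(metabolite = character(), species = character(),
                      role = character(), amount = numeric(),
                      share = numeric(), stringsAsFactors = FALSE)
  if (is.null(records) || nrow(records) == 0L) return(empty)
  rec <- records
  rec$produced <- pmax(rec$amount, 0)
  rec$consumed <- pmax(-rec$amount, 0)
  agg <- stats::aggregate(cbind(produced, consumed) ~ species + metabolite,
                          rec, sum)
  out <- list()
  for (role in c("producer", "consumer")) {
    col <- if (role == "producer") "produced" else "consumed"
    for (met in unique(agg$metabolite)) {
      sub <- agg[agg$metabolite == met & agg[[col]] > 0, ]
      tot <- sum(sub[[col]])
      if (tot <= 0) next                    # metabolite absent in this role
      sub <- sub[order(-sub[[col]], sub$species), ]
      share <- 100 * sub[[col]] / tot
      keep <- seq_len(min(nrow(sub), top_n))
      keep <- keep[share[keep] >= min_share]
      if (length(keep) == 0L) next
      out[[length(out) + 1L]] <- data.frame(
        metabolite = met, species = sub$species[keep], role = role,
        amount = sub[[col]][keep], share = share[keep],
        stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0L) return(empty)
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Restrict an interaction table to non-dietary metabolites
#'
#' Drops rows whose metabolite enters the arena with the diet at nonzero
#' influx concentration, leaving only metabolites exclusively produced by
#' bacteria.
#'
#' @param table an interaction table.
#' @param diet a [diet_spec()].
#' @return the filtered table.
#' @export
filter_nondietary <- function(table, diet) {
  dietary <- dietary_metabolites(diet)
  out <- table[!(table$metabolite %in% dietary), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Select keystone-associated cross-fed metabolites
#'
#' Applies three filters to production/consumption share tables from the
#' two community groups: (1) at least `keystone_share` percent of a
#' metabolite's production or consumption is attributed to a single
#' keystone taxon in at least one group; (2) at least `cross_fed_share`
#' percent of the produced amount is consumed by at least one taxon other
#' than the top producer (the metabolite is genuinely cross-fed); (3)
#' metabolites whose top producer is the same taxon in both groups are
#' excluded. Each filter can be toggled.
#'
#' @param shares_a,shares_b [contribution_shares()] tables (unfiltered,
#'   i.e. built with `top_n = Inf, min_share = 0`) for the two groups.
#' @param keystone_taxa character vector of keystone species ids.
#' @param keystone_share,cross_fed_share thresholds in percent.
#' @param apply_keystone,apply_crossfed,apply_distinct_top logical toggles
#'   for the three filters.
#' @return character vector of selected metabolite ids.
#' @export
select_keystone_metabolites <- function(shares_a, shares_b, keystone_taxa,
                                        keystone_share = 30,
                                        cross_fed_share = 1,
                                        apply_keystone = TRUE,
                                        apply_crossfed = TRUE,
                                        apply_distinct_top = TRUE) {
  known <- unique(c(shares_a$species, shares_b$species))
  unknown <- setdiff(keystone_taxa, known)
  if (length(unknown) > 0L) {
    stop("unknown keystone id(s): ", paste(unknown, collapse = ", "))
  }
  mets <- sort(unique(c(shares_a$metabolite, shares_b$metabolite)))
  top_producer <- function(shares, met) {
    sub <- shares[shares$metabolite == met & shares$role == "producer", ]
    if (nrow(sub) == 0L) return(NA_character_)
    sub$species[which.max(sub$share)]
  }
  keep <- vapply(mets, function(met) {
    if (apply_keystone) {
      ka <- shares_a[shares_a$metabolite == met &
                       shares_a$species %in% keystone_taxa, "share"]
      kb <- shares_b[shares_b$metabolite == met &
                       shares_b$species %in% keystone_taxa, "share"]
      if (!any(c(ka, kb) >= keystone_share)) return(FALSE)
    }
    if (apply_crossfed) {
      ok <- any(vapply(list(shares_a, shares_b), function(sh) {
        tp <- top_producer(sh, met)
        cons <- sh[sh$metabolite == met & sh$role == "consumer" &
                     sh$species != tp, , drop = FALSE]
        prod_tot <- sum(sh[sh$metabolite == met & sh$role == "producer",
                           "amount"])
        prod_tot > 0 && sum(cons$amount) >= cross_fed_share / 100 * prod_tot
      }, TRUE))
      if (!ok) return(FALSE)
    }
    if (apply_distinct_top) {
      ta <- top_producer(shares_a, met)
      tb <- top_producer(shares_b, met)
      if (!is.na(ta) && !is.na(tb) && ta == tb) return(FALSE)
    }
    TRUE
  }, TRUE)
  mets[keep]
}
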