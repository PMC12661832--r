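rec_row <- function(sp, met, flux, it = 1L, rep = 1L) {
  data.frame(replicate = rep, iteration = it, species = sp,
             metabolite = met, flux = flux, amount = flux * 1e-12,
             stringsAsFactors = FALSE)
}

test_that("producer/consumer extraction follows the threshold and merge rules", {
  recs <- rbind(rec_row("A", "ac", 5), rec_row("B", "ac", -2))
  tab <- extract_interactions(recs)
  expect_identical(nrow(tab), 1L)
  expect_identical(tab$producer, "A")
  expect_identical(tab$consumer, "B")
  expect_identical(tab$metabolite, "ac")

  # below-threshold fluxes are noise
  tiny <- rbind(rec_row("A", "ac", 1e-8), rec_row("B", "ac", -2))
  expect_identical(nrow(extract_interactions(tiny)), 0L)
  expect_identical(nrow(extract_interactions(recs[0, ])), 0L)

  # a species in both roles is excluded from its own pairs only
  recs2 <- rbind(rec_row("A", "lac", 5, it = 1L),
                 rec_row("A", "lac", -3, it = 2L),
                 rec_row("B", "lac", -2),
                 rec_row("C", "lac", 4))
  tab2 <- extract_interactions(recs2)
  key <- paste(tab2$producer, tab2$consumer)
  expect_false("A A" %in% key)
  expect_true(all(c("A B", "C A", "C B") %in% key))
})

test_that("extraction is invariant to ordering and replicate splitting", {
  set.seed(42)
  recs <- do.call(rbind, lapply(1:40, function(i) {
    rec_row(sample(c("A", "B", "C"), 1), sample(c("ac", "lac"), 1),
            runif(1, -3, 3), it = sample(1:4, 1), rep = 1L)
  }))
  shuffled <- recs[sample(nrow(recs)), ]
  expect_identical(extract_interactions(recs),
                   extract_interactions(shuffled))
  # duplicating the run as a second replicate leaves averages unchanged
  rep2 <- recs; rep2$replicate <- 2L
  expect_identical(extract_interactions(recs),
                   extract_interactions(rbind(recs, rep2)))
})

test_that("cross-feeding coefficient counts ordered pairs over S(S-1)", {
  tab <- extract_interactions(rbind(rec_row("A", "ac", 5),
                                    rec_row("B", "ac", -2)))
  expect_equal(cross_feeding_coefficient(tab, 2), 0.5)
  expect_equal(cross_feeding_coefficient(tab[0, ], 3), 0)
  # all six ordered pairs among three species
  full <- rbind(rec_row("A", "ac", 5, it = 1L), rec_row("A", "ac", -5, it = 2L),
                rec_row("B", "ac", 5, it = 1L), rec_row("B", "ac", -5, it = 2L),
                rec_row("C", "ac", 5, it = 1L), rec_row("C", "ac", -5, it = 2L))
  expect_equal(cross_feeding_coefficient(extract_interactions(full), 3), 1)
  expect_error(cross_feeding_coefficient(tab, 1), "at least 2")
})

test_that("CFC equals brute-force pair enumeration and is monotone", {
  set.seed(7)
  for (k in 1:10) {
    recs <- do.call(rbind, lapply(1:30, function(i) {
      rec_row(sample(LETTERS[1:5], 1), sample(c("m1", "m2", "m3"), 1),
              runif(1, -4, 4), it = sample(1:3, 1))
    }))
    tab <- extract_interactions(recs)
    # oracle: loop over all ordered pairs, count realized ones
    realized <- 0L
    for (p in LETTERS[1:5]) for (q in LETTERS[1:5]) {
      if (p != q && any(tab$producer == p & tab$consumer == q)) {
        realized <- realized + 1L
      }
    }
    expect_equal(cross_feeding_coefficient(tab, 5), realized / 20)
    # adding one more interaction row never decreases the coefficient
    extra <- rbind(tab, data.frame(producer = "A", consumer = "E",
                                   metabolite = "m9", production = 1,
                                   consumption = 1))
    expect_gte(cross_feeding_coefficient(extra, 5),
               cross_feeding_coefficient(tab, 5))
  }
})

test_that("group pooling normalises by pair occurrence across samples", {
  one_pair <- function() {
    extract_interactions(rbind(rec_row("A", "ac", 5),
                               rec_row("B", "ac", -2)))
  }
  norm <- normalize_across_samples(list(one_pair(), one_pair(), one_pair()))
  expect_equal(norm$weight, 1)
  expect_identical(norm$n_samples_present, 3L)

  three_mets <- extract_interactions(rbind(
    rec_row("A", "m1", 5), rec_row("B", "m1", -2),
    rec_row("A", "m2", 5), rec_row("B", "m2", -2),
    rec_row("A", "m3", 5), rec_row("B", "m3", -2)))
  norm3 <- normalize_across_samples(list(three_mets, one_pair()[0, ]))
  expect_equal(sum(norm3$weight), 3)
  expect_identical(nrow(normalize_across_samples(list(one_pair()[0, ]))), 0L)
})

test_that("hub detection applies both thresholds over both roles", {
  tab <- do.call(rbind, lapply(1:12, function(m) {
    data.frame(producer = "hub", consumer = paste0("p", ((m - 1) %% 10) + 1),
               metabolite = paste0("m", m), production = 1, consumption = 1,
               stringsAsFactors = FALSE)
  }))
  h <- identify_hubs(tab)
  expect_true(h$is_hub[h$species == "hub"])
  expect_identical(h$n_partners[h$species == "hub"], 10L)
  expect_identical(h$n_metabolites[h$species == "hub"], 12L)
  # partners below threshold: not a hub however many metabolites
  tab9 <- do.call(rbind, lapply(1:30, function(m) {
    data.frame(producer = "hub", consumer = paste0("p", ((m - 1) %% 9) + 1),
               metabolite = paste0("m", m), production = 1, consumption = 1,
               stringsAsFactors = FALSE)
  }))
  h9 <- identify_hubs(tab9)
  expect_false(h9$is_hub[h9$species == "hub"])
  expect_identical(nrow(identify_hubs(tab[0, ])), 0L)
})

test_that("clique clustering recovers block structure and matches a naive linkage", {
  # two blocks of taxa that interact only within their block
  block_tab <- do.call(rbind, lapply(list(c("a1", "a2", "a3"),
                                          c("b1", "b2", "b3")), function(g) {
    do.call(rbind, lapply(utils::combn(g, 2, simplify = FALSE), function(p) {
      data.frame(producer = p[1], consumer = p[2], metabolite = "m",
                 production = 1, consumption = 1, weight = 5,
                 stringsAsFactors = FALSE)
    }))
  }))
  lab <- cluster_cliques(block_tab, k = 2)
  expect_length(unique(lab[c("a1", "a2", "a3")]), 1L)
  expect_length(unique(lab[c("b1", "b2", "b3")]), 1L)
  expect_false(lab[["a1"]] == lab[["b1"]])
  # identical profiles cluster together; k = n gives singletons
  expect_length(unique(cluster_cliques(block_tab, k = 6)), 6L)
  expect_error(cluster_cliques(block_tab, k = 7), "exceeds")
  # cross-check the tree cut against a naive complete-linkage implementation
  taxa <- sort(unique(c(block_tab$producer, block_tab$consumer)))
  prof <- matrix(0, length(taxa), length(taxa),
                 dimnames = list(taxa, taxa))
  for (i in seq_len(nrow(block_tab))) {
    prof[block_tab$producer[i], block_tab$consumer[i]] <-
      prof[block_tab$producer[i], block_tab$consumer[i]] + 5
    prof[block_tab$consumer[i], block_tab$producer[i]] <-
      prof[block_tab$consumer[i], block_tab$producer[i]] + 5
  }
  naive <- naive_complete_linkage(prof, 2)
  agree <- table(naive, cluster_cliques(block_tab, k = 2)[taxa])
  expect_true(all(rowSums(agree > 0) == 1))
})

test_that("contribution shares sum to 100 per role and honour top-n filtering", {
  recs <- rbind(rec_row("A", "ac", 3), rec_row("B", "ac", 1),
                rec_row("C", "ac", -2))
  sh <- contribution_shares(recs)
  prod <- sh[sh$role == "producer" & sh$metabolite == "ac", ]
  expect_equal(sort(prod$share), c(25, 75))
  cons <- sh[sh$role == "consumer" & sh$metabolite == "ac", ]
  expect_equal(cons$share, 100)
  for (met in unique(sh$metabolite)) for (role in unique(sh$role)) {
    s <- sh$share[sh$metabolite == met & sh$role == role]
    if (length(s) > 0) expect_equal(sum(s), 100, tolerance = 1e-9)
  }
  top <- contribution_shares(rbind(recs, rec_row("D", "ac", 0.1)),
                             top_n = 3, min_share = 5)
  expect_false("D" %in% top$species)
  expect_lte(max(table(top$metabolite, top$role)), 3)
})

test_that("dietary metabolites are filtered from interaction tables", {
  tab <- extract_interactions(rbind(
    rec_row("A", "ac", 5), rec_row("B", "ac", -2),
    rec_row("A", "glc", 5), rec_row("B", "glc", -2)))
  filtered <- filter_nondietary(tab, generate_diet())
  expect_identical(unique(filtered$metabolite), "ac")
  empty_diet <- diet_spec(data.frame(metabolite = character(),
                                     raw_concentration = numeric(),
                                     absorption_fraction = numeric()))
  expect_identical(nrow(filter_nondietary(tab, empty_diet)), nrow(tab))
})

test_that("keystone-metabolite filters act independently", {
  mk_shares <- function(top_sp, top_share) {
    rbind(
      data.frame(metabolite = "m", species = c(top_sp, "other"),
                 role = "producer",
                 amount = c(top_share, 100 - top_share),
                 share = c(top_share, 100 - top_share),
                 stringsAsFactors = FALSE),
      data.frame(metabolite = "m", species = "third", role = "consumer",
                 amount = 5, share = 100, stringsAsFactors = FALSE))
  }
  a <- mk_shares("key", 60)      # keystone dominates production in group A
  b <- mk_shares("notkey", 90)   # a different taxon dominates in group B
  # keystone >= 30%, >= 1% cross-consumed, distinct top producers: selected
  expect_identical(select_keystone_metabolites(a, b, "key"), "m")
  # keystone at 20% everywhere -> excluded by the 30% filter
  low_a <- mk_shares("someone", 80)
  low_a$species[low_a$role == "producer"][2] <- "key"
  expect_identical(select_keystone_metabolites(low_a, b, "key"), character())
  # same top producer in both groups -> excluded
  expect_identical(select_keystone_metabolites(a, a, "key"), character())
  # not cross-fed: no consumption by taxa other than the top producer
  nc_a <- a[a$role == "producer", ]
  nc_b <- b[b$role == "producer", ]
  expect_identical(select_keystone_metabolites(nc_a, nc_b, "key"),
                   character())
  expect_error(select_keystone_metabolites(a, b, "ghost"), "unknown keystone")
})
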