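# Sample-level functional-content metrics: incidence matrices,
# dissimilarities, ordination, mutual information, community metabolic
# dissimilarity (CMD) and metabolic resource overlap (MRO).

#' Build a sample x feature incidence matrix
#'
#' Binary mode marks a feature present when any member species' model
#' carries it; weighted mode sums members' relative abundances over the
#' species carrying the feature.
#'
#' @param samples list of [community_sample()]s.
#' @param models named list of [gem()]s covering every member species.
#' @param mode `"binary"` or `"weighted"`.
#' @param feature `"reaction"`, `"pathway"` or `"EC"`.
#' @return numeric matrix, samples x features.
#' @export
build_incidence <- function(samples, models,
                            mode = c("binary", "weighted"),
                            feature = c("reaction", "pathway", "EC")) {
  mode <- match.arg(mode)
  feature <- match.arg(feature)
  feat_fun <- switch(feature, reaction = reaction_id_set,
                     pathway = pathway_set, EC = ec_set)
  all_members <- unique(unlist(lapply(samples, function(s) names(s$members))))
  missing <- setdiff(all_members, names(models))
  if (length(missing) > 0L) {
    stop("species lacking model: ", paste(missing, collapse = ", "))
  }
  feats <- lapply(models, feat_fun)
  universe <- sort(unique(unlist(feats, use.names = FALSE)))
  M <- matrix(0, length(samples), length(universe),
              dimnames = list(vapply(samples, `[[`, "", "sample_id"),
                              universe))
  for (i in seq_along(samples)) {
    s <- samples[[i]]
    for (sp in names(s$members)) {
      f <- feats[[sp]]
      if (length(f) == 0L) next
      M[i, f] <- M[i, f] + if (mode == "weighted") s$members[[sp]] else 1
    }
  }
  if (mode == "binary") M <- (M > 0) + 0
  M
}

#' Pairwise dissimilarity between samples
#'
#' Jaccard distances on binary incidence, Bray-Curtis on non-negative
#' abundance-weighted incidence (both via [vegan::vegdist()]).
#'
#' @param matrix samples x features matrix.
#' @param metric `"jaccard"` or `"bray_curtis"`.
#' @return symmetric distance matrix with zero diagonal.
#' @export
dissimilarity <- function(matrix, metric = c("jaccard", "bray_curtis")) {
  metric <- match.arg(metric)
  if (any(matrix < 0)) stop("negative values in incidence matrix")
  if (metric == "jaccard" && !all(matrix %in% c(0, 1))) {
    stop("Jaccard distance requires a binary matrix")
  }
  d <- switch(metric,
              jaccard = vegan::vegdist(matrix, method = "jaccard",
                                       binary = TRUE),
              bray_curtis = vegan::vegdist(matrix, method = "bray"))
  as.matrix(d)
}

#' Principal coordinate analysis
#'
#' Classical scaling (centred-Gram eigendecomposition via
#' [stats::cmdscale()]); axes are ordered by eigenvalue and percent
#' variance is eigenvalue over the sum of positive eigenvalues.
#'
#' @param distances symmetric distance matrix.
#' @param k number of axes to return (default all with positive
#'   eigenvalue).
#' @return list with `coordinates` (samples x axes) and
#'   `percent_variance`.
#' @export
pcoa <- function(distances, k = NULL) {
  distances <- as.matrix(distances)
  if (!isTRUE(all.equal(distances, t(distances), tolerance = 1e-8))) {
    stop("distance matrix must be symmetric")
  }
  n <- nrow(distances)
  fit <- suppressWarnings(
    stats::cmdscale(stats::as.dist(distances), k = n - 1, eig = TRUE))
  eig <- fit$eig
  pos <- eig > 1e-10
  n_pos <- sum(pos)
  if (n_pos == 0L) {
    return(list(coordinates = matrix(0, n, 1,
                                     dimnames = list(rownames(distances),
                                                     "PCo1")),
                percent_variance = 0))
  }
  if (is.null(k)) k <- n_pos
  k <- min(k, n_pos)
  coords <- fit$points[, seq_len(k), drop = FALSE]
  colnames(coords) <- paste0("PCo", seq_len(k))
  pv <- 100 * eig[seq_len(k)] / sum(eig[pos])
  list(coordinates = coords, percent_variance = pv)
}

#' Mutual information between two binary functional profiles
#'
#' Treats the R features of the shared universe as R paired observations
#' of (x, y) in {0,1}^2 and returns the discrete mutual information
#' `sum p(x,y) log(p(x,y) / (p(x) p(y)))` in nats, with 0 log 0 = 0.
#'
#' @param x,y binary vectors over the same feature universe.
#' @return non-negative mutual information (nats).
#' @export
mutual_information <- function(x, y) {
  if (length(x) == 0L) stop("empty feature universe")
  if (length(x) != length(y)) stop("profiles must share one universe")
  n <- length(x)
  mi <- 0
  for (a in c(0, 1)) for (b in c(0, 1)) {
    pxy <- sum(x == a & y == b) / n
    if (pxy > 0) {
      px <- sum(x == a) / n
      py <- sum(y == b) / n
      mi <- mi + pxy * log(pxy / (px * py))
    }
  }
  max(mi, 0)
}

#' Pairwise mutual-information matrix over samples
#'
#' @param incidence binary samples x features matrix (see
#'   [build_incidence()]).
#' @return symmetric matrix of MI scores (nats).
#' @export
mi_matrix <- function(incidence) {
  n <- nrow(incidence)
  M <- matrix(0, n, n, dimnames = list(rownames(incidence),
                                       rownames(incidence)))
  if (n < 2L) return(M)
  for (i in seq_len(n - 1L)) for (j in seq(i + 1L, n)) {
    M[i, j] <- M[j, i] <- mutual_information(incidence[i, ], incidence[j, ])
  }
  M
}

#' Community metabolic dissimilarity
#'
#' Mean off-diagonal pairwise Jaccard distance between member species' EC
#' sets, adjusted for community size by multiplying with `log2(S)` so that
#' additional species contribute with diminishing weight. The unadjusted
#' mean is returned alongside so other adjustments can be applied.
#'
#' @param models list of member [gem()]s (length S >= 2) whose EC sets are
#'   compared.
#' @return list with `cmd` (adjusted), `mean_distance` (unadjusted) and
#'   `n_species`.
#' @export
cmd_score <- function(models) {
  S <- length(models)
  if (S < 2L) stop("community must contain at least 2 species")
  sets <- lapply(models, ec_set)
  d <- 0; npair <- 0L
  for (i in seq_len(S - 1L)) for (j in seq(i + 1L, S)) {
    a <- sets[[i]]; b <- sets[[j]]
    u <- length(union(a, b))
    d <- d + if (u == 0L) 0 else 1 - length(intersect(a, b)) / u
    npair <- npair + 1L
  }
  mean_d <- d / npair
  list(cmd = mean_d * log2(S), mean_distance = mean_d, n_species = S)
}

#' Metabolic resource overlap
#'
#' Computes each member's minimal nutrient requirement on the diet (via
#' [minimal_medium()]) and returns the mean over unordered member pairs of
#' `|Mi intersect Mj| / min(|Mi|, |Mj|)`.
#'
#' @param models list of member [gem()]s (length >= 2).
#' @param diet_nutrients character vector of candidate nutrients (the
#'   dietary metabolites).
#' @param growth_threshold minimum growth rate defining "grows".
#' @param minimal_media optional precomputed list of minimal media (named
#'   by species id) to avoid recomputation.
#' @return list with `mro`, `minimal_media` and `n_species`.
#' @export
mro_score <- function(models, diet_nutrients,
                      growth_threshold = cecosim_tolerances()$growth_threshold,
                      minimal_media = NULL) {
  S <- length(models)
  if (S < 2L) stop("community must contain at least 2 species")
  ids <- vapply(models, `[[`, "", "species_id")
  if (is.null(minimal_media)) {
    minimal_media <- lapply(models, function(m) {
      tryCatch(minimal_medium(m, diet_nutrients, growth_threshold),
               error = function(e) {
                 stop("member fails to grow on the diet: ", m$species_id,
                      call. = FALSE)
               })
    })
    names(minimal_media) <- ids
  }
  media <- minimal_media[ids]
  tot <- 0; npair <- 0L
  for (i in seq_len(S - 1L)) for (j in seq(i + 1L, S)) {
    a <- media[[i]]; b <- media[[j]]
    mn <- min(length(a), length(b))
    tot <- tot + if (mn == 0L) 0 else length(intersect(a, b)) / mn
    npair <- npair + 1L
  }
  list(mro = tot / npair, minimal_media = media, n_species = S)
}
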