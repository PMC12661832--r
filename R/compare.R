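# Group-level comparison of exchange fluxes and SCFA validation.

#' Aggregate exchange fluxes per sample
#'
#' For each metabolite: at every hour, species fluxes are summed and
#' divided by the total number of individuals at that hour; the normalised
#' hourly values are summed over the simulation and averaged over
#' replicates.
#'
#' @param records FluxRecord data.frame of one sample (replicate,
#'   iteration, species, metabolite, flux).
#' @param population population series of the same run (replicate,
#'   iteration, species, count).
#' @return named numeric vector, metabolite -> normalised aggregate net
#'   flux.
#' @export
aggregate_exchange_fluxes <- function(records, population) {
  if (is.null(records) || nrow(records) == 0L) return(numeric())
  totals <- stats::aggregate(count ~ replicate + iteration, population, sum)
  key <- paste(totals$replicate, totals$iteration)
  N <- stats::setNames(totals$count, key)
  rk <- paste(records$replicate, records$iteration)
  miss <- setdiff(unique(rk), names(N))
  if (length(miss) > 0L) {
    stop("population series does not cover recorded hours: ",
         paste(miss, collapse = ", "))
  }
  if (any(N[unique(rk)] == 0)) {
    stop("zero population at a recorded hour: inconsistent records")
  }
  norm <- records$flux / N[rk]
  agg <- tapply(norm, records$metabolite, sum)
  n_rep <- length(unique(records$replicate))
  stats::setNames(as.numeric(agg) / n_rep, names(agg))
}

#' Wilcoxon rank-sum test
#'
#' Exact enumeration p-value for group sizes up to `exact_max` without
#' ties; tie-corrected normal approximation (with continuity correction)
#' otherwise.
#'
#' @param x,y numeric samples.
#' @param exact_max switch point for the exact test.
#' @return two-sided p-value.
#' @export
wilcoxon_p <- function(x, y, exact_max = 8) {
  if (length(unique(c(x, y))) == 1L) return(1)   # no evidence either way
  ties <- anyDuplicated(c(x, y)) > 0L
  use_exact <- length(x) <= exact_max && length(y) <= exact_max && !ties
  suppressWarnings(
    stats::wilcox.test(x, y, exact = use_exact,
                       correct = !use_exact)$p.value)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' @param p numeric vector of p-values.
#' @return step-up FDR-adjusted q-values (monotone, capped at 1).
#' @export
bh_adjust <- function(p) stats::p.adjust(p, method = "BH")

exchange_categories <- function() {
  c("increased consumption in HB", "increased production in HB",
    "increased consumption in NB", "increased production in NB",
    "production in NB to consumption in HB",
    "consumption in NB to production in HB",
    "not significant")
}

#' Compare exchange fluxes between two community groups
#'
#' Runs a Wilcoxon rank-sum test per metabolite on per-sample normalised
#' aggregate net fluxes, applies Benjamini-Hochberg correction across
#' metabolites, computes the log2 fold change of group means of flux
#' magnitudes (with pseudo-count, since net fluxes may cross zero between
#' groups), and assigns one of six exchange-direction categories from the
#' signs of the group means. A metabolite is categorised only when
#' `q < alpha` and `|log2FC| > fc_label_threshold`; otherwise it is "not
#' significant".
#'
#' @param values matrix of per-sample aggregate net fluxes (samples x
#'   metabolites) or data.frame thereof.
#' @param groups factor/character vector per sample, with levels `HB` and
#'   `NB`.
#' @param alpha FDR significance level.
#' @param fc_label_threshold minimum absolute log2 fold change for
#'   category labelling.
#' @param pseudo pseudo-count added to mean magnitudes before the ratio.
#' @return data.frame: metabolite, mean_HB, mean_NB, log2FC, p, q,
#'   significant, category.
#' @export
compare_groups <- function(values, groups, alpha = 0.05,
                           fc_label_threshold = 0.7, pseudo = 1e-9) {
  values <- as.matrix(values)
  groups <- as.character(groups)
  if (length(groups) != nrow(values)) {
    stop("one group label per sample row required")
  }
  if (!all(groups %in% c("HB", "NB"))) stop("groups must be HB or NB")
  if (sum(groups == "HB") < 2 || sum(groups == "NB") < 2) {
    stop("each group needs at least 2 samples")
  }
  hb <- values[groups == "HB", , drop = FALSE]
  nb <- values[groups == "NB", , drop = FALSE]
  mets <- colnames(values)
  p <- vapply(seq_along(mets), function(j) wilcoxon_p(hb[, j], nb[, j]), 0)
  q <- bh_adjust(p)
  mean_hb <- colMeans(hb)
  mean_nb <- colMeans(nb)
  log2fc <- log2((abs(mean_hb) + pseudo) / (abs(mean_nb) + pseudo))
  significant <- q < alpha
  category <- vapply(seq_along(mets), function(j) {
    if (!significant[j] || abs(log2fc[j]) <= fc_label_threshold) {
      return("not significant")
    }
    mh <- mean_hb[j]; mn <- mean_nb[j]
    if (mh >= 0 && mn >= 0) {
      if (mh > mn) "increased production in HB" else
        "increased production in NB"
    } else if (mh <= 0 && mn <= 0) {
      if (mh < mn) "increased consumption in HB" else
        "increased consumption in NB"
    } else if (mn > 0 && mh < 0) {
      "production in NB to consumption in HB"
    } else {
      "consumption in NB to production in HB"
    }
  }, "")
  data.frame(metabolite = mets, mean_HB = as.numeric(mean_hb),
             mean_NB = as.numeric(mean_nb), log2FC = as.numeric(log2fc),
             p = p, q = q, significant = significant, category = category,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Spearman validation of predicted against measured concentrations
#'
#' Tie-corrected Spearman rank correlation per metabolite; exact
#' permutation p-value for n <= 9 without ties, t approximation otherwise.
#' Constant vectors give an undefined correlation, reported as `NA` with a
#' note.
#'
#' @param predicted,measured numeric matrices or data.frames (samples x
#'   metabolites) with matching dimensions, or plain vectors for a single
#'   metabolite.
#' @return data.frame: metabolite, rho, p, n, note.
#' @export
validate_scfa <- function(predicted, measured) {
  predicted <- as.matrix(predicted)
  measured <- as.matrix(measured)
  if (!all(dim(predicted) == dim(measured))) {
    stop("predicted and measured must have matching dimensions")
  }
  mets <- colnames(predicted)
  if (is.null(mets)) mets <- paste0("V", seq_len(ncol(predicted)))
  rows <- lapply(seq_len(ncol(predicted)), function(j) {
    x <- predicted[, j]; y <- measured[, j]
    ok <- stats::complete.cases(x, y)
    x <- x[ok]; y <- y[ok]
    n <- length(x)
    if (n < 3L) {
      return(data.frame(metabolite = mets[j], rho = NA_real_, p = NA_real_,
                        n = n, note = "fewer than 3 pairs",
                        stringsAsFactors = FALSE))
    }
    if (stats::sd(x) == 0 || stats::sd(y) == 0) {
      return(data.frame(metabolite = mets[j], rho = NA_real_, p = NA_real_,
                        n = n, note = "constant vector: rho undefined",
                        stringsAsFactors = FALSE))
    }
    ties <- anyDuplicated(x) > 0L || anyDuplicated(y) > 0L
    ct <- suppressWarnings(
      stats::cor.test(x, y, method = "spearman",
                      exact = n <= 9 && !ties))
    data.frame(metabolite = mets[j], rho = unname(ct$estimate),
               p = ct$p.value, n = n, note = "", stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
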