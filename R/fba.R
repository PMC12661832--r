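# Flux balance analysis and minimal-medium computation.

#' Package-wide numeric tolerances
#'
#' Single place for the numeric tolerances used throughout: LP feasibility,
#' optimality comparisons, and the default growth threshold (1/h) below
#' which a model is considered not to grow.
#'
#' @return named list with `feasibility`, `optimality`, `growth_threshold`.
#' @export
cecosim_tolerances <- function() {
  list(feasibility = 1e-9, optimality = 1e-6, growth_threshold = 1e-4)
}

#' Flux balance analysis with parsimonious secondary objective
#'
#' Maximises biomass flux subject to steady state (`S v = 0`) and reaction
#' bounds, with each exchange reaction's lower bound tightened to
#' `-uptake_bounds[metabolite]` (0 for metabolites not listed, i.e. the
#' environment supplies nothing by default). At the fixed growth optimum a
#' second LP minimises the sum of absolute fluxes (parsimonious FBA) so
#' that reported exchange fluxes — the raw data of every downstream
#' statistic — are reproducible rather than an arbitrary member of the
#' optimal face.
#'
#' @param model a [gem()].
#' @param uptake_bounds named numeric vector, metabolite id -> maximal
#'   uptake rate (mmol/gDW/h, non-negative).
#' @param pfba logical; run the parsimonious second stage (default TRUE).
#' @return an object of class `fba_solution`: list with `objective_value`
#'   (growth rate 1/h), `fluxes` (named, mmol/gDW/h), `status`
#'   ("optimal" or "infeasible").
#' @export
solve_fba <- function(model, uptake_bounds = numeric(), pfba = TRUE) {
  solve_fba_compiled(compile_fba(model), uptake_bounds, pfba = pfba)
}

# Precompute the LP skeleton of a model once; the simulator calls this per
# species rather than per individual-hour.
compile_fba <- function(model) {
  S <- stoichiometric_matrix(model)
  rxn_ids <- colnames(S)
  lb <- vapply(model$reactions, `[[`, 0, "lower_bound")[rxn_ids]
  ub <- vapply(model$reactions, `[[`, 0, "upper_bound")[rxn_ids]
  ex <- Filter(function(r) r$is_exchange, model$reactions)
  list(S = S, rxn_ids = rxn_ids, lb = lb, ub = ub,
       biomass_idx = match(model$biomass_reaction_id, rxn_ids),
       ex_rxn = vapply(ex, `[[`, "", "id"),
       ex_met = vapply(ex, function(r) names(r$stoichiometry), ""))
}

solve_fba_compiled <- function(prob, uptake_bounds = numeric(), pfba = TRUE) {
  if (length(uptake_bounds) > 0L) {
    if (is.null(names(uptake_bounds))) {
      stop("uptake_bounds must be named by metabolite id")
    }
    if (any(uptake_bounds < 0)) stop("negative uptake bound")
  }
  lb <- prob$lb
  ub <- prob$ub
  caps <- stats::setNames(rep(0, length(prob$ex_met)), prob$ex_met)
  hit <- intersect(names(uptake_bounds), prob$ex_met)
  caps[hit] <- uptake_bounds[hit]
  lb[prob$ex_rxn] <- pmax(lb[prob$ex_rxn], -caps)
  lb[prob$ex_rxn] <- pmin(lb[prob$ex_rxn], ub[prob$ex_rxn])
  if (any(lb > ub)) stop("malformed bounds: lower bound exceeds upper bound")
  rxn_ids <- prob$rxn_ids
  n <- length(rxn_ids)
  obj <- numeric(n)
  obj[prob$biomass_idx] <- 1
  res <- lp_solve_bounded(obj, prob$S, rep(0, nrow(prob$S)), lb, ub,
                          maximize = TRUE)
  if (res$status != "optimal") {
    return(structure(list(objective_value = NA_real_,
                          fluxes = NULL, status = "infeasible"),
                     class = "fba_solution"))
  }
  mu <- res$objective
  v <- res$x
  if (mu < 1e-10 && all(lb <= 0) && all(ub >= 0)) {
    # zero growth with a free origin: the parsimonious optimum is v = 0
    v <- numeric(n)
    mu <- 0
  } else if (pfba && n > 0L) {
    v2 <- pfba_stage(prob$S, lb, ub, prob$biomass_idx, mu)
    if (!is.null(v2)) v <- v2
  }
  structure(list(objective_value = mu,
                 fluxes = stats::setNames(v, rxn_ids),
                 status = "optimal"),
            class = "fba_solution")
}

# Minimise sum |v| at fixed growth: split v = p - q with p, q >= 0.
pfba_stage <- function(S, lb, ub, biomass_idx, mu) {
  n <- ncol(S)
  big <- 1e6
  up <- pmin(pmax(ub, 0), big)     # cap on p
  uq <- pmin(pmax(-lb, 0), big)    # cap on q
  # equality rows: S(p - q) = 0 plus fixed biomass flux
  A_eq <- cbind(S, -S)
  b_eq <- rep(0, nrow(S))
  bio <- numeric(2 * n)
  bio[biomass_idx] <- 1
  bio[n + biomass_idx] <- -1
  A_eq <- rbind(A_eq, bio)
  b_eq <- c(b_eq, mu)
  # bound rows: p <= up, q <= uq, and original l <= v for l > 0 / v <= u for u < 0
  A_ub <- rbind(cbind(diag(1, n), matrix(0, n, n)),
                cbind(matrix(0, n, n), diag(1, n)))
  b_ub <- c(up, uq)
  pos_lb <- which(lb > 0)
  if (length(pos_lb) > 0L) {
    extra <- matrix(0, length(pos_lb), 2 * n)
    extra[cbind(seq_along(pos_lb), pos_lb)] <- -1
    extra[cbind(seq_along(pos_lb), n + pos_lb)] <- 1
    A_ub <- rbind(A_ub, extra)
    b_ub <- c(b_ub, -lb[pos_lb])
  }
  neg_ub <- which(ub < 0)
  if (length(neg_ub) > 0L) {
    extra <- matrix(0, length(neg_ub), 2 * n)
    extra[cbind(seq_along(neg_ub), neg_ub)] <- 1
    extra[cbind(seq_along(neg_ub), n + neg_ub)] <- -1
    A_ub <- rbind(A_ub, extra)
    b_ub <- c(b_ub, ub[neg_ub])
  }
  res <- lp_solve(rep(1, 2 * n), A_ub = A_ub, b_ub = b_ub,
                  A_eq = A_eq, b_eq = b_eq, maximize = FALSE)
  if (res$status != "optimal") return(NULL)
  res$x[seq_len(n)] - res$x[n + seq_len(n)]
}

#' @export
print.fba_solution <- function(x, ...) {
  cat("<fba_solution> status:", x$status, "\n")
  if (x$status == "optimal") {
    cat("  growth rate:", format(x$objective_value, digits = 6), "1/h\n")
    nz <- x$fluxes[abs(x$fluxes) > 1e-9]
    cat("  nonzero fluxes:", length(nz), "of", length(x$fluxes), "\n")
  }
  invisible(x)
}

#' Growth rate on a defined nutrient set
#'
#' Convenience wrapper: uptake opened (at `vmax`) only for the given
#' metabolites.
#'
#' @param model a [gem()].
#' @param nutrients character vector of metabolite ids.
#' @param vmax uptake cap applied to each nutrient (mmol/gDW/h).
#' @return growth rate (1/h); 0 if infeasible.
#' @export
growth_on <- function(model, nutrients, vmax = 10) {
  ub <- stats::setNames(rep(vmax, length(nutrients)), nutrients)
  sol <- solve_fba(model, ub, pfba = FALSE)
  if (sol$status != "optimal") 0 else sol$objective_value
}

#' Minimal growth-supporting nutrient set
#'
#' Finds a minimal subset of `candidate_nutrients` on which the model grows
#' at or above `growth_threshold`. Two modes: deterministic greedy
#' elimination in lexicographic metabolite order (default; each nutrient is
#' dropped in turn and left out permanently if growth persists), or exact
#' exhaustive search over all subsets by increasing cardinality
#' (`exact = TRUE`, practical for <= 12 candidates). Both are deterministic
#' for fixed inputs.
#'
#' @param model a [gem()].
#' @param candidate_nutrients character vector of metabolite ids to choose
#'   from.
#' @param growth_threshold minimum growth rate (1/h).
#' @param vmax per-nutrient uptake cap used during the search.
#' @param exact logical; exhaustive minimal-cardinality search.
#' @return character vector of metabolite ids (lexicographically sorted).
#' @export
minimal_medium <- function(model, candidate_nutrients,
                           growth_threshold = cecosim_tolerances()$growth_threshold,
                           vmax = 10, exact = FALSE) {
  cand <- sort(unique(as.character(candidate_nutrients)))
  if (growth_on(model, cand, vmax) < growth_threshold) {
    stop("model cannot grow on medium: '", model$species_id,
         "' fails to reach the growth threshold on the full candidate set")
  }
  if (exact) {
    if (length(cand) > 12L) {
      stop("exact search supported for at most 12 candidates")
    }
    for (k in 0:length(cand)) {
      subsets <- utils::combn(cand, k, simplify = FALSE)
      for (s in subsets) {
        if (growth_on(model, s, vmax) >= growth_threshold) return(sort(s))
      }
    }
  }
  keep <- cand
  for (met in cand) {
    trial <- setdiff(keep, met)
    if (growth_on(model, trial, vmax) >= growth_threshold) keep <- trial
  }
  sort(keep)
}
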