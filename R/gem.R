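# Genome-scale metabolic model (GEM) containers.
#
# A GEM here is a plain list-based S3 object: metabolites, reactions with
# stoichiometry/bounds/annotations, and a designated biomass reaction whose
# flux is the growth rate (1/h). Exchange reactions move a single metabolite
# across the cell boundary; by convention their stoichiometry is
# {metabolite: -1}, so negative flux is uptake and positive flux secretion.

#' Construct a reaction
#'
#' @param id short unique reaction identifier.
#' @param stoichiometry named numeric vector, metabolite id -> signed
#'   coefficient (negative = consumed).
#' @param lower_bound,upper_bound flux bounds in mmol/gDW/h.
#' @param is_exchange logical; exchange reactions must touch exactly one
#'   metabolite.
#' @param ec_numbers character vector of EC numbers.
#' @param pathways character vector of pathway labels.
#' @return an object of class `gem_reaction`.
#' @export
reaction <- function(id, stoichiometry, lower_bound = 0, upper_bound = 1000,
                     is_exchange = FALSE, ec_numbers = character(),
                     pathways = character()) {
  stopifnot(is.character(id), length(id) == 1L)
  if (length(stoichiometry) == 0L) {
    stop("reaction '", id, "': stoichiometry must be non-empty")
  }
  if (is.null(names(stoichiometry)) || any(!nzchar(names(stoichiometry)))) {
    stop("reaction '", id, "': stoichiometry must be a named vector")
  }
  if (!is.numeric(lower_bound) || !is.numeric(upper_bound) ||
      lower_bound > upper_bound) {
    stop("reaction '", id, "': lower_bound must not exceed upper_bound")
  }
  if (isTRUE(is_exchange) && length(stoichiometry) != 1L) {
    stop("reaction '", id, "': exchange reactions touch exactly one metabolite")
  }
  structure(
    list(id = id,
         stoichiometry = stats::setNames(as.numeric(stoichiometry),
                                         names(stoichiometry)),
         lower_bound = as.numeric(lower_bound),
         upper_bound = as.numeric(upper_bound),
         is_exchange = isTRUE(is_exchange),
         ec_numbers = as.character(ec_numbers),
         pathways = as.character(pathways)),
    class = "gem_reaction")
}

#' Construct a metabolite
#'
#' @param id short unique metabolite identifier.
#' @param name free-text name.
#' @param is_dietary logical; whether the metabolite enters with the diet
#'   influx at nonzero concentration (see [mark_dietary()]).
#' @return an object of class `gem_metabolite`.
#' @export
metabolite <- function(id, name = id, is_dietary = FALSE) {
  stopifnot(is.character(id), length(id) == 1L)
  structure(list(id = id, name = name, is_dietary = isTRUE(is_dietary)),
            class = "gem_metabolite")
}

#' Construct a genome-scale metabolic model
#'
#' Validates structural invariants: the biomass reaction must exist, every
#' stoichiometry key must resolve to a declared metabolite, and metabolite
#' ids must be unique.
#'
#' @param species_id species identifier used in all downstream tables.
#' @param metabolites list of [metabolite()] objects.
#' @param reactions list of [reaction()] objects.
#' @param biomass_reaction_id id of the biomass (objective) reaction.
#' @return an object of class `gem`.
#' @export
gem <- function(species_id, metabolites, reactions, biomass_reaction_id) {
  met_ids <- vapply(metabolites, `[[`, "", "id")
  if (anyDuplicated(met_ids)) stop("duplicate metabolite ids in model")
  rxn_ids <- vapply(reactions, `[[`, "", "id")
  if (anyDuplicated(rxn_ids)) stop("duplicate reaction ids in model")
  if (!biomass_reaction_id %in% rxn_ids) {
    stop("no biomass reaction: '", biomass_reaction_id,
         "' not among reactions of '", species_id, "'")
  }
  for (r in reactions) {
    unknown <- setdiff(names(r$stoichiometry), met_ids)
    if (length(unknown) > 0L) {
      stop("reaction '", r$id, "' references unknown metabolite id(s): ",
           paste(unknown, collapse = ", "))
    }
  }
  names(metabolites) <- met_ids
  names(reactions) <- rxn_ids
  structure(
    list(species_id = species_id,
         metabolites = metabolites,
         reactions = reactions,
         biomass_reaction_id = biomass_reaction_id),
    class = "gem")
}

#' @export
print.gem <- function(x, ...) {
  cat("<gem>", x$species_id, "\n")
  cat("  reactions:  ", length(x$reactions),
      " (", sum(vapply(x$reactions, `[[`, TRUE, "is_exchange")),
      " exchange)\n", sep = "")
  cat("  metabolites:", length(x$metabolites), "\n")
  cat("  biomass:    ", x$biomass_reaction_id, "\n")
  cat("  ECs:", length(ec_set(x)), " pathways:", length(pathway_set(x)), "\n")
  invisible(x)
}

#' Derived annotation sets of a model
#'
#' `ec_set()` is the union of reaction EC numbers, `pathway_set()` the union
#' of pathway labels, `reaction_id_set()` the reaction identifiers.
#'
#' @param model a [gem()].
#' @return character vector (sorted, unique).
#' @export
ec_set <- function(model) {
  sort(unique(unlist(lapply(model$reactions, `[[`, "ec_numbers"),
                     use.names = FALSE)))
}

#' @rdname ec_set
#' @export
pathway_set <- function(model) {
  sort(unique(unlist(lapply(model$reactions, `[[`, "pathways"),
                     use.names = FALSE)))
}

#' @rdname ec_set
#' @export
reaction_id_set <- function(model) sort(names(model$reactions))

#' Exchange metabolites of a model
#'
#' @param model a [gem()].
#' @return named character vector mapping exchange reaction id -> metabolite
#'   id.
#' @export
exchange_metabolites <- function(model) {
  ex <- Filter(function(r) r$is_exchange, model$reactions)
  vapply(ex, function(r) names(r$stoichiometry), "")
}

#' Stoichiometric matrix of a model
#'
#' @param model a [gem()].
#' @return numeric matrix, metabolites x reactions.
#' @export
stoichiometric_matrix <- function(model) {
  met_ids <- names(model$metabolites)
  rxn_ids <- names(model$reactions)
  S <- matrix(0, length(met_ids), length(rxn_ids),
              dimnames = list(met_ids, rxn_ids))
  for (r in model$reactions) {
    S[names(r$stoichiometry), r$id] <- r$stoichiometry
  }
  S
}

#' Flag dietary metabolites from a diet specification
#'
#' Sets each metabolite's `is_dietary` flag to whether the diet delivers it
#' at nonzero influx concentration, keeping model and diet consistent.
#'
#' @param model a [gem()].
#' @param diet a [diet_spec()].
#' @return the model with updated flags.
#' @export
mark_dietary <- function(model, diet) {
  dietary <- dietary_metabolites(diet)
  model$metabolites <- lapply(model$metabolites, function(m) {
    m$is_dietary <- m$id %in% dietary
    m
  })
  model
}
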