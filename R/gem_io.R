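# Model readers/writers.
#
# Two formats are supported: a compact JSON dialect (documented in
# inst/extdata/model-schema.md, lossless round-trip) and SBML Level 3 with
# the fbc extension (read-only). The JSON dialect flags exchange reactions
# with an explicit boolean rather than relying on an "EX_" naming
# convention, which differs between toolchains.

#' Read a metabolic model
#'
#' @param path path to the model file.
#' @param format `"json"` for the package's JSON dialect, `"sbml"` for SBML
#'   Level 3 + fbc.
#' @return a [gem()].
#' @export
read_model <- function(path, format = c("json", "sbml")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("model file does not exist: ", path)
  switch(format,
         json = read_model_json(path),
         sbml = read_model_sbml(path))
}

#' Write a metabolic model in the JSON dialect
#'
#' `read_model(write_model(m, f), "json")` reproduces `m` exactly.
#'
#' @param model a [gem()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_model <- function(model, path) {
  mets <- lapply(model$metabolites, function(m) {
    list(id = m$id, name = m$name, is_dietary = m$is_dietary)
  })
  rxns <- lapply(model$reactions, function(r) {
    list(id = r$id,
         stoichiometry = as.list(r$stoichiometry),
         lower_bound = r$lower_bound,
         upper_bound = r$upper_bound,
         is_exchange = r$is_exchange,
         ec_numbers = as.list(r$ec_numbers),
         pathways = as.list(r$pathways))
  })
  obj <- list(species_id = model$species_id,
              biomass_reaction_id = model$biomass_reaction_id,
              metabolites = unname(mets),
              reactions = unname(rxns))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

read_model_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  for (field in c("species_id", "biomass_reaction_id", "metabolites",
                  "reactions")) {
    if (is.null(obj[[field]])) {
      if (field == "biomass_reaction_id") stop("no biomass reaction in ", path)
      stop("model JSON missing field '", field, "': ", path)
    }
  }
  mets <- lapply(obj$metabolites, function(m) {
    metabolite(m$id, name = if (is.null(m$name)) m$id else m$name,
               is_dietary = isTRUE(m$is_dietary))
  })
  rxns <- lapply(obj$reactions, function(r) {
    st <- unlist(r$stoichiometry)
    reaction(r$id, st,
             lower_bound = r$lower_bound,
             upper_bound = r$upper_bound,
             is_exchange = isTRUE(r$is_exchange),
             ec_numbers = unlist(r$ec_numbers) %||% character(),
             pathways = unlist(r$pathways) %||% character())
  })
  gem(obj$species_id, mets, rxns, obj$biomass_reaction_id)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

read_model_sbml <- function(path) {
  doc <- xml2::read_xml(path)
  # strip namespaces for uniform XPath; fbc attributes keep their prefix in
  # the attribute name, which xml2 exposes verbatim
  model_node <- xml2::xml_find_first(doc, ".//*[local-name()='model']")
  if (is.na(xml2::xml_name(model_node))) stop("no <model> element in ", path)
  species_id <- xml2::xml_attr(model_node, "id") %||% "model"
  if (is.na(species_id)) species_id <- "model"

  sp_nodes <- xml2::xml_find_all(
    doc, ".//*[local-name()='listOfSpecies']/*[local-name()='species']")
  sp_ids <- xml2::xml_attr(sp_nodes, "id")
  boundary <- xml2::xml_attr(sp_nodes, "boundaryCondition") %in% "true"
  names(boundary) <- sp_ids
  sp_names <- xml2::xml_attr(sp_nodes, "name")
  sp_names[is.na(sp_names)] <- sp_ids[is.na(sp_names)]

  par_nodes <- xml2::xml_find_all(
    doc, ".//*[local-name()='listOfParameters']/*[local-name()='parameter']")
  par_val <- as.numeric(xml2::xml_attr(par_nodes, "value"))
  names(par_val) <- xml2::xml_attr(par_nodes, "id")

  # objective -> biomass reaction
  fo <- xml2::xml_find_first(doc, ".//*[local-name()='fluxObjective']")
  if (is.na(xml2::xml_name(fo))) stop("no biomass reaction (SBML file has no fbc objective): ", path)
  biomass_id <- xml2::xml_attr(fo, "reaction")
  if (is.na(biomass_id)) {
    attrs <- xml2::xml_attrs(fo)
    hit <- grep("reaction$", names(attrs))
    if (length(hit) == 0L) stop("no biomass reaction (objective lacks a reaction reference): ", path)
    biomass_id <- attrs[[hit[1L]]]
  }

  rx_nodes <- xml2::xml_find_all(
    doc, ".//*[local-name()='listOfReactions']/*[local-name()='reaction']")
  any_ec <- FALSE
  rxns <- lapply(rx_nodes, function(node) {
    rid <- xml2::xml_attr(node, "id")
    attrs <- xml2::xml_attrs(node)
    get_fbc <- function(key, default) {
      hit <- grep(paste0(key, "$"), names(attrs))
      if (length(hit) == 0L) return(default)
      v <- par_val[attrs[[hit[1L]]]]
      if (is.na(v)) default else v
    }
    reversible <- identical(xml2::xml_attr(node, "reversible"), "true")
    lb <- get_fbc("lowerFluxBound", if (reversible) -1000 else 0)
    ub <- get_fbc("upperFluxBound", 1000)
    refs <- function(which) {
      rn <- xml2::xml_find_all(
        node, paste0("./*[local-name()='", which,
                     "']/*[local-name()='speciesReference']"))
      ids <- xml2::xml_attr(rn, "species")
      coef <- as.numeric(xml2::xml_attr(rn, "stoichiometry"))
      coef[is.na(coef)] <- 1
      stats::setNames(coef, ids)
    }
    reac <- refs("listOfReactants")
    prod <- refs("listOfProducts")
    st <- c(-reac, prod)
    st <- tapply(st, names(st), sum)
    st <- stats::setNames(as.numeric(st), names(st))
    bflag <- boundary[names(st)]
    bflag[is.na(bflag)] <- FALSE
    internal <- st[!bflag]
    ec <- character()
    res <- xml2::xml_find_all(node, ".//*[local-name()='li']")
    if (length(res) > 0L) {
      uris <- unlist(xml2::xml_attrs(res))
      hits <- grep("ec-code", uris, value = TRUE)
      ec <- sub(".*ec-code[/:]", "", hits)
      if (length(ec) > 0L) any_ec <<- TRUE
    }
    reaction(rid, internal,
             lower_bound = lb, upper_bound = ub,
             is_exchange = length(internal) == 1L,
             ec_numbers = ec)
  })

  if (!any_ec) {
    warning("no EC annotations found in ", basename(path),
            "; ec_set will be empty")
  }
  used <- unique(unlist(lapply(rxns, function(r) names(r$stoichiometry))))
  keep <- sp_ids %in% used
  mets <- Map(metabolite, sp_ids[keep], sp_names[keep])
  gem(species_id, mets, rxns, biomass_id)
}
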