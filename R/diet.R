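# Diet specification: what flows into the cecum each hour.
#
# Each entry carries the raw upstream concentration (mM) and the fraction
# absorbed before material reaches the cecum; the effective influx
# concentration is raw * (1 - absorption_fraction).

#' Construct a diet specification
#'
#' @param entries data.frame with columns `metabolite`, `raw_concentration`
#'   (mM) and `absorption_fraction` (in \[0,1\]).
#' @return object of class `diet_spec` with a derived `influx_concentration`
#'   column.
#' @export
diet_spec <- function(entries) {
  req <- c("metabolite", "raw_concentration", "absorption_fraction")
  if (!all(req %in% names(entries))) {
    stop("diet entries need columns: ", paste(req, collapse = ", "))
  }
  if (any(entries$raw_concentration < 0)) {
    stop("negative concentration in diet")
  }
  if (any(entries$absorption_fraction < 0 | entries$absorption_fraction > 1)) {
    stop("absorption_fraction must lie in [0, 1]")
  }
  if (anyDuplicated(entries$metabolite)) stop("duplicate diet metabolite")
  entries$influx_concentration <-
    entries$raw_concentration * (1 - entries$absorption_fraction)
  rownames(entries) <- NULL
  structure(entries, class = c("diet_spec", "data.frame"))
}

#' Default synthetic cecal diet
#'
#' A toy rendering of a corn-based feed after upper-gut absorption: a
#' starch-like polysaccharide whose concentration is reduced by 97% before
#' reaching the cecum, a cellulose-like fiber that largely escapes
#' absorption, residual free glucose, plus urea and a mucin-derived sugar
#' (sialic-acid-like) contributed by the host and therefore not absorbed
#' upstream.
#'
#' @param overrides optional data.frame in the same format as
#'   [diet_spec()] entries; rows replace or extend the defaults by
#'   metabolite id.
#' @return a [diet_spec()].
#' @export
generate_diet <- function(overrides = NULL) {
  base <- data.frame(
    metabolite = c("starch", "fiber", "glc", "urea", "mucin"),
    raw_concentration = c(100, 40, 50, 30, 5),
    absorption_fraction = c(0.97, 0.10, 0.90, 0, 0),
    stringsAsFactors = FALSE)
  if (!is.null(overrides)) {
    overrides <- as.data.frame(overrides)
    keep <- !(base$metabolite %in% overrides$metabolite)
    base <- rbind(base[keep, , drop = FALSE],
                  overrides[, names(base), drop = FALSE])
  }
  diet_spec(base)
}

#' Metabolites delivered by a diet
#'
#' @param diet a [diet_spec()].
#' @return character vector of metabolite ids with nonzero influx
#'   concentration.
#' @export
dietary_metabolites <- function(diet) {
  diet$metabolite[diet$influx_concentration > 0]
}

#' Read or write a diet table
#'
#' Plain TSV with columns metabolite, raw_concentration,
#' absorption_fraction.
#'
#' @param path file path.
#' @return [read_diet()]: a [diet_spec()]; [write_diet()]: `path`,
#'   invisibly.
#' @export
read_diet <- function(path) {
  diet_spec(utils::read.delim(path, stringsAsFactors = FALSE))
}

#' @rdname read_diet
#' @param diet a [diet_spec()].
#' @export
write_diet <- function(diet, path) {
  utils::write.table(as.data.frame(diet)[, c("metabolite",
                                             "raw_concentration",
                                             "absorption_fraction")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
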