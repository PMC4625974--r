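# Reader/writer for the community genome-scale-model JSON dialect
# (metabolites/reactions arrays; each reaction carries a metabolite->coefficient
# map, bounds and an objective coefficient). Genome-scale models distributed
# in this dialect (e.g. BiGG exports) load unmodified.

#' Read a metabolic model from file
#'
#' @param path file path.
#' @param format `"json"` (community model dialect), `"sbml"` (Level 3 with
#'   the flux-balance extension), or `"auto"` to pick by file extension.
#' @param biomass_id optional explicit biomass reaction id; by default the
#'   reaction with a non-zero objective coefficient is used.
#' @return a validated [metabolic_model()].
#' @export
read_metabolic_model <- function(path, format = c("auto", "json", "sbml"),
                                 biomass_id = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "auto") {
    format <- if (grepl("\\.(xml|sbml)$", path, ignore.case = TRUE)) "sbml"
              else "json"
  }
  switch(format,
         json = read_model_json(path, biomass_id),
         sbml = read_model_sbml(path, biomass_id))
}

#' Write a metabolic model to file
#'
#' Serialization is deterministic: fields appear in a fixed order and numbers
#' are printed at full precision, so identical models produce byte-identical
#' files.
#'
#' @param model a `metabolic_model`.
#' @param path output file path.
#' @param format `"json"`, `"sbml"`, or `"auto"` (by extension).
#' @return `path`, invisibly.
#' @export
write_metabolic_model <- function(model, path,
                                  format = c("auto", "json", "sbml")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.(xml|sbml)$", path, ignore.case = TRUE)) "sbml"
              else "json"
  }
  switch(format,
         json = write_model_json(model, path),
         sbml = write_model_sbml(model, path))
  invisible(path)
}

read_model_json <- function(path, biomass_id = NULL) {
  doc <- tryCatch(
    jsonlite::fromJSON(path, simplifyVector = FALSE),
    error = function(e) {
      stop("cannot parse '", path, "' as model JSON: ", conditionMessage(e),
           call. = FALSE)
    }
  )
  if (is.null(doc$metabolites) || is.null(doc$reactions)) {
    stop("model JSON must contain 'metabolites' and 'reactions' arrays",
         call. = FALSE)
  }
  mets <- tibble::tibble(
    id = vapply(doc$metabolites, function(m) as.character(m$id), character(1)),
    name = vapply(doc$metabolites,
                  function(m) as.character(m$name %||% m$id), character(1)),
    compartment = vapply(doc$metabolites,
                         function(m) as.character(m$compartment %||% "c"),
                         character(1)),
    boundary = vapply(doc$metabolites,
                      function(m) isTRUE(m$boundary) ||
                        grepl("_b$", as.character(m$id)), logical(1))
  )
  rxn_id <- vapply(doc$reactions, function(r) as.character(r$id), character(1))
  rxns <- tibble::tibble(
    id = rxn_id,
    name = vapply(doc$reactions,
                  function(r) as.character(r$name %||% r$id), character(1)),
    lower_bound = vapply(doc$reactions,
                         function(r) as.numeric(r$lower_bound %||% -1000),
                         numeric(1)),
    upper_bound = vapply(doc$reactions,
                         function(r) as.numeric(r$upper_bound %||% 1000),
                         numeric(1)),
    objective_coefficient = vapply(
      doc$reactions,
      function(r) as.numeric(r$objective_coefficient %||% 0), numeric(1))
  )
  st <- purrr::map2_dfr(doc$reactions, rxn_id, function(r, id) {
    sm <- r$metabolites
    if (is.null(sm) || length(sm) == 0) {
      stop("reaction '", id, "' has empty stoichiometry", call. = FALSE)
    }
    tibble::tibble(reaction = id, metabolite = names(sm),
                   coefficient = as.numeric(unlist(sm)))
  })
  if (is.null(biomass_id)) {
    obj <- rxns$id[rxns$objective_coefficient != 0]
    if (length(obj) == 0) {
      stop("no reaction with non-zero objective coefficient; ",
           "pass biomass_id explicitly", call. = FALSE)
    }
    biomass_id <- obj[[1L]]
  }
  ann <- doc[setdiff(names(doc), c("metabolites", "reactions", "genes"))]
  metabolic_model(mets, rxns, st, biomass_id, annotations = ann)
}

write_model_json <- function(model, path) {
  met_list <- purrr::pmap(model$metabolites, function(id, name, compartment,
                                                      boundary, ...) {
    out <- list(id = id, name = name, compartment = compartment)
    if (isTRUE(boundary)) out$boundary <- TRUE
    out
  })
  st <- model$stoichiometry
  rxn_list <- purrr::pmap(
    model$reactions,
    function(id, name, lower_bound, upper_bound, objective_coefficient, ...) {
      sub <- st[st$reaction == id, ]
      sub <- sub[order(sub$metabolite), ]
      mets <- as.list(sub$coefficient)
      names(mets) <- sub$metabolite
      list(id = id, name = name, metabolites = mets,
           lower_bound = lower_bound, upper_bound = upper_bound,
           objective_coefficient = objective_coefficient)
    })
  doc <- list(metabolites = met_list, reactions = rxn_list,
              id = model$annotations$id %||% "model")
  json <- jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  writeLines(json, path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
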