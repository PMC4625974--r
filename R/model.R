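# Constraint-based metabolic model container.
#
# A model is a stoichiometric network: metabolites (rows of S), reactions
# (columns of S, each with flux bounds and an objective coefficient), and a
# named biomass reaction. Boundary pseudo-species are carried but excluded
# from the steady-state balance, following the usual constraint-based
# convention.

#' Construct a metabolic model
#'
#' @param metabolites data frame with columns `id`, `name`, `compartment`,
#'   `boundary` (logical; boundary pseudo-species are excluded from mass
#'   balance and are never flux-sum scan candidates). Missing `name`,
#'   `compartment`, `boundary` columns are filled with defaults.
#' @param reactions data frame with columns `id`, `name`, `lower_bound`,
#'   `upper_bound`, `objective_coefficient` (bounds in mmol/gDCW-hr).
#' @param stoichiometry data frame with columns `reaction`, `metabolite`,
#'   `coefficient` (negative = consumed).
#' @param biomass_id id of the biomass reaction.
#' @param annotations free-form named list carried along with the model.
#' @return an object of class `metabolic_model`.
#' @details Exchange reactions are detected as reactions whose stoichiometry
#'   touches exactly one internal (non-boundary) metabolite, and are flagged
#'   in the `exchange` column of `$reactions`. Feasibility of the network is
#'   *not* checked at construction: an infeasible model is a reportable solve
#'   status, not a construction error.
#' @export
#' @examples
#' m <- two_branch_model()
#' m$reactions
metabolic_model <- function(metabolites, reactions, stoichiometry,
                            biomass_id, annotations = list()) {
  metabolites <- tibble::as_tibble(metabolites)
  reactions <- tibble::as_tibble(reactions)
  stoichiometry <- tibble::as_tibble(stoichiometry)

  if (!"name" %in% names(metabolites)) metabolites$name <- metabolites$id
  if (!"compartment" %in% names(metabolites)) metabolites$compartment <- "c"
  if (!"boundary" %in% names(metabolites)) metabolites$boundary <- FALSE
  if (!"name" %in% names(reactions)) reactions$name <- reactions$id
  if (!"objective_coefficient" %in% names(reactions)) {
    reactions$objective_coefficient <- 0
  }

  stopifnot(
    all(c("id") %in% names(metabolites)),
    all(c("id", "lower_bound", "upper_bound") %in% names(reactions)),
    all(c("reaction", "metabolite", "coefficient") %in% names(stoichiometry))
  )
  if (anyDuplicated(metabolites$id)) {
    stop("duplicate metabolite id(s): ",
         paste(unique(metabolites$id[duplicated(metabolites$id)]),
               collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(reactions$id)) {
    stop("duplicate reaction id(s): ",
         paste(unique(reactions$id[duplicated(reactions$id)]),
               collapse = ", "), call. = FALSE)
  }
  unknown_met <- setdiff(stoichiometry$metabolite, metabolites$id)
  if (length(unknown_met) > 0) {
    stop("reaction references unknown metabolite(s): ",
         paste(unknown_met, collapse = ", "), call. = FALSE)
  }
  unknown_rxn <- setdiff(stoichiometry$reaction, reactions$id)
  if (length(unknown_rxn) > 0) {
    stop("stoichiometry references unknown reaction(s): ",
         paste(unknown_rxn, collapse = ", "), call. = FALSE)
  }
  if (any(!is.finite(stoichiometry$coefficient)) ||
      any(stoichiometry$coefficient == 0)) {
    stop("stoichiometric coefficients must be finite and non-zero",
         call. = FALSE)
  }
  empty <- setdiff(reactions$id, stoichiometry$reaction)
  if (length(empty) > 0) {
    stop("reaction(s) with empty stoichiometry: ",
         paste(empty, collapse = ", "), call. = FALSE)
  }
  if (any(reactions$lower_bound > reactions$upper_bound)) {
    bad <- reactions$id[reactions$lower_bound > reactions$upper_bound]
    stop("lower bound exceeds upper bound for: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  if (!biomass_id %in% reactions$id) {
    stop("biomass reaction '", biomass_id, "' not found in model",
         call. = FALSE)
  }

  internal <- metabolites$id[!metabolites$boundary]
  n_internal <- vapply(reactions$id, function(r) {
    sum(stoichiometry$metabolite[stoichiometry$reaction == r] %in% internal)
  }, integer(1))
  reactions$exchange <- n_internal == 1L

  structure(
    list(
      metabolites = metabolites,
      reactions = reactions[, c("id", "name", "lower_bound", "upper_bound",
                                "objective_coefficient", "exchange")],
      stoichiometry = stoichiometry[, c("reaction", "metabolite",
                                        "coefficient")],
      biomass_id = biomass_id,
      annotations = annotations
    ),
    class = "metabolic_model"
  )
}

#' @export
print.metabolic_model <- function(x, ...) {
  cat("<metabolic_model> ",
      nrow(x$metabolites), " metabolites (",
      sum(!x$metabolites$boundary), " internal), ",
      nrow(x$reactions), " reactions (",
      sum(x$reactions$exchange), " exchange)\n", sep = "")
  cat("  biomass: ", x$biomass_id, "\n", sep = "")
  invisible(x)
}

#' Stoichiometric matrix of a model
#'
#' @param model a `metabolic_model`.
#' @param internal_only drop boundary pseudo-species rows (default): the
#'   steady-state balance applies to internal metabolites only.
#' @return dense numeric matrix, metabolites in rows, reactions in columns.
#' @export
stoichiometric_matrix <- function(model, internal_only = TRUE) {
  mets <- model$metabolites$id
  if (internal_only) mets <- model$metabolites$id[!model$metabolites$boundary]
  S <- matrix(0, length(mets), nrow(model$reactions),
              dimnames = list(mets, model$reactions$id))
  st <- model$stoichiometry[model$stoichiometry$metabolite %in% mets, ]
  S[cbind(match(st$metabolite, mets), match(st$reaction, colnames(S)))] <-
    st$coefficient
  S
}

#' Internal metabolites of a model
#'
#' @param model a `metabolic_model`.
#' @return character vector of non-boundary metabolite ids.
#' @export
internal_metabolites <- function(model) {
  model$metabolites$id[!model$metabolites$boundary]
}

# reactions incident to a metabolite: tibble(reaction, coefficient)
incident_reactions <- function(model, metabolite_id) {
  st <- model$stoichiometry
  st[st$metabolite == metabolite_id, c("reaction", "coefficient")]
}

# assert a metabolite exists and is internal
check_internal_metabolite <- function(model, metabolite_id) {
  if (!metabolite_id %in% model$metabolites$id) {
    stop("unknown metabolite '", metabolite_id, "'", call. = FALSE)
  }
  if (model$metabolites$boundary[match(metabolite_id, model$metabolites$id)]) {
    stop("flux-sum is undefined for boundary metabolite '", metabolite_id,
         "' (boundary species are not mass-balanced)", call. = FALSE)
  }
  invisible(TRUE)
}
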