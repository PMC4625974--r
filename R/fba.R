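# Flux balance analysis: the LP core of the package. A model's steady state
# is sum_j S_ij v_j = 0 for every internal metabolite i, with capacity bounds
# alpha_j <= v_j <= beta_j; FBA maximizes (or minimizes) a linear objective
# c'v over that polytope.

#' Solver configuration
#'
#' @param lp_tolerance feasibility/optimality tolerance of the simplex.
#' @param integer_tolerance integrality tolerance for the branch-and-bound
#'   binaries.
#' @param big_M flux cap (mmol/gDCW-hr) bounding the generation/consumption
#'   split variables so indicator binaries can switch them off. Validated
#'   against the model's largest finite bound when the flux-sum machinery is
#'   built, and auto-raised with a warning if too small.
#' @param time_limit wall-clock limit in seconds for one branch-and-bound
#'   solve.
#' @param lex_slack_rel,lex_slack_abs slack used when the first objective of
#'   a lexicographic solve is held fixed during the second: the primary
#'   optimum may degrade by at most
#'   `max(lex_slack_abs, lex_slack_rel * |optimum|)`.
#' @param reduce_forced_splits presolve reduction: omit indicator binaries
#'   for reactions whose bounds confine the flux to one sign, where the
#'   generation/consumption split is forced. Mathematically equivalent;
#'   disable to exercise the full indicator machinery.
#' @param max_iter simplex iteration cap.
#' @return a list of class `solve_config`.
#' @export
solve_config <- function(lp_tolerance = 1e-9,
                         integer_tolerance = 1e-6,
                         big_M = 1000,
                         time_limit = Inf,
                         lex_slack_rel = 1e-9,
                         lex_slack_abs = 1e-9,
                         reduce_forced_splits = TRUE,
                         max_iter = 20000L) {
  stopifnot(lp_tolerance > 0, integer_tolerance > 0, big_M > 0,
            time_limit > 0, lex_slack_rel >= 0, lex_slack_abs >= 0)
  structure(list(lp_tolerance = lp_tolerance,
                 integer_tolerance = integer_tolerance,
                 big_M = big_M, time_limit = time_limit,
                 lex_slack_rel = lex_slack_rel,
                 lex_slack_abs = lex_slack_abs,
                 reduce_forced_splits = reduce_forced_splits,
                 max_iter = as.integer(max_iter)),
            class = "solve_config")
}

# LP skeleton shared by all solves: one variable per reaction, one
# steady-state row per internal metabolite.
build_fba_problem <- function(model) {
  prob <- new_lp_problem()
  prob <- lp_add_vars(prob, model$reactions$id,
                      lb = model$reactions$lower_bound,
                      ub = model$reactions$upper_bound)
  S <- stoichiometric_matrix(model)
  for (i in seq_len(nrow(S))) {
    nz <- which(S[i, ] != 0)
    prob <- lp_add_row(prob, colnames(S)[nz], S[i, nz], "=", 0,
                       name = rownames(S)[i])
  }
  prob
}

check_reaction <- function(model, id) {
  if (!id %in% model$reactions$id) {
    stop("unknown reaction '", id, "'", call. = FALSE)
  }
  invisible(TRUE)
}

new_flux_distribution <- function(model, res, objective_id) {
  structure(
    list(
      fluxes = if (res$status == "optimal") {
        res$x[model$reactions$id]
      } else {
        stats::setNames(numeric(0), character(0))
      },
      objective_id = objective_id,
      objective_value = if (res$status == "optimal") res$objval else NA_real_,
      status = res$status
    ),
    class = "flux_distribution"
  )
}

#' @export
print.flux_distribution <- function(x, ...) {
  cat("<flux_distribution> status=", x$status,
      " objective[", paste(x$objective_id, collapse = "+"), "]=",
      format(x$objective_value), "\n", sep = "")
  invisible(x)
}

#' Tidy a flux distribution into a reaction/flux table
#'
#' @param x a `flux_distribution`.
#' @param ... unused.
#' @return a tibble with columns `reaction`, `flux`.
#' @export
tidy.flux_distribution <- function(x, ...) {
  tibble::tibble(reaction = names(x$fluxes), flux = unname(x$fluxes))
}

#' One-row summary of a flux distribution
#'
#' @param x a `flux_distribution`.
#' @param ... unused.
#' @return a tibble with `objective_id`, `objective_value`, `status`.
#' @export
glance.flux_distribution <- function(x, ...) {
  tibble::tibble(objective_id = paste(x$objective_id, collapse = "+"),
                 objective_value = x$objective_value, status = x$status)
}

#' Flux balance analysis
#'
#' Optimizes a reaction flux (or the model's declared objective c'v) over
#' the steady-state polytope.
#'
#' @param model a `metabolic_model`.
#' @param objective reaction id to optimize; `NULL` uses the model's
#'   objective coefficients (the biomass reaction, in a conventional model).
#' @param sense `"max"` or `"min"`.
#' @param config a [solve_config()].
#' @return a `flux_distribution` with `status` one of `"optimal"`,
#'   `"infeasible"`, `"unbounded"`; fluxes are empty unless optimal.
#' @export
#' @examples
#' sol <- solve_fba(two_branch_model())
#' sol$objective_value # 10
solve_fba <- function(model, objective = NULL, sense = c("max", "min"),
                      config = solve_config()) {
  sense <- match.arg(sense)
  prob <- build_fba_problem(model)
  if (is.null(objective)) {
    has <- model$reactions$objective_coefficient != 0
    if (!any(has)) stop("model declares no objective coefficients",
                        call. = FALSE)
    prob <- lp_set_objective(prob, model$reactions$id[has],
                             model$reactions$objective_coefficient[has])
    objective_id <- model$reactions$id[has]
  } else {
    check_reaction(model, objective)
    prob <- lp_set_objective(prob, objective, 1)
    objective_id <- objective
  }
  res <- solve_lp(prob, maximize = sense == "max",
                  tol = config$lp_tolerance, max_iter = config$max_iter)
  new_flux_distribution(model, res, objective_id)
}

#' Lexicographic two-step flux balance analysis
#'
#' Optimizes a primary objective, then re-optimizes a secondary objective
#' with the primary held at its step-1 optimum (as an inequality with a
#' small configurable slack). This is the standard device for removing
#' alternate-optima ambiguity: the returned flux distribution is step 2's,
#' so secondary quantities read off it are worst/best-case values at the
#' primary optimum rather than an arbitrary vertex.
#'
#' @param model a `metabolic_model`.
#' @param primary,secondary reaction ids.
#' @param primary_sense,secondary_sense `"max"` or `"min"`.
#' @param config a [solve_config()].
#' @return a `flux_distribution` from step 2; its `objective_value` is the
#'   secondary optimum, and attribute `primary_value` records step 1's.
#' @export
#' @examples
#' m <- two_branch_model()
#' sol <- lexicographic_fba(m, "BIOMASS", "EX_E",
#'                          primary_sense = "max", secondary_sense = "min")
#' attr(sol, "primary_value") # 10
#' sol$objective_value        # 0
lexicographic_fba <- function(model, primary, secondary,
                              primary_sense = c("max", "min"),
                              secondary_sense = c("max", "min"),
                              config = solve_config()) {
  primary_sense <- match.arg(primary_sense)
  secondary_sense <- match.arg(secondary_sense)
  check_reaction(model, primary)
  check_reaction(model, secondary)

  step1 <- solve_fba(model, primary, primary_sense, config)
  if (step1$status != "optimal") return(step1)
  opt <- step1$objective_value
  slack <- max(config$lex_slack_abs, config$lex_slack_rel * abs(opt))

  prob <- build_fba_problem(model)
  prob <- lp_add_row(prob, primary, 1,
                     if (primary_sense == "max") ">=" else "<=",
                     if (primary_sense == "max") opt - slack else opt + slack,
                     name = "lexicographic_primary")
  prob <- lp_set_objective(prob, secondary, 1)
  res <- solve_lp(prob, maximize = secondary_sense == "max",
                  tol = config$lp_tolerance, max_iter = config$max_iter)
  if (res$status != "optimal") {
    stop("lexicographic step 2 unexpectedly ", res$status,
         " (primary '", primary, "' fixed at ", format(opt), ")",
         call. = FALSE)
  }
  out <- new_flux_distribution(model, res, secondary)
  attr(out, "primary_id") <- primary
  attr(out, "primary_value") <- opt
  out
}
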