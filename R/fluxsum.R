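# Flux-sum quantification and its mixed-integer linearization.
#
# The flux-sum of an internal metabolite i at a steady-state flux vector v is
#   Phi_i = 0.5 * sum_j |S_ij v_j|,
# half the summed absolute rate of every reaction producing or consuming it;
# at steady state generation equals consumption, so Phi_i is the turnover of
# the metabolite. |S_ij v_j| is linearized with a generation/consumption
# split S_ij v_j = g+ - g-, g+/- >= 0, switched by exclusive binary
# indicators via big-M caps: g+ <= M*I, g- <= M*(1-I).

#' Evaluate metabolite flux-sums on a flux distribution
#'
#' @param distribution an optimal `flux_distribution`.
#' @param model the `metabolic_model` it was solved on.
#' @param metabolites metabolite ids; default all internal metabolites.
#'   Boundary pseudo-species are not mass-balanced, so their flux-sum is
#'   undefined and requesting one is an error.
#' @return a tibble with columns `metabolite`, `flux_sum` (mmol/gDCW-hr).
#' @export
#' @examples
#' m <- two_branch_model()
#' flux_sum(solve_fba(m), m, "C") # 10
flux_sum <- function(distribution, model, metabolites = NULL) {
  stopifnot(inherits(distribution, "flux_distribution"))
  if (distribution$status != "optimal") {
    stop("flux-sum requires an optimal flux distribution (status: ",
         distribution$status, ")", call. = FALSE)
  }
  if (is.null(metabolites)) metabolites <- internal_metabolites(model)
  for (met in metabolites) check_internal_metabolite(model, met)
  v <- distribution$fluxes
  phi <- vapply(metabolites, function(met) {
    inc <- incident_reactions(model, met)
    0.5 * sum(abs(inc$coefficient * v[inc$reaction]))
  }, numeric(1))
  tibble::tibble(metabolite = metabolites, flux_sum = unname(phi))
}

# Model-level effective big-M: auto-raised when the largest finite bound
# exceeds the configured cap, so indicator constraints can never clip a
# feasible flux.
effective_big_M <- function(model, config) {
  b <- c(model$reactions$lower_bound, model$reactions$upper_bound)
  maxb <- max(abs(b[is.finite(b)]), 0)
  if (maxb > config$big_M) {
    warning("big_M (", config$big_M, ") below the largest finite bound (",
            maxb, "); raising to ", 10 * maxb, call. = FALSE)
    return(10 * maxb)
  }
  config$big_M
}

#' Attach flux-sum linearization machinery to a linear problem
#'
#' Adds, for every reaction incident to `metabolite_id`, the
#' generation/consumption split variables and big-M indicator constraints
#' that make the flux-sum a linear expression. Reactions whose bounds
#' confine the flux to one sign need no binaries (the split is forced) and
#' are reduced to plain linear terms unless
#' `config$reduce_forced_splits = FALSE`.
#'
#' @param prob an `lp_problem` already carrying the reaction flux variables
#'   and steady-state rows (see [solve_fba()] internals).
#' @param model the `metabolic_model`.
#' @param metabolite_id internal metabolite to instrument.
#' @param config a [solve_config()].
#' @param big_M optional pre-validated big-M value; defaults to
#'   [solve_config()]'s after model-level validation.
#' @return list with `prob` (the extended problem), `terms` (a tibble of
#'   `var`, `coef` such that `Phi = sum(coef * var)`), `split_vars`
#'   (generation/consumption variable names) and `n_binaries`.
#' @keywords internal
#' @export
attach_fluxsum_machinery <- function(prob, model, metabolite_id,
                                     config = solve_config(),
                                     big_M = NULL) {
  check_internal_metabolite(model, metabolite_id)
  inc <- incident_reactions(model, metabolite_id)
  if (nrow(inc) == 0) {
    stop("metabolite '", metabolite_id, "' has no incident reactions; ",
         "its flux-sum is degenerate", call. = FALSE)
  }
  if (is.null(big_M)) big_M <- effective_big_M(model, config)

  terms_var <- character(0); terms_coef <- numeric(0)
  split_vars <- character(0)
  n_bin <- 0L
  ri <- match(inc$reaction, model$reactions$id)
  lbs <- model$reactions$lower_bound[ri]
  ubs <- model$reactions$upper_bound[ri]

  for (k in seq_len(nrow(inc))) {
    rxn <- inc$reaction[k]; s <- inc$coefficient[k]
    confined <- lbs[k] >= 0 || ubs[k] <= 0
    if (confined && config$reduce_forced_splits) {
      # |S v| = |s| v for v >= 0, -|s| v for v <= 0
      terms_var <- c(terms_var, rxn)
      terms_coef <- c(terms_coef,
                      if (lbs[k] >= 0) 0.5 * abs(s) else -0.5 * abs(s))
      next
    }
    gp <- paste0("gp.", rxn); gn <- paste0("gn.", rxn)
    ind <- paste0("I.", rxn)
    prob <- lp_add_vars(prob, c(gp, gn), lb = 0, ub = big_M)
    prob <- lp_add_vars(prob, ind, lb = 0, ub = 1, binary = TRUE)
    n_bin <- n_bin + 1L
    # S_ij v_j = g+ - g-
    prob <- lp_add_row(prob, c(rxn, gp, gn), c(s, -1, 1), "=", 0,
                       name = paste0("split.", metabolite_id, ".", rxn))
    # g+ <= M I ; g- <= M (1 - I)
    prob <- lp_add_row(prob, c(gp, ind), c(1, -big_M), "<=", 0,
                       name = paste0("capp.", rxn))
    prob <- lp_add_row(prob, c(gn, ind), c(1, big_M), "<=", big_M,
                       name = paste0("capn.", rxn))
    terms_var <- c(terms_var, gp, gn)
    terms_coef <- c(terms_coef, 0.5, 0.5)
    split_vars <- c(split_vars, gp, gn)
  }
  list(prob = prob,
       terms = tibble::tibble(var = terms_var, coef = terms_coef),
       split_vars = split_vars,
       n_binaries = n_bin,
       big_M = big_M,
       metabolite = metabolite_id)
}

# evaluate Phi from a solved vector using machinery terms
phi_value <- function(mach, x) {
  sum(mach$terms$coef * x[mach$terms$var])
}

# post-solve big-M validity: no split variable may sit at the cap
check_big_M <- function(mach, res, tol = 1e-6) {
  if (res$status != "optimal" || length(mach$split_vars) == 0) return(invisible())
  g <- res$x[mach$split_vars]
  if (any(g >= mach$big_M - tol)) {
    stop("big_M (", mach$big_M, ") attained by a split variable for ",
         "metabolite '", mach$metabolite, "'; increase big_M", call. = FALSE)
  }
  invisible()
}

#' Feasible range of a metabolite's flux-sum
#'
#' Solves two mixed-integer programs per metabolite, minimizing and
#' maximizing the linearized flux-sum under mass balance and flux bounds
#' only (no growth constraint): the feasible range within which the
#' metabolite's turnover can be attenuated or intensified.
#'
#' @param model a `metabolic_model`.
#' @param metabolites metabolite ids; default all internal metabolites.
#' @param config a [solve_config()].
#' @return a tibble with columns `metabolite`, `phi_min`, `phi_max`
#'   (`phi_max` is `Inf` when the maximization is unbounded) and `status`.
#' @export
#' @examples
#' flux_sum_extrema(two_branch_model(), "C") # 0 .. 10
flux_sum_extrema <- function(model, metabolites = NULL,
                             config = solve_config()) {
  if (is.null(metabolites)) metabolites <- internal_metabolites(model)
  big_M <- effective_big_M(model, config)
  base <- build_fba_problem(model)
  rows <- purrr::map(metabolites, function(met) {
    mach <- attach_fluxsum_machinery(base, model, met, config, big_M = big_M)
    prob <- lp_set_objective(mach$prob, mach$terms$var, mach$terms$coef)
    lo <- solve_milp(prob, maximize = FALSE, tol = config$lp_tolerance,
                     int_tol = config$integer_tolerance,
                     max_iter = config$max_iter)
    hi <- solve_milp(prob, maximize = TRUE, tol = config$lp_tolerance,
                     int_tol = config$integer_tolerance,
                     max_iter = config$max_iter)
    check_big_M(mach, lo); check_big_M(mach, hi)
    status <- if (lo$status == "optimal" &&
                  hi$status %in% c("optimal", "unbounded")) "optimal"
              else lo$status
    tibble::tibble(
      metabolite = met,
      phi_min = if (lo$status == "optimal") max(0, lo$objval) else NA_real_,
      phi_max = if (hi$status == "optimal") hi$objval
                else if (hi$status == "unbounded") Inf else NA_real_,
      status = status)
  })
  dplyr::bind_rows(rows)
}
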