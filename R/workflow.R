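# The flux-sum target-identification workflow:
#   1. reference state: FBA growth maximum, then a lexicographic re-solve of
#      the target exchange in the goal-adverse sense to fix the wild-type
#      flux distribution (and hence the wild-type flux-sums) free of
#      alternate-optima ambiguity;
#   2. feasible flux-sum range [phi_min, phi_max] of every candidate
#      metabolite (no growth constraint);
#   3. for each metabolite, direction and perturbation level k, the maximum
#      growth B_ik under the single flux-sum constraint
#        attenuation   (C1):  Phi_i <= phi_min + k_att (phi_wt - phi_min)
#        intensification (C2): Phi_i >= phi_wt + k_int (phi_max - phi_wt);
#   4. the guaranteed (worst-case) target production: the target exchange
#      optimized in the goal-adverse sense with growth floored at B_ik.
# Metabolites with at least one point whose worst-case production improves
# on the wild-type value are classified as engineering targets.

fsa_goal_adverse <- function(goal) if (goal == "maximize") "min" else "max"

#' Wild-type reference state
#'
#' Step 1 of the flux-sum workflow: maximum growth, the worst-case (i.e.
#' guaranteed) target production at that growth, and the wild-type flux-sum
#' of every candidate metabolite evaluated on the lexicographic flux
#' distribution.
#'
#' @param model a `metabolic_model`.
#' @param target target exchange reaction id.
#' @param goal `"maximize"` (desired product) or `"minimize"` (unwanted
#'   by-product).
#' @param metabolites candidate metabolites; default all internal.
#' @param config a [solve_config()].
#' @return list with `wt_growth`, `wt_production`, `phi_wt` (tibble
#'   `metabolite`, `phi_wt`) and `distribution` (the lexicographic
#'   `flux_distribution`).
#' @export
#' @examples
#' reference_state(two_branch_model(), "EX_E")[c("wt_growth", "wt_production")]
reference_state <- function(model, target, goal = c("maximize", "minimize"),
                            metabolites = NULL, config = solve_config()) {
  goal <- match.arg(goal)
  check_reaction(model, target)
  if (is.null(metabolites)) metabolites <- internal_metabolites(model)

  growth <- solve_fba(model, model$biomass_id, "max", config)
  if (growth$status != "optimal") {
    stop("wild-type growth solve is ", growth$status,
         "; cannot establish a reference state", call. = FALSE)
  }
  wt <- lexicographic_fba(model, model$biomass_id, target,
                          primary_sense = "max",
                          secondary_sense = fsa_goal_adverse(goal),
                          config = config)
  phi <- flux_sum(wt, model, metabolites)
  names(phi)[names(phi) == "flux_sum"] <- "phi_wt"
  list(wt_growth = growth$objective_value,
       wt_production = wt$objective_value,
       phi_wt = phi,
       distribution = wt)
}

#' Reference flux-sum table
#'
#' Combines the wild-type flux-sums with the feasible extrema into one
#' record per metabolite. Tiny numerical excursions of the wild-type value
#' outside [phi_min, phi_max] are clamped so the interpolated perturbation
#' caps are always well defined.
#'
#' @inheritParams reference_state
#' @return tibble with `metabolite`, `phi_min`, `phi_wt`, `phi_max`.
#' @export
flux_sum_reference <- function(model, target, goal = c("maximize", "minimize"),
                               metabolites = NULL, config = solve_config()) {
  goal <- match.arg(goal)
  if (is.null(metabolites)) metabolites <- internal_metabolites(model)
  ref <- reference_state(model, target, goal, metabolites, config)
  ext <- flux_sum_extrema(model, metabolites, config)
  out <- dplyr::left_join(ext, ref$phi_wt, by = "metabolite")
  out$phi_wt <- pmin(pmax(out$phi_wt, out$phi_min), out$phi_max)
  out[, c("metabolite", "phi_min", "phi_wt", "phi_max")]
}

# shared problem assembly: machinery + C1/C2 row
perturbed_problem <- function(model, metabolite, direction, k, record,
                              config, big_M = NULL) {
  prob <- build_fba_problem(model)
  mach <- attach_fluxsum_machinery(prob, model, metabolite, config,
                                   big_M = big_M)
  cap <- if (direction == "attenuation") {
    record$phi_min + k * (record$phi_wt - record$phi_min)
  } else {
    record$phi_wt + k * (record$phi_max - record$phi_wt)
  }
  prob <- lp_add_row(mach$prob, mach$terms$var, mach$terms$coef,
                     if (direction == "attenuation") "<=" else ">=",
                     cap, name = paste0("fluxsum_", direction))
  mach$prob <- prob
  mach$cap <- cap
  mach
}

fsa_degenerate <- function(direction, record, tol) {
  if (direction == "attenuation") record$phi_wt - record$phi_min <= tol
  else record$phi_max - record$phi_wt <= tol
}

#' Maximum growth under a flux-sum perturbation
#'
#' Step 3: the maximum biomass flux under mass balance, bounds, the
#' flux-sum machinery for one metabolite and the single interpolated
#' attenuation/intensification constraint.
#'
#' @param model a `metabolic_model`.
#' @param metabolite internal metabolite id.
#' @param direction `"attenuation"` or `"intensification"`.
#' @param k perturbation level in `[0, 1]`: 1 is the weakest attenuation
#'   (cap at the wild-type flux-sum) and 0 the strongest; 0 is the weakest
#'   intensification and 1 the strongest.
#' @param record one-row data frame with `phi_min`, `phi_wt`, `phi_max`
#'   for the metabolite (see [flux_sum_reference()]).
#' @param config a [solve_config()].
#' @return list with `status` (`"optimal"`, `"infeasible"`,
#'   `"degenerate_range"`) and `growth` (`NA` unless optimal). A degenerate
#'   range (`phi_wt` equal to the relevant extremum within tolerance) means
#'   the metabolite is not scannable in that direction.
#' @export
growth_under_perturbation <- function(model, metabolite,
                                      direction = c("attenuation",
                                                    "intensification"),
                                      k, record, config = solve_config()) {
  direction <- match.arg(direction)
  stopifnot(k >= 0, k <= 1)
  if (fsa_degenerate(direction, record, config$integer_tolerance)) {
    return(list(status = "degenerate_range", growth = NA_real_))
  }
  mach <- perturbed_problem(model, metabolite, direction, k, record, config)
  prob <- lp_set_objective(mach$prob, model$biomass_id, 1)
  res <- solve_milp(prob, maximize = TRUE, tol = config$lp_tolerance,
                    int_tol = config$integer_tolerance,
                    max_iter = config$max_iter)
  check_big_M(mach, res)
  list(status = res$status,
       growth = if (res$status == "optimal") res$objval else NA_real_)
}

#' Guaranteed target production under a flux-sum perturbation
#'
#' Step 4: optimizes the target exchange in the goal-adverse sense
#' (minimize when the goal is to maximize production, and vice versa) under
#' the same constraint set plus the growth floor `v_biomass >= B_ik`. The
#' result is the production level guaranteed by the perturbation.
#'
#' @inheritParams growth_under_perturbation
#' @param target target exchange reaction id.
#' @param goal `"maximize"` or `"minimize"`.
#' @param growth_floor the value B_ik from [growth_under_perturbation()].
#' @return list with `status` and `production`.
#' @export
worst_case_production <- function(model, target,
                                  goal = c("maximize", "minimize"),
                                  metabolite,
                                  direction = c("attenuation",
                                                "intensification"),
                                  k, record, growth_floor,
                                  config = solve_config()) {
  goal <- match.arg(goal)
  direction <- match.arg(direction)
  check_reaction(model, target)
  mach <- perturbed_problem(model, metabolite, direction, k, record, config)
  slack <- max(config$lex_slack_abs,
               config$lex_slack_rel * abs(growth_floor))
  prob <- lp_add_row(mach$prob, model$biomass_id, 1, ">=",
                     growth_floor - slack, name = "growth_floor")
  prob <- lp_set_objective(prob, target, 1)
  res <- solve_milp(prob, maximize = fsa_goal_adverse(goal) == "max",
                    tol = config$lp_tolerance,
                    int_tol = config$integer_tolerance,
                    max_iter = config$max_iter)
  check_big_M(mach, res)
  if (res$status != "optimal") {
    warning("worst-case production solve ", res$status, " for ",
            metabolite, "/", direction, " at k=", k,
            " despite attainable growth floor", call. = FALSE)
  }
  list(status = res$status,
       production = if (res$status == "optimal") res$objval else NA_real_)
}

#' Scan all metabolites for flux-sum engineering targets
#'
#' Runs the full four-step workflow over every candidate metabolite,
#' direction and perturbation level, and classifies attenuation /
#' intensification targets: metabolites with at least one scan point whose
#' guaranteed (worst-case) target production improves on the wild-type
#' value by more than the improvement threshold.
#'
#' @param model a `metabolic_model`.
#' @param target target exchange reaction id.
#' @param goal `"maximize"` (desired product) or `"minimize"` (unwanted
#'   by-product).
#' @param directions scan directions, default both.
#' @param k_grid perturbation levels, sorted, within `[0, 1]`.
#' @param exclude metabolite ids to leave out of the candidate set (e.g.
#'   currency metabolites); empty by default.
#' @param improvement_rel,improvement_abs classification threshold: a point
#'   counts as an improvement when it beats the wild-type production by more
#'   than `max(improvement_abs, improvement_rel * |wt_production|)`.
#' @param verbose emit one `message()` per scan point with solve statuses
#'   and wall time.
#' @param config a [solve_config()].
#' @return an object of class `fsa_scan`: list with `points` (tibble:
#'   `metabolite`, `direction`, `k`, `growth`, `production`,
#'   `growth_status`, `production_status`), `targets` (tibble: `metabolite`,
#'   `direction`, `best_k`, `best_production`, `growth_at_best`), `records`
#'   (the flux-sum reference table), `skipped` (degenerate or excluded
#'   candidates with reason codes), `reference` and `metadata` (every
#'   numeric convention used). Deterministic given model and configuration.
#' @export
#' @examples
#' \donttest{
#' scan <- fsa_scan(two_branch_model(), "EX_E", k_grid = seq(0, 1, 0.5))
#' scan$targets
#' }
fsa_scan <- function(model, target, goal = c("maximize", "minimize"),
                     directions = c("attenuation", "intensification"),
                     k_grid = seq(0, 1, by = 0.1),
                     exclude = character(),
                     improvement_rel = 1e-3, improvement_abs = 1e-6,
                     verbose = FALSE,
                     config = solve_config()) {
  goal <- match.arg(goal)
  directions <- match.arg(directions, several.ok = TRUE)
  check_reaction(model, target)
  stopifnot(length(k_grid) > 0, all(k_grid >= 0), all(k_grid <= 1),
            !is.unsorted(k_grid))

  candidates <- setdiff(internal_metabolites(model), exclude)
  skipped <- tibble::tibble(metabolite = character(),
                            direction = character(), reason = character())
  if (length(candidates) == 0) {
    stop("no candidate metabolites left after exclusions", call. = FALSE)
  }

  ref <- reference_state(model, target, goal, candidates, config)
  ext <- flux_sum_extrema(model, candidates, config)
  records <- dplyr::left_join(ext, ref$phi_wt, by = "metabolite")
  records$phi_wt <- pmin(pmax(records$phi_wt, records$phi_min),
                         records$phi_max)
  records <- records[, c("metabolite", "phi_min", "phi_wt", "phi_max")]
  big_M <- effective_big_M(model, config)

  pts <- list()
  for (met in candidates) {
    rec <- records[records$metabolite == met, ]
    for (dir in directions) {
      if (fsa_degenerate(dir, rec, config$integer_tolerance)) {
        skipped <- dplyr::bind_rows(skipped, tibble::tibble(
          metabolite = met, direction = dir, reason = "degenerate_range"))
        next
      }
      for (k in k_grid) {
        t0 <- proc.time()[["elapsed"]]
        g <- growth_under_perturbation(model, met, dir, k, rec, config)
        if (g$status != "optimal") {
          pts[[length(pts) + 1L]] <- tibble::tibble(
            metabolite = met, direction = dir, k = k,
            growth = NA_real_, production = NA_real_,
            growth_status = g$status, production_status = "not_attempted")
          if (verbose) {
            message(sprintf("%s %s k=%.3g growth=%s", met, dir, k, g$status))
          }
          next
        }
        p <- worst_case_production(model, target, goal, met, dir, k, rec,
                                   g$growth, config)
        pts[[length(pts) + 1L]] <- tibble::tibble(
          metabolite = met, direction = dir, k = k,
          growth = g$growth, production = p$production,
          growth_status = g$status, production_status = p$status)
        if (verbose) {
          message(sprintf(
            "%s %s k=%.3g growth=%s production=%s [%.2fs]", met, dir, k,
            g$status, p$status, proc.time()[["elapsed"]] - t0))
        }
      }
    }
  }
  points <- if (length(pts) > 0) dplyr::bind_rows(pts) else
    tibble::tibble(metabolite = character(), direction = character(),
                   k = numeric(), growth = numeric(), production = numeric(),
                   growth_status = character(),
                   production_status = character())

  threshold <- max(improvement_abs,
                   improvement_rel * abs(ref$wt_production))
  sgn <- if (goal == "maximize") 1 else -1
  ok <- points[points$production_status == "optimal" &
                 !is.na(points$production), ]
  ok$improvement <- sgn * (ok$production - ref$wt_production)
  targets <- ok |>
    dplyr::group_by(.data$metabolite, .data$direction) |>
    dplyr::filter(max(.data$improvement) > threshold) |>
    dplyr::slice_min(order_by = -.data$improvement, n = 1,
                     with_ties = FALSE) |>
    dplyr::ungroup() |>
    dplyr::transmute(metabolite = .data$metabolite,
                     direction = .data$direction,
                     best_k = .data$k,
                     best_production = .data$production,
                     growth_at_best = .data$growth) |>
    dplyr::arrange(.data$metabolite, .data$direction)

  structure(
    list(points = points, targets = targets, records = records,
         skipped = skipped,
         reference = list(target = target, goal = goal,
                          wt_growth = ref$wt_growth,
                          wt_production = ref$wt_production,
                          non_growing = abs(ref$wt_growth) <=
                            config$integer_tolerance),
         metadata = list(
           k_grid = k_grid, directions = directions, exclude = exclude,
           improvement_rel = improvement_rel,
           improvement_abs = improvement_abs,
           improvement_threshold = threshold,
           phi_wt_convention = "lexicographic (growth max, then goal-adverse target)",
           big_M = big_M,
           lp_tolerance = config$lp_tolerance,
           integer_tolerance = config$integer_tolerance,
           lex_slack_rel = config$lex_slack_rel,
           lex_slack_abs = config$lex_slack_abs,
           reduce_forced_splits = config$reduce_forced_splits)),
    class = "fsa_scan")
}

#' @export
print.fsa_scan <- function(x, ...) {
  cat("<fsa_scan> target=", x$reference$target, " goal=", x$reference$goal,
      "\n  wild type: growth=", format(x$reference$wt_growth),
      ", guaranteed production=", format(x$reference$wt_production),
      "\n  ", nrow(x$points), " scan points, ", nrow(x$targets),
      " target(s)\n", sep = "")
  if (nrow(x$targets) > 0) print(x$targets)
  invisible(x)
}

#' Tidy an FSA scan into its point table
#'
#' @param x an `fsa_scan`.
#' @param ... unused.
#' @return the tibble of scan points.
#' @export
tidy.fsa_scan <- function(x, ...) x$points

#' One-row summary of an FSA scan
#'
#' @param x an `fsa_scan`.
#' @param ... unused.
#' @return a one-row tibble.
#' @export
glance.fsa_scan <- function(x, ...) {
  tibble::tibble(target = x$reference$target, goal = x$reference$goal,
                 wt_growth = x$reference$wt_growth,
                 wt_production = x$reference$wt_production,
                 n_points = nrow(x$points), n_targets = nrow(x$targets),
                 n_skipped = nrow(x$skipped))
}

#' Production/growth profile of one scanned pair
#'
#' @param scan an `fsa_scan`.
#' @param metabolite metabolite id.
#' @param direction `"attenuation"` or `"intensification"`.
#' @return tibble `(k, growth, production)` sorted by `k`, one row per
#'   feasible scan point.
#' @export
production_profile <- function(scan, metabolite,
                               direction = c("attenuation",
                                             "intensification")) {
  direction <- match.arg(direction)
  stopifnot(inherits(scan, "fsa_scan"))
  sub <- scan$points[scan$points$metabolite == metabolite &
                       scan$points$direction == direction, ]
  if (nrow(sub) == 0) {
    stop("pair (", metabolite, ", ", direction,
         ") was not scanned (degenerate, excluded or absent)", call. = FALSE)
  }
  sub <- sub[sub$growth_status == "optimal", ]
  sub <- sub[order(sub$k), c("k", "growth", "production")]
  tibble::as_tibble(sub)
}
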