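# Independent binary-free LP oracles for all-irreversible networks.
#
# When every reaction flux is confined to v >= 0, |S_ij v_j| = |S_ij| v_j
# is linear, so every quantity in the flux-sum workflow has a pure-LP
# formulation with no split variables and no indicators. These oracles
# assemble that formulation directly from the stoichiometry table and are
# used to cross-check the mixed-integer machinery.

oracle_assert_irreversible <- function(model) {
  stopifnot(all(model$reactions$lower_bound >= 0))
}

oracle_base <- function(model) {
  prob <- new_lp_problem()
  prob <- lp_add_vars(prob, model$reactions$id,
                      lb = model$reactions$lower_bound,
                      ub = model$reactions$upper_bound)
  st <- model$stoichiometry
  for (met in internal_metabolites(model)) {
    sub <- st[st$metabolite == met, ]
    prob <- lp_add_row(prob, sub$reaction, sub$coefficient, "=", 0, name = met)
  }
  prob
}

# Phi_i as linear terms on the flux variables (irreversible networks only)
oracle_phi_terms <- function(model, met) {
  st <- model$stoichiometry
  sub <- st[st$metabolite == met, ]
  list(vars = sub$reaction, coefs = 0.5 * abs(sub$coefficient))
}

oracle_fba <- function(model, rxn, sense) {
  prob <- lp_set_objective(oracle_base(model), rxn, 1)
  solve_lp(prob, maximize = sense == "max")
}

oracle_lex <- function(model, primary, psense, secondary, ssense) {
  s1 <- oracle_fba(model, primary, psense)
  stopifnot(s1$status == "optimal")
  slack <- max(1e-9, 1e-9 * abs(s1$objval))
  prob <- oracle_base(model)
  prob <- lp_add_row(prob, primary, 1,
                     if (psense == "max") ">=" else "<=",
                     if (psense == "max") s1$objval - slack
                     else s1$objval + slack)
  prob <- lp_set_objective(prob, secondary, 1)
  s2 <- solve_lp(prob, maximize = ssense == "max")
  stopifnot(s2$status == "optimal")
  list(primary_value = s1$objval, secondary_value = s2$objval, x = s2$x)
}

oracle_extrema <- function(model, met) {
  oracle_assert_irreversible(model)
  tm <- oracle_phi_terms(model, met)
  prob <- lp_set_objective(oracle_base(model), tm$vars, tm$coefs)
  lo <- solve_lp(prob, maximize = FALSE)
  hi <- solve_lp(prob, maximize = TRUE)
  stopifnot(lo$status == "optimal", hi$status == "optimal")
  c(phi_min = lo$objval, phi_max = hi$objval)
}

oracle_cap <- function(direction, k, rec) {
  if (direction == "attenuation") {
    rec$phi_min + k * (rec$phi_wt - rec$phi_min)
  } else {
    rec$phi_wt + k * (rec$phi_max - rec$phi_wt)
  }
}

oracle_growth <- function(model, met, direction, k, rec) {
  oracle_assert_irreversible(model)
  tm <- oracle_phi_terms(model, met)
  prob <- oracle_base(model)
  prob <- lp_add_row(prob, tm$vars, tm$coefs,
                     if (direction == "attenuation") "<=" else ">=",
                     oracle_cap(direction, k, rec))
  prob <- lp_set_objective(prob, model$biomass_id, 1)
  solve_lp(prob, maximize = TRUE)
}

oracle_production <- function(model, target, goal, met, direction, k, rec,
                              growth_floor) {
  oracle_assert_irreversible(model)
  tm <- oracle_phi_terms(model, met)
  prob <- oracle_base(model)
  prob <- lp_add_row(prob, tm$vars, tm$coefs,
                     if (direction == "attenuation") "<=" else ">=",
                     oracle_cap(direction, k, rec))
  slack <- max(1e-9, 1e-9 * abs(growth_floor))
  prob <- lp_add_row(prob, model$biomass_id, 1, ">=", growth_floor - slack)
  prob <- lp_set_objective(prob, target, 1)
  solve_lp(prob, maximize = goal == "minimize")
}

# closed-form flux-sum from a named flux vector
oracle_flux_sum_eval <- function(model, v, met) {
  st <- model$stoichiometry
  sub <- st[st$metabolite == met, ]
  0.5 * sum(abs(sub$coefficient * v[sub$reaction]))
}

# a config exercising the full indicator machinery (no presolve reduction)
full_machinery_config <- function() solve_config(reduce_forced_splits = FALSE)
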