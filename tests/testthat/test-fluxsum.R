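# Flux-sum evaluation, the indicator linearization, and flux-sum extrema.

test_that("flux-sum is half the summed absolute incident rate", {
  m <- two_branch_model()
  wt <- solve_fba(m)
  # 10 units flow through C (in via R2, out via R4): Phi = 0.5*(10+10)
  expect_equal(flux_sum(wt, m, "C")$flux_sum, 10, tolerance = 1e-8)
  # B carries no flux at maximum growth
  expect_equal(flux_sum(wt, m, "B")$flux_sum, 0, tolerance = 1e-8)
  # all internal metabolites at once
  tbl <- flux_sum(wt, m)
  expect_setequal(tbl$metabolite, c("A", "B", "C", "E", "F"))
  expect_true(all(tbl$flux_sum >= 0))

  # boundary species are not mass-balanced: flux-sum undefined
  mb <- m
  mb$metabolites$boundary[mb$metabolites$id == "E"] <- TRUE
  mb <- metabolic_model(mb$metabolites, mb$reactions, mb$stoichiometry,
                        mb$biomass_id)
  expect_error(flux_sum(solve_fba(mb), mb, "E"), "boundary")

  # non-optimal distributions are rejected
  m2 <- two_branch_model()
  m2$reactions$lower_bound[m2$reactions$id == "R3"] <- 20
  m2 <- metabolic_model(m2$metabolites, m2$reactions, m2$stoichiometry,
                        m2$biomass_id)
  expect_error(flux_sum(solve_fba(m2), m2, "C"), "optimal")
})

test_that("indicator machinery reproduces the absolute-value split", {
  # a reversible inflow forced negative: 5 units enter, at most 3 may leave
  # through the sink, so the reversible exchange must carry v <= -2
  mets <- tibble::tibble(id = "A")
  rxns <- tibble::tibble(id = c("SRC", "REV", "SNK"),
                         lower_bound = c(5, -1000, 0),
                         upper_bound = c(5, 1000, 3),
                         objective_coefficient = c(0, 0, 1))
  st <- tibble::tibble(reaction = c("SRC", "REV", "SNK"),
                       metabolite = "A", coefficient = c(1, 1, -1))
  m <- metabolic_model(mets, rxns, st, "SNK")

  cfg <- full_machinery_config()
  prob <- fluxsum:::build_fba_problem(m)
  mach <- attach_fluxsum_machinery(prob, m, "A", cfg)
  expect_equal(mach$n_binaries, 3) # no reduction: every incident reaction
  p <- fluxsum:::lp_set_objective(mach$prob, "SNK", 1)
  res <- solve_milp(p, maximize = FALSE)
  expect_equal(res$status, "optimal")
  v_rev <- res$x[["REV"]]
  expect_equal(v_rev, -5, tolerance = 1e-7) # SNK minimized to 0
  # S=+1, v<0: the consumption side is active, the generation side off
  expect_equal(res$x[["gn.REV"]], abs(v_rev), tolerance = 1e-6)
  expect_equal(res$x[["gp.REV"]], 0, tolerance = 1e-6)
  expect_equal(res$x[["I.REV"]], 0, tolerance = 1e-6)

  # generation equals consumption at any feasible point of the machinery
  gp <- res$x[grep("^gp\\.", names(res$x))]
  gn <- res$x[grep("^gn\\.", names(res$x))]
  expect_equal(sum(gp), sum(gn), tolerance = 1e-6)

  # degenerate metabolite: no incident reactions
  m2 <- two_branch_model()
  m2$metabolites <- dplyr::bind_rows(m2$metabolites,
                                     tibble::tibble(id = "ORPHAN",
                                                    name = "ORPHAN",
                                                    compartment = "c",
                                                    boundary = FALSE))
  m2 <- metabolic_model(m2$metabolites, m2$reactions, m2$stoichiometry,
                        m2$biomass_id)
  prob2 <- fluxsum:::build_fba_problem(m2)
  expect_error(attach_fluxsum_machinery(prob2, m2, "ORPHAN"),
               "no incident reactions")
})

test_that("machinery is a conservative extension of the base problem", {
  # attaching flux-sum variables for a metabolite must not move an optimum
  # that ignores them, including with a genuinely reversible reaction
  m <- mixed_acid_model()
  base <- solve_fba(m)$objective_value
  for (cfg in list(solve_config(), full_machinery_config())) {
    prob <- fluxsum:::build_fba_problem(m)
    mach <- attach_fluxsum_machinery(prob, m, "co2", cfg)
    p <- fluxsum:::lp_set_objective(mach$prob, "BIOMASS", 1)
    res <- solve_milp(p, maximize = TRUE)
    expect_equal(res$objval, base, tolerance = 1e-7)
  }
})

test_that("flux-sum extrema match forced and analytic ranges", {
  m <- two_branch_model()
  ext <- flux_sum_extrema(m, c("A", "C"))
  expect_equal(ext$phi_min[ext$metabolite == "C"], 0, tolerance = 1e-8)
  expect_equal(ext$phi_max[ext$metabolite == "C"], 10, tolerance = 1e-8)
  # uptake is pinned at 10, so the turnover of A is forced
  expect_equal(ext$phi_min[ext$metabolite == "A"], 10, tolerance = 1e-8)
  expect_equal(ext$phi_max[ext$metabolite == "A"], 10, tolerance = 1e-8)

  # single producer fixed at [5,5], single consumer: range collapses to 5
  mets <- tibble::tibble(id = "X")
  rxns <- tibble::tibble(id = c("IN", "OUT"), lower_bound = c(5, 0),
                         upper_bound = c(5, 1000),
                         objective_coefficient = c(0, 1))
  st <- tibble::tibble(reaction = c("IN", "OUT"), metabolite = "X",
                       coefficient = c(1, -1))
  mm <- metabolic_model(mets, rxns, st, "OUT")
  e <- flux_sum_extrema(mm, "X")
  expect_equal(e$phi_min, 5, tolerance = 1e-8)
  expect_equal(e$phi_max, 5, tolerance = 1e-8)
})

test_that("any feasible flux-sum lies within the computed extrema", {
  m <- mixed_acid_model()
  mets <- c("pyr", "pep", "accoa", "nadh", "co2")
  ext <- flux_sum_extrema(m, mets)
  set.seed(101)
  for (rep in 1:100) {
    # random-objective LP vertex = a random feasible steady-state point
    prob <- fluxsum:::build_fba_problem(m)
    prob <- fluxsum:::lp_set_objective(prob, m$reactions$id,
                                       stats::rnorm(nrow(m$reactions)))
    res <- solve_lp(prob, maximize = TRUE)
    expect_equal(res$status, "optimal")
    for (met in mets) {
      phi <- oracle_flux_sum_eval(m, res$x, met)
      row <- ext[ext$metabolite == met, ]
      expect_gte(phi, row$phi_min - 1e-6)
      expect_lte(phi, row$phi_max + 1e-6)
    }
  }
})

test_that("flux-sum values are invariant to reaction relabeling", {
  m <- two_branch_model()
  perm <- c(5, 3, 8, 1, 7, 2, 6, 4)
  m2 <- metabolic_model(m$metabolites, m$reactions[perm, ],
                        m$stoichiometry, m$biomass_id)
  e1 <- flux_sum_extrema(m, c("B", "C", "F"))
  e2 <- flux_sum_extrema(m2, c("B", "C", "F"))
  expect_equal(e1$phi_min, e2$phi_min, tolerance = 1e-6)
  expect_equal(e1$phi_max, e2$phi_max, tolerance = 1e-6)
})

test_that("big-M is validated against the model's bounds", {
  m <- two_branch_model()
  m$reactions$upper_bound[m$reactions$id == "EX_F"] <- 5000
  m <- metabolic_model(m$metabolites, m$reactions, m$stoichiometry,
                       m$biomass_id)
  expect_warning(v <- fluxsum:::effective_big_M(m, solve_config()),
                 "big_M")
  expect_equal(v, 50000)
  expect_silent(fluxsum:::effective_big_M(two_branch_model(), solve_config()))
})
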