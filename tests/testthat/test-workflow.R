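# The four-step target-identification workflow.

test_that("reference state matches the two-branch analytics", {
  m <- two_branch_model()
  ref <- reference_state(m, "EX_E")
  expect_equal(ref$wt_growth, 10, tolerance = 1e-8)
  expect_equal(ref$wt_production, 0, tolerance = 1e-8)
  phi <- ref$phi_wt
  expect_equal(phi$phi_wt[phi$metabolite == "C"], 10, tolerance = 1e-6)
  expect_equal(phi$phi_wt[phi$metabolite == "B"], 0, tolerance = 1e-6)

  # growth clamped to zero: reference still consistent with a feasible point
  m0 <- m
  m0$reactions$upper_bound[m0$reactions$id == "BIOMASS"] <- 0
  m0 <- metabolic_model(m0$metabolites, m0$reactions, m0$stoichiometry,
                        m0$biomass_id)
  ref0 <- reference_state(m0, "EX_E")
  expect_equal(ref0$wt_growth, 0, tolerance = 1e-9)
  # all 10 uptake units must exit somewhere at zero growth
  expect_equal(ref0$phi_wt$phi_wt[ref0$phi_wt$metabolite == "A"], 10,
               tolerance = 1e-6)
})

test_that("perturbed growth follows the analytic two-branch solution", {
  m <- two_branch_model()
  rec <- flux_sum_reference(m, "EX_E")
  rC <- rec[rec$metabolite == "C", ]
  expect_equal(unlist(rC[, c("phi_min", "phi_wt", "phi_max")]),
               c(phi_min = 0, phi_wt = 10, phi_max = 10), tolerance = 1e-6)

  # weakest constraints reproduce the wild type
  g <- growth_under_perturbation(m, "C", "attenuation", 1, rC)
  expect_equal(g$growth, 10, tolerance = 1e-6)
  rB <- rec[rec$metabolite == "B", ]
  g0 <- growth_under_perturbation(m, "B", "intensification", 0, rB)
  expect_equal(g0$growth, 10, tolerance = 1e-6)

  # halving the C turnover halves the only biomass-feeding path
  g5 <- growth_under_perturbation(m, "C", "attenuation", 0.5, rC)
  expect_equal(g5$growth, 5, tolerance = 1e-6)
  p5 <- worst_case_production(m, "EX_E", "maximize", "C", "attenuation",
                              0.5, rC, g5$growth)
  expect_equal(p5$production, 5, tolerance = 1e-6)

  # degenerate range: A's turnover is pinned by the fixed uptake
  rA <- rec[rec$metabolite == "A", ]
  expect_equal(growth_under_perturbation(m, "A", "attenuation", 0.5,
                                         rA)$status,
               "degenerate_range")

  # goal = minimize: starving the C path kills F production entirely
  recF <- flux_sum_reference(m, "EX_F", goal = "minimize")
  rC2 <- recF[recF$metabolite == "C", ]
  gk0 <- growth_under_perturbation(m, "C", "attenuation", 0, rC2)
  expect_equal(gk0$growth, 0, tolerance = 1e-6)
  pk0 <- worst_case_production(m, "EX_F", "minimize", "C", "attenuation",
                               0, rC2, gk0$growth)
  expect_equal(pk0$production, 0, tolerance = 1e-6)
})

test_that("full scan recovers the derived two-branch target set and profile", {
  m <- two_branch_model()
  scan <- fsa_scan(m, "EX_E", goal = "maximize")

  # the four equivalent pins of the branch split, frozen from the analytic
  # derivation: restricting C's turnover, restricting F's, or forcing flux
  # into B or E all guarantee E production
  expect_identical(
    paste(scan$targets$metabolite, scan$targets$direction),
    c("B intensification", "C attenuation", "E intensification",
      "F attenuation"))

  prof <- production_profile(scan, "C", "attenuation")
  expect_equal(nrow(prof), 11)
  expect_equal(prof$production, 10 * (1 - prof$k), tolerance = 1e-6)
  expect_equal(prof$growth, 10 * prof$k, tolerance = 1e-6)
  expect_true(all(diff(prof$production) < 0))

  # A is skipped in both directions (turnover pinned by the fixed uptake)
  expect_true(all(c("attenuation", "intensification") %in%
                    scan$skipped$direction[scan$skipped$metabolite == "A"]))
  expect_error(production_profile(scan, "A", "attenuation"), "not scanned")

  # reports every convention it used
  expect_true(all(c("improvement_threshold", "phi_wt_convention", "big_M") %in%
                    names(scan$metadata)))
})

test_that("a perfect wild-type guarantee admits no reduction targets", {
  # goal = minimize EX_F on the two-branch network: the growth guarantee
  # already forces every unit of F into biomass, so the wild-type worst-case
  # secretion is 0 and no flux-sum perturbation can improve on it
  m <- two_branch_model()
  scan <- fsa_scan(m, "EX_F", goal = "minimize")
  expect_equal(scan$reference$wt_production, 0, tolerance = 1e-6)
  expect_equal(nrow(scan$targets), 0)
  ok <- scan$points$production[scan$points$production_status == "optimal"]
  expect_true(all(ok <= 1e-6))
})

test_that("growth is monotone in k and endpoints anchor at the wild type", {
  m <- mixed_acid_model()
  scan <- fsa_scan(m, "EX_succ", goal = "maximize",
                   k_grid = seq(0, 1, by = 0.25))
  ref <- scan$reference
  for (key in split(scan$points,
                    paste(scan$points$metabolite, scan$points$direction))) {
    ok <- key[key$growth_status == "optimal", ]
    ok <- ok[order(ok$k), ]
    if (nrow(ok) < 2) next
    d <- diff(ok$growth)
    if (key$direction[1] == "attenuation") {
      expect_true(all(d >= -1e-6), info = paste(key$metabolite[1],
                                                key$direction[1]))
      anchor <- ok[ok$k == 1, ]
    } else {
      expect_true(all(d <= 1e-6), info = paste(key$metabolite[1],
                                               key$direction[1]))
      anchor <- ok[ok$k == 0, ]
    }
    if (nrow(anchor) == 1) {
      expect_equal(anchor$growth, ref$wt_growth, tolerance = 1e-6)
      expect_equal(anchor$production, ref$wt_production, tolerance = 1e-6)
    }
  }
})

test_that("worst-case production never exceeds the best case", {
  m <- mixed_acid_model()
  rec <- flux_sum_reference(m, "EX_succ")
  rp <- rec[rec$metabolite == "pyr", ]
  for (k in c(0.25, 0.5, 0.75)) {
    g <- growth_under_perturbation(m, "pyr", "attenuation", k, rp)
    worst <- worst_case_production(m, "EX_succ", "maximize", "pyr",
                                   "attenuation", k, rp, g$growth)
    # flipping the final sense gives the best case under the same constraints
    best <- worst_case_production(m, "EX_succ", "minimize", "pyr",
                                  "attenuation", k, rp, g$growth)
    expect_lte(worst$production, best$production + 1e-6)
  }
})

test_that("scans are deterministic", {
  m <- mixed_acid_model()
  s1 <- fsa_scan(m, "EX_succ", k_grid = c(0, 0.5, 1),
                 exclude = c("nad", "nadh", "atp", "adp", "co2"))
  s2 <- fsa_scan(m, "EX_succ", k_grid = c(0, 0.5, 1),
                 exclude = c("nad", "nadh", "atp", "adp", "co2"))
  expect_identical(s1$points, s2$points)
  expect_identical(s1$targets, s2$targets)
})
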