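# Programmatic toy networks. These are first-class study systems, not just
# test scaffolding: the two-branch network gives exact closed-form answers
# for every step of the flux-sum workflow, and the mixed-acid network is a
# reduced anaerobic fermentation model that reproduces, at toy scale, the
# qualitative behavior of E. coli by-product secretion under flux-sum
# perturbation (triangular succinate profile under pyruvate attenuation,
# ethanol gains from pyruvate-decarboxylase insertion).

rxn_row <- function(id, lb, ub, obj = 0, name = id) {
  tibble::tibble(id = id, name = name, lower_bound = lb, upper_bound = ub,
                 objective_coefficient = obj)
}

stoich_rows <- function(reaction, ...) {
  coefs <- c(...)
  tibble::tibble(reaction = reaction, metabolite = names(coefs),
                 coefficient = unname(coefs))
}

#' Two-branch toy network with closed-form flux-sum behavior
#'
#' A fixed uptake of 10 units of metabolite A splits over two parallel
#' irreversible branches, A -> B -> E (secreted product E) and
#' A -> C -> F (F feeds the biomass reaction). At maximum growth all 10
#' units flow through C, so growth is 10 and the guaranteed production of
#' E is 0; attenuating the flux-sum of C to a fraction k of its wild-type
#' value forces production of E at exactly 10(1-k) while growth drops to
#' 10k. Every quantity in the flux-sum workflow has an exact analytic value
#' on this network, which the test-suite oracles exploit.
#'
#' @return a `metabolic_model` with 5 internal metabolites and 8 irreversible
#'   reactions.
#' @export
#' @examples
#' m <- two_branch_model()
#' solve_fba(m)$objective_value # 10
two_branch_model <- function() {
  mets <- tibble::tibble(id = c("A", "B", "C", "E", "F"))
  rxns <- dplyr::bind_rows(
    rxn_row("UPTAKE", 10, 10),
    rxn_row("R1", 0, 1000),
    rxn_row("R2", 0, 1000),
    rxn_row("R3", 0, 1000),
    rxn_row("R4", 0, 1000),
    rxn_row("EX_E", 0, 1000),
    rxn_row("EX_F", 0, 1000),
    rxn_row("BIOMASS", 0, 1000, obj = 1)
  )
  st <- dplyr::bind_rows(
    stoich_rows("UPTAKE", A = 1),
    stoich_rows("R1", A = -1, B = 1),
    stoich_rows("R2", A = -1, C = 1),
    stoich_rows("R3", B = -1, E = 1),
    stoich_rows("R4", C = -1, F = 1),
    stoich_rows("EX_E", E = -1),
    stoich_rows("EX_F", F = -1),
    stoich_rows("BIOMASS", F = -1)
  )
  metabolic_model(mets, rxns, st, "BIOMASS",
                  annotations = list(id = "two_branch"))
}

#' Reduced anaerobic mixed-acid fermentation network
#'
#' A toy analogue of anaerobic E. coli central carbon metabolism: glucose
#' enters through a PEP-consuming phosphotransferase step (PTS), lumped
#' glycolysis converts glucose 6-phosphate to two PEP with net ATP and NADH
#' gain, and the PEP node splits between pyruvate kinase (PYK) and PEP
#' carboxylase (PPC). The PPC branch runs through oxaloacetate, malate and
#' fumarate to succinate via fumarate reductase; pyruvate feeds lactate
#' (LDH), formate plus acetyl-CoA (PFL) or acetyl-CoA plus NADH (PDH);
#' acetyl-CoA feeds acetate (PTA/ACK, with ATP gain) or ethanol
#' (ACALD/ALCD, burning NADH). NAD/NADH and ATP/ADP are balanced inside the
#' network; biomass is ATP regeneration. Exchanges exist for glucose (uptake
#' capped at 10), succinate, ethanol, acetate, formate, lactate and CO2
#' (freely exchanged, since PPC fixes CO2).
#'
#' With `with_pdc = TRUE` a single extra reaction, pyruvate decarboxylase
#' (pyruvate -> acetaldehyde + CO2), is added and nothing else changes, so
#' the engineered network's feasible flux space is a superset of the
#' wild-type one.
#'
#' All reactions are irreversible except the CO2 exchange. One reaction
#' (lumped glycolysis) carries stoichiometric coefficient 2 on PEP, NAD and
#' NADH: the PTS uptake step consumes one PEP per glucose, so with unit
#' coefficients throughout the network could never show a net PEP gain.
#'
#' @param with_pdc insert the pyruvate decarboxylase reaction.
#' @return a `metabolic_model` with 20 internal metabolites and 22 (23 with
#'   PDC) reactions.
#' @export
mixed_acid_model <- function(with_pdc = FALSE) {
  mets <- tibble::tibble(id = c(
    "glc", "g6p", "pep", "pyr", "oaa", "mal", "fum", "succ", "lac",
    "accoa", "actp", "ac", "acald", "etoh", "for", "co2",
    "nad", "nadh", "atp", "adp"))
  rxns <- dplyr::bind_rows(
    rxn_row("EX_glc", 0, 10),
    rxn_row("PTS", 0, 1000),
    rxn_row("GLY", 0, 1000),
    rxn_row("PYK", 0, 1000),
    rxn_row("PPC", 0, 1000),
    rxn_row("MDH", 0, 1000),
    rxn_row("FUM", 0, 1000),
    rxn_row("FRD", 0, 1000),
    rxn_row("LDH", 0, 1000),
    rxn_row("PFL", 0, 1000),
    rxn_row("PDH", 0, 1000),
    rxn_row("PTA", 0, 1000),
    rxn_row("ACK", 0, 1000),
    rxn_row("ACALD", 0, 1000),
    rxn_row("ALCD", 0, 1000),
    rxn_row("BIOMASS", 0, 1000, obj = 1),
    rxn_row("EX_succ", 0, 1000),
    rxn_row("EX_etoh", 0, 1000),
    rxn_row("EX_ac", 0, 1000),
    rxn_row("EX_for", 0, 1000),
    rxn_row("EX_lac", 0, 1000),
    rxn_row("EX_co2", -1000, 1000)
  )
  st <- dplyr::bind_rows(
    stoich_rows("EX_glc", glc = 1),
    stoich_rows("PTS", glc = -1, pep = -1, g6p = 1, pyr = 1),
    stoich_rows("GLY", g6p = -1, adp = -1, nad = -2,
                pep = 2, atp = 1, nadh = 2),
    stoich_rows("PYK", pep = -1, adp = -1, pyr = 1, atp = 1),
    stoich_rows("PPC", pep = -1, co2 = -1, oaa = 1),
    stoich_rows("MDH", oaa = -1, nadh = -1, mal = 1, nad = 1),
    stoich_rows("FUM", mal = -1, fum = 1),
    stoich_rows("FRD", fum = -1, nadh = -1, succ = 1, nad = 1),
    stoich_rows("LDH", pyr = -1, nadh = -1, lac = 1, nad = 1),
    stoich_rows("PFL", pyr = -1, accoa = 1, `for` = 1),
    stoich_rows("PDH", pyr = -1, nad = -1, accoa = 1, co2 = 1, nadh = 1),
    stoich_rows("PTA", accoa = -1, actp = 1),
    stoich_rows("ACK", actp = -1, adp = -1, ac = 1, atp = 1),
    stoich_rows("ACALD", accoa = -1, nadh = -1, acald = 1, nad = 1),
    stoich_rows("ALCD", acald = -1, nadh = -1, etoh = 1, nad = 1),
    stoich_rows("BIOMASS", atp = -1, adp = 1),
    stoich_rows("EX_succ", succ = -1),
    stoich_rows("EX_etoh", etoh = -1),
    stoich_rows("EX_ac", ac = -1),
    stoich_rows("EX_for", `for` = -1),
    stoich_rows("EX_lac", lac = -1),
    stoich_rows("EX_co2", co2 = -1)
  )
  if (with_pdc) {
    rxns <- dplyr::bind_rows(rxns, rxn_row("PDC", 0, 1000))
    st <- dplyr::bind_rows(st, stoich_rows("PDC", pyr = -1, acald = 1,
                                           co2 = 1))
  }
  metabolic_model(mets, rxns, st, "BIOMASS",
                  annotations = list(
                    id = if (with_pdc) "mixed_acid_pdc" else "mixed_acid"))
}

#' Random all-irreversible toy network
#'
#' Generates a layered irreversible network for property-based testing: a
#' capped uptake feeds the first layer, random unit-coefficient reactions
#' connect consecutive layers, the last layer feeds a biomass reaction and a
#' secreted target, and every metabolite can drain through a spill exchange
#' so the network is never trivially infeasible. All bounds are finite and
#' all reactions irreversible, so the flux-sum of every metabolite has an
#' exact linear-programming formulation, which the oracle-equivalence tests
#' rely on.
#'
#' @param n_mets number of internal metabolites (>= 3).
#' @param n_extra number of extra random internal reactions beyond the
#'   backbone chain.
#' @param seed integer seed; the generator is deterministic given
#'   (`n_mets`, `n_extra`, `seed`).
#' @return a `metabolic_model` whose annotations record the target exchange
#'   id under `$target`.
#' @export
random_irreversible_model <- function(n_mets = 6, n_extra = 4, seed = 1) {
  stopifnot(n_mets >= 3)
  rng <- local({
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
            else suppressWarnings(rm(".Random.seed", envir = globalenv())))
    set.seed(seed)
    list(
      edges = replicate(n_extra, sort(sample.int(n_mets, 2)), simplify = FALSE),
      ub = round(stats::runif(n_extra + n_mets + 4, 2, 15), 3),
      uptake = sample(5:10, 1)
    )
  })
  mets <- tibble::tibble(id = paste0("M", seq_len(n_mets)))
  rxns <- rxn_row("UPTAKE", 0, rng$uptake)
  st <- stoich_rows("UPTAKE", M1 = 1)
  # backbone chain M1 -> M2 -> ... -> Mn
  for (i in seq_len(n_mets - 1)) {
    id <- paste0("CHAIN_", i)
    rxns <- dplyr::bind_rows(rxns, rxn_row(id, 0, rng$ub[i]))
    coefs <- c(-1, 1)
    names(coefs) <- paste0("M", c(i, i + 1))
    st <- dplyr::bind_rows(st, tibble::tibble(
      reaction = id, metabolite = names(coefs), coefficient = unname(coefs)))
  }
  # extra forward shortcuts (skip self-loops, always lower -> higher index)
  kept <- 0L
  for (e in rng$edges) {
    if (e[1] == e[2]) next
    kept <- kept + 1L
    id <- paste0("X", kept)
    rxns <- dplyr::bind_rows(rxns, rxn_row(id, 0, rng$ub[n_mets - 1 + kept]))
    st <- dplyr::bind_rows(st, tibble::tibble(
      reaction = id, metabolite = paste0("M", e),
      coefficient = c(-1, 1)))
  }
  last <- paste0("M", n_mets)
  mid <- paste0("M", max(2L, n_mets %/% 2L))
  rxns <- dplyr::bind_rows(
    rxns,
    rxn_row("BIOMASS", 0, 1000, obj = 1),
    rxn_row("EX_TARGET", 0, 1000),
    rxn_row("EX_SPILL", 0, 1000)
  )
  st <- dplyr::bind_rows(
    st,
    tibble::tibble(reaction = "BIOMASS", metabolite = last, coefficient = -1),
    tibble::tibble(reaction = "EX_TARGET", metabolite = mid, coefficient = -1),
    tibble::tibble(reaction = "EX_SPILL", metabolite = last, coefficient = -1)
  )
  metabolic_model(mets, rxns, st, "BIOMASS",
                  annotations = list(
                    id = sprintf("random_irreversible_%d", seed),
                    target = "EX_TARGET"))
}
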