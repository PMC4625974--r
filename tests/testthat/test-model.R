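# Model container, validation, fixtures and file formats.

test_that("constructor validates identifiers, bounds and stoichiometry", {
  mets <- tibble::tibble(id = c("A", "B"))
  rxns <- tibble::tibble(id = c("r1", "r2"), lower_bound = 0, upper_bound = 1)
  st <- tibble::tibble(reaction = c("r1", "r2"),
                       metabolite = c("A", "B"), coefficient = c(1, -1))
  expect_s3_class(metabolic_model(mets, rxns, st, "r1"), "metabolic_model")

  expect_error(metabolic_model(mets, rxns,
                               dplyr::mutate(st, metabolite = c("A", "X")),
                               "r1"),
               "unknown metabolite.*X")
  expect_error(metabolic_model(mets, rxns, st, "nope"), "biomass")
  expect_error(metabolic_model(mets,
                               dplyr::mutate(rxns, lower_bound = c(2, 0)),
                               st, "r1"),
               "lower bound exceeds")
  expect_error(metabolic_model(mets, rxns,
                               dplyr::mutate(st, coefficient = c(0, 1)),
                               "r1"),
               "finite and non-zero")
  expect_error(metabolic_model(mets, rxns, st[1, ], "r1"),
               "empty stoichiometry")
  expect_error(metabolic_model(dplyr::bind_rows(mets, mets[1, ]), rxns, st,
                               "r1"),
               "duplicate metabolite")
})

test_that("exchange reactions are those touching exactly one internal metabolite", {
  m <- two_branch_model()
  ex <- m$reactions$id[m$reactions$exchange]
  # the biomass reaction consumes only F, so it is formally an exchange too
  expect_setequal(ex, c("UPTAKE", "EX_E", "EX_F", "BIOMASS"))
  m2 <- mixed_acid_model()
  expect_false(m2$reactions$exchange[m2$reactions$id == "BIOMASS"])
  expect_true(all(c("EX_glc", "EX_succ", "EX_co2") %in%
                    m2$reactions$id[m2$reactions$exchange]))
})

test_that("fixture generators are deterministic and self-consistent", {
  expect_identical(two_branch_model(), two_branch_model())
  expect_identical(mixed_acid_model(TRUE), mixed_acid_model(TRUE))
  expect_identical(random_irreversible_model(seed = 3),
                   random_irreversible_model(seed = 3))
  expect_false(identical(random_irreversible_model(seed = 3),
                         random_irreversible_model(seed = 4)))

  # PDC insertion adds exactly one reaction and changes nothing else
  a <- mixed_acid_model(FALSE); b <- mixed_acid_model(TRUE)
  expect_equal(nrow(b$reactions), nrow(a$reactions) + 1)
  expect_identical(a$metabolites, b$metabolites)
  common <- intersect(a$reactions$id, b$reactions$id)
  expect_identical(a$reactions[match(common, a$reactions$id), ],
                   b$reactions[match(common, b$reactions$id),
                               names(a$reactions)])
})

test_that("JSON round-trip preserves the model exactly", {
  m <- two_branch_model()
  f <- tempfile(fileext = ".json")
  write_metabolic_model(m, f)
  m2 <- read_metabolic_model(f)
  expect_identical(m$reactions, m2$reactions)
  expect_identical(dplyr::arrange(m$stoichiometry, reaction, metabolite),
                   dplyr::arrange(m2$stoichiometry, reaction, metabolite))
  expect_identical(m$biomass_id, m2$biomass_id)

  # byte-stable serialization
  f2 <- tempfile(fileext = ".json")
  write_metabolic_model(m2, f2)
  expect_identical(readLines(f), readLines(f2))
})

test_that("JSON with a reaction citing an undeclared metabolite errors by name", {
  doc <- list(
    metabolites = list(list(id = "A", name = "A", compartment = "c")),
    reactions = list(list(id = "r1", name = "r1",
                          metabolites = list(A = -1, X = 1),
                          lower_bound = 0, upper_bound = 1,
                          objective_coefficient = 1)))
  f <- tempfile(fileext = ".json")
  jsonlite::write_json(doc, f, auto_unbox = TRUE)
  expect_error(read_metabolic_model(f), "unknown metabolite.*X")
})

test_that("SBML round-trip preserves stoichiometry, bounds and objective", {
  for (m in list(two_branch_model(), mixed_acid_model(TRUE))) {
    f <- tempfile(fileext = ".xml")
    write_metabolic_model(m, f)
    m2 <- read_metabolic_model(f)
    expect_equal(m$reactions$lower_bound, m2$reactions$lower_bound)
    expect_equal(m$reactions$upper_bound, m2$reactions$upper_bound)
    expect_equal(m$reactions$objective_coefficient,
                 m2$reactions$objective_coefficient)
    expect_identical(
      dplyr::arrange(m$stoichiometry, reaction, metabolite),
      dplyr::arrange(m2$stoichiometry, reaction, metabolite))
    expect_identical(m$biomass_id, m2$biomass_id)
    f2 <- tempfile(fileext = ".xml")
    write_metabolic_model(m2, f2)
    expect_identical(readLines(f), readLines(f2))
  }
})

test_that("SBML with kinetic-law bounds or boundary species is handled", {
  f <- tempfile(fileext = ".xml")
  write_metabolic_model(two_branch_model(), f)
  doc <- readLines(f)
  i <- grep("<reaction ", doc)[1]
  doc[i] <- sub(">$", "><kineticLaw/>", doc[i])
  writeLines(doc, f)
  expect_error(read_metabolic_model(f), "kinetic-law")

  # a boundaryCondition species is flagged and excluded from the balance
  m <- two_branch_model()
  m$metabolites$boundary[m$metabolites$id == "E"] <- TRUE
  m <- metabolic_model(m$metabolites, m$reactions, m$stoichiometry,
                       m$biomass_id)
  f2 <- tempfile(fileext = ".xml")
  write_metabolic_model(m, f2)
  m2 <- read_metabolic_model(f2)
  expect_true(m2$metabolites$boundary[m2$metabolites$id == "E"])
  expect_false("E" %in% rownames(stoichiometric_matrix(m2)))
  expect_false("E" %in% internal_metabolites(m2))
})

test_that("stoichiometric matrix matches the stoichiometry table", {
  m <- mixed_acid_model()
  S <- stoichiometric_matrix(m)
  expect_equal(dim(S), c(20, 22))
  expect_equal(S["pep", "GLY"], 2)
  expect_equal(S["pep", "PTS"], -1)
  expect_equal(S["glc", "EX_glc"], 1)
  expect_equal(sum(S != 0), nrow(m$stoichiometry))
})
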