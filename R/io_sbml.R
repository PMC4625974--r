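# SBML Level 3 reader/writer covering the subset needed for constraint-based
# models: compartments, species (with boundaryCondition), reactions with
# reactant/product stoichiometry, and the flux-balance ("fbc") extension for
# bounds (parameter-referenced) and the active objective. Bounds encoded in
# kinetic laws are rejected with a clear error rather than guessed at.

FBC_NS <- "http://www.sbml.org/sbml/level3/version1/fbc/version2"

read_model_sbml <- function(path, biomass_id = NULL) {
  doc <- tryCatch(xml2::read_xml(path), error = function(e) {
    stop("cannot parse '", path, "' as XML: ", conditionMessage(e),
         call. = FALSE)
  })
  ns <- c(s = xml2::xml_ns(doc)[["d1"]] %||%
            "http://www.sbml.org/sbml/level3/version1/core",
          fbc = FBC_NS)
  mdl <- xml2::xml_find_first(doc, ".//s:model", ns)
  if (inherits(mdl, "xml_missing")) {
    stop("no <model> element found in '", path, "'", call. = FALSE)
  }

  sp_nodes <- xml2::xml_find_all(mdl, ".//s:listOfSpecies/s:species", ns)
  mets <- tibble::tibble(
    id = xml2::xml_attr(sp_nodes, "id"),
    name = dplyr::coalesce(xml2::xml_attr(sp_nodes, "name"),
                           xml2::xml_attr(sp_nodes, "id")),
    compartment = dplyr::coalesce(xml2::xml_attr(sp_nodes, "compartment"), "c"),
    boundary = xml2::xml_attr(sp_nodes, "boundaryCondition") %in%
      c("true", "1")
  )

  par_nodes <- xml2::xml_find_all(mdl, ".//s:listOfParameters/s:parameter", ns)
  par_val <- stats::setNames(
    as.numeric(xml2::xml_attr(par_nodes, "value")),
    xml2::xml_attr(par_nodes, "id"))

  rx_nodes <- xml2::xml_find_all(mdl, ".//s:listOfReactions/s:reaction", ns)
  if (length(rx_nodes) == 0) {
    stop("model in '", path, "' declares no reactions", call. = FALSE)
  }
  kinetic <- xml2::xml_find_all(mdl, ".//s:reaction/s:kineticLaw", ns)
  if (length(kinetic) > 0) {
    stop("kinetic-law-encoded flux bounds are not supported; ",
         "use the fbc flux-bounds attributes", call. = FALSE)
  }

  bound_of <- function(node, attr, default) {
    ref <- xml2::xml_attr(node, attr, ns = ns)
    if (is.na(ref)) return(default)
    if (!ref %in% names(par_val) || is.na(par_val[[ref]])) {
      stop("flux bound parameter '", ref, "' is undefined", call. = FALSE)
    }
    par_val[[ref]]
  }
  rev_attr <- xml2::xml_attr(rx_nodes, "reversible") %in% c("true", "1")
  rxns <- tibble::tibble(
    id = xml2::xml_attr(rx_nodes, "id"),
    name = dplyr::coalesce(xml2::xml_attr(rx_nodes, "name"),
                           xml2::xml_attr(rx_nodes, "id")),
    lower_bound = purrr::map2_dbl(rx_nodes, rev_attr, function(n, rv) {
      bound_of(n, "fbc:lowerFluxBound", if (rv) -1000 else 0)
    }),
    upper_bound = purrr::map_dbl(rx_nodes, function(n) {
      bound_of(n, "fbc:upperFluxBound", 1000)
    }),
    objective_coefficient = 0
  )

  st <- purrr::map_dfr(rx_nodes, function(n) {
    id <- xml2::xml_attr(n, "id")
    reac <- xml2::xml_find_all(n, "./s:listOfReactants/s:speciesReference", ns)
    prod <- xml2::xml_find_all(n, "./s:listOfProducts/s:speciesReference", ns)
    coef <- function(nodes, sign) {
      if (length(nodes) == 0) return(NULL)
      tibble::tibble(
        reaction = id,
        metabolite = xml2::xml_attr(nodes, "species"),
        coefficient = sign * dplyr::coalesce(
          as.numeric(xml2::xml_attr(nodes, "stoichiometry")), 1))
    }
    dplyr::bind_rows(coef(reac, -1), coef(prod, 1))
  })
  # net out species appearing on both sides of one reaction
  st <- dplyr::summarise(dplyr::group_by(st, reaction, metabolite),
                         coefficient = sum(coefficient), .groups = "drop")
  st <- st[st$coefficient != 0, ]

  obj_nodes <- xml2::xml_find_all(
    mdl, ".//fbc:listOfObjectives/fbc:objective/fbc:listOfFluxObjectives/fbc:fluxObjective",
    ns)
  if (length(obj_nodes) > 0) {
    oid <- xml2::xml_attr(obj_nodes, "fbc:reaction", ns = ns)
    ocoef <- as.numeric(xml2::xml_attr(obj_nodes, "fbc:coefficient", ns = ns))
    ocoef[is.na(ocoef)] <- 1
    rxns$objective_coefficient[match(oid, rxns$id)] <- ocoef
  }
  if (is.null(biomass_id)) {
    obj <- rxns$id[rxns$objective_coefficient != 0]
    if (length(obj) == 0) {
      stop("no flux objective declared; pass biomass_id explicitly",
           call. = FALSE)
    }
    biomass_id <- obj[[1L]]
  }
  metabolic_model(mets, rxns, st, biomass_id,
                  annotations = list(id = xml2::xml_attr(mdl, "id")))
}

write_model_sbml <- function(model, path) {
  esc <- function(x) {
    x <- gsub("&", "&amp;", x, fixed = TRUE)
    x <- gsub("<", "&lt;", x, fixed = TRUE)
    gsub(">", "&gt;", x, fixed = TRUE)
  }
  num <- function(x) formatC(x, format = "g", digits = 17)

  bounds <- sort(unique(c(model$reactions$lower_bound,
                          model$reactions$upper_bound)))
  par_id <- stats::setNames(paste0("fb_", seq_along(bounds)),
                            as.character(bounds))
  lines <- c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    paste0('<sbml xmlns="http://www.sbml.org/sbml/level3/version1/core" ',
           'xmlns:fbc="', FBC_NS, '" level="3" version="1" fbc:required="false">'),
    paste0('  <model id="', esc(model$annotations$id %||% "model"),
           '" fbc:strict="true">'),
    '    <listOfCompartments>')
  for (cp in sort(unique(model$metabolites$compartment))) {
    lines <- c(lines, paste0('      <compartment id="', esc(cp),
                             '" constant="true"/>'))
  }
  lines <- c(lines, '    </listOfCompartments>', '    <listOfSpecies>')
  for (i in seq_len(nrow(model$metabolites))) {
    m <- model$metabolites[i, ]
    lines <- c(lines, paste0(
      '      <species id="', esc(m$id), '" name="', esc(m$name),
      '" compartment="', esc(m$compartment),
      '" hasOnlySubstanceUnits="false" constant="false" boundaryCondition="',
      if (m$boundary) "true" else "false", '"/>'))
  }
  lines <- c(lines, '    </listOfSpecies>', '    <listOfParameters>')
  for (b in names(par_id)) {
    lines <- c(lines, paste0('      <parameter id="', par_id[[b]],
                             '" value="', num(as.numeric(b)),
                             '" constant="true"/>'))
  }
  lines <- c(lines, '    </listOfParameters>', '    <listOfReactions>')
  st <- model$stoichiometry
  for (i in seq_len(nrow(model$reactions))) {
    r <- model$reactions[i, ]
    sub <- st[st$reaction == r$id, ]
    sub <- sub[order(sub$metabolite), ]
    lines <- c(lines, paste0(
      '      <reaction id="', esc(r$id), '" name="', esc(r$name),
      '" reversible="', if (r$lower_bound < 0) "true" else "false",
      '" fast="false" fbc:lowerFluxBound="',
      par_id[[as.character(r$lower_bound)]],
      '" fbc:upperFluxBound="', par_id[[as.character(r$upper_bound)]], '">'))
    reac <- sub[sub$coefficient < 0, ]
    prods <- sub[sub$coefficient > 0, ]
    if (nrow(reac) > 0) {
      lines <- c(lines, '        <listOfReactants>',
                 paste0('          <speciesReference species="',
                        esc(reac$metabolite), '" stoichiometry="',
                        num(-reac$coefficient), '" constant="true"/>'),
                 '        </listOfReactants>')
    }
    if (nrow(prods) > 0) {
      lines <- c(lines, '        <listOfProducts>',
                 paste0('          <speciesReference species="',
                        esc(prods$metabolite), '" stoichiometry="',
                        num(prods$coefficient), '" constant="true"/>'),
                 '        </listOfProducts>')
    }
    lines <- c(lines, '      </reaction>')
  }
  lines <- c(lines,
    '    </listOfReactions>',
    '    <fbc:listOfObjectives fbc:activeObjective="obj">',
    '      <fbc:objective fbc:id="obj" fbc:type="maximize">',
    '        <fbc:listOfFluxObjectives>')
  has_obj <- model$reactions$objective_coefficient != 0
  for (i in which(has_obj)) {
    r <- model$reactions[i, ]
    lines <- c(lines, paste0(
      '          <fbc:fluxObjective fbc:reaction="', esc(r$id),
      '" fbc:coefficient="', num(r$objective_coefficient), '"/>'))
  }
  lines <- c(lines,
    '        </fbc:listOfFluxObjectives>',
    '      </fbc:objective>',
    '    </fbc:listOfObjectives>',
    '  </model>',
    '</sbml>')
  writeLines(lines, path)
  invisible(path)
}
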