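# Minimal SBML Level 3 (+ fbc version 2) reader/writer built on xml2.
# Covers the constraint-based subset: compartments, species, reactions with
# stoichiometry, flux bounds as fbc bound parameters, the fbc objective, and
# gene associations (written both as nested fbc elements and as a verbatim
# GENE_ASSOCIATION note so rule strings round-trip exactly). Boundary
# species (boundaryCondition="true") are collapsed on read so exchanges take
# the single-metabolite form. Kinetic laws, events and unit algebra are out
# of scope.

SBML_NS <- "http://www.sbml.org/sbml/level3/version1/core"
FBC_NS <- "http://www.sbml.org/sbml/level3/version1/fbc/version2"

.write_model_sbml <- function(model, path) {
  doc <- xml2::xml_new_root(
    "sbml",
    xmlns = SBML_NS, "xmlns:fbc" = FBC_NS,
    level = "3", version = "1", "fbc:required" = "false")
  mdl <- xml2::xml_add_child(doc, "model", id = model$id,
                             "fbc:strict" = "true")

  lc <- xml2::xml_add_child(mdl, "listOfCompartments")
  for (tag in names(model$compartments)) {
    xml2::xml_add_child(lc, "compartment", id = tag,
                        name = model$compartments[[tag]], constant = "true")
  }

  ls <- xml2::xml_add_child(mdl, "listOfSpecies")
  for (i in seq_len(nrow(model$metabolites))) {
    m <- model$metabolites[i, ]
    sp <- xml2::xml_add_child(ls, "species", id = m$id, name = m$name,
                              compartment = m$compartment,
                              hasOnlySubstanceUnits = "false",
                              boundaryCondition = "false", constant = "false")
    if (!is.na(m$formula))
      xml2::xml_set_attr(sp, "fbc:chemicalFormula", m$formula)
  }

  # one bound parameter per distinct value
  bnds <- sort(unique(c(model$reactions$lower_bound,
                        model$reactions$upper_bound)))
  numfmt <- function(v) format(v, trim = TRUE, digits = 17, scientific = FALSE)
  pid <- function(v) sprintf("bnd_%s", gsub("[^0-9A-Za-z]", "_", numfmt(v)))
  lp <- xml2::xml_add_child(mdl, "listOfParameters")
  for (v in bnds) {
    xml2::xml_add_child(lp, "parameter", id = pid(v), value = numfmt(v),
                        constant = "true")
  }

  lr <- xml2::xml_add_child(mdl, "listOfReactions")
  for (i in seq_len(nrow(model$reactions))) {
    r <- model$reactions[i, ]
    rx <- xml2::xml_add_child(
      lr, "reaction", id = r$id, name = r$name,
      reversible = if (r$lower_bound < 0) "true" else "false",
      fast = "false",
      "fbc:lowerFluxBound" = pid(r$lower_bound),
      "fbc:upperFluxBound" = pid(r$upper_bound))
    if (isTRUE(r$exchange_annotated)) {
      note <- xml2::xml_add_child(rx, "notes")
      body <- xml2::xml_add_child(note, "body",
                                  xmlns = "http://www.w3.org/1999/xhtml")
      xml2::xml_add_child(body, "p", "EXCHANGE: true")
    }
    if (!is.na(r$gene_rule)) {
      note <- xml2::xml_find_first(rx, "./notes")
      if (inherits(note, "xml_missing")) {
        note <- xml2::xml_add_child(rx, "notes")
        xml2::xml_add_child(note, "body",
                            xmlns = "http://www.w3.org/1999/xhtml")
      }
      body <- xml2::xml_find_first(note, "./*")
      xml2::xml_add_child(body, "p",
                          paste0("GENE_ASSOCIATION: ", r$gene_rule))
    }
    if (!is.na(r$gene_rule)) {
      gpa <- xml2::xml_add_child(rx, "fbc:geneProductAssociation")
      .rule_to_gpa(gpa, parse_gene_rule(r$gene_rule))
    }
    st <- model$stoichiometry[[r$id]]
    reac <- st[st < 0]; prod <- st[st > 0]
    if (length(reac) > 0) {
      lrct <- xml2::xml_add_child(rx, "listOfReactants")
      for (met in names(reac))
        xml2::xml_add_child(lrct, "speciesReference", species = met,
                            stoichiometry = formatC(-reac[[met]], format = "g",
                                                    digits = 17),
                            constant = "true")
    }
    if (length(prod) > 0) {
      lprd <- xml2::xml_add_child(rx, "listOfProducts")
      for (met in names(prod))
        xml2::xml_add_child(lprd, "speciesReference", species = met,
                            stoichiometry = formatC(prod[[met]], format = "g",
                                                    digits = 17),
                            constant = "true")
    }
  }

  if (length(model$genes) > 0) {
    lg <- xml2::xml_add_child(mdl, "fbc:listOfGeneProducts")
    for (g in model$genes)
      xml2::xml_add_child(lg, "fbc:geneProduct", "fbc:id" = g,
                          "fbc:label" = g)
  }

  obj_rxns <- model$reactions[model$reactions$objective_coefficient != 0, ]
  lo <- xml2::xml_add_child(mdl, "fbc:listOfObjectives",
                            "fbc:activeObjective" = "obj")
  ob <- xml2::xml_add_child(lo, "fbc:objective", "fbc:id" = "obj",
                            "fbc:type" = "maximize")
  lfo <- xml2::xml_add_child(ob, "fbc:listOfFluxObjectives")
  for (i in seq_len(nrow(obj_rxns))) {
    xml2::xml_add_child(lfo, "fbc:fluxObjective",
                        "fbc:reaction" = obj_rxns$id[i],
                        "fbc:coefficient" = formatC(
                          obj_rxns$objective_coefficient[i],
                          format = "g", digits = 17))
  }

  xml2::write_xml(doc, path)
}

.read_model_sbml <- function(path) {
  doc <- tryCatch(xml2::read_xml(path), error = function(e)
    stop("SBML parse failure in ", path, ": ", conditionMessage(e)))
  ns <- c(s = SBML_NS, fbc = FBC_NS)
  mdl <- xml2::xml_find_first(doc, "./s:model", ns)
  if (inherits(mdl, "xml_missing"))
    stop("SBML parse failure: no <model> element in ", path)

  comps <- xml2::xml_find_all(mdl, "./s:listOfCompartments/s:compartment", ns)
  ctags <- xml2::xml_attr(comps, "id")
  cnames <- xml2::xml_attr(comps, "name")
  cnames[is.na(cnames)] <- ctags[is.na(cnames)]
  if (length(ctags) == 0) { ctags <- "c"; cnames <- "cytosol" }
  exo <- intersect(c("e", "extracellular"), ctags)
  model <- new_model(id = xml2::xml_attr(mdl, "id") %||% "model",
                     compartments = stats::setNames(cnames, ctags),
                     extracellular_tags = exo)

  species <- xml2::xml_find_all(mdl, "./s:listOfSpecies/s:species", ns)
  boundary_ids <- character()
  for (sp in species) {
    sid <- xml2::xml_attr(sp, "id")
    if (is.na(sid)) stop("SBML parse failure: species without id")
    if (identical(xml2::xml_attr(sp, "boundaryCondition"), "true")) {
      boundary_ids <- c(boundary_ids, sid)
      next
    }
    model <- add_metabolite(
      model, sid,
      name = xml2::xml_attr(sp, "name") %||% sid,
      compartment = xml2::xml_attr(sp, "compartment"),
      formula = xml2::xml_attr(sp, "chemicalFormula") %||% NA_character_)
  }

  pars <- xml2::xml_find_all(mdl, "./s:listOfParameters/s:parameter", ns)
  pvals <- stats::setNames(as.numeric(xml2::xml_attr(pars, "value")),
                           xml2::xml_attr(pars, "id"))

  # objective coefficients
  fobj <- xml2::xml_find_all(
    mdl, "./fbc:listOfObjectives/fbc:objective/fbc:listOfFluxObjectives/fbc:fluxObjective",
    ns)
  obj_map <- stats::setNames(
    as.numeric(xml2::xml_attr(fobj, "coefficient")),
    xml2::xml_attr(fobj, "reaction"))

  rxns <- xml2::xml_find_all(mdl, "./s:listOfReactions/s:reaction", ns)
  for (rx in rxns) {
    rid <- xml2::xml_attr(rx, "id")
    if (is.na(rid)) stop("SBML parse failure: reaction without id")
    st <- numeric()
    for (sr in xml2::xml_find_all(rx, "./s:listOfReactants/s:speciesReference", ns)) {
      met <- xml2::xml_attr(sr, "species")
      coef <- as.numeric(xml2::xml_attr(sr, "stoichiometry") %||% "1")
      if (!met %in% boundary_ids) st[met] <- (st[met] %|na|% 0) - coef
    }
    for (sr in xml2::xml_find_all(rx, "./s:listOfProducts/s:speciesReference", ns)) {
      met <- xml2::xml_attr(sr, "species")
      coef <- as.numeric(xml2::xml_attr(sr, "stoichiometry") %||% "1")
      if (!met %in% boundary_ids) st[met] <- (st[met] %|na|% 0) + coef
    }
    if (length(st) == 0)
      stop("SBML reaction ", rid, " has no non-boundary species")

    lb_id <- xml2::xml_attr(rx, "lowerFluxBound")
    ub_id <- xml2::xml_attr(rx, "upperFluxBound")
    lb <- if (!is.na(lb_id) && lb_id %in% names(pvals)) pvals[[lb_id]]
          else if (identical(xml2::xml_attr(rx, "reversible"), "true"))
            -DEFAULT_BOUND else 0
    ub <- if (!is.na(ub_id) && ub_id %in% names(pvals)) pvals[[ub_id]]
          else DEFAULT_BOUND

    notes <- xml2::xml_text(
      xml2::xml_find_all(rx, "./s:notes//*[local-name()='p']", ns))
    rule <- NA_character_
    ga <- grep("^GENE_ASSOCIATION:", notes, value = TRUE)
    if (length(ga) > 0) {
      rule <- trimws(sub("^GENE_ASSOCIATION:", "", ga[[1L]]))
      if (!nzchar(rule)) rule <- NA_character_
    } else {
      gpa <- xml2::xml_find_first(rx, "./fbc:geneProductAssociation/*", ns)
      if (!inherits(gpa, "xml_missing")) rule <- .gpa_to_rule(gpa, ns)
    }
    exch <- any(grepl("^EXCHANGE: true", notes))

    model <- add_reaction(model, rid, st,
                          lower_bound = lb, upper_bound = ub,
                          gene_rule = rule,
                          objective_coefficient = obj_map[rid] %|na|% 0,
                          name = xml2::xml_attr(rx, "name") %||% rid,
                          exchange_annotated = exch)
  }

  gps <- xml2::xml_find_all(mdl, "./fbc:listOfGeneProducts/fbc:geneProduct", ns)
  labels <- xml2::xml_attr(gps, "label")
  ids <- xml2::xml_attr(gps, "id")
  labels[is.na(labels)] <- ids[is.na(labels)]
  model$genes <- union(model$genes, labels[!is.na(labels)])
  model
}

# rule AST -> nested fbc:and / fbc:or / fbc:geneProductRef elements
.rule_to_gpa <- function(parent, ast) {
  if (!is.null(ast$gene)) {
    xml2::xml_add_child(parent, "fbc:geneProductRef",
                        "fbc:geneProduct" = ast$gene, "fbc:label" = ast$gene)
  } else {
    node <- xml2::xml_add_child(parent, paste0("fbc:", ast$op))
    for (arg in ast$args) .rule_to_gpa(node, arg)
  }
}

# recursive fbc geneProductAssociation -> rule string
.gpa_to_rule <- function(node, ns) {
  nm <- xml2::xml_name(node)
  if (nm == "geneProductRef") {
    lab <- xml2::xml_attr(node, "label")
    if (is.na(lab)) lab <- xml2::xml_attr(node, "geneProduct")
    return(lab)
  }
  kids <- xml2::xml_children(node)
  parts <- vapply(kids, .gpa_to_rule, character(1), ns = ns)
  op <- if (nm == "and") " and " else " or "
  paste0("(", paste(parts, collapse = op), ")")
}

`%|na|%` <- function(a, b) {
  if (length(a) == 0 || is.na(a)) b else a
}
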