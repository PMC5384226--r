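# JSON model dialect (cobrapy-compatible). Documented in the package
# vignette; fixtures are hand-writable:
# {
#   "id": "toy",
#   "compartments": {"c": "cytosol", "e": "extracellular"},
#   "extracellular_tags": ["e"],
#   "metabolites": [{"id","name","compartment","formula"}],
#   "reactions":   [{"id","name","metabolites": {met: coef},
#                    "lower_bound","upper_bound","gene_reaction_rule",
#                    "objective_coefficient"}],
#   "genes": [{"id"}]
# }

#' Read a model from a file
#'
#' @param path file path.
#' @param format `"json"` or `"sbml"`; default guesses from the extension.
#' @return a validated `stoichiometric_model`.
#' @export
read_model <- function(path, format = c("auto", "json", "sbml")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("model file not found: ", path)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext %in% c("xml", "sbml")) "sbml" else "json"
  }
  model <- switch(format,
                  json = .read_model_json(path),
                  sbml = .read_model_sbml(path))
  validate_model(model)
  model
}

#' Write a model to a file
#'
#' The written file round-trips losslessly through [read_model()]: ids,
#' stoichiometry, bounds, gene rules and objective coefficients are
#' preserved.
#'
#' @param model a valid `stoichiometric_model`.
#' @param path output path.
#' @param format `"json"` or `"sbml"`; default guesses from the extension.
#' @export
write_model <- function(model, path, format = c("auto", "json", "sbml")) {
  format <- match.arg(format)
  validate_model(model)
  if (nrow(model$reactions) == 0)
    stop("refusing to write a model with no reactions")
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext %in% c("xml", "sbml")) "sbml" else "json"
  }
  switch(format,
         json = .write_model_json(model, path),
         sbml = .write_model_sbml(model, path))
  invisible(path)
}

.read_model_json <- function(path) {
  doc <- jsonlite::read_json(path)
  comp <- unlist(doc$compartments)
  if (is.null(comp)) comp <- c(c = "cytosol", e = "extracellular")
  exo <- unlist(doc$extracellular_tags)
  if (is.null(exo)) exo <- intersect(c("e", "extracellular"), names(comp))
  model <- new_model(id = doc$id %||% "model", compartments = comp,
                     extracellular_tags = exo)
  for (met in doc$metabolites) {
    if (is.null(met$id)) stop("json parse error: metabolite without id")
    model <- add_metabolite(model, met$id, met$name %||% met$id,
                            met$compartment %||% names(comp)[1L],
                            met$formula %||% NA_character_)
  }
  for (rxn in doc$reactions) {
    if (is.null(rxn$id)) stop("json parse error: reaction without id")
    st <- unlist(rxn$metabolites)
    rule <- rxn$gene_reaction_rule
    if (is.null(rule) || !nzchar(rule)) rule <- NA_character_
    model <- add_reaction(
      model, rxn$id, st,
      lower_bound = rxn$lower_bound %||% -DEFAULT_BOUND,
      upper_bound = rxn$upper_bound %||% DEFAULT_BOUND,
      gene_rule = rule,
      objective_coefficient = rxn$objective_coefficient %||% 0,
      name = rxn$name %||% rxn$id,
      exchange_annotated = isTRUE(rxn$exchange_annotated))
  }
  extra_genes <- vapply(doc$genes, function(g) g$id %||% "", character(1))
  model$genes <- union(model$genes, extra_genes[nzchar(extra_genes)])
  model
}

.write_model_json <- function(model, path) {
  mets <- lapply(seq_len(nrow(model$metabolites)), function(i) {
    m <- model$metabolites[i, ]
    out <- list(id = m$id, name = m$name, compartment = m$compartment)
    if (!is.na(m$formula)) out$formula <- m$formula
    out
  })
  rxns <- lapply(seq_len(nrow(model$reactions)), function(i) {
    r <- model$reactions[i, ]
    out <- list(id = r$id, name = r$name,
                metabolites = as.list(model$stoichiometry[[r$id]]),
                lower_bound = r$lower_bound, upper_bound = r$upper_bound,
                gene_reaction_rule = if (is.na(r$gene_rule)) "" else r$gene_rule,
                objective_coefficient = r$objective_coefficient)
    if (isTRUE(r$exchange_annotated)) out$exchange_annotated <- TRUE
    out
  })
  doc <- list(id = model$id,
              compartments = as.list(model$compartments),
              extracellular_tags = as.list(model$extracellular_tags),
              metabolites = mets,
              reactions = rxns,
              genes = lapply(model$genes, function(g) list(id = g)))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
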