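# Constraint-based model container: metabolites, reactions, stoichiometry,
# flux bounds, gene rules and an objective, with structural queries.

DEFAULT_BOUND <- 1000

#' Create an empty stoichiometric model
#'
#' The model is an S3 list holding an ordered metabolite table, an ordered
#' reaction table with flux bounds / gene rules / objective coefficients, and
#' per-reaction stoichiometry maps. The implied stoichiometric matrix S has
#' one row per metabolite and one column per reaction.
#'
#' @param id model identifier.
#' @param compartments named character vector of compartment tags
#'   (names = tags, values = display names). Tags used by metabolites must be
#'   declared here.
#' @param extracellular_tags compartment tags treated as extracellular, used
#'   by the exchange/efflux machinery.
#' @return an object of class `stoichiometric_model`.
#' @export
new_model <- function(id = "model",
                      compartments = c(c = "cytosol", e = "extracellular"),
                      extracellular_tags = "e") {
  structure(list(
    id = id,
    metabolites = data.frame(id = character(), name = character(),
                             compartment = character(), formula = character(),
                             stringsAsFactors = FALSE),
    reactions = data.frame(id = character(), name = character(),
                           lower_bound = numeric(), upper_bound = numeric(),
                           gene_rule = character(),
                           objective_coefficient = numeric(),
                           exchange_annotated = logical(),
                           stringsAsFactors = FALSE),
    stoichiometry = list(),        # reaction id -> named numeric vector
    genes = character(),
    compartments = compartments,
    extracellular_tags = extracellular_tags,
    annotations = list()
  ), class = "stoichiometric_model")
}

#' Add a metabolite to a model
#'
#' @param model a `stoichiometric_model`.
#' @param id unique metabolite id.
#' @param name display name.
#' @param compartment compartment tag; must be declared in the model.
#' @param formula optional chemical formula.
#' @return the updated model.
#' @export
add_metabolite <- function(model, id, name = id, compartment = "c",
                           formula = NA_character_) {
  stopifnot(inherits(model, "stoichiometric_model"))
  if (id %in% model$metabolites$id)
    stop("duplicate metabolite id: ", id)
  if (!compartment %in% names(model$compartments))
    stop("undeclared compartment tag '", compartment, "' for metabolite ", id)
  model$metabolites <- rbind(model$metabolites, data.frame(
    id = id, name = name, compartment = compartment, formula = formula,
    stringsAsFactors = FALSE))
  model
}

#' Add a reaction to a model
#'
#' @inheritParams add_metabolite
#' @param stoichiometry named numeric vector: metabolite id -> signed
#'   coefficient (negative = consumed). Must be non-empty and reference only
#'   metabolites already in the model.
#' @param lower_bound,upper_bound flux bounds; `-Inf`/`Inf` are replaced by
#'   the `+-1000` proxy.
#' @param gene_rule optional boolean gene rule string using `and`, `or` and
#'   parentheses, e.g. `"(g1 and g2) or g3"`.
#' @param objective_coefficient weight in the model objective.
#' @param exchange_annotated mark the reaction explicitly as an exchange.
#' @export
add_reaction <- function(model, id, stoichiometry,
                         lower_bound = -DEFAULT_BOUND,
                         upper_bound = DEFAULT_BOUND,
                         gene_rule = NA_character_,
                         objective_coefficient = 0,
                         name = id,
                         exchange_annotated = FALSE) {
  stopifnot(inherits(model, "stoichiometric_model"))
  if (id %in% model$reactions$id)
    stop("duplicate reaction id: ", id)
  if (length(stoichiometry) == 0)
    stop("reaction ", id, " has empty stoichiometry")
  if (is.null(names(stoichiometry)) || any(!nzchar(names(stoichiometry))))
    stop("stoichiometry of ", id, " must be a named numeric vector")
  missing_mets <- setdiff(names(stoichiometry), model$metabolites$id)
  if (length(missing_mets) > 0)
    stop("reaction ", id, " references undeclared metabolite(s): ",
         paste(missing_mets, collapse = ", "))
  lower_bound <- .clamp_bound(lower_bound)
  upper_bound <- .clamp_bound(upper_bound)
  if (lower_bound > upper_bound)
    stop("reaction ", id, ": lower bound exceeds upper bound")
  model$reactions <- rbind(model$reactions, data.frame(
    id = id, name = name, lower_bound = lower_bound,
    upper_bound = upper_bound, gene_rule = gene_rule,
    objective_coefficient = objective_coefficient,
    exchange_annotated = exchange_annotated, stringsAsFactors = FALSE))
  model$stoichiometry[[id]] <- stoichiometry
  if (!is.na(gene_rule))
    model$genes <- union(model$genes, gene_rule_ids(gene_rule))
  model
}

.clamp_bound <- function(x) {
  if (!is.finite(x)) sign(x) * DEFAULT_BOUND else x
}

#' Validate a stoichiometric model
#'
#' Checks the structural invariants: unique ids, declared compartments,
#' non-empty stoichiometries referencing existing metabolites, ordered
#' bounds, and gene rules whose genes are in the model's gene set.
#'
#' @param model a `stoichiometric_model`.
#' @return invisibly `TRUE`; otherwise an error describing the violation.
#' @export
validate_model <- function(model) {
  stopifnot(inherits(model, "stoichiometric_model"))
  if (anyDuplicated(model$metabolites$id))
    stop("duplicate metabolite ids")
  if (anyDuplicated(model$reactions$id))
    stop("duplicate reaction ids")
  if (!all(model$metabolites$compartment %in% names(model$compartments)))
    stop("metabolite with undeclared compartment tag")
  if (!setequal(names(model$stoichiometry), model$reactions$id))
    stop("stoichiometry map out of step with reaction table")
  for (rid in model$reactions$id) {
    st <- model$stoichiometry[[rid]]
    if (length(st) == 0) stop("reaction ", rid, " has empty stoichiometry")
    if (!all(names(st) %in% model$metabolites$id))
      stop("reaction ", rid, " references unknown metabolites")
  }
  if (any(model$reactions$lower_bound > model$reactions$upper_bound))
    stop("reaction with lower bound above upper bound")
  rules <- model$reactions$gene_rule
  rule_genes <- unique(unlist(lapply(rules[!is.na(rules)], gene_rule_ids)))
  if (!all(rule_genes %in% model$genes))
    stop("gene rule references gene outside the model gene set")
  invisible(TRUE)
}

#' Assemble the stoichiometric matrix S
#'
#' @param model a `stoichiometric_model`.
#' @return dense numeric matrix, metabolites (rows) x reactions (columns),
#'   with dimnames set to the ids.
#' @export
s_matrix <- function(model) {
  m <- nrow(model$metabolites)
  n <- nrow(model$reactions)
  S <- matrix(0, m, n,
              dimnames = list(model$metabolites$id, model$reactions$id))
  for (rid in model$reactions$id) {
    st <- model$stoichiometry[[rid]]
    S[names(st), rid] <- st
  }
  S
}

#' Identify exchange reactions
#'
#' A reaction is an exchange iff its stoichiometry involves exactly one
#' metabolite (the boundary convention) or it is explicitly annotated as an
#' exchange. Sign convention: for an exchange written `{met: -1}`, positive
#' flux secretes the metabolite out of the system and negative flux takes it
#' up.
#'
#' @param model a `stoichiometric_model`.
#' @return character vector of reaction ids.
#' @export
find_exchange_reactions <- function(model) {
  single <- vapply(model$stoichiometry[model$reactions$id],
                   function(st) length(st) == 1L, logical(1))
  model$reactions$id[single | model$reactions$exchange_annotated]
}

#' Remove reactions from a model
#'
#' @param model a `stoichiometric_model`.
#' @param ids reaction ids to drop.
#' @export
remove_reactions <- function(model, ids) {
  keep <- !model$reactions$id %in% ids
  model$reactions <- model$reactions[keep, , drop = FALSE]
  rownames(model$reactions) <- NULL
  model$stoichiometry <- model$stoichiometry[model$reactions$id]
  model
}

#' Set flux bounds of a reaction
#'
#' @param model a `stoichiometric_model`.
#' @param id reaction id.
#' @param lower_bound,upper_bound new bounds.
#' @export
set_bounds <- function(model, id, lower_bound, upper_bound) {
  i <- match(id, model$reactions$id)
  if (is.na(i)) stop("unknown reaction: ", id)
  model$reactions$lower_bound[i] <- .clamp_bound(lower_bound)
  model$reactions$upper_bound[i] <- .clamp_bound(upper_bound)
  if (model$reactions$lower_bound[i] > model$reactions$upper_bound[i])
    stop("reaction ", id, ": lower bound exceeds upper bound")
  model
}

#' Which metabolites are extracellular?
#'
#' @param model a `stoichiometric_model`.
#' @param met_ids metabolite ids (default: all).
#' @return named logical vector.
#' @export
is_extracellular <- function(model, met_ids = model$metabolites$id) {
  comp <- model$metabolites$compartment[match(met_ids, model$metabolites$id)]
  stats::setNames(comp %in% model$extracellular_tags, met_ids)
}

#' Objective reaction of a model
#'
#' @param model a `stoichiometric_model`.
#' @return id of the reaction with nonzero objective coefficient, or `NA`.
#' @export
objective_reaction <- function(model) {
  hit <- model$reactions$id[model$reactions$objective_coefficient != 0]
  if (length(hit) == 0) NA_character_ else hit[[1L]]
}

#' @export
print.stoichiometric_model <- function(x, ...) {
  cat(sprintf("stoichiometric_model '%s': %d metabolites, %d reactions, %d genes\n",
              x$id, nrow(x$metabolites), nrow(x$reactions), length(x$genes)))
  invisible(x)
}

#' Structural equality of two models
#'
#' Compares ids, stoichiometries, bounds, gene rules and objective
#' coefficients, ignoring row order differences inside stoichiometry maps.
#'
#' @param a,b models to compare.
#' @param tol numeric tolerance on coefficients and bounds.
#' @return `TRUE` or `FALSE`.
#' @export
models_equal <- function(a, b, tol = 1e-9) {
  if (!identical(a$metabolites$id, b$metabolites$id)) return(FALSE)
  if (!identical(a$metabolites$compartment, b$metabolites$compartment)) return(FALSE)
  if (!identical(a$reactions$id, b$reactions$id)) return(FALSE)
  ra <- a$reactions; rb <- b$reactions
  if (max(abs(ra$lower_bound - rb$lower_bound),
          abs(ra$upper_bound - rb$upper_bound),
          abs(ra$objective_coefficient - rb$objective_coefficient)) > tol)
    return(FALSE)
  ga <- ifelse(is.na(ra$gene_rule), "", ra$gene_rule)
  gb <- ifelse(is.na(rb$gene_rule), "", rb$gene_rule)
  if (!identical(ga, gb)) return(FALSE)
  for (rid in ra$id) {
    sa <- a$stoichiometry[[rid]]; sb <- b$stoichiometry[[rid]]
    if (!setequal(names(sa), names(sb))) return(FALSE)
    if (max(abs(sa - sb[names(sa)])) > tol) return(FALSE)
  }
  TRUE
}

# --- gene rules -------------------------------------------------------------

#' Gene ids referenced by a boolean gene rule
#'
#' @param rule rule string over gene ids with `and`, `or`, parentheses.
#' @return character vector of gene ids.
#' @export
gene_rule_ids <- function(rule) {
  if (is.na(rule) || !nzchar(trimws(rule))) return(character())
  toks <- .gene_rule_tokens(rule)
  unique(toks[!toks %in% c("and", "or", "(", ")")])
}

.gene_rule_tokens <- function(rule) {
  rule <- gsub("\\(", " ( ", rule)
  rule <- gsub("\\)", " ) ", rule)
  toks <- strsplit(trimws(rule), "\\s+")[[1L]]
  toks[nzchar(toks)]
}

#' Parse a gene rule into a boolean syntax tree
#'
#' Grammar: `expr := term ("or" term)*`, `term := factor ("and" factor)*`,
#' `factor := gene | "(" expr ")"`.
#'
#' @param rule rule string.
#' @return nested list: either `list(gene = id)` or
#'   `list(op = "and"|"or", args = list(...))`.
#' @export
parse_gene_rule <- function(rule) {
  toks <- .gene_rule_tokens(rule)
  pos <- 1L
  peek <- function() if (pos <= length(toks)) toks[[pos]] else NULL
  take <- function() { tk <- toks[[pos]]; pos <<- pos + 1L; tk }
  parse_expr <- function() {
    args <- list(parse_term())
    while (identical(peek(), "or")) { take(); args <- c(args, list(parse_term())) }
    if (length(args) == 1L) args[[1L]] else list(op = "or", args = args)
  }
  parse_term <- function() {
    args <- list(parse_factor())
    while (identical(peek(), "and")) { take(); args <- c(args, list(parse_factor())) }
    if (length(args) == 1L) args[[1L]] else list(op = "and", args = args)
  }
  parse_factor <- function() {
    tk <- peek()
    if (is.null(tk)) stop("malformed gene rule: ", rule)
    if (tk == "(") {
      take()
      inner <- parse_expr()
      if (!identical(peek(), ")")) stop("unbalanced parentheses in gene rule: ", rule)
      take()
      inner
    } else if (tk %in% c(")", "and", "or")) {
      stop("malformed gene rule: ", rule)
    } else {
      list(gene = take())
    }
  }
  out <- parse_expr()
  if (pos <= length(toks)) stop("trailing tokens in gene rule: ", rule)
  out
}

#' Evaluate a gene rule under a knockout pattern
#'
#' @param rule rule string (`NA` means no gene dependence and evaluates to
#'   `TRUE`).
#' @param knocked_out character vector of gene ids set to `FALSE`; all other
#'   genes are `TRUE`.
#' @return logical scalar.
#' @export
eval_gene_rule <- function(rule, knocked_out = character()) {
  if (is.na(rule) || !nzchar(trimws(rule))) return(TRUE)
  toks <- .gene_rule_tokens(rule)
  expr <- vapply(toks, function(tk) {
    switch(tk,
           "and" = "&&", "or" = "||", "(" = "(", ")" = ")",
           if (grepl("^[A-Za-z0-9_.:-]+$", tk)) {
             if (tk %in% knocked_out) "FALSE" else "TRUE"
           } else stop("invalid token in gene rule: ", tk))
  }, character(1))
  eval(parse(text = paste(expr, collapse = " ")), envir = baseenv())
}
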