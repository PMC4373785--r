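#' Create a metabolite
#'
#' Metabolites are the nodes of a metabolic network. A boundary metabolite
#' (`boundary = TRUE`) represents a species outside the balanced system --
#' for instance a blood metabolite exchanged with the tissue, or an
#' intracellular cofactor whose turnover is handled by reactions outside the
#' model -- and is excluded from the steady-state mass balance.
#'
#' @param id Unique metabolite identifier (e.g. `"M_glc_DASH_D_c"`).
#' @param name Human-readable name. Defaults to `id`.
#' @param compartment Compartment identifier, e.g. `"c"`, `"m"`, `"e"`.
#' @param boundary Logical; is the species external (not balanced to zero)?
#' @return A list of class `"metabolite"`.
#' @export
metabolite <- function(id, name = id, compartment = "c", boundary = FALSE) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  if (!is.character(compartment) || length(compartment) != 1L || !nzchar(compartment))
    stop("metabolite ", id, ": compartment must be a non-empty string")
  structure(list(id = id, name = name, compartment = compartment,
                 boundary = isTRUE(boundary)),
            class = "metabolite")
}

#' Create a reaction
#'
#' @param id Unique reaction identifier (e.g. `"R_HEX1"`).
#' @param stoichiometry Named numeric vector mapping metabolite ids to signed
#'   coefficients; negative coefficients are consumed, positive produced.
#' @param name Human-readable name.
#' @param reversible Logical; can the reaction carry negative flux?
#' @param gene_association Optional boolean gene association string, e.g.
#'   `"(g1 and g2) or g3"`. `NA` when no genes are linked.
#' @param pathway Optional pathway label used for sub-network queries.
#' @return A list of class `"reaction"`.
#' @export
reaction <- function(id, stoichiometry, name = id, reversible = TRUE,
                     gene_association = NA_character_, pathway = NA_character_) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  if (length(stoichiometry) == 0L)
    stop("reaction ", id, ": stoichiometry must be non-empty")
  if (is.null(names(stoichiometry)) || any(!nzchar(names(stoichiometry))))
    stop("reaction ", id, ": stoichiometry must be a named numeric vector")
  ## duplicate species references are summed into one net coefficient
  stoichiometry <- tapply(as.numeric(stoichiometry), names(stoichiometry), sum)
  stoichiometry <- stoichiometry[stoichiometry != 0 | duplicated(names(stoichiometry))]
  structure(list(id = id, name = name,
                 stoichiometry = c(stoichiometry),
                 reversible = isTRUE(reversible),
                 gene_association = as.character(gene_association),
                 pathway = as.character(pathway)),
            class = "reaction")
}

#' Create a metabolic model
#'
#' A `metabolic_model` holds an ordered list of reactions over a set of
#' metabolites. The reaction order is stable and defines the component order
#' of every flux vector derived from the model.
#'
#' @param metabolites List of [metabolite()] objects.
#' @param reactions Ordered list of [reaction()] objects.
#' @param id Model identifier.
#' @param name Model name.
#' @param annotations Optional named list mapping pathway names to character
#'   vectors of reaction ids. When omitted it is derived from the reactions'
#'   `pathway` fields.
#' @return An object of class `"metabolic_model"`.
#' @export
metabolic_model <- function(metabolites = list(), reactions = list(),
                            id = "model", name = id, annotations = NULL) {
  met_ids <- vapply(metabolites, `[[`, character(1), "id")
  rxn_ids <- vapply(reactions, `[[`, character(1), "id")
  if (anyDuplicated(met_ids)) stop("duplicate metabolite ids: ",
                                   paste(unique(met_ids[duplicated(met_ids)]), collapse = ", "))
  if (anyDuplicated(rxn_ids)) stop("duplicate reaction ids: ",
                                   paste(unique(rxn_ids[duplicated(rxn_ids)]), collapse = ", "))
  for (r in reactions) {
    missing <- setdiff(names(r$stoichiometry), met_ids)
    if (length(missing))
      stop("reaction ", r$id, " references undeclared metabolites: ",
           paste(missing, collapse = ", "))
  }
  names(metabolites) <- met_ids
  names(reactions) <- rxn_ids
  if (is.null(annotations)) {
    pw <- vapply(reactions, `[[`, character(1), "pathway")
    keep <- !is.na(pw) & nzchar(pw)
    annotations <- split(rxn_ids[keep], pw[keep])
  }
  structure(list(id = id, name = name, metabolites = metabolites,
                 reactions = reactions, annotations = annotations),
            class = "metabolic_model")
}

#' @export
print.metabolic_model <- function(x, ...) {
  nb <- sum(vapply(x$metabolites, `[[`, logical(1), "boundary"))
  cat("Metabolic model:", x$id, "\n")
  cat(" ", length(x$reactions), "reactions,", length(x$metabolites),
      "metabolites (", nb, "boundary )\n")
  if (length(x$annotations))
    cat("  pathways:", paste(names(x$annotations), collapse = ", "), "\n")
  invisible(x)
}

reaction_ids <- function(model) names(model$reactions)
metabolite_ids <- function(model) names(model$metabolites)

boundary_ids <- function(model) {
  ids <- metabolite_ids(model)
  ids[vapply(model$metabolites, `[[`, logical(1), "boundary")]
}

#' Stoichiometric matrix of the internal metabolites
#'
#' Builds the matrix `E` whose rows are the internal (non-boundary)
#' metabolites and whose columns are the reactions in model order; entry
#' `(i, j)` is the signed coefficient of metabolite `i` in reaction `j`.
#' Boundary metabolites are excluded because they are not balanced to zero
#' at steady state.
#'
#' @param model A [metabolic_model()].
#' @return A numeric matrix with metabolite ids as row names and reaction
#'   ids as column names.
#' @export
stoichiometric_matrix <- function(model) {
  stopifnot(inherits(model, "metabolic_model"))
  internal <- setdiff(metabolite_ids(model), boundary_ids(model))
  E <- matrix(0, nrow = length(internal), ncol = length(model$reactions),
              dimnames = list(internal, reaction_ids(model)))
  for (j in seq_along(model$reactions)) {
    st <- model$reactions[[j]]$stoichiometry
    st <- st[names(st) %in% internal]
    if (length(st)) E[names(st), j] <- st
  }
  E
}

#' Select a sub-network by reaction, pathway or gene
#'
#' Returns the union of reactions matched by any selector, together with
#' only the metabolites those reactions reference. Gene selection matches
#' reactions whose gene association mentions the gene identifier.
#'
#' @param model A [metabolic_model()].
#' @param reaction_ids Character vector of reaction ids, or `NULL`.
#' @param pathways Character vector of pathway names, or `NULL`.
#' @param genes Character vector of gene ids, or `NULL`.
#' @return A new [metabolic_model()] restricted to the selection. Selectors
#'   matching nothing yield an empty model with a warning.
#' @export
select_submodel <- function(model, reaction_ids = NULL, pathways = NULL,
                            genes = NULL) {
  stopifnot(inherits(model, "metabolic_model"))
  if (is.null(reaction_ids) && is.null(pathways) && is.null(genes))
    stop("provide at least one selector (reaction_ids, pathways or genes)")
  keep <- character(0)
  if (!is.null(reaction_ids)) {
    unknown <- setdiff(reaction_ids, names(model$reactions))
    if (length(unknown))
      warning("unknown reaction ids ignored: ", paste(unknown, collapse = ", "))
    keep <- c(keep, intersect(reaction_ids, names(model$reactions)))
  }
  if (!is.null(pathways))
    keep <- c(keep, unlist(model$annotations[intersect(pathways, names(model$annotations))],
                           use.names = FALSE))
  if (!is.null(genes)) {
    assoc <- extract_gene_associations(model)
    hit <- vapply(assoc, function(g) any(genes %in% g), logical(1))
    keep <- c(keep, names(assoc)[hit])
  }
  keep <- intersect(names(model$reactions), unique(keep))  # model order
  if (!length(keep)) warning("selection matched no reactions; returning an empty model")
  rxns <- model$reactions[keep]
  used <- unique(unlist(lapply(rxns, function(r) names(r$stoichiometry)), use.names = FALSE))
  metabolic_model(metabolites = unname(model$metabolites[intersect(metabolite_ids(model), used)]),
                  reactions = unname(rxns), id = model$id, name = model$name)
}

#' Remove reactions from a model
#'
#' Drops the listed reactions; metabolites that are no longer referenced by
#' any remaining reaction are removed as well.
#'
#' @param model A [metabolic_model()].
#' @param reaction_ids Character vector of reaction ids to remove. Unknown
#'   ids are an error.
#' @return A new [metabolic_model()].
#' @export
remove_reactions <- function(model, reaction_ids) {
  stopifnot(inherits(model, "metabolic_model"))
  unknown <- setdiff(reaction_ids, names(model$reactions))
  if (length(unknown))
    stop("unknown reaction ids: ", paste(unknown, collapse = ", "))
  rxns <- model$reactions[setdiff(names(model$reactions), reaction_ids)]
  used <- unique(unlist(lapply(rxns, function(r) names(r$stoichiometry)), use.names = FALSE))
  metabolic_model(metabolites = unname(model$metabolites[intersect(metabolite_ids(model), used)]),
                  reactions = unname(rxns), id = model$id, name = model$name)
}

#' Extract gene-reaction associations
#'
#' Flattens each reaction's boolean gene association to the set of mentioned
#' gene identifiers. The original expression string is retained as an
#' attribute so policy-aware aggregation (AND-complexes vs OR-isoforms) can
#' recover the structure.
#'
#' @param model A [metabolic_model()].
#' @return A named list mapping reaction id to a character vector of gene
#'   ids, with attribute `"expression"` holding the original association
#'   strings. Reactions without an association are absent.
#' @export
extract_gene_associations <- function(model) {
  stopifnot(inherits(model, "metabolic_model"))
  out <- list(); expr <- character(0)
  for (r in model$reactions) {
    ga <- r$gene_association
    if (is.na(ga) || !nzchar(trimws(ga))) next
    out[[r$id]] <- parse_gene_association(ga, r$id)
    expr[r$id] <- ga
  }
  attr(out, "expression") <- expr
  out
}

## Tokenize a boolean gene-association string ("(g1 and g2) or g3",
## case-insensitive keywords, BiGG/COBRA note syntax) into its gene set.
parse_gene_association <- function(x, reaction_id = "?") {
  x <- sub("^\\s*GENE_?ASSOCIATION\\s*:\\s*", "", x, ignore.case = TRUE)
  toks <- regmatches(x, gregexpr("[^()\\s]+", x, perl = TRUE))[[1]]
  bad <- grepl("[()]", gsub("[^()]", "", x)) &&
    nchar(gsub("[^(]", "", x)) != nchar(gsub("[^)]", "", x))
  if (bad) stop("malformed gene association in reaction ", reaction_id, ": ", x)
  genes <- toks[!tolower(toks) %in% c("and", "or")]
  if (any(grepl("^(and|or)$", tolower(genes))))
    stop("malformed gene association in reaction ", reaction_id, ": ", x)
  unique(genes)
}

## Structured parse of an association string into nested OR-of-AND lists.
## Returns a list with elements $or -> list of character vectors (AND groups).
## Used by the structured aggregation policy.
parse_gene_association_structure <- function(x) {
  x <- sub("^\\s*GENE_?ASSOCIATION\\s*:\\s*", "", x, ignore.case = TRUE)
  x <- gsub("\\s+", " ", trimws(x))
  if (!nzchar(x)) return(list(or = list()))
  # recursive descent on parentheses
  parse_expr <- function(s) {
    s <- trimws(s)
    depth <- 0L; or_splits <- integer(0); and_splits <- integer(0)
    i <- 1L; n <- nchar(s)
    while (i <= n) {
      ch <- substr(s, i, i)
      if (ch == "(") depth <- depth + 1L
      if (ch == ")") depth <- depth - 1L
      if (depth == 0L) {
        if (tolower(substr(s, i, i + 3)) == " or " ) or_splits <- c(or_splits, i)
        if (tolower(substr(s, i, i + 4)) == " and ") and_splits <- c(and_splits, i)
      }
      i <- i + 1L
    }
    if (length(or_splits)) {
      parts <- split_at(s, or_splits, 4L)
      return(unlist(lapply(parts, function(p) parse_expr(p)), recursive = FALSE))
    }
    if (length(and_splits)) {
      parts <- split_at(s, and_splits, 5L)
      groups <- lapply(parts, function(p) parse_expr(p))
      return(list(unique(unlist(groups))))
    }
    if (startsWith(s, "(") && endsWith(s, ")"))
      return(parse_expr(substr(s, 2L, nchar(s) - 1L)))
    list(s)
  }
  split_at <- function(s, pos, width) {
    starts <- c(1L, pos + width)
    ends <- c(pos - 1L, nchar(s))
    mapply(function(a, b) substr(s, a, b), starts, ends, USE.NAMES = FALSE)
  }
  list(or = parse_expr(x))
}

#' Export a stoichiometric matrix as delimited text
#'
#' Writes the matrix with a header row of reaction ids and the metabolite
#' ids in the first column.
#'
#' @param model A [metabolic_model()].
#' @param path Output file path.
#' @param sep Field separator, default tab.
#' @return The path, invisibly.
#' @export
write_stoichiometry <- function(model, path, sep = "\t") {
  E <- stoichiometric_matrix(model)
  df <- data.frame(metabolite = rownames(E), E, check.names = FALSE)
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}
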