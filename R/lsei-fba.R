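#' Create a gene fold-change table
#'
#' Holds linear fold changes (disease / control expression ratios) per gene.
#' Log2 input is converted to linear scale (`2^value`), because scaling a
#' reference flux by a fold change is only meaningful in linear space.
#'
#' @param x Named numeric vector of fold changes.
#' @param scale `"linear"` or `"log2"`, the scale of `x`.
#' @return An object of class `"fold_change_table"`: a named numeric vector
#'   of linear fold changes.
#' @export
fold_change_table <- function(x, scale = c("linear", "log2")) {
  scale <- match.arg(scale)
  if (is.null(names(x)) || any(!nzchar(names(x))))
    stop("fold changes must be a named numeric vector (gene ids)")
  v <- if (scale == "log2") 2^as.numeric(x) else as.numeric(x)
  names(v) <- names(x)
  if (any(!is.finite(v)) || any(v <= 0))
    stop("all fold changes must be positive and finite on the linear scale")
  structure(v, class = "fold_change_table")
}

#' Read a fold-change table from CSV
#'
#' Expects two columns, `gene_id` and `fold_change`. The scale can be given
#' explicitly or via a `# scale: log2` comment in the header.
#'
#' @param path CSV file path.
#' @param scale `"linear"` or `"log2"`.
#' @return A [fold_change_table()].
#' @export
read_fold_changes <- function(path, scale = c("linear", "log2")) {
  first <- readLines(path, n = 1L)
  if (grepl("^#", first)) {
    if (grepl("log2", first, ignore.case = TRUE)) scale <- "log2"
    df <- utils::read.csv(path, skip = 1L, stringsAsFactors = FALSE)
  } else df <- utils::read.csv(path, stringsAsFactors = FALSE)
  scale <- match.arg(scale)
  fold_change_table(stats::setNames(df[[2]], df[[1]]), scale = scale)
}

#' Aggregate gene fold changes onto reactions
#'
#' Maps per-gene fold changes to per-reaction fold changes through the
#' gene-reaction associations. When several genes are linked to one
#' reaction, the chosen policy combines their (linear) fold changes;
#' the default is the arithmetic mean. Genes absent from the table are
#' skipped within a reaction; reactions whose genes are all absent are
#' omitted from the result.
#'
#' With `structured = TRUE`, the boolean structure of the association is
#' honored instead of flattening: the minimum is taken over genes of an
#' AND-complex and the chosen policy over OR-isoforms.
#'
#' @param associations Named list of gene-id vectors per reaction, as
#'   returned by [extract_gene_associations()].
#' @param fc A [fold_change_table()].
#' @param policy `"average"`, `"minimum"` or `"geometric_mean"`.
#' @param structured Honor AND/OR structure (default `FALSE`, flattening).
#' @return Named numeric vector of per-reaction fold changes.
#' @export
aggregate_fold_changes <- function(associations, fc,
                                   policy = c("average", "minimum", "geometric_mean"),
                                   structured = FALSE) {
  policy <- match.arg(policy)
  agg <- switch(policy,
                average = mean,
                minimum = min,
                geometric_mean = function(v) exp(mean(log(v))))
  out <- numeric(0)
  exprs <- attr(associations, "expression")
  for (rid in names(associations)) {
    if (structured && !is.null(exprs) && !is.na(exprs[rid])) {
      groups <- parse_gene_association_structure(exprs[[rid]])$or
      vals <- vapply(groups, function(gset) {
        present <- intersect(gset, names(fc))
        if (!length(present)) NA_real_ else min(unclass(fc)[present])
      }, numeric(1))
      vals <- vals[!is.na(vals)]
    } else {
      present <- intersect(associations[[rid]], names(fc))
      vals <- unclass(fc)[present]
    }
    if (length(vals)) out[rid] <- agg(vals)
  }
  if (!length(out))
    warning("no reaction shares a gene with the fold-change table")
  out
}

#' Expression-scaled rough flux estimate
#'
#' Multiplies each reference flux by the fold change of the genes mapped to
#' that reaction. The sign of the reference flux is preserved: the fold
#' change scales the signed value, so a release flux (negative) stays a
#' release flux.
#'
#' @param reference_flux Named numeric vector (or `flux_vector`) of
#'   reference fluxes, mmol/min.
#' @param reaction_fc Named numeric vector of per-reaction fold changes.
#' @return Named numeric vector of target fluxes for the keyed reactions.
#' @export
rough_estimate <- function(reference_flux, reaction_fc) {
  if (inherits(reference_flux, "flux_vector")) reference_flux <- reference_flux$values
  if (!length(reaction_fc)) return(stats::setNames(numeric(0), character(0)))
  missing <- setdiff(names(reaction_fc), names(reference_flux))
  if (length(missing))
    stop("reference flux undefined for reaction(s): ",
         paste(missing, collapse = ", "))
  reference_flux[names(reaction_fc)] * reaction_fc
}

#' Predict a disease flux distribution from gene-expression fold changes
#'
#' Lsei-FBA: (1) aggregate gene fold changes onto reactions, (2) scale the
#' reference (healthy) flux of each mapped reaction by its fold change to
#' obtain a rough target estimate, (3) project the targets onto the
#' steady-state and irreversibility constraint set by minimizing the sum of
#' squared deviations between the final fluxes and the targets.
#'
#' No exchange flux is fixed in the disease problem: uptake and release
#' rates under the disease condition are outputs of the prediction, not
#' inputs. Reactions without gene data (including most transport reactions)
#' are not constrained by expression and are determined by mass balance and
#' irreversibility alone.
#'
#' @param model A [metabolic_model()].
#' @param reference_flux Named numeric vector or `flux_vector` of reference
#'   fluxes satisfying the model constraints (e.g. an FBA solution).
#' @param fc A [fold_change_table()].
#' @param policy Aggregation policy, see [aggregate_fold_changes()].
#' @param structured Honor AND/OR association structure (default `FALSE`).
#' @return An object of class `c("lsei_fba_fit", "flux_vector")` with
#'   elements `values` (predicted fluxes), `report` (per-reaction data
#'   frame: reference, fold change, target, final, deviation) and
#'   `residual_ss`.
#' @export
lsei_fba <- function(model, reference_flux, fc,
                     policy = c("average", "minimum", "geometric_mean"),
                     structured = FALSE) {
  stopifnot(inherits(model, "metabolic_model"))
  policy <- match.arg(policy)
  if (inherits(reference_flux, "flux_vector")) reference_flux <- reference_flux$values
  labels <- reaction_ids(model)
  if (!all(labels %in% names(reference_flux)))
    stop("reference_flux must cover every reaction of the model")
  reference_flux <- reference_flux[labels]

  assoc <- extract_gene_associations(model)
  rfc <- aggregate_fold_changes(assoc, fc, policy = policy, structured = structured)
  targets <- rough_estimate(reference_flux, rfc)

  lim <- build_lim(model)  # no fixed exchange fluxes in the disease problem
  n <- length(labels)
  A <- matrix(0, length(targets), n, dimnames = list(names(targets), labels))
  A[cbind(seq_along(targets), match(names(targets), labels))] <- 1

  sol <- solve_lsei(lim$E, lim$f, lim$G, lim$h, A, as.numeric(targets))
  values <- stats::setNames(sol$x, labels)
  report <- data.frame(
    reaction = names(targets),
    reference = unname(reference_flux[names(targets)]),
    fold_change = unname(rfc[names(targets)]),
    target = unname(targets),
    final = unname(values[names(targets)]),
    deviation = unname(values[names(targets)] - targets),
    row.names = NULL)
  structure(list(values = values, report = report,
                 residual_ss = sol$residual_ss,
                 reference = reference_flux, policy = policy),
            class = c("lsei_fba_fit", "flux_vector"))
}

#' @export
print.lsei_fba_fit <- function(x, ...) {
  cat("Lsei-FBA prediction (", length(x$values), " fluxes )\n", sep = "")
  cat("  expression-constrained reactions:", nrow(x$report), "\n")
  cat("  attained sum of squared deviations:",
      format(x$residual_ss, digits = 6), "\n")
  invisible(x)
}

#' @export
coef.lsei_fba_fit <- function(object, ...) object$values

#' @export
residuals.lsei_fba_fit <- function(object, ...) {
  stats::setNames(object$report$deviation, object$report$reaction)
}

#' @export
fitted.lsei_fba_fit <- function(object, ...) {
  stats::setNames(object$report$final, object$report$reaction)
}

#' @export
summary.lsei_fba_fit <- function(object, ...) object$report
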