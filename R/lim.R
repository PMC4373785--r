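#' Assemble a linear inverse model from a metabolic model
#'
#' Builds the constraint system of flux balance analysis:
#' \deqn{E x = f \quad (\mathrm{steady\ state\ and\ fixed\ fluxes})}
#' \deqn{G x \ge h \quad (\mathrm{irreversibility})}
#' \deqn{A x = b + \epsilon \quad (\mathrm{measured\ fluxes,\ error\ sd})}
#' The first rows of `E` are the stoichiometric balances of the internal
#' metabolites with `f = 0`; one equality row is appended per fixed flux.
#' `G` holds one row per irreversible reaction (a single `+1` entry, `h = 0`).
#' Reversible reactions carry no bounds unless fixed. Measured fluxes with
#' standard deviations populate the approximate-equality block `A, b, sd`
#' used by the ensemble sampler.
#'
#' @param model A [metabolic_model()].
#' @param fixed_fluxes Named numeric vector of exactly known fluxes
#'   (mmol/min), fixed via appended `E` rows.
#' @param measured_fluxes Optional data frame or named list with elements
#'   `value` and `sd` per reaction id (see examples), entered as approximate
#'   equalities.
#' @return An object of class `"lim"` with fields `E`, `f`, `G`, `h`, `A`,
#'   `b`, `sd` and `reaction_labels`.
#' @examples
#' toy <- metabolic_model(
#'   metabolites = list(metabolite("A_b", boundary = TRUE), metabolite("A"),
#'                      metabolite("B"), metabolite("B_b", boundary = TRUE)),
#'   reactions = list(
#'     reaction("R1", c(A_b = -1, A = 1), reversible = FALSE),
#'     reaction("R2", c(A = -1, B = 1), reversible = FALSE),
#'     reaction("R3", c(B = -1, B_b = 1), reversible = FALSE)))
#' lim <- build_lim(toy, fixed_fluxes = c(R1 = 1))
#' @export
build_lim <- function(model, fixed_fluxes = NULL, measured_fluxes = NULL) {
  stopifnot(inherits(model, "metabolic_model"))
  E <- stoichiometric_matrix(model)
  f <- rep(0, nrow(E))
  labels <- reaction_ids(model)
  n <- length(labels)

  if (length(fixed_fluxes)) {
    unknown <- setdiff(names(fixed_fluxes), labels)
    if (length(unknown))
      stop("fixed flux on unknown reaction(s): ", paste(unknown, collapse = ", "))
    for (id in names(fixed_fluxes)) {
      row <- numeric(n); row[match(id, labels)] <- 1
      E <- rbind(E, row)
      rownames(E)[nrow(E)] <- paste0("fix_", id)
      f <- c(f, as.numeric(fixed_fluxes[[id]]))
    }
  }

  irrev <- which(!vapply(model$reactions, `[[`, logical(1), "reversible"))
  G <- matrix(0, length(irrev), n, dimnames = list(labels[irrev], labels))
  if (length(irrev)) G[cbind(seq_along(irrev), irrev)] <- 1
  h <- rep(0, length(irrev))

  A <- NULL; b <- NULL; sdv <- NULL
  if (!is.null(measured_fluxes) && length(measured_fluxes)) {
    mf <- as_measured(measured_fluxes)
    unknown <- setdiff(mf$reaction, labels)
    if (length(unknown))
      stop("measured flux on unknown reaction(s): ", paste(unknown, collapse = ", "))
    if (any(mf$sd <= 0)) stop("measurement sd must be strictly positive")
    A <- matrix(0, nrow(mf), n, dimnames = list(mf$reaction, labels))
    A[cbind(seq_len(nrow(mf)), match(mf$reaction, labels))] <- 1
    b <- mf$value; sdv <- mf$sd
  }

  structure(list(E = E, f = f, G = G, h = h, A = A, b = b, sd = sdv,
                 reaction_labels = labels),
            class = "lim")
}

as_measured <- function(x) {
  if (is.data.frame(x)) {
    if (!all(c("reaction", "value", "sd") %in% names(x)))
      stop("measured_fluxes data frame needs columns reaction, value, sd")
    return(x[c("reaction", "value", "sd")])
  }
  ## named list: list(R1 = c(value, sd), ...)
  data.frame(reaction = names(x),
             value = vapply(x, function(v) as.numeric(v[[1]]), numeric(1)),
             sd = vapply(x, function(v) as.numeric(v[[2]]), numeric(1)),
             stringsAsFactors = FALSE)
}

#' @export
print.lim <- function(x, ...) {
  cat("Linear inverse model:", length(x$reaction_labels), "fluxes\n")
  cat("  equalities:  ", nrow(x$E), "rows (", sum(grepl("^fix_", rownames(x$E))),
      "fixed fluxes )\n")
  cat("  inequalities:", nrow(x$G), "irreversibility rows\n")
  if (!is.null(x$A))
    cat("  measured:    ", nrow(x$A), "approximate equalities\n")
  invisible(x)
}

#' Define a linear flux objective
#'
#' @param coefficients Named numeric vector of signed weights over reaction
#'   ids, e.g. `c(R_ATPS4m = 1, R_HEX1 = -1)`.
#' @param sense `"maximize"` or `"minimize"`.
#' @return An object of class `"objective_spec"`.
#' @export
objective_spec <- function(coefficients, sense = c("maximize", "minimize")) {
  sense <- match.arg(sense)
  if (is.null(names(coefficients)) || any(!nzchar(names(coefficients))))
    stop("objective coefficients must be a named numeric vector")
  structure(list(coefficients = coefficients, sense = sense),
            class = "objective_spec")
}

objective_vector <- function(objective, labels) {
  unknown <- setdiff(names(objective$coefficients), labels)
  if (length(unknown))
    stop("objective references unknown reaction(s): ",
         paste(unknown, collapse = ", "))
  v <- numeric(length(labels)); names(v) <- labels
  v[names(objective$coefficients)] <- objective$coefficients
  v
}

#' Read an objective from a JSON file
#'
#' Expects fields `coefficients` (object of reaction id to weight) and
#' `sense`.
#'
#' @param path JSON file path.
#' @return An [objective_spec()].
#' @export
read_objective <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  objective_spec(unlist(obj$coefficients),
                 sense = if (is.null(obj$sense)) "maximize" else obj$sense)
}
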