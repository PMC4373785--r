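#' Flux balance analysis by linear programming
#'
#' Optimizes a linear flux objective subject to the equality and inequality
#' constraints of a linear inverse model. The returned flux vector satisfies
#' `||E x - f||_inf <= eps_feas` and `G x >= h - eps_feas` with
#' `eps_feas = 1e-9`. When the optimum is not unique the solver returns one
#' deterministic vertex for a fixed input ordering; use
#' [flux_variability()] to delimit alternate optima.
#'
#' @param lim A [build_lim()] object.
#' @param objective An [objective_spec()].
#' @return An object of class `c("fba_fit", "flux_vector")` with elements
#'   `values` (named fluxes, mmol/min) and `objective_value`.
#' @export
solve_fba <- function(lim, objective) {
  stopifnot(inherits(lim, "lim"), inherits(objective, "objective_spec"))
  cvec <- objective_vector(objective, lim$reaction_labels)
  res <- solve_lp(cvec, lim$E, lim$f, lim$G, lim$h, sense = objective$sense)
  if (res$status == "infeasible")
    stop("FBA problem is infeasible (max constraint residual ",
         format(res$max_residual, digits = 3), "); conflicting rows: ",
         paste(utils::head(res$conflict, 5), collapse = ", "), call. = FALSE)
  if (res$status == "unbounded") {
    drv <- lim$reaction_labels[which.max(abs(res$ray))]
    stop("FBA problem is unbounded along a ray driven by reaction ", drv,
         call. = FALSE)
  }
  values <- stats::setNames(res$x, lim$reaction_labels)
  structure(list(values = values, objective_value = res$objective,
                 objective = objective, lim = lim),
            class = c("fba_fit", "flux_vector"))
}

#' @export
print.fba_fit <- function(x, ...) {
  cat("FBA solution (", length(x$values), " fluxes )\n", sep = "")
  cat("  objective (", x$objective$sense, "): ",
      format(x$objective_value, digits = 6), "\n", sep = "")
  nz <- sum(abs(x$values) > 1e-9)
  cat("  nonzero fluxes:", nz, "\n")
  invisible(x)
}

#' @export
coef.fba_fit <- function(object, ...) object$values

#' @export
summary.fba_fit <- function(object, ...) {
  df <- data.frame(reaction = names(object$values),
                   flux = unname(object$values), row.names = NULL)
  attr(df, "objective_value") <- object$objective_value
  df
}

#' Flux variability analysis
#'
#' For every reaction, computes the minimum and maximum flux compatible with
#' the constraints of `lim` and with an objective value at least
#' `optimum_fraction` times the optimum (for maximization; at most
#' `optimum / optimum_fraction`-style relaxation applies symmetrically for
#' minimization). Ranges of width (numerically) zero indicate that the flux
#' is uniquely determined at the optimum.
#'
#' @param lim A [build_lim()] object.
#' @param objective An [objective_spec()].
#' @param optimum_fraction Fraction of the optimal objective that must be
#'   retained, in `(0, 1]`.
#' @return A data frame with columns `reaction`, `min`, `max`, the FBA
#'   solution value in `fba` and the range `width`.
#' @export
flux_variability <- function(lim, objective, optimum_fraction = 1.0) {
  stopifnot(optimum_fraction > 0, optimum_fraction <= 1)
  fit <- solve_fba(lim, objective)
  cvec <- objective_vector(objective, lim$reaction_labels)
  opt <- fit$objective_value
  ## objective retention enters as one additional inequality row
  bound <- if (objective$sense == "maximize") {
    if (opt >= 0) optimum_fraction * opt else opt / optimum_fraction
  } else {
    if (opt >= 0) opt / optimum_fraction else optimum_fraction * opt
  }
  grow <- if (objective$sense == "maximize") cvec else -cvec
  gh <- if (objective$sense == "maximize") bound else -bound
  G2 <- rbind(lim$G, objective = grow)
  h2 <- c(lim$h, gh)
  n <- length(lim$reaction_labels)
  lo <- hi <- numeric(n)
  for (j in seq_len(n)) {
    ej <- numeric(n); ej[j] <- 1
    rmin <- solve_lp(ej, lim$E, lim$f, G2, h2, sense = "minimize")
    rmax <- solve_lp(ej, lim$E, lim$f, G2, h2, sense = "maximize")
    lo[j] <- if (rmin$status == "unbounded") -Inf else rmin$objective
    hi[j] <- if (rmax$status == "unbounded") Inf else rmax$objective
  }
  data.frame(reaction = lim$reaction_labels, min = lo, max = hi,
             fba = unname(fit$values), width = hi - lo, row.names = NULL)
}

#' Write a flux vector as CSV
#'
#' @param fluxes A named numeric vector, `flux_vector` or `fba_fit`.
#' @param path Output file path.
#' @param objective_value Optional objective value recorded as an
#'   `objective` pseudo-row.
#' @return The path, invisibly.
#' @export
write_flux_csv <- function(fluxes, path, objective_value = NULL) {
  if (inherits(fluxes, "flux_vector")) {
    if (is.null(objective_value)) objective_value <- fluxes$objective_value
    fluxes <- fluxes$values
  }
  df <- data.frame(reaction_id = names(fluxes), value = unname(fluxes))
  if (!is.null(objective_value))
    df <- rbind(df, data.frame(reaction_id = "objective", value = objective_value))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a constraint or flux CSV
#'
#' Accepts two-column (`reaction_id, value`) or three-column
#' (`reaction_id, value, sd`) files.
#'
#' @param path CSV file path.
#' @return A data frame.
#' @export
read_flux_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  names(df)[1:2] <- c("reaction_id", "value")
  df
}
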