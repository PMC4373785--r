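#' Sampler configuration
#'
#' Defaults follow the study configuration for the brain model ensemble:
#' burn-in of 1e7 Monte-Carlo steps, 1e7 sampling steps thinned to every
#' 100th vector (ensemble size 1e5) and a relative jump parameter of 0.1.
#' Tests and examples use scaled-down chains.
#'
#' @param n_burnin Number of burn-in steps.
#' @param n_iter Number of post-burn-in steps.
#' @param thin Keep every `thin`-th state.
#' @param jump Relative proposal step size: the per-direction Gaussian
#'   proposal standard deviation is `jump` times an estimate of the feasible
#'   range along that direction.
#' @param seed Integer seed; identical seed, configuration and input yield
#'   an identical ensemble.
#' @return An object of class `"sampler_config"`.
#' @export
sampler_config <- function(n_burnin = 1e7, n_iter = 1e7, thin = 100,
                           jump = 0.1, seed = 1868) {
  stopifnot(n_iter >= thin, thin >= 1, jump > 0, n_burnin >= 0)
  structure(list(n_burnin = as.numeric(n_burnin), n_iter = as.numeric(n_iter),
                 thin = as.integer(thin), jump = as.numeric(jump),
                 seed = as.integer(seed)),
            class = "sampler_config")
}

#' Sample an ensemble of feasible flux vectors
#'
#' Metropolis-Hastings sampling of the constraint polytope
#' `{x : E x = f, G x >= h}` with a Gaussian likelihood on the measured
#' fluxes, `L(x) = exp(-1/2 * sum(((A x - b) / sd)^2))`. The
#' equality-feasible affine subspace is parameterized as `x = x0 + Z q`
#' with `Z` an orthonormal null-space basis of `E`; proposals are Gaussian
#' steps in `q`, and proposals that violate inequality constraints are
#' reflected across the violated hyperplanes until feasible (the "mirror"
#' move, which keeps the proposal symmetric). Every kept sample satisfies
#' all constraints exactly (up to numerical feasibility tolerance).
#'
#' @param lim A [build_lim()] object with measured fluxes (`A`, `b`, `sd`).
#' @param config A [sampler_config()].
#' @param initial Optional feasible starting flux vector, typically the FBA
#'   solution; defaults to a least-squares feasible point.
#' @return An object of class `"flux_ensemble"`: list with `samples`
#'   (matrix, kept samples by reactions), `reaction_labels`, `config` and
#'   `acceptance_rate`.
#' @export
sample_ensemble <- function(lim, config = sampler_config(), initial = NULL) {
  stopifnot(inherits(lim, "lim"), inherits(config, "sampler_config"))
  if (is.null(lim$A))
    stop("lim must carry measured fluxes (A, b, sd) for ensemble sampling")
  labels <- lim$reaction_labels
  n <- length(labels)

  dec <- nullspace_decompose(lim$E, lim$f)
  if (dec$residual > 1e-7 * max(1, abs(lim$f)))
    stop("equality constraints are inconsistent; no feasible start", call. = FALSE)
  x0 <- dec$x0; Z <- dec$Z; d <- ncol(Z)

  isd <- 1 / lim$sd
  ## Rotate the null-space basis onto the singular directions of the
  ## sd-scaled measurement map, so that likelihood-informed and
  ## likelihood-flat coordinates decouple: flat coordinates can then take
  ## large steps (scaled by the polytope range) without perturbing the
  ## likelihood, which makes the chain mix across the whole feasible set.
  if (d > 0L) {
    W <- (lim$A %*% Z) * isd
    Z <- Z %*% svd(W, nv = d)$v
  }


  feas_tol <- 1e-9 * max(1, abs(lim$h), abs(lim$f))
  if (!is.null(initial)) {
    if (inherits(initial, "flux_vector")) initial <- initial$values
    initial <- initial[labels]
    if (max(abs(lim$E %*% initial - lim$f)) > 1e-6)
      stop("initial point does not satisfy the equality constraints")
    q <- as.numeric(crossprod(Z, initial - x0))
  } else {
    q <- numeric(d)
    if (nrow(lim$G) && any(lim$G %*% x0 < lim$h - feas_tol)) {
      qs <- feasible_start(lim$G %*% Z, lim$h - as.numeric(lim$G %*% x0),
                           tol = feas_tol)
      if (is.null(qs)) stop("no feasible starting point exists", call. = FALSE)
      q <- qs
    }
  }

  N <- lim$G %*% Z; g <- lim$h - as.numeric(lim$G %*% x0)
  CZ <- lim$A %*% Z
  r0 <- as.numeric(lim$A %*% x0) - lim$b
  loglik <- function(q) -0.5 * sum(((r0 + as.numeric(CZ %*% q)) * isd)^2)

  if (d == 0L) {
    ## the equalities determine a unique point: the "chain" sits on it
    if (nrow(lim$G) && any(lim$G %*% x0 < lim$h - feas_tol))
      stop("no feasible starting point exists: the equality-determined ",
           "point violates the inequality constraints", call. = FALSE)
    n_keep <- max(1L, floor(config$n_iter / config$thin))
    samples <- matrix(x0, n_keep, n, byrow = TRUE,
                      dimnames = list(NULL, labels))
    return(structure(list(samples = samples, reaction_labels = labels,
                          config = config, acceptance_rate = 1),
                     class = "flux_ensemble"))
  }

  ## Per-direction scale of the proposal: the feasible range along each
  ## null-space direction from the starting point, capped by the width the
  ## Gaussian measurement likelihood allows in that direction (so that
  ## directions spanning a wide polytope but a narrow posterior still mix).
  range_est <- numeric(d)
  slack <- if (nrow(N)) as.numeric(N %*% q - g) else numeric(0)
  for (j in seq_len(d)) {
    if (nrow(N)) {
      nj <- N[, j]
      pos <- which(nj > 1e-12); negv <- which(nj < -1e-12)
      tmax <- if (length(negv)) min(-slack[negv] / nj[negv]) else Inf
      tmin <- if (length(pos)) max(-slack[pos] / nj[pos]) else -Inf
      range_est[j] <- tmax - tmin
    } else range_est[j] <- Inf
    lscale <- sqrt(sum((CZ[, j] * isd)^2))  # 1/posterior-sd along direction j
    lik_width <- if (lscale > 0) 6 / lscale else Inf
    range_est[j] <- min(range_est[j], lik_width)
    if (!is.finite(range_est[j]) || range_est[j] <= 0) range_est[j] <- 1
  }
  sigma <- config$jump * range_est

  set.seed(config$seed)
  total <- config$n_burnin + config$n_iter
  n_keep <- floor(config$n_iter / config$thin)
  samples <- matrix(NA_real_, n_keep, n)
  colnames(samples) <- labels
  ll <- loglik(q)
  accept <- 0; kept <- 0L
  nrm2 <- if (nrow(N)) rowSums(N^2) else numeric(0)
  burn_accept <- 0

  for (step in seq_len(total)) {
    qp <- q + sigma * stats::rnorm(d)
    ok <- TRUE
    if (nrow(N)) {
      for (bounce in seq_len(1000L)) {
        vio <- N %*% qp - g
        i <- which.min(vio)
        if (vio[i] >= -feas_tol) break
        qp <- qp + (-2 * vio[i] / nrm2[i]) * N[i, ]
        if (bounce == 1000L) ok <- FALSE
      }
    }
    if (ok) {
      llp <- loglik(qp)
      if (llp - ll >= 0 || stats::runif(1) < exp(llp - ll)) {
        q <- qp; ll <- llp
        if (step > config$n_burnin) accept <- accept + 1
        else burn_accept <- burn_accept + 1
      }
    }
    if (step > config$n_burnin) {
      k <- step - config$n_burnin
      if (k %% config$thin == 0) {
        kept <- kept + 1L
        samples[kept, ] <- x0 + as.numeric(Z %*% q)
      }
    }
  }
  if (config$n_burnin > 0 && burn_accept == 0 && accept == 0)
    stop("zero acceptance over the whole chain; decrease the jump parameter",
         call. = FALSE)
  structure(list(samples = samples[seq_len(kept), , drop = FALSE],
                 reaction_labels = labels, config = config,
                 acceptance_rate = accept / max(1, config$n_iter)),
            class = "flux_ensemble")
}

#' @export
print.flux_ensemble <- function(x, ...) {
  cat("Flux ensemble:", nrow(x$samples), "samples x",
      ncol(x$samples), "reactions\n")
  cat("  acceptance rate:", format(x$acceptance_rate, digits = 3), "\n")
  invisible(x)
}

#' Autocorrelation function of one sampled flux
#'
#' Standard normalized autocorrelation of the Markov-chain trace of one
#' reaction, used (together with trace inspection) to assess convergence.
#' A constant trace is returned as lag-0 autocorrelation 1 and 0 elsewhere,
#' with attribute `constant = TRUE`.
#'
#' @param ensemble A [sample_ensemble()] result.
#' @param reaction Reaction id.
#' @param max_lag Maximum lag.
#' @return Numeric vector of autocorrelations for lags `0:max_lag`.
#' @export
autocorrelation <- function(ensemble, reaction, max_lag = 20L) {
  stopifnot(inherits(ensemble, "flux_ensemble"))
  x <- ensemble$samples[, reaction]
  if (length(x) <= max_lag)
    stop("max_lag must be smaller than the number of kept samples")
  if (stats::sd(x) == 0 || !is.finite(stats::sd(x)))
    return(structure(c(1, rep(0, max_lag)), constant = TRUE))
  ac <- stats::acf(x, lag.max = max_lag, plot = FALSE, demean = TRUE)
  structure(as.numeric(ac$acf), constant = FALSE)
}

#' Summary statistics of a flux ensemble
#'
#' @param ensemble A [sample_ensemble()] result.
#' @param probs Quantile probabilities.
#' @return A data frame with per-reaction mean, sd and quantiles.
#' @export
ensemble_summary <- function(ensemble, probs = c(0.025, 0.5, 0.975)) {
  stopifnot(inherits(ensemble, "flux_ensemble"), nrow(ensemble$samples) >= 2)
  qs <- t(apply(ensemble$samples, 2, stats::quantile, probs = probs))
  colnames(qs) <- paste0("q", probs * 100)
  data.frame(reaction = colnames(ensemble$samples),
             mean = colMeans(ensemble$samples),
             sd = apply(ensemble$samples, 2, stats::sd),
             qs, row.names = NULL, check.names = FALSE)
}

#' @export
summary.flux_ensemble <- function(object, ...) ensemble_summary(object, ...)

#' Histograms of sampled fluxes
#'
#' Plots per-reaction histograms of the ensemble with the sample mean and
#' standard deviation printed above each panel.
#'
#' @param x A `flux_ensemble`.
#' @param reactions Reaction ids to plot (default: first 4).
#' @param ... Passed to [graphics::hist()].
#' @return `x`, invisibly.
#' @export
plot.flux_ensemble <- function(x, reactions = NULL, ...) {
  if (is.null(reactions))
    reactions <- utils::head(x$reaction_labels, 4)
  old <- graphics::par(mfrow = grDevices::n2mfrow(length(reactions)))
  on.exit(graphics::par(old))
  for (r in reactions) {
    v <- x$samples[, r]
    graphics::hist(v, main = sprintf("%s\nmean %.3f sd %.3f", r,
                                     mean(v), stats::sd(v)),
                   xlab = "flux (mmol/min)", ...)
  }
  invisible(x)
}

#' Persist an ensemble as CSV plus JSON sidecar
#'
#' @param ensemble A `flux_ensemble`.
#' @param csv_path Sample matrix CSV path (header = reaction ids).
#' @param json_path Sidecar path for the sampler configuration and the
#'   acceptance rate.
#' @return `csv_path`, invisibly.
#' @export
write_ensemble <- function(ensemble, csv_path, json_path = NULL) {
  utils::write.csv(as.data.frame(ensemble$samples), csv_path, row.names = FALSE)
  if (!is.null(json_path))
    jsonlite::write_json(c(unclass(ensemble$config),
                           list(acceptance_rate = ensemble$acceptance_rate)),
                         json_path, auto_unbox = TRUE, digits = NA)
  invisible(csv_path)
}
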