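## Shared fixtures and independent oracles for the test suite.

## Linear chain A_b -> A -> B -> B_b; boundary species at both ends.
toy_chain_model <- function(reversible = FALSE) {
  metabolic_model(
    metabolites = list(
      metabolite("A_b", boundary = TRUE), metabolite("A"),
      metabolite("B"), metabolite("B_b", boundary = TRUE)),
    reactions = list(
      reaction("R1", c(A_b = -1, A = 1), reversible = reversible),
      reaction("R2", c(A = -1, B = 1), reversible = reversible),
      reaction("R3", c(B = -1, B_b = 1), reversible = reversible)),
    id = "toy_chain")
}

## Source -> A, two parallel irreversible routes A -> B, B -> sink.
branched_model <- function() {
  metabolic_model(
    metabolites = list(
      metabolite("S_b", boundary = TRUE), metabolite("A"),
      metabolite("B"), metabolite("P_b", boundary = TRUE)),
    reactions = list(
      reaction("R_in", c(S_b = -1, A = 1), reversible = FALSE,
               gene_association = "g0"),
      reaction("R_1", c(A = -1, B = 1), reversible = FALSE,
               gene_association = "g1"),
      reaction("R_2", c(A = -1, B = 1), reversible = FALSE,
               gene_association = "g2"),
      reaction("R_out", c(B = -1, P_b = 1), reversible = FALSE,
               gene_association = "g3")),
    id = "toy_branched")
}

## Random bounded LP/LSEI instance with n reactions and d net degrees of
## freedom: E x = f consistent with a strictly interior positive point,
## G = [I; -I] boxes every variable into [0, ub].
random_instance <- function(seed, n = NULL, d = NULL, ub = 10) {
  set.seed(seed)
  if (is.null(n)) n <- sample(4:8, 1)
  if (is.null(d)) d <- sample(1:3, 1)
  k <- n - d
  repeat {
    E <- matrix(stats::rnorm(k * n), k, n)
    if (qr(E)$rank == k) break
  }
  x_int <- stats::runif(n, 1, ub - 1)
  f <- as.numeric(E %*% x_int)
  G <- rbind(diag(n), -diag(n))
  h <- c(rep(0, n), rep(-ub, n))
  cvec <- stats::rnorm(n)
  list(E = E, f = f, G = G, h = h, cvec = cvec, n = n, d = d, x_int = x_int)
}

## Brute-force LP oracle: enumerate vertices as solutions of E plus d
## active inequality rows; the optimum of a bounded feasible LP is the
## best feasible vertex.
oracle_lp_vertex <- function(inst, sense = "maximize") {
  with(inst, {
    best <- NULL; best_x <- NULL
    sets <- utils::combn(nrow(G), d, simplify = FALSE)
    for (S in sets) {
      M <- rbind(E, G[S, , drop = FALSE])
      if (abs(det(M)) < 1e-10) next
      x <- tryCatch(solve(M, c(f, h[S])), error = function(e) NULL)
      if (is.null(x)) next
      if (any(G %*% x < h - 1e-8)) next
      val <- sum(cvec * x)
      if (is.null(best) ||
          (sense == "maximize" && val > best) ||
          (sense == "minimize" && val < best)) { best <- val; best_x <- x }
    }
    list(objective = best, x = best_x)
  })
}

## Brute-force LSEI oracle: enumerate active subsets of the inequalities,
## solve the equality-constrained least-squares problem on each face with
## pseudo-inverses, keep the best feasible candidate.
oracle_lsei_active_set <- function(inst, A, b) {
  with(inst, {
    pinv_ <- function(M, tol = 1e-10) {
      sv <- svd(M); pos <- sv$d > max(dim(M)) * max(sv$d, 0) * tol
      if (!any(pos)) return(matrix(0, ncol(M), nrow(M)))
      sv$v[, pos, drop = FALSE] %*% (t(sv$u[, pos, drop = FALSE]) / sv$d[pos])
    }
    nullb <- function(M) {
      sv <- svd(M, nv = ncol(M))
      tol <- max(dim(M)) * max(sv$d, 0) * 1e-10
      r <- sum(sv$d > tol)
      if (r < ncol(M)) sv$v[, (r + 1):ncol(M), drop = FALSE]
      else matrix(0, ncol(M), 0)
    }
    best <- Inf; best_x <- NULL
    for (sz in 0:d) {
      sets <- if (sz == 0) list(integer(0)) else
        utils::combn(nrow(G), sz, simplify = FALSE)
      for (S in sets) {
        Eq <- rbind(E, G[S, , drop = FALSE]); rq <- c(f, h[S])
        x0 <- as.numeric(pinv_(Eq) %*% rq)
        if (max(abs(Eq %*% x0 - rq)) > 1e-8) next
        Z <- nullb(Eq)
        x <- x0
        if (ncol(Z)) {
          u <- pinv_(A %*% Z) %*% (b - A %*% x0)
          x <- x0 + as.numeric(Z %*% u)
        }
        if (any(G %*% x < h - 1e-8)) next
        val <- sum((A %*% x - b)^2)
        if (val < best - 1e-12) { best <- val; best_x <- x }
      }
    }
    list(residual_ss = best, x = best_x)
  })
}

## Effective-sample-size-aware Monte-Carlo standard error of a chain mean.
mc_se <- function(x) {
  n <- length(x)
  if (stats::sd(x) == 0) return(0)
  ac <- stats::acf(x, lag.max = min(200, n - 1), plot = FALSE)$acf[-1]
  ## initial positive sequence
  pos <- which(ac <= 0)
  tau <- 1 + 2 * sum(ac[seq_len(if (length(pos)) pos[1] - 1 else length(ac))])
  stats::sd(x) * sqrt(max(tau, 1) / n)
}

## Moments of the normal(mu, sd) truncated to [0, Inf).
truncnorm_moments <- function(mu, sd) {
  a <- -mu / sd
  lambda <- stats::dnorm(a) / (1 - stats::pnorm(a))
  m <- mu + sd * lambda
  v <- sd^2 * (1 + a * lambda - lambda^2)
  c(mean = m, sd = sqrt(v))
}

## One free flux v >= 0 with likelihood N(b, sd): a single boundary-to-
## boundary reaction measured directly.
one_dof_lim <- function(b, sdev) {
  m <- metabolic_model(
    metabolites = list(metabolite("S_b", boundary = TRUE),
                       metabolite("P_b", boundary = TRUE)),
    reactions = list(reaction("v", c(S_b = -1, P_b = 1), reversible = FALSE)))
  build_lim(m, measured_fluxes = data.frame(reaction = "v", value = b, sd = sdev))
}

## Two independent nonnegative fluxes, each measured.
two_dof_lim <- function(b1, sd1, b2, sd2) {
  m <- metabolic_model(
    metabolites = list(metabolite("S1_b", boundary = TRUE),
                       metabolite("P1_b", boundary = TRUE),
                       metabolite("S2_b", boundary = TRUE),
                       metabolite("P2_b", boundary = TRUE)),
    reactions = list(
      reaction("v1", c(S1_b = -1, P1_b = 1), reversible = FALSE),
      reaction("v2", c(S2_b = -1, P2_b = 1), reversible = FALSE)))
  build_lim(m, measured_fluxes = data.frame(
    reaction = c("v1", "v2"), value = c(b1, b2), sd = c(sd1, sd2)))
}

## Structural equality of two models up to canonical ordering.
expect_models_equal <- function(a, b) {
  testthat::expect_setequal(names(a$reactions), names(b$reactions))
  testthat::expect_setequal(names(a$metabolites), names(b$metabolites))
  for (id in names(a$reactions)) {
    ra <- a$reactions[[id]]; rb <- b$reactions[[id]]
    sa <- ra$stoichiometry[order(names(ra$stoichiometry))]
    sb <- rb$stoichiometry[order(names(rb$stoichiometry))]
    testthat::expect_equal(sa, sb, tolerance = 1e-12, info = id)
    testthat::expect_identical(ra$reversible, rb$reversible, info = id)
  }
  for (id in names(a$metabolites))
    testthat::expect_identical(a$metabolites[[id]]$boundary,
                               b$metabolites[[id]]$boundary, info = id)
}

brain_reference_fit <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      m <- build_brain_model()
      lim <- build_lim(m, fixed_fluxes = brain_fixed_fluxes())
      cache <<- list(model = m, lim = lim,
                     fit = solve_fba(lim, brain_atp_objective()))
    }
    cache
  }
})
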