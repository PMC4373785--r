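## Dense two-phase primal simplex for linear inverse models.
##
## Solves  max/min c'x  subject to  E x = f,  G x >= h  with free variables.
## Written for the moderate problem sizes of curated metabolic models
## (tens to a few hundred reactions). Variables covered by a canonical
## irreversibility row of G (single +1 entry, zero right-hand side) are
## handled as nonnegative variables directly; remaining free variables are
## split x = x+ - x-, and general inequality rows receive surplus columns.
## Phase 1 minimizes artificial infeasibility; phase 2 optimizes c'x.
## Dantzig pricing with an automatic switch to Bland's rule guards against
## cycling on degenerate polytopes.

LP_TOL <- 1e-9

solve_lp <- function(cvec, E, f, G = NULL, h = NULL,
                     sense = c("maximize", "minimize")) {
  sense <- match.arg(sense)
  n <- length(cvec)
  E <- as.matrix(E)
  if (ncol(E) != n) stop("E must have ", n, " columns")
  f <- as.numeric(f)
  if (is.null(G)) { G <- matrix(0, 0, n); h <- numeric(0) }
  G <- as.matrix(G); h <- as.numeric(h)

  ## canonical irreversibility rows -> variable lower bounds at 0
  nonneg <- rep(FALSE, n)
  general <- rep(TRUE, nrow(G))
  if (nrow(G)) {
    for (i in seq_len(nrow(G))) {
      nz <- which(abs(G[i, ]) > 0)
      if (length(nz) == 1L && G[i, nz] == 1 && h[i] == 0) {
        nonneg[nz] <- TRUE
        general[i] <- FALSE
      }
    }
  }
  Gg <- G[general, , drop = FALSE]; hg <- h[general]
  free <- which(!nonneg); pos <- which(nonneg)

  ## columns: [x_pos | x_free+ | x_free- | surplus]
  npos <- length(pos); nfree <- length(free); ng <- nrow(Gg)
  ncols <- npos + 2L * nfree + ng
  build_row <- function(row) {
    c(row[pos], row[free], -row[free], numeric(ng))
  }
  M <- matrix(0, nrow(E) + ng, ncols)
  d <- c(f, hg)
  for (i in seq_len(nrow(E))) M[i, ] <- build_row(E[i, ])
  if (ng) for (i in seq_len(ng)) {
    M[nrow(E) + i, ] <- build_row(Gg[i, ])
    M[nrow(E) + i, npos + 2L * nfree + i] <- -1
  }
  neg <- d < 0
  M[neg, ] <- -M[neg, , drop = FALSE]; d[neg] <- -d[neg]

  obj_full <- c(cvec[pos], cvec[free], -cvec[free], numeric(ng))
  if (sense == "maximize") obj_full <- -obj_full   # internally minimize

  res <- simplex_two_phase(M, d, obj_full)
  if (res$status == "infeasible") {
    ## residuals at the least-infeasible point found in phase 1
    x <- recover_x(res$z, pos, free, n)
    r_eq <- as.numeric(E %*% x - f)
    r_in <- if (nrow(G)) pmin(as.numeric(G %*% x - h), 0) else numeric(0)
    resid <- c(abs(r_eq), abs(r_in))
    labs <- c(paste0("equality[", seq_along(r_eq), "]"),
              if (nrow(G)) paste0("inequality[", seq_len(nrow(G)), "]"))
    ord <- order(resid, decreasing = TRUE)
    return(list(status = "infeasible",
                conflict = labs[ord[resid[ord] > 1e-7]],
                max_residual = max(resid)))
  }
  if (res$status == "unbounded") {
    ray <- recover_x(res$ray, pos, free, n)
    return(list(status = "unbounded", ray = ray))
  }
  x <- recover_x(res$z, pos, free, n)
  obj <- sum(cvec * x)
  list(status = "optimal", x = x, objective = obj)
}

recover_x <- function(z, pos, free, n) {
  npos <- length(pos); nfree <- length(free)
  x <- numeric(n)
  if (npos) x[pos] <- z[seq_len(npos)]
  if (nfree) x[free] <- z[npos + seq_len(nfree)] - z[npos + nfree + seq_len(nfree)]
  x
}

## Minimize obj'z s.t. Mz = d (d >= 0), z >= 0.
simplex_two_phase <- function(M, d, obj) {
  m <- nrow(M); nc <- ncol(M)
  ## Phase 1 tableau with artificials
  A <- cbind(M, diag(m))
  basis <- nc + seq_len(m)
  cost1 <- c(numeric(nc), rep(1, m))
  r1 <- simplex_core(A, d, cost1, basis)
  if (r1$status != "optimal" || r1$value > 1e-7)
    return(list(status = "infeasible",
                z = r1$z[seq_len(nc)]))
  A <- r1$A; d <- r1$d; basis <- r1$basis
  ## drive artificials out of the basis, dropping redundant rows
  keep <- rep(TRUE, length(basis))
  for (i in seq_along(basis)) {
    if (basis[i] > nc) {
      piv <- which(abs(A[i, seq_len(nc)]) > LP_TOL)
      piv <- piv[!piv %in% basis]
      if (length(piv)) {
        A_sub <- pivot_tableau(A, d, i, piv[1])
        A <- A_sub$A; d <- A_sub$d; basis[i] <- piv[1]
      } else keep[i] <- FALSE
    }
  }
  A <- A[keep, seq_len(nc), drop = FALSE]
  d <- d[keep]; basis <- basis[keep]
  r2 <- simplex_core(A, d, obj, basis)
  if (r2$status == "unbounded")
    return(list(status = "unbounded", ray = r2$ray[seq_len(nc)]))
  list(status = "optimal", z = r2$z[seq_len(nc)], value = r2$value)
}

## Core iteration on tableau A z = d, z >= 0, basis given (A[, basis] must be
## reducible to the identity; entered with a feasible basic solution).
simplex_core <- function(A, d, cost, basis) {
  m <- nrow(A); nc <- ncol(A)
  ## normalize so that basic columns form the identity
  for (i in seq_len(m)) {
    p <- A[i, basis[i]]
    if (abs(p - 1) > LP_TOL || TRUE) { A[i, ] <- A[i, ] / p; d[i] <- d[i] / p }
    nz <- which(abs(A[, basis[i]]) > LP_TOL & seq_len(m) != i)
    for (r in nz) { d[r] <- d[r] - A[r, basis[i]] * d[i]
                    A[r, ] <- A[r, ] - A[r, basis[i]] * A[i, ] }
  }
  maxit <- 200L * (m + nc)
  bland_after <- 20L * (m + nc)
  for (it in seq_len(maxit)) {
    cb <- cost[basis]
    red <- cost - as.numeric(crossprod(A, cb))  # reduced costs
    red[basis] <- 0
    cand <- which(red < -1e-9)
    if (!length(cand)) {
      z <- numeric(nc); z[basis] <- d
      return(list(status = "optimal", z = z, value = sum(cost[basis] * d),
                  A = A, d = d, basis = basis))
    }
    j <- if (it > bland_after) cand[1] else cand[which.min(red[cand])]
    col <- A[, j]
    up <- which(col > LP_TOL)
    if (!length(up)) {
      ray <- numeric(nc); ray[j] <- 1; ray[basis] <- -col
      return(list(status = "unbounded", ray = ray))
    }
    ratio <- d[up] / col[up]
    i <- up[which(ratio <= min(ratio) + 1e-12)]
    if (length(i) > 1L) i <- i[which.min(basis[i])]  # Bland tie-break
    i <- i[1]
    pv <- pivot_tableau(A, d, i, j)
    A <- pv$A; d <- pv$d; basis[i] <- j
  }
  stop("simplex iteration limit exceeded")
}

pivot_tableau <- function(A, d, i, j) {
  p <- A[i, j]
  A[i, ] <- A[i, ] / p; d[i] <- d[i] / p
  other <- which(abs(A[, j]) > 0 & seq_len(nrow(A)) != i)
  if (length(other)) {
    d[other] <- d[other] - A[other, j] * d[i]
    A[other, ] <- A[other, ] - outer(A[other, j], A[i, ])
  }
  list(A = A, d = d)
}
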