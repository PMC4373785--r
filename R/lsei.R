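## Least squares with equality and inequality constraints:
##
##   minimize ||A x - b||^2   subject to   E x = f,   G x >= h.
##
## The equalities are eliminated through an orthonormal null-space basis of
## E obtained from the SVD (x = x0 + Z q with x0 the minimum-norm particular
## solution), after which a primal active-set method solves the reduced
## problem. Each equality-constrained subproblem is solved with
## pseudo-inverses, so rank-deficient A never raises an error and the
## representative returned on the final active set is the minimum-norm one.
## Because x0 lies in the row space of E and Z spans its null space,
## ||x||^2 = ||x0||^2 + ||q||^2, and minimizing ||q|| is equivalent to
## minimizing ||x|| among minimizers.

RANK_TOL <- 1e-10

## Orthonormal null-space basis and min-norm particular solution of E x = f.
nullspace_decompose <- function(E, f) {
  n <- ncol(E)
  if (nrow(E) == 0L)
    return(list(x0 = numeric(n), Z = diag(n), rank = 0L, residual = 0))
  sv <- svd(E, nu = nrow(E), nv = n)
  tol <- max(dim(E)) * max(sv$d, 0) * RANK_TOL
  r <- sum(sv$d > tol)
  x0 <- if (r == 0L) numeric(n) else
    sv$v[, seq_len(r), drop = FALSE] %*%
      ((crossprod(sv$u[, seq_len(r), drop = FALSE], f)) / sv$d[seq_len(r)])
  Z <- if (r < n) sv$v[, (r + 1L):n, drop = FALSE] else matrix(0, n, 0)
  resid <- sqrt(sum((E %*% x0 - f)^2))
  list(x0 = as.numeric(x0), Z = Z, rank = r, residual = resid)
}

pinv <- function(M, tol = RANK_TOL) {
  if (length(M) == 0L) return(t(M))
  sv <- svd(M)
  pos <- sv$d > max(dim(M)) * max(sv$d, 0) * tol
  if (!any(pos)) return(matrix(0, ncol(M), nrow(M)))
  sv$v[, pos, drop = FALSE] %*% (t(sv$u[, pos, drop = FALSE]) / sv$d[pos])
}

#' Solve a least-squares problem with equality and inequality constraints
#'
#' Returns the minimizer of `||A x - b||^2` subject to `E x = f` and
#' `G x >= h`. When the minimizer is not unique along null directions of
#' `A`, the minimum-Euclidean-norm representative (over the final active
#' set) is returned. Rank deficiency in any of the matrices is handled.
#'
#' @param E,f Equality constraint matrix and right-hand side.
#' @param G,h Inequality constraint matrix and right-hand side (`G x >= h`);
#'   may be `NULL`.
#' @param A,b Approximate-equality (target) matrix and vector.
#' @param tol Feasibility tolerance.
#' @return A list with `x` (solution), `residual_ss` (attained
#'   `||Ax - b||^2`) and `active` (indices of active inequalities).
#' @export
solve_lsei <- function(E, f, G = NULL, h = NULL, A, b, tol = 1e-9) {
  n <- if (!is.null(E) && nrow(E)) ncol(E) else if (!is.null(A)) ncol(A)
       else if (!is.null(G)) ncol(G) else stop("cannot infer dimension")
  if (is.null(E)) { E <- matrix(0, 0, n); f <- numeric(0) }
  if (is.null(G)) { G <- matrix(0, 0, n); h <- numeric(0) }
  if (is.null(A)) { A <- matrix(0, 0, n); b <- numeric(0) }
  E <- as.matrix(E); G <- as.matrix(G); A <- as.matrix(A)
  f <- as.numeric(f); h <- as.numeric(h); b <- as.numeric(b)

  dec <- nullspace_decompose(E, f)
  scale_f <- max(1, abs(f), abs(h))
  if (dec$residual > 1e-7 * scale_f)
    stop("equality constraints are inconsistent (residual ",
         format(dec$residual, digits = 3), ")", call. = FALSE)
  x0 <- dec$x0; Z <- dec$Z
  d <- ncol(Z)
  if (d == 0L) {
    if (nrow(G) && any(G %*% x0 < h - 1e-7 * scale_f))
      stop("constraints are infeasible: equalities determine a point ",
           "violating the inequalities", call. = FALSE)
    return(list(x = x0, residual_ss = sum((A %*% x0 - b)^2), active = integer(0)))
  }

  Cm <- A %*% Z; r <- b - as.numeric(A %*% x0)
  N <- G %*% Z; g <- h - as.numeric(G %*% x0)

  q <- feasible_start(N, g, tol = 1e-9 * scale_f)
  if (is.null(q))
    stop("constraints are infeasible: no point satisfies E x = f and G x >= h",
         call. = FALSE)

  res <- active_set_ls(Cm, r, N, g, q, tol = max(tol, 1e-11 * scale_f))
  x <- as.numeric(x0 + Z %*% res$q)
  list(x = x, residual_ss = sum((A %*% x - b)^2), active = res$active)
}

feasible_start <- function(N, g, tol) {
  d <- ncol(N)
  if (nrow(N) == 0L || all(g <= tol)) return(numeric(d))
  lp <- solve_lp(numeric(d), matrix(0, 0, d), numeric(0), N, g,
                 sense = "minimize")
  if (lp$status != "optimal") return(NULL)
  lp$x
}

## Primal active-set method for min ||C q - r|| s.t. N q >= g from a
## feasible start. Subproblems use pseudo-inverses (min-norm).
active_set_ls <- function(Cm, r, N, g, q, tol = 1e-9, max_iter = 400L) {
  m <- nrow(N)
  act <- if (m) which(N %*% q - g <= tol) else integer(0)
  nrmN <- if (m) sqrt(rowSums(N^2)) else numeric(0)
  for (it in seq_len(max_iter)) {
    ## solve equality-constrained LS on the active set, min-norm
    if (length(act)) {
      Na <- N[act, , drop = FALSE]
      qW <- pinv(Na) %*% g[act]
      ZW <- nullspace_basis(Na)
    } else {
      qW <- matrix(0, ncol(N), 1)
      ZW <- diag(ncol(N))
    }
    qhat <- as.numeric(qW)
    if (ncol(ZW)) {
      u <- pinv(Cm %*% ZW) %*% (r - Cm %*% qW)
      qhat <- qhat + as.numeric(ZW %*% u)
    }
    viol <- if (m) which(N %*% qhat - g < -tol) else integer(0)
    if (!length(viol)) {
      ## candidate optimal for subproblem; check multipliers
      q <- qhat
      if (!length(act)) return(list(q = q, active = act))
      w <- as.numeric(crossprod(Cm, Cm %*% q - r))
      lambda <- as.numeric(pinv(t(N[act, , drop = FALSE])) %*% w)
      neg <- which(lambda < -1e-8 * max(1, max(abs(lambda))))
      if (!length(neg)) return(list(q = q, active = act))
      act <- act[-neg[which.min(lambda[neg])]]
    } else {
      ## step toward qhat until a blocking constraint
      dq <- qhat - q
      Nd <- as.numeric(N %*% dq)
      slack <- as.numeric(N %*% q - g)
      block <- which(Nd < -tol)
      alpha <- pmin(1, ifelse(Nd[block] < 0, -slack[block] / Nd[block], 1))
      astar <- min(alpha)
      jb <- block[which(alpha <= astar + 1e-12)]
      q <- q + max(astar, 0) * dq
      act <- sort(unique(c(act, jb[1])))
    }
  }
  stop("active-set iteration limit exceeded in solve_lsei")
}

nullspace_basis <- function(M) {
  n <- ncol(M)
  if (nrow(M) == 0L) return(diag(n))
  sv <- svd(M, nv = n)
  tol <- max(dim(M)) * max(sv$d, 0) * RANK_TOL
  r <- sum(sv$d > tol)
  if (r < n) sv$v[, (r + 1L):n, drop = FALSE] else matrix(0, n, 0)
}
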