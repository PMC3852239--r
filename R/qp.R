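## Small dense convex quadratic programming:
##   min 1/2 x'Hx + g'x   s.t.  Aeq x = beq,  lb <= x <= ub
##
## Primal active-set method with feasible iterates (the textbook algorithm):
## every step solves the equality-constrained QP on the current working set of
## bound constraints, then either moves to that minimiser or stops at the first
## blocking bound.  H must be positive definite on the null space of the
## constraints, which holds for both callers in this package (identity Hessian
## for equilibrium-constant balancing; prior-regularised Gaussian posterior for
## parameter balancing).  A feasible starting point is found by phase-1 LP when
## none is supplied.
qp_solve <- function(H, g, Aeq = NULL, beq = NULL, lb = NULL, ub = NULL,
                     x0 = NULL, tol = 1e-10, maxit = 500L) {
  H <- as.matrix(H)
  n <- ncol(H)
  g <- as.numeric(g)
  if (is.null(lb)) lb <- rep(-1e12, n)
  if (is.null(ub)) ub <- rep(1e12, n)
  lb <- pmax(as.numeric(lb), -1e12); ub <- pmin(as.numeric(ub), 1e12)
  if (is.null(Aeq)) { Aeq <- matrix(0, 0, n); beq <- numeric(0) }
  Aeq <- as.matrix(Aeq); beq <- as.numeric(beq)
  meq <- nrow(Aeq)
  if (any(lb > ub + 1e-12)) return(list(status = "infeasible", x = NULL))

  ## feasible start
  if (is.null(x0)) {
    if (meq == 0L) {
      x <- pmin(pmax(rep(0, n), lb), ub)
    } else {
      r <- lp_solve(rep(0, n), Aeq, beq, lb, ub)
      if (r$status != "optimal") return(list(status = "infeasible", x = NULL))
      x <- r$x
    }
  } else {
    x <- pmin(pmax(as.numeric(x0), lb), ub)
    if (meq > 0 && max(abs(Aeq %*% x - beq)) > 1e-8 * max(1, max(abs(beq))))
      stop("qp_solve: supplied x0 does not satisfy the equality constraints")
  }

  bnd_tol <- 1e-11
  act_lo <- x - lb <= bnd_tol
  act_up <- ub - x <= bnd_tol & !act_lo
  fixed <- (ub - lb) <= bnd_tol         # permanently pinned variables

  for (it in seq_len(maxit)) {
    idx_lo <- which(act_lo); idx_up <- which(act_up)
    nb <- length(idx_lo) + length(idx_up)
    Eb <- diag(1, n)[c(idx_lo, idx_up), , drop = FALSE]
    E <- rbind(Aeq, Eb)
    me <- nrow(E)
    grad <- as.vector(H %*% x) + g
    KKT <- rbind(cbind(H, t(E)), cbind(E, matrix(0, me, me)))
    rhs <- c(-grad, rep(0, me))
    sol <- tryCatch(solve(KKT, rhs), error = function(e) NULL)
    if (is.null(sol)) sol <- qr.solve(qr(KKT, LAPACK = TRUE), rhs)
    p <- sol[1:n]
    nu <- if (me > 0) sol[(n + 1L):(n + me)] else numeric(0)

    if (max(abs(p)) <= tol * max(1, max(abs(x)))) {
      ## stationary on working set: check bound multipliers
      ## Hx + g = -Aeq' nu_eq - sum nu_k e_k  =>  lower: mu = -nu_k >= 0,
      ## upper: mu = nu_k >= 0
      nu_b <- if (nb > 0) nu[(meq + 1L):me] else numeric(0)
      mult <- c(-nu_b[seq_along(idx_lo)],
                if (length(idx_up)) nu_b[length(idx_lo) + seq_along(idx_up)] else numeric(0))
      rel_ok <- c(!fixed[idx_lo], !fixed[idx_up])
      viol <- which(mult < -1e-9 * max(1, max(abs(grad))) & rel_ok)
      if (length(viol) == 0L)
        return(list(status = "optimal", x = x, nu_eq = nu[seq_len(meq)],
                    iterations = it))
      drop <- viol[which.min(mult[viol])]
      k <- c(idx_lo, idx_up)[drop]
      if (drop <= length(idx_lo)) act_lo[k] <- FALSE else act_up[k] <- FALSE
      next
    }
    ## step to nearest blocking inactive bound
    alpha <- 1; block <- 0L; block_up <- FALSE
    for (k in seq_len(n)) {
      if (act_lo[k] || act_up[k]) next
      if (p[k] > tol) {
        a <- (ub[k] - x[k]) / p[k]
        if (a < alpha - 1e-14) { alpha <- a; block <- k; block_up <- TRUE }
      } else if (p[k] < -tol) {
        a <- (lb[k] - x[k]) / p[k]
        if (a < alpha - 1e-14) { alpha <- a; block <- k; block_up <- FALSE }
      }
    }
    alpha <- max(alpha, 0)
    x <- x + alpha * p
    if (block > 0L) {
      if (block_up) { x[block] <- ub[block]; act_up[block] <- TRUE }
      else { x[block] <- lb[block]; act_lo[block] <- TRUE }
    }
  }
  stop("qp_solve: active-set iteration limit reached")
}
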