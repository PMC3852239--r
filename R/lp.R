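## Dense bounded-variable two-phase primal simplex.
##
## No linear-programming package ships with this R stack, so flux balance
## analysis and the thermodynamic feasibility test run on this small solver.
## It is written for the toy-to-medium networks the package targets
## (hundreds of variables at most): the basis is refactorised by a dense
## solve at every pivot, and Bland's smallest-index rule is used throughout,
## which makes the solution path deterministic and cycling-free.

## min c'x  s.t.  A x = b,  lb <= x <= ub  (all bounds finite)
## Returns list(status, x, objective, basis, atub).
## status: "optimal" | "infeasible".  `warm` may carry basis/atub from a prior
## solve of a problem with the same A to skip phase 1 (used heavily by the
## flux-variability scans inside geometric FBA).
lp_solve <- function(cvec, A, b, lb, ub, tol = 1e-9, maxit = 50000L, warm = NULL) {
  A <- as.matrix(A)
  m <- nrow(A); n <- ncol(A)
  cvec <- as.numeric(cvec); b <- as.numeric(b)
  lb <- as.numeric(lb); ub <- as.numeric(ub)
  stopifnot(length(cvec) == n, length(b) == m, length(lb) == n, length(ub) == n)
  if (!all(is.finite(lb)) || !all(is.finite(ub)))
    stop("lp_solve requires finite bounds")
  if (any(lb > ub + 1e-12)) return(list(status = "infeasible", x = NULL, objective = NA_real_))
  ub <- pmax(ub, lb)

  if (m == 0L) { # box-only problem
    x <- ifelse(cvec > 0, lb, ub)
    return(list(status = "optimal", x = x, objective = sum(cvec * x)))
  }
  nt <- n + m

  ## warm start: reuse a feasible basis, skip phase 1
  if (!is.null(warm) && length(warm$basis) == m && length(warm$atub) == nt) {
    Aa <- cbind(A, diag(1, m))
    lba <- c(lb, rep(0, m)); uba <- c(ub, rep(0, m))
    basis <- warm$basis; atub <- warm$atub
    xa <- ifelse(atub, uba, lba)
    nb <- setdiff(seq_len(nt), basis)
    rhs <- b - as.vector(Aa[, nb, drop = FALSE] %*% xa[nb])
    xB <- tryCatch(solve(Aa[, basis, drop = FALSE], rhs), error = function(e) NULL)
    if (!is.null(xB)) {
      xa[basis] <- xB
      ok <- all(xa >= lba - 1e-7) && all(xa <= uba + 1e-7)
      if (ok) {
        xa <- pmin(pmax(xa, lba), uba)
        c2 <- c(cvec, rep(0, m))
        st2 <- simplex_pivot(Aa, c2, lba, uba, basis, xa, atub, tol, maxit)
        if (st2$status == "optimal") {
          x <- st2$x[1:n]
          return(list(status = "optimal", x = x, objective = sum(cvec * x),
                      basis = st2$basis, atub = st2$atub))
        }
      }
    }
    ## fall through to a cold start on any inconsistency
  }

  ## start all structural variables at the bound of smaller magnitude
  x0 <- ifelse(abs(lb) <= abs(ub), lb, ub)
  r <- b - as.vector(A %*% x0)
  sgn <- ifelse(r >= 0, 1, -1)
  Aa <- cbind(A, diag(sgn, nrow = m, ncol = m))
  lba <- c(lb, rep(0, m))
  uba <- c(ub, abs(r) + 1)
  xa <- c(x0, abs(r))
  basis <- (n + 1L):nt
  at_upper <- abs(ub) < abs(lb)           # structural nonbasic status
  atub <- c(at_upper, rep(FALSE, m))

  scale <- max(1, max(abs(b)))
  ## phase 1: drive artificials to zero
  c1 <- c(rep(0, n), rep(1, m))
  st <- simplex_pivot(Aa, c1, lba, uba, basis, xa, atub, tol, maxit)
  if (st$status != "optimal") stop("simplex phase 1 failed: ", st$status)
  if (sum(st$x[(n + 1L):nt]) > 1e-7 * scale)
    return(list(status = "infeasible", x = NULL, objective = NA_real_))
  ## pin artificials at zero for phase 2
  lba[(n + 1L):nt] <- 0
  uba[(n + 1L):nt] <- 0
  xa <- st$x
  xa[(n + 1L):nt][abs(xa[(n + 1L):nt]) < 1e-7 * scale] <- 0
  c2 <- c(cvec, rep(0, m))
  st2 <- simplex_pivot(Aa, c2, lba, uba, st$basis, xa, st$atub, tol, maxit)
  if (st2$status != "optimal") stop("simplex phase 2 failed: ", st2$status)
  x <- st2$x[1:n]
  list(status = "optimal", x = x, objective = sum(cvec * x),
       basis = st2$basis, atub = st2$atub)
}

## core pivoting loop; mutates copies of its state and returns them
simplex_pivot <- function(Aa, ca, lba, uba, basis, xa, atub, tol, maxit) {
  m <- nrow(Aa); nt <- ncol(Aa)
  is_basic <- rep(FALSE, nt); is_basic[basis] <- TRUE
  for (it in seq_len(maxit)) {
    B <- Aa[, basis, drop = FALSE]
    y <- tryCatch(solve(t(B), ca[basis]), error = function(e) NULL)
    if (is.null(y)) stop("singular basis in simplex")
    d <- ca - as.vector(crossprod(Aa, y))
    enter <- 0L; dir <- 0
    for (j in seq_len(nt)) {               # Bland: smallest eligible index
      if (is_basic[j] || lba[j] == uba[j]) next
      if (!atub[j] && d[j] < -tol) { enter <- j; dir <- 1; break }
      if (atub[j] && d[j] > tol)   { enter <- j; dir <- -1; break }
    }
    if (enter == 0L)
      return(list(status = "optimal", x = xa, basis = basis, atub = atub))
    w <- solve(B, Aa[, enter])
    ## entering variable moves by t*dir >= 0; basic i changes by -dir*w[i]*t
    tmax <- uba[enter] - lba[enter]
    tbest <- tmax; leave_pos <- 0L; leave_to_upper <- FALSE
    for (i in seq_len(m)) {
      delta <- -dir * w[i]
      bi <- basis[i]
      if (delta > tol) {
        ti <- (uba[bi] - xa[bi]) / delta
        if (ti < tbest - 1e-12 ||
            (ti <= tbest + 1e-12 && (leave_pos == 0L || bi < basis[leave_pos]))) {
          tbest <- ti; leave_pos <- i; leave_to_upper <- TRUE
        }
      } else if (delta < -tol) {
        ti <- (xa[bi] - lba[bi]) / (-delta)
        if (ti < tbest - 1e-12 ||
            (ti <= tbest + 1e-12 && (leave_pos == 0L || bi < basis[leave_pos]))) {
          tbest <- ti; leave_pos <- i; leave_to_upper <- FALSE
        }
      }
    }
    tbest <- max(tbest, 0)
    if (!is.finite(tbest)) stop("unbounded direction in simplex (bounds not finite?)")
    xa[enter] <- xa[enter] + dir * tbest
    if (m > 0) xa[basis] <- xa[basis] - dir * tbest * w
    if (leave_pos == 0L) {                 # bound-to-bound flip
      atub[enter] <- !atub[enter]
      xa[enter] <- if (atub[enter]) uba[enter] else lba[enter]
    } else {
      old <- basis[leave_pos]
      xa[old] <- if (leave_to_upper) uba[old] else lba[old]
      atub[old] <- leave_to_upper
      is_basic[old] <- FALSE
      basis[leave_pos] <- enter
      is_basic[enter] <- TRUE
    }
  }
  list(status = "maxit", x = xa, basis = basis, atub = atub)
}
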