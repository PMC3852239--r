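## Step 1/2 of the workflow: a unique, thermodynamically exploitable
## stationary flux distribution (geometric FBA), export of the flux-carrying
## subnetwork with all fluxes made positive, and the sign-feasibility test.

#' Geometric flux balance analysis
#'
#' Computes the unique central stationary flux distribution: first the
#' objective flux is maximised by plain FBA, then -- with the objective pinned
#' at its optimum -- the total flux `sum(|v|)` is minimised (the minimal
#' sum-of-fluxes principle), and finally any remaining degeneracy on the
#' optimal face is removed by iteratively centring each flux inside its
#' flux-variability range until all ranges collapse.  The result is
#' deterministic and independent of reaction ordering (Bland-rule simplex
#' pivoting throughout).
#'
#' @param network a [stoichiometric_network()].
#' @param data_bundle optional [data_bundle()]; its flux entries constrain the
#'   corresponding reactions to `[lower, upper]`.
#' @param objective reaction id whose flux is maximised (the growth/biomass
#'   objective).
#' @param default_bound flux bound (mM/s) for reactions without data;
#'   reversible reactions get `[-default_bound, default_bound]`, irreversible
#'   ones `[0, default_bound]`.
#' @param range_tol flux-variability range below which the solution face is
#'   considered a point.
#' @return object of class `flux_distribution`: named flux vector `v` (mM/s),
#'   `objective_id`, `objective_value`, and the achieved `l1_norm`.
#' @export
geometric_fba <- function(network, data_bundle = NULL, objective,
                          default_bound = 1000, range_tol = 1e-9) {
  rids <- reaction_ids(network)
  if (!objective %in% rids)
    stop("objective '", objective, "' is not a reaction id")
  N <- network$N
  m <- nrow(N); n <- ncol(N)
  lb <- ifelse(vapply(network$reactions, `[[`, TRUE, "reversible"),
               -default_bound, 0)
  ub <- rep(default_bound, n)
  names(lb) <- names(ub) <- rids
  if (!is.null(data_bundle) && nrow(data_bundle$flux)) {
    fx <- data_bundle$flux[data_bundle$flux$reaction %in% rids, , drop = FALSE]
    lb[fx$reaction] <- fx$lower
    ub[fx$reaction] <- fx$upper
  }
  if (any(lb > ub))
    stop("infeasible flux bounds (lower > upper) for: ",
         paste(rids[lb > ub], collapse = ", "))

  ## phase A: maximise the objective
  cobj <- rep(0, n); cobj[match(objective, rids)] <- -1
  r1 <- lp_solve(cobj, N, rep(0, m), lb, ub)
  if (r1$status != "optimal")
    fba_infeasibility_report(network, data_bundle, lb, ub, default_bound)
  fstar <- -r1$objective

  ## phase B: minimise sum |v| with the objective fixed (split v = p - q)
  lb2 <- lb; ub2 <- ub
  iobj <- match(objective, rids)
  lb2[iobj] <- ub2[iobj] <- fstar
  big <- max(abs(lb), abs(ub)) + 1
  ## vars: v (n), p (n), q (n); rows: N v = 0 (m), v - p + q = 0 (n)
  A <- rbind(cbind(N, matrix(0, m, 2 * n)),
             cbind(diag(1, n), -diag(1, n), diag(1, n)))
  b <- rep(0, m + n)
  lbx <- c(lb2, rep(0, 2 * n)); ubx <- c(ub2, rep(big, 2 * n))
  cl1 <- c(rep(0, n), rep(1, 2 * n))
  r2 <- lp_solve(cl1, A, b, lbx, ubx)
  if (r2$status != "optimal") stop("L1 minimisation LP infeasible (internal)")
  l1 <- r2$objective

  ## phase C: centre within the optimal face.
  ## polytope: A x = b, bounds, sum(p+q) <= l1 (slack s0)
  A <- cbind(A, 0)
  A <- rbind(A, c(rep(0, n), rep(1, 2 * n), 1))
  b <- c(b, l1)
  lbx <- c(lbx, 0); ubx <- c(ubx, 1e-7 * max(1, l1))
  x <- c(r2$x, 0)
  v <- x[1:n]
  warm <- NULL
  for (iter in 1:10) {
    lo <- v; hi <- v
    for (j in seq_len(n)) {
      cj <- rep(0, ncol(A)); cj[j] <- 1
      rj <- lp_solve(cj, A, b, lbx, ubx, warm = warm)
      warm <- rj; lo[j] <- rj$x[j]
      rj <- lp_solve(-cj, A, b, lbx, ubx, warm = warm)
      warm <- rj; hi[j] <- rj$x[j]
    }
    mid <- (lo + hi) / 2
    if (max(hi - lo) < range_tol) {
      ## nail the final point: closest feasible point to the midpoints
      v <- centre_solve(A, b, lbx, ubx, mid, n)$v
      break
    }
    cs <- centre_solve(A, b, lbx, ubx, mid, n)
    v <- cs$v
    ## pin the attained distance and iterate on the remaining face
    A <- cs$A; b <- cs$b; lbx <- cs$lb; ubx <- cs$ub
    warm <- NULL
  }
  v <- setNames(v, rids)
  v[abs(v) < 1e-12] <- 0
  structure(list(v = v, objective_id = objective,
                 objective_value = unname(v[objective]), l1_norm = sum(abs(v))),
            class = "flux_distribution")
}

## minimise the L1 distance of v to `mid` over the polytope; returns the
## solution and the polytope extended with the distance pinned at its optimum
centre_solve <- function(A, b, lbx, ubx, mid, n) {
  nv <- ncol(A)
  big <- max(abs(lbx), abs(ubx)) + 1
  ## add d+ (n), d- (n), slack (1); rows v - d+ + d- = mid
  A2 <- rbind(cbind(A, matrix(0, nrow(A), 2 * n + 1)),
              cbind(diag(1, n), matrix(0, n, nv - n), -diag(1, n), diag(1, n),
                    rep(0, n)))
  b2 <- c(b, mid)
  lb2 <- c(lbx, rep(0, 2 * n + 1))
  ub2 <- c(ubx, rep(big, 2 * n), 0)  # slack closed until distance is known
  cc <- c(rep(0, nv), rep(1, 2 * n), 0)
  r <- lp_solve(cc, A2, b2, lb2, ub2)
  if (r$status != "optimal") stop("centring LP infeasible (internal)")
  dist <- r$objective
  ## pin sum(d+ + d-) <= dist via the slack row
  A2 <- rbind(A2, c(rep(0, nv), rep(1, 2 * n), 1))
  b2 <- c(b2, dist)
  ub2[length(ub2)] <- 1e-9 * max(1, dist)
  list(v = r$x[1:n], A = A2, b = b2, lb = lb2, ub = ub2)
}

## deletion-filter style irreducible conflict report for infeasible FBA input
fba_infeasibility_report <- function(network, data_bundle, lb, ub, default_bound) {
  rids <- reaction_ids(network)
  N <- network$N
  feasible <- function(l, u) {
    r <- lp_solve(rep(0, ncol(N)), N, rep(0, nrow(N)), l, u)
    r$status == "optimal"
  }
  data_rxns <- if (!is.null(data_bundle)) intersect(data_bundle$flux$reaction, rids)
               else character(0)
  lb0 <- ifelse(vapply(network$reactions, `[[`, TRUE, "reversible"),
                -default_bound, 0)
  ub0 <- rep(default_bound, length(rids))
  names(lb0) <- names(ub0) <- rids
  suspects <- data_rxns
  for (rid in data_rxns) {
    trial <- setdiff(suspects, rid)
    l <- lb0; u <- ub0
    l[trial] <- lb[trial]; u[trial] <- ub[trial]
    if (!feasible(l, u)) suspects <- trial  # still infeasible without rid
  }
  stop("infeasible flux constraints; irreducible conflicting bound set: {",
       paste(suspects, collapse = ", "), "}")
}

#' @export
print.flux_distribution <- function(x, ...) {
  cat(sprintf("Flux distribution: %d reactions, objective %s = %.6g mM/s, sum|v| = %.6g\n",
              length(x$v), x$objective_id, x$objective_value, sum(abs(x$v))))
  invisible(x)
}

#' Extract the active (flux-carrying) subnetwork
#'
#' Removes reactions with `|v| <= cutoff`, reverses reactions with negative
#' flux (stoichiometric signs flipped and flux negated so that every retained
#' flux is positive), and drops species that no longer participate in any
#' reaction.
#'
#' @param network a [stoichiometric_network()].
#' @param flux_distribution result of [geometric_fba()] (or a compatible
#'   object with a named `v`).
#' @param cutoff non-negative flux threshold (mM/s).  When `cutoff > 0`, a
#'   warning reminds the caller that geometric FBA must be re-run on the
#'   reduced network, since removing small but nonzero fluxes breaks
#'   stationarity.
#' @return list with elements `network` (the reduced, reoriented network) and
#'   `flux` (the matching all-positive `flux_distribution`).
#' @export
extract_active_subnetwork <- function(network, flux_distribution, cutoff = 0) {
  if (!is.numeric(cutoff) || length(cutoff) != 1L || cutoff < 0)
    stop("cutoff must be a non-negative scalar")
  v <- flux_distribution$v
  keep <- names(v)[abs(v) > cutoff]
  if (length(keep) == 0L) stop("no reaction carries flux above the cutoff")
  if (cutoff > 0)
    warning("cutoff > 0: geometric FBA should be re-run on the reduced network ",
            "to restore a stationary solution")
  reactions <- lapply(network$reactions[keep], function(r) {
    if (v[[r$id]] < 0) r$stoich <- -r$stoich
    r
  })
  used <- unique(c(unlist(lapply(reactions, function(r) names(r$stoich))),
                   unlist(lapply(reactions, function(r) r$modifiers$species))))
  species <- network$species[network$species$id %in% used, , drop = FALSE]
  net2 <- stoichiometric_network(species, unname(reactions))
  v2 <- abs(v[keep])
  obj <- flux_distribution$objective_id
  fd2 <- structure(list(v = v2,
                        objective_id = if (!is.null(obj) && obj %in% keep) obj else NA_character_,
                        objective_value = if (!is.null(obj) && obj %in% keep)
                          unname(v2[obj]) else NA_real_,
                        l1_norm = sum(v2)),
                   class = "flux_distribution")
  list(network = net2, flux = fd2)
}

#' Thermodynamic sign-feasibility of a flux distribution
#'
#' Tests whether chemical potentials exist under which every flux-carrying
#' reaction dissipates free energy, i.e. whether a potential vector `mu` over
#' the participating species satisfies `-sum_i n_ij mu_i >= eps` for every
#' reaction `j` carrying flux (reactions are oriented along their flux before
#' testing).  Boundary species receive free potentials as well: pathways
#' driven by external nutrients are feasible, while genuine futile cycles --
#' internal loops with no net turnover of boundary species -- are not.
#'
#' @param network a [stoichiometric_network()].
#' @param flux_distribution optional; reactions with `v == 0` are ignored and
#'   negative fluxes orient the test.  Without it all reactions are tested
#'   forward.
#' @param eps strict-inequality margin in (arbitrary) potential units.
#' @return list of class `feasibility_report`: `feasible`, `potentials`
#'   (named, when feasible), `violating_cycle` (reaction ids of a minimal
#'   infeasible loop, when infeasible).
#' @export
check_sign_feasibility <- function(network, flux_distribution = NULL, eps = 1) {
  Nfull <- stoich_matrix(network, internal_only = FALSE)
  if (!is.null(flux_distribution)) {
    v <- flux_distribution$v[colnames(Nfull)]
    active <- which(abs(v) > 0)
    Nfull <- Nfull[, active, drop = FALSE]
    Nfull <- sweep(Nfull, 2, sign(v[active]), `*`)
  }
  n <- ncol(Nfull)
  if (n == 0L) return(structure(list(feasible = TRUE, potentials = numeric(0)),
                                class = "feasibility_report"))
  keep_sp <- rowSums(Nfull != 0) > 0
  Ns <- Nfull[keep_sp, , drop = FALSE]
  m <- nrow(Ns)
  ## -Ns' mu - s = eps, s >= 0, |mu| <= 1e6
  A <- cbind(-t(Ns), -diag(1, n))
  b <- rep(eps, n)
  lb <- c(rep(-1e6, m), rep(0, n))
  ub <- c(rep(1e6, m), rep(2e6 * max(abs(Ns)) + eps, n))
  r <- lp_solve(rep(0, m + n), A, b, lb, ub)
  if (r$status == "optimal") {
    return(structure(list(feasible = TRUE,
                          potentials = setNames(r$x[1:m], rownames(Ns))),
                     class = "feasibility_report"))
  }
  ## Farkas: find y >= 0, Ns y = 0, sum y = 1 -- its support is a futile cycle
  A2 <- rbind(Ns, rep(1, n))
  b2 <- c(rep(0, m), 1)
  r2 <- lp_solve(rep(0, n), A2, b2, rep(0, n), rep(1, n))
  cyc <- if (r2$status == "optimal") colnames(Ns)[r2$x > 1e-8] else character(0)
  structure(list(feasible = FALSE, violating_cycle = cyc),
            class = "feasibility_report")
}

#' @export
print.feasibility_report <- function(x, ...) {
  if (x$feasible) cat("Flux directions are thermodynamically feasible.\n")
  else cat("Infeasible flux directions; violating cycle: ",
           paste(x$violating_cycle, collapse = " -> "), "\n")
  invisible(x)
}
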