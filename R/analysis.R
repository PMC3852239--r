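## Verification and characterisation of a constructed model: steady-state
## location, Jacobian stability, metabolic control analysis (MCA) and
## perturbation simulations.
##
## Conserved moieties (e.g. ATP + ADP) make the full Jacobian singular, so all
## computations run on the reduced system: independent species are chosen by
## QR factorisation with pivoting of the stoichiometric matrix over dynamic
## species, and the link matrix L maps changes of the independent species to
## changes of the full dynamic vector, N_dyn = L %*% N_R.

dynamic_species <- function(model) {
  sp <- model$network$species
  ids <- sp$id[!sp$boundary]
  ids[!vapply(ids, function(s) isTRUE(model$fixed[[s]]), TRUE)]
}

## stoichiometric matrix over dynamic (internal, non-fixed) species
dyn_stoich <- function(model) {
  N <- stoich_matrix(model$network, internal_only = FALSE)
  N[dynamic_species(model), , drop = FALSE]
}

## reduction to independent species: list(N_R, L, ind, dep)
link_matrix <- function(Nd, tol = 1e-10) {
  if (nrow(Nd) == 0L) stop("structural error: no dynamic species")
  q <- qr(t(Nd), tol = tol)
  r <- q$rank
  ind <- sort(q$pivot[seq_len(r)])
  NR <- Nd[ind, , drop = FALSE]
  ## L solves Nd = L NR  (rows of NR span the row space of Nd)
  L <- t(solve(tcrossprod(NR), NR %*% t(Nd)))
  dimnames(L) <- list(rownames(Nd), rownames(NR))
  list(N_R = NR, L = L, ind = ind, dep = setdiff(seq_len(nrow(Nd)), ind))
}

#' Elasticity matrix at a given state
#'
#' Analytic partial derivatives `E[j, i] = d rate_j / d c_i` of every rate law
#' with respect to the dynamic (internal, non-fixed) species.
#'
#' @param model a `kinetic_model`.
#' @param conc named concentrations; defaults to the construction state.
#' @return matrix reactions x dynamic species (mM/s per mM).
#' @export
elasticity_matrix <- function(model, conc = model$conc) {
  dyn <- dynamic_species(model)
  rids <- reaction_ids(model$network)
  E <- matrix(0, length(rids), length(dyn), dimnames = list(rids, dyn))
  for (rid in rids)
    E[rid, ] <- eval_drate(model$network$reactions[[rid]], model$laws[[rid]],
                           conc, dyn)
  E
}

## right-hand side and Jacobian of the reduced ODE system
model_odes <- function(model) {
  dyn <- dynamic_species(model)
  Nd <- dyn_stoich(model)
  full0 <- model$conc
  f <- function(cd) {
    cc <- full0; cc[dyn] <- cd
    as.vector(Nd %*% model_rates(model, cc))
  }
  jac <- function(cd) {
    cc <- full0; cc[dyn] <- cd
    Nd %*% elasticity_matrix(model, cc)
  }
  list(f = f, jac = jac, Nd = Nd, dyn = dyn)
}

#' Locate a steady state
#'
#' Damped Newton iteration on the reduced (moiety-conserved) system, with an
#' ODE-relaxation fallback when Newton stalls.  Conservation totals are those
#' of the starting state; fixed and boundary species are held constant.
#'
#' @param model a `kinetic_model` (assembled and rescaled).
#' @param c0 named starting concentrations (default: construction state).
#' @param tol stationarity tolerance on `max |N v|` (mM/s).
#' @param max_newton Newton iteration cap.
#' @return list: `conc` (full named vector), `flux`, `residual`, `converged`.
#' @export
find_steady_state <- function(model, c0 = NULL, tol = 1e-9, max_newton = 100L) {
  dyn <- dynamic_species(model)
  cc <- model$conc
  if (!is.null(c0)) cc[intersect(names(c0), names(cc))] <- c0[intersect(names(c0), names(cc))]
  Nd <- dyn_stoich(model)
  red <- link_matrix(Nd)
  x <- cc[dyn][red$ind]

  full_from_x <- function(x) {
    cd <- cc[dyn]
    cd_new <- cd + as.vector(red$L %*% (x - cc[dyn][red$ind]))
    cd_new[red$ind] <- x
    out <- cc; out[dyn] <- cd_new
    out
  }
  resid <- function(cfull) as.vector(red$N_R %*% model_rates(model, cfull))

  cfull <- full_from_x(x)
  r <- resid(cfull)
  for (it in seq_len(max_newton)) {
    if (max(abs(r)) < tol) break
    J <- red$N_R %*% elasticity_matrix(model, cfull) %*% red$L
    dx <- tryCatch(solve(J, -r), error = function(e) NULL)
    if (is.null(dx)) dx <- -qr.solve(qr(J, LAPACK = TRUE), r)
    step <- 1; improved <- FALSE
    for (k in 1:30) {
      xn <- x + step * dx
      cn <- full_from_x(xn)
      if (all(cn[dyn] > 0)) {
        rn <- resid(cn)
        if (max(abs(rn)) < max(abs(r))) {
          x <- xn; cfull <- cn; r <- rn; improved <- TRUE
          break
        }
      }
      step <- step / 2
    }
    if (!improved) {
      ## relax by integration, then resume Newton
      od <- model_odes(model)
      sc <- max(abs(od$jac(cfull[dyn])))
      t_relax <- if (is.finite(sc) && sc > 0) 100 / sc else 100
      sim <- ode_integrate(od$f, od$jac, cfull[dyn], t_end = t_relax, n_out = 2L)
      cfull[dyn] <- sim$y[2L, ]
      x <- cfull[dyn][red$ind]
      r <- resid(cfull)
    }
  }
  flux <- model_rates(model, cfull)
  res <- max(abs(Nd %*% flux))
  if (res > tol)
    warning("steady-state search did not reach tolerance (residual ",
            format(res), ")")
  list(conc = cfull, flux = flux, residual = res, converged = res <= tol)
}

#' Jacobian stability of a steady state
#'
#' Eigenvalues of the reduced Jacobian `N_R E L` at the given state; the state
#' is asymptotically stable iff every eigenvalue has a negative real part.
#'
#' @param model a `kinetic_model`.
#' @param conc steady-state concentrations (default: construction state).
#' @return list: `eigenvalues` (complex, 1/s), `is_stable`, `max_re`.
#' @export
stability <- function(model, conc = model$conc) {
  red <- link_matrix(dyn_stoich(model))
  J <- red$N_R %*% elasticity_matrix(model, conc) %*% red$L
  ev <- eigen(J, only.values = TRUE)$values
  list(eigenvalues = ev, is_stable = all(Re(ev) < 0), max_re = max(Re(ev)),
       jacobian = J)
}

#' Metabolic control analysis
#'
#' Control coefficients from the standard matrix identities on the reduced
#' system: unscaled `C_S = -L (N_R E L)^-1 N_R` and `C_J = I + E C_S`; scaled
#' variants normalise by steady-state fluxes and concentrations, so that
#' scaled flux-control rows sum to one and scaled concentration-control rows
#' to zero (summation theorems).
#'
#' @param model a `kinetic_model`.
#' @param state optional result of [find_steady_state()]; default: the
#'   construction state.
#' @return object of class `mca_result`: elasticities `E`, unscaled/scaled
#'   control matrices, Jacobian eigenvalues, overall control ranking.
#' @export
control_coefficients <- function(model, state = NULL) {
  cc <- if (is.null(state)) model$conc else state$conc
  v <- model_rates(model, cc)
  dyn <- dynamic_species(model)
  red <- link_matrix(dyn_stoich(model))
  E <- elasticity_matrix(model, cc)
  M <- red$N_R %*% E %*% red$L
  Minv <- tryCatch(solve(M), error = function(e)
    stop("structural error: singular (N_R E L) - zero-elasticity degenerate state"))
  CS <- -red$L %*% Minv %*% red$N_R          # dyn species x reactions
  CJ <- diag(1, length(v)) + E %*% CS        # reactions x reactions
  dimnames(CJ) <- list(names(v), names(v))
  dimnames(CS) <- list(dyn, names(v))
  CJs <- sweep(sweep(CJ, 2, v, `*`), 1, v, `/`)
  CSs <- sweep(sweep(CS, 2, v, `*`), 1, cc[dyn], `/`)
  st <- stability(model, cc)
  res <- structure(list(E = E, C_J = CJ, C_S = CS,
                        C_J_scaled = CJs, C_S_scaled = CSs,
                        flux = v, conc = cc,
                        jacobian_eigenvalues = st$eigenvalues,
                        is_stable = st$is_stable),
                   class = "mca_result")
  oc <- overall_flux_control(res)
  res$overall <- oc$overall
  res$high_control <- oc$high_control
  res
}

#' Overall flux control and high-control reactions
#'
#' The general flux control exerted by reaction `j` is the root sum of squares
#' of its scaled flux control coefficients,
#' `C_j = sqrt(sum_i (C^Ji_j)^2)`; the top 5% of reactions (rounded up) are
#' flagged high-control, ties broken by reaction id.
#'
#' @param result an `mca_result` (or any list with `C_J_scaled`).
#' @return list: named `overall`, character `high_control`.
#' @export
overall_flux_control <- function(result) {
  CJs <- result$C_J_scaled
  cj <- sqrt(colSums(CJs^2))
  k <- ceiling(0.05 * length(cj))
  ord <- order(-cj, names(cj))
  list(overall = cj, high_control = sort(names(cj)[ord[seq_len(k)]]))
}

#' @export
print.mca_result <- function(x, ...) {
  cat(sprintf("MCA at steady state (%d reactions, %d species):\n",
              ncol(x$C_J), nrow(x$C_S)))
  cat(sprintf("  stable: %s (max Re lambda = %.3g 1/s)\n", x$is_stable,
              max(Re(x$jacobian_eigenvalues))))
  cat(sprintf("  summation residuals: flux %.2g, concentration %.2g\n",
              max(abs(rowSums(x$C_J_scaled) - 1)), max(abs(rowSums(x$C_S_scaled)))))
  cat("  high-control reactions:", paste(x$high_control, collapse = ", "), "\n")
  invisible(x)
}

#' Finite-difference control coefficients (validation oracle)
#'
#' Perturbs each maximal velocity `u_j` by a small relative step, re-solves
#' the steady state, and differences the fluxes and concentrations.  Slower
#' but model-agnostic; used to cross-validate [control_coefficients()].
#'
#' @param model a rescaled `kinetic_model`.
#' @param rel_step relative perturbation of `u` (central differences).
#' @return list with `C_J_scaled` and `C_S_scaled` matrices.
#' @export
control_coefficients_fd <- function(model, rel_step = 1e-6) {
  rids <- reaction_ids(model$network)
  dyn <- dynamic_species(model)
  base <- find_steady_state(model, tol = 1e-12 * max(abs(model$target_flux)))
  J0 <- base$flux; c0 <- base$conc[dyn]
  CJ <- matrix(0, length(rids), length(rids), dimnames = list(rids, rids))
  CS <- matrix(0, length(dyn), length(rids), dimnames = list(dyn, rids))
  for (j in rids) {
    up <- model; up$laws[[j]]$u <- up$laws[[j]]$u * (1 + rel_step)
    dn <- model; dn$laws[[j]]$u <- dn$laws[[j]]$u * (1 - rel_step)
    su <- find_steady_state(up, c0 = base$conc, tol = 1e-13 * max(abs(J0)))
    sd <- find_steady_state(dn, c0 = base$conc, tol = 1e-13 * max(abs(J0)))
    CJ[, j] <- (su$flux - sd$flux) / (2 * rel_step) / J0
    CS[, j] <- (su$conc[dyn] - sd$conc[dyn]) / (2 * rel_step) / c0
  }
  list(C_J_scaled = CJ, C_S_scaled = CS)
}

#' Simulate the response to a boundary-species perturbation
#'
#' Multiplies the concentration of a fixed/boundary species by `factor` at
#' time zero, integrates the stiff ODE system for the internal species, and --
#' when `restore_at` is given -- resets the species to its original value at
#' that time, so that the relaxation back towards the original steady state
#' can be mapped.
#'
#' @param model a rescaled `kinetic_model`.
#' @param species id of a boundary or fixed species.
#' @param factor positive multiplier.
#' @param duration total simulated time (s).
#' @param restore_at time (s) at which the perturbation is removed (default:
#'   not removed).
#' @param n_out number of output time points.
#' @param relax_tol tolerance for the relaxation diagnostic.
#' @param rtol,atol local error tolerances of the implicit integrator.
#' @return object of class `perturbation_sim`: `times`, concentration matrix
#'   `conc`, flux matrix `flux`, and diagnostics `returned_to_reference`,
#'   `final_distance`, `final_residual`.
#' @export
simulate_perturbation <- function(model, species, factor, duration,
                                  restore_at = NULL, n_out = 201L,
                                  relax_tol = 1e-6, rtol = 1e-6, atol = 1e-10) {
  if (!species %in% model$network$species$id)
    stop("unknown species '", species, "'")
  if (!(isTRUE(model$fixed[[species]]) ||
        model$network$species$boundary[match(species, model$network$species$id)]))
    stop("'", species, "' is not a boundary/fixed species")
  if (!is.numeric(factor) || factor <= 0) stop("factor must be positive")

  ref <- model$conc
  pert <- model
  pert$conc[[species]] <- ref[[species]] * factor
  od <- model_odes(pert)
  dyn <- od$dyn
  y0 <- ref[dyn]

  run <- function(mod, y0, t_end, n_out) {
    od <- model_odes(mod)
    ode_integrate(od$f, od$jac, y0, t_end, n_out = n_out,
                  rtol = rtol, atol = atol)
  }
  if (!is.null(restore_at) && restore_at < duration) {
    n1 <- max(3L, round(n_out * restore_at / duration))
    s1 <- run(pert, y0, restore_at, n1)
    s2 <- run(model, s1$y[nrow(s1$y), ], duration - restore_at, n_out - n1 + 1L)
    times <- c(s1$times, restore_at + s2$times[-1])
    Y <- rbind(s1$y, s2$y[-1, , drop = FALSE])
    final_model <- model
  } else {
    s1 <- run(pert, y0, duration, n_out)
    times <- s1$times; Y <- s1$y
    final_model <- pert
  }
  flux <- t(apply(Y, 1, function(cd) {
    cc <- final_model$conc; cc[dyn] <- cd
    model_rates(final_model, cc)
  }))
  cf <- final_model$conc; cf[dyn] <- Y[nrow(Y), ]
  final_res <- max(abs(dyn_stoich(final_model) %*% model_rates(final_model, cf)))
  dist <- max(abs(Y[nrow(Y), ] - ref[dyn]) / pmax(abs(ref[dyn]), 1e-12))
  structure(list(times = times, conc = Y, flux = flux,
                 species = species, factor = factor,
                 returned_to_reference = dist < relax_tol,
                 final_distance = dist, final_residual = final_res),
            class = "perturbation_sim")
}

#' @export
print.perturbation_sim <- function(x, ...) {
  cat(sprintf("Perturbation: %s x %.3g, %d time points over %.4g s\n",
              x$species, x$factor, length(x$times), max(x$times)))
  cat(sprintf("  final relative distance to reference state: %.3g (%s)\n",
              x$final_distance,
              if (x$returned_to_reference) "returned" else "not returned"))
  invisible(x)
}

#' @export
plot.perturbation_sim <- function(x, what = c("conc", "flux"), ...) {
  what <- match.arg(what)
  Y <- x[[what]]
  matplot(x$times, Y, type = "l", lty = 1, xlab = "time (s)",
          ylab = if (what == "conc") "concentration (mM)" else "flux (mM/s)",
          main = sprintf("%s response to %s x %.3g", what, x$species, x$factor), ...)
  invisible(x)
}
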