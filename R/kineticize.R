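#' Build a thermodynamically consistent kinetic model from network and data
#'
#' One-shot fitting interface running the whole construction workflow:
#' \enumerate{
#'   \item geometric FBA for a unique stationary flux distribution matching
#'     the flux data ([geometric_fba()]);
#'   \item extraction of the flux-carrying subnetwork with all fluxes made
#'     positive ([extract_active_subnetwork()]);
#'   \item assignment of a complete concentration vector and of equilibrium
#'     constants satisfying the Wegscheider conditions, transport rule and
#'     flux-force bounds ([assign_concentrations()],
#'     [balance_equilibrium_constants()]);
#'   \item per-reaction parameter balancing of Michaelis and catalytic
#'     constants under the Haldane relationship ([balance_all()]);
#'   \item insertion of common modular rate laws (clamped linlog laws for
#'     biomass-type reactions), optional allosteric regulation
#'     ([assemble_kinetic_model()], [apply_regulation()]);
#'   \item rescaling of the maximal velocities so the model actualises the
#'     computed steady state ([rescale_vmax()]).
#' }
#'
#' @param network a [stoichiometric_network()] (e.g. from [read_network()]).
#' @param data a [data_bundle()] (e.g. from [read_data_bundle()]).
#' @param objective reaction id of the growth/biomass objective for FBA.
#' @param regulation optional regulation table (see [apply_regulation()]).
#' @param priors a [balancing_priors()] object.
#' @param cutoff flux cutoff for subnetwork extraction (default 0: keep every
#'   nonzero flux).
#' @param keq_margin flux-force margin (default 1.1).
#' @param ... passed to [geometric_fba()].
#' @return object of class `kinetic_model`; see [model_rates()],
#'   [find_steady_state()], [control_coefficients()],
#'   [simulate_perturbation()], [write_kinetic_model()] and the usual methods
#'   (`print`, `summary`, `coef`, `predict`, `fitted`, `residuals`,
#'   `simulate`, `plot`).
#' @export
kineticize <- function(network, data, objective, regulation = NULL,
                       priors = balancing_priors(), cutoff = 0,
                       keq_margin = 1.1, ...) {
  fd <- geometric_fba(network, data, objective, ...)
  ex <- extract_active_subnetwork(network, fd, cutoff = cutoff)
  if (cutoff > 0) {
    fd <- geometric_fba(ex$network, data,
                        if (!is.na(ex$flux$objective_id)) ex$flux$objective_id
                        else objective, ...)
    ex <- extract_active_subnetwork(ex$network, fd, cutoff = 0)
  }
  conc <- assign_concentrations(ex$network, data)
  ts <- balance_equilibrium_constants(ex$network, conc, data$keq,
                                      flux = ex$flux$v, margin = keq_margin)
  ps <- balance_all(ex$network, ts, data, priors)
  model <- assemble_kinetic_model(ex$network, ts, ps, ex$flux,
                                  regulation = regulation)
  model <- rescale_vmax(model)
  model$call <- match.call()
  model$full_network <- network
  model
}

#' @export
print.kinetic_model <- function(x, ...) {
  net <- x$network
  cat(sprintf("Kinetic model: %d reactions, %d species (%d boundary)\n",
              length(net$reactions), nrow(net$species), sum(net$species$boundary)))
  kinds <- table(vapply(x$laws, `[[`, "", "kind"))
  cat("  rate laws:", paste(sprintf("%s x %d", names(kinds), kinds), collapse = ", "), "\n")
  nreg <- sum(vapply(x$laws, function(l) NROW(l$regulation), 0L))
  if (nreg) cat(sprintf("  %d regulation term(s)\n", nreg))
  cat(sprintf("  rescaled to steady state: %s\n", x$rescaled))
  if (x$rescaled)
    cat(sprintf("  |N v(c*)| = %.3g mM/s\n",
                max(abs(dyn_stoich(x) %*% model_rates(x)))))
  invisible(x)
}

#' @export
summary.kinetic_model <- function(object, ...) {
  st <- stability(object)
  rates <- model_rates(object)
  res <- list(n_reactions = length(object$laws),
              n_species = nrow(object$network$species),
              flux_range = range(rates),
              steady_state_residual = max(abs(dyn_stoich(object) %*% rates)),
              rate_match_error = if (object$rescaled)
                max(abs(rates - object$target_flux) / object$target_flux) else NA,
              is_stable = st$is_stable,
              max_re_eigenvalue = st$max_re,
              keq = if (!is.null(object$thermo)) object$thermo$keq,
              wegscheider_residual = object$thermo$wegscheider_residual %||% NA)
  class(res) <- "summary.kinetic_model"
  res
}

#' @export
print.summary.kinetic_model <- function(x, ...) {
  cat("Kinetic model summary\n")
  cat(sprintf("  reactions: %d, species: %d\n", x$n_reactions, x$n_species))
  cat(sprintf("  steady-state residual |N v(c*)|: %.3g mM/s\n",
              x$steady_state_residual))
  if (!is.na(x$rate_match_error))
    cat(sprintf("  max relative rate/target mismatch: %.3g\n", x$rate_match_error))
  cat(sprintf("  stable: %s (max Re lambda = %.4g 1/s)\n", x$is_stable,
              x$max_re_eigenvalue))
  if (!is.null(x$keq))
    cat(sprintf("  keq range: [%.3g, %.3g]; Wegscheider residual %.2g\n",
                min(x$keq), max(x$keq), x$wegscheider_residual))
  invisible(x)
}

#' @export
coef.kinetic_model <- function(object, ...) {
  out <- c()
  for (rid in names(object$laws)) {
    l <- object$laws[[rid]]
    out[paste0(rid, ".u")] <- l$u
    if (l$kind == "common_modular") {
      out[paste0(rid, ".kcat_forward")] <- l$kcatf
      out[paste0(rid, ".kcat_backward")] <- l$kcatr
      for (s in names(l$km)) out[paste0(rid, ".km.", s)] <- l$km[[s]]
    } else {
      out[paste0(rid, ".vref")] <- l$vref
    }
    if (!is.null(object$thermo)) out[paste0(rid, ".keq")] <- object$thermo$keq[[rid]]
  }
  out
}

#' Predict reaction rates at given concentrations
#'
#' @param object a `kinetic_model`.
#' @param newdata named concentration vector (mM), a data frame with columns
#'   `species`/`conc`, or `NULL` for the construction state.
#' @param ... unused.
#' @return named vector of rates (mM/s).
#' @export
predict.kinetic_model <- function(object, newdata = NULL, ...) {
  conc <- object$conc
  if (!is.null(newdata)) {
    nd <- if (is.data.frame(newdata)) setNames(newdata$conc, newdata$species) else newdata
    conc[intersect(names(nd), names(conc))] <- nd[intersect(names(nd), names(conc))]
  }
  model_rates(object, conc)
}

#' @export
fitted.kinetic_model <- function(object, ...) object$target_flux

#' @export
residuals.kinetic_model <- function(object, ...) {
  model_rates(object) - object$target_flux
}

#' Simulate a kinetic model after a boundary perturbation
#'
#' `simulate()` method wrapping [simulate_perturbation()].
#'
#' @param object a rescaled `kinetic_model`.
#' @param nsim unused (one deterministic trajectory).
#' @param seed unused (the ODE solve is deterministic).
#' @param species boundary/fixed species to perturb; defaults to the first
#'   boundary species.
#' @param factor concentration multiplier (default 1.3, a 30% increase).
#' @param duration simulated time (s).
#' @param ... passed to [simulate_perturbation()].
#' @return a `perturbation_sim`.
#' @export
simulate.kinetic_model <- function(object, nsim = 1, seed = NULL,
                                   species = NULL, factor = 1.3,
                                   duration = 100, ...) {
  if (is.null(species))
    species <- object$network$species$id[object$network$species$boundary][1]
  simulate_perturbation(object, species, factor, duration, ...)
}

#' @export
plot.kinetic_model <- function(x, ...) {
  ev <- stability(x)$eigenvalues
  plot(Re(ev), Im(ev), xlab = "Re(lambda) (1/s)", ylab = "Im(lambda) (1/s)",
       main = "Jacobian spectrum at the constructed steady state", pch = 19, ...)
  abline(v = 0, lty = 2)
  invisible(x)
}
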