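## Steps 5-6: insert rate laws with the balanced constants, optionally add
## allosteric regulation, and rescale the maximal velocities so that the
## model actualises the predefined steady state exactly.

#' Assemble a kinetic model from the pipeline stages
#'
#' Every reaction receives a common modular rate law with the balanced
#' constants, except reactions flagged as biomass/growth/lipid production,
#' which receive a clamped linlog law referenced at the construction state.
#' The returned model is *not* yet rescaled: call [rescale_vmax()] (or use
#' [kineticize()], which does) before relying on the steady state.
#'
#' @param network oriented [stoichiometric_network()].
#' @param thermo_state result of [balance_equilibrium_constants()].
#' @param params a `parameter_set` from [balance_all()].
#' @param fluxes a `flux_distribution` (or named vector): the target
#'   steady-state fluxes (mM/s, all positive).
#' @param regulation optional regulation table (see [apply_regulation()]).
#' @param linlog_elasticities named-vector override of the linlog
#'   elasticities; default `|n_i|` for substrates, 0 for products.
#' @return object of class `kinetic_model`.
#' @export
assemble_kinetic_model <- function(network, thermo_state, params, fluxes,
                                   regulation = NULL,
                                   linlog_elasticities = NULL) {
  v <- if (inherits(fluxes, "flux_distribution")) fluxes$v else fluxes
  rids <- reaction_ids(network)
  if (!all(rids %in% names(v)))
    stop("target fluxes missing for: ", paste(setdiff(rids, names(v)), collapse = ", "))
  if (any(v[rids] <= 0))
    stop("all target fluxes must be positive (orient the network first)")
  conc <- setNames(thermo_state$conc$conc, thermo_state$conc$species)
  missing_sp <- setdiff(network$species$id, names(conc))
  if (length(missing_sp))
    stop("no concentration for species: ", paste(missing_sp, collapse = ", "))
  fixed <- setNames(thermo_state$conc$fixed, thermo_state$conc$species)
  fixed[network$species$id[network$species$boundary]] <- TRUE

  laws <- lapply(network$reactions, function(r) {
    if (r$biomass) {
      st <- r$stoich
      eps <- setNames(ifelse(st < 0, abs(st), 0), names(st))
      if (!is.null(linlog_elasticities)) {
        ov <- intersect(names(linlog_elasticities), names(eps))
        eps[ov] <- linlog_elasticities[ov]
      }
      list(kind = "linlog_clamped", u = 1, vref = unname(v[[r$id]]),
           eps = eps, cref = conc[names(st)], regulation = NULL)
    } else {
      p <- params[[r$id]]
      if (is.null(p)) stop("no balanced parameters for reaction '", r$id, "'")
      list(kind = "common_modular", u = 1, kcatf = p$kcatf, kcatr = p$kcatr,
           km = p$km, regulation = NULL)
    }
  })
  model <- structure(list(network = network, conc = conc[network$species$id],
                          fixed = fixed[network$species$id], laws = laws,
                          target_flux = v[rids], thermo = thermo_state,
                          posteriors = params, rescaled = FALSE),
                     class = "kinetic_model")
  if (!is.null(regulation)) model <- apply_regulation(model, regulation)
  model
}

#' Evaluate all reaction rates of a kinetic model
#'
#' @param model a `kinetic_model`.
#' @param conc named concentrations (mM); defaults to the construction state.
#' @return named vector of rates (mM/s).
#' @export
model_rates <- function(model, conc = model$conc) {
  vapply(reaction_ids(model$network), function(rid)
    eval_rate(model$network$reactions[[rid]], model$laws[[rid]], conc), 0)
}

#' Add allosteric regulation to an assembled model
#'
#' Each row multiplies the reaction rate by a hyperbolic prefactor:
#' `c/(c + K_A)` for activators, `K_I/(c + K_I)` for inhibitors.  Because the
#' prefactors change the rates at the construction state, [rescale_vmax()]
#' must be run afterwards so that the model actualises the same steady state
#' as the unregulated variant.
#'
#' @param model a `kinetic_model`.
#' @param regulation data frame with columns `reaction`, `species`, `mode`
#'   (`"activator"`/`"inhibitor"`) and `constant` (mM).
#' @return the model with regulation terms attached (`rescaled` reset).
#' @export
apply_regulation <- function(model, regulation) {
  if (is.null(regulation) || nrow(regulation) == 0L) return(model)
  regulation <- as.data.frame(regulation, stringsAsFactors = FALSE)
  need <- c("reaction", "species", "mode", "constant")
  if (!all(need %in% names(regulation)))
    stop("regulation table needs columns: ", paste(need, collapse = ", "))
  unk_r <- setdiff(regulation$reaction, reaction_ids(model$network))
  unk_s <- setdiff(regulation$species, model$network$species$id)
  if (length(unk_r) || length(unk_s))
    stop("validation error: unknown ids in regulation table - reactions: [",
         paste(unk_r, collapse = ", "), "], species: [",
         paste(unk_s, collapse = ", "), "]")
  if (!all(regulation$mode %in% c("activator", "inhibitor")))
    stop("regulation mode must be 'activator' or 'inhibitor'")
  if (any(regulation$constant <= 0)) stop("regulation constants must be positive")
  for (i in seq_len(nrow(regulation))) {
    rid <- regulation$reaction[i]
    model$laws[[rid]]$regulation <- rbind(model$laws[[rid]]$regulation,
                                          regulation[i, c("species", "mode", "constant")])
  }
  model$rescaled <- FALSE
  model
}

#' Rescale maximal velocities to actualise the target steady state
#'
#' The earlier stages guarantee that every rate already points in the
#' direction of its target flux; a positive per-reaction factor
#' `u_j <- u_j * v_j / rate_j(c*)` therefore suffices to make the model
#' stationary at the construction state: afterwards `rate_j(c*) = v_j`
#' exactly and `N %*% rate(c*) = 0`.
#'
#' @param model a `kinetic_model`.
#' @param target_fluxes named positive fluxes (default: the model's stored
#'   targets).
#' @return the rescaled model (`rescaled = TRUE`).
#' @export
rescale_vmax <- function(model, target_fluxes = model$target_flux) {
  rates <- model_rates(model)
  v <- target_fluxes[names(rates)]
  bad <- which(rates == 0 | sign(rates) != sign(v))
  if (length(bad))
    stop("scaling error: rate sign/zero mismatch at the construction state for ",
         paste(names(rates)[bad], collapse = ", "),
         " (upstream thermodynamic inconsistency)")
  for (rid in names(rates))
    model$laws[[rid]]$u <- model$laws[[rid]]$u * v[[rid]] / rates[[rid]]
  model$target_flux <- v
  model$rescaled <- TRUE
  model
}
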