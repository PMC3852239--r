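## Step 4: parameter balancing of the kinetic constants, reaction by reaction.
##
## With the equilibrium constant of each reaction predetermined (Step 3) and
## held fixed, the kinetic constants of a single reaction form a small
## Gaussian estimation problem in log-space.  The independent basis is
## {ln kcat+, ln KM_i}; ln kcat- is a dependent quantity through the Haldane
## relationship of the common modular rate law,
##     kcat+ / kcat- = keq * prod_i KM_i^(-n_i)
## (n_i signed, products positive), so every prior, pseudo value and datum is
## a linear map of the basis plus a fixed offset in ln keq.  The posterior
## mode is a box-constrained convex quadratic programme; the posterior
## covariance comes from the quadratic form, and mode = median in log-space.

#' Default priors, pseudo values and box bounds for parameter balancing
#'
#' Log-normal priors: median 10/s with geometric SD 10 for catalytic
#' constants, median 0.1 mM with geometric SD 10 for Michaelis constants; a
#' pseudo value on the velocity constant `sqrt(kcat+ * kcat-)` (median 10/s,
#' geometric SD 10) encodes prior knowledge on the dependent combination.
#' Box bounds keep modes inside physiological ranges.
#'
#' @param kcat_median,kcat_gsd,km_median,km_gsd,kv_median,kv_gsd prior
#'   medians/geometric SDs.
#' @param kcat_bounds,km_bounds two-element vectors (1/s and mM).
#' @param use_pseudo include the velocity-constant pseudo value.
#' @return a list of class `balancing_priors`.
#' @export
balancing_priors <- function(kcat_median = 10, kcat_gsd = 10,
                             km_median = 0.1, km_gsd = 10,
                             kv_median = 10, kv_gsd = 10,
                             kcat_bounds = c(1e-4, 1e4),
                             km_bounds = c(1e-4, 1e3),
                             use_pseudo = TRUE) {
  structure(list(kcat_median = kcat_median, kcat_gsd = kcat_gsd,
                 km_median = km_median, km_gsd = km_gsd,
                 kv_median = kv_median, kv_gsd = kv_gsd,
                 kcat_bounds = kcat_bounds, km_bounds = km_bounds,
                 use_pseudo = use_pseudo),
            class = "balancing_priors")
}

#' Inject default Michaelis-constant pseudo data
#'
#' For every (reaction, participant) pair lacking a KM datum, a pseudo datum
#' equal to the participant's steady-state concentration is added with the
#' default KM geometric SD -- the initialisation rule "KM starts at the
#' concentration of its metabolite".  Existing data are never overwritten;
#' boundary species receive pseudo data like any other participant.
#'
#' @param network a [stoichiometric_network()].
#' @param concentrations named vector or [assign_concentrations()] frame.
#' @param data_bundle a [data_bundle()]; its `km` table is extended.
#' @param gsd geometric SD attached to the injected pseudo data.
#' @return the data bundle with the augmented `km` table.
#' @export
default_km_initialisation <- function(network, concentrations, data_bundle,
                                      gsd = DEFAULT_GSD[["km"]]) {
  cvec <- if (is.data.frame(concentrations))
    setNames(concentrations$conc, concentrations$species) else concentrations
  have <- paste(data_bundle$km$reaction, data_bundle$km$species)
  add <- list()
  for (r in network$reactions) {
    for (s in names(r$stoich)) {
      if (paste(r$id, s) %in% have) next
      if (!s %in% names(cvec))
        stop("no concentration available for species '", s, "'")
      add[[length(add) + 1L]] <- data.frame(reaction = r$id, species = s,
                                            value = cvec[[s]], gsd = gsd)
    }
  }
  if (length(add)) data_bundle$km <- rbind(data_bundle$km, do.call(rbind, add))
  data_bundle
}

#' Balance the kinetic constants of a single reaction
#'
#' @param reaction a reaction of a [stoichiometric_network()] (named signed
#'   `stoich`).
#' @param keq the reaction's fixed equilibrium constant (from Step 3).
#' @param data_bundle a [data_bundle()]; its `km` and `kcat` entries for this
#'   reaction enter the likelihood.
#' @param priors a [balancing_priors()] object.
#' @return object of class `reaction_posterior`: data frame `quantities`
#'   (quantity, species, mode, median, gsd), the fixed `keq`, the Haldane
#'   residual (zero by construction) and the posterior covariance of the
#'   basis.
#' @export
balance_reaction <- function(reaction, keq, data_bundle = NULL,
                             priors = balancing_priors()) {
  if (!is.numeric(keq) || keq <= 0) stop("keq must be fixed and positive")
  st <- reaction$stoich
  sps <- names(st)
  nb <- 1L + length(sps)                # basis: ln kcat+, ln KM_i
  bn <- c("kcatf", paste0("km_", sps))
  lk <- log(keq)

  ## linear maps a'x + b of the basis for each nameable quantity
  map_kcatf <- list(a = c(1, rep(0, length(sps))), b = 0)
  map_km <- function(s) { a <- rep(0, nb); a[1 + match(s, sps)] <- 1; list(a = a, b = 0) }
  ## Haldane: ln kcat- = ln kcat+ - ln keq + sum_i n_i ln KM_i
  map_kcatr <- list(a = c(1, unname(st)), b = -lk)
  ## velocity constant ln kv = (ln kcat+ + ln kcat-)/2
  map_kv <- list(a = c(1, unname(st) / 2), b = -lk / 2)

  terms <- list()
  add_term <- function(map, y, sd) {
    terms[[length(terms) + 1L]] <<- list(a = map$a, b = map$b, y = y, sd = sd)
  }
  ## priors (kcat- prior acts through its linear map)
  add_term(map_kcatf, log(priors$kcat_median), log(priors$kcat_gsd))
  add_term(map_kcatr, log(priors$kcat_median), log(priors$kcat_gsd))
  for (s in sps) add_term(map_km(s), log(priors$km_median), log(priors$km_gsd))
  if (isTRUE(priors$use_pseudo))
    add_term(map_kv, log(priors$kv_median), log(priors$kv_gsd))
  ## data
  if (!is.null(data_bundle)) {
    kmd <- data_bundle$km[data_bundle$km$reaction == reaction$id, , drop = FALSE]
    for (i in seq_len(nrow(kmd))) {
      if (!kmd$species[i] %in% sps) next
      if (kmd$value[i] <= 0) stop("validation error: non-positive KM datum")
      add_term(map_km(kmd$species[i]), log(kmd$value[i]), log(kmd$gsd[i]))
    }
    kcd <- data_bundle$kcat[data_bundle$kcat$reaction == reaction$id, , drop = FALSE]
    for (i in seq_len(nrow(kcd))) {
      if (kcd$value[i] <= 0) stop("validation error: non-positive kcat datum")
      add_term(if (kcd$direction[i] == "forward") map_kcatf else map_kcatr,
               log(kcd$value[i]), log(kcd$gsd[i]))
    }
  }

  H <- matrix(0, nb, nb); g <- rep(0, nb)
  for (tm in terms) {
    w <- 1 / tm$sd^2
    H <- H + w * tcrossprod(tm$a)
    g <- g + w * tm$a * (tm$b - tm$y)
  }
  lo <- c(log(priors$kcat_bounds[1]), rep(log(priors$km_bounds[1]), length(sps)))
  hi <- c(log(priors$kcat_bounds[2]), rep(log(priors$km_bounds[2]), length(sps)))
  sol <- qp_solve(H, g, lb = lo, ub = hi,
                  x0 = pmin(pmax(rep(0, nb), lo), hi))
  if (!identical(sol$status, "optimal"))
    stop("numerical error: posterior mode optimisation failed for '",
         reaction$id, "'")
  x <- sol$x
  Sigma <- tryCatch(solve(H), error = function(e) {
    warning("singular posterior information for '", reaction$id,
            "'; covariance by pseudo-inverse")
    sv <- svd(H); pos <- sv$d > 1e-12 * max(sv$d)
    sv$v[, pos, drop = FALSE] %*% (t(sv$u[, pos, drop = FALSE]) / sv$d[pos])
  })

  qrow <- function(qty, species, map) {
    mode <- exp(sum(map$a * x) + map$b)
    gsd <- exp(sqrt(max(0, as.numeric(t(map$a) %*% Sigma %*% map$a))))
    data.frame(quantity = qty, species = species, mode = mode, median = mode,
               gsd = gsd, stringsAsFactors = FALSE)
  }
  q <- rbind(qrow("kcat_forward", NA, map_kcatf),
             qrow("kcat_backward", NA, map_kcatr),
             do.call(rbind, lapply(sps, function(s) qrow("km", s, map_km(s)))))
  kcf <- q$mode[1]; kcr <- q$mode[2]
  km <- setNames(q$mode[q$quantity == "km"], q$species[q$quantity == "km"])
  haldane_res <- log(kcf / kcr) - lk + sum(st * log(km))
  structure(list(reaction_id = reaction$id, quantities = q, keq = keq,
                 kcatf = kcf, kcatr = kcr, km = km,
                 haldane_residual = haldane_res, covariance = Sigma,
                 basis = setNames(x, bn)),
            class = "reaction_posterior")
}

#' @export
print.reaction_posterior <- function(x, ...) {
  cat(sprintf("Balanced constants for %s (keq = %.4g):\n", x$reaction_id, x$keq))
  print(x$quantities, row.names = FALSE)
  invisible(x)
}

#' Balance all reactions of a network
#'
#' Reaction-by-reaction parameter balancing; global consistency is inherited
#' because the shared quantities -- equilibrium constants and concentrations --
#' are fixed beforehand, so the independently balanced reactions can be
#' plugged together without losing thermodynamic feasibility.
#'
#' @param network a [stoichiometric_network()] (oriented).
#' @param thermo_state a `thermo_state` from
#'   [balance_equilibrium_constants()].
#' @param data_bundle a [data_bundle()].
#' @param priors a [balancing_priors()] object.
#' @param km_init inject the concentration-valued KM pseudo data
#'   ([default_km_initialisation()]) before balancing.
#' @return list of class `parameter_set`: one `reaction_posterior` per
#'   reaction.
#' @export
balance_all <- function(network, thermo_state, data_bundle = NULL,
                        priors = balancing_priors(), km_init = TRUE) {
  if (is.null(data_bundle)) data_bundle <- data_bundle()
  if (km_init) {
    data_bundle <- default_km_initialisation(network, thermo_state$conc, data_bundle)
  }
  out <- lapply(network$reactions, function(r) {
    tryCatch(balance_reaction(r, thermo_state$keq[[r$id]], data_bundle, priors),
             error = function(e) stop("balancing failed for reaction '", r$id,
                                      "': ", conditionMessage(e), call. = FALSE))
  })
  structure(out, class = "parameter_set")
}

#' @export
print.parameter_set <- function(x, ...) {
  cat(sprintf("Balanced parameter set: %d reactions, max |Haldane residual| = %.3g\n",
              length(x), max(abs(vapply(x, `[[`, 0, "haldane_residual")))))
  invisible(x)
}

#' @export
as.data.frame.parameter_set <- function(x, ...) {
  do.call(rbind, lapply(unclass(x), function(p) {
    q <- p$quantities
    q$reaction <- p$reaction_id
    q[, c("reaction", "quantity", "species", "mode", "median", "gsd")]
  }))
}
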