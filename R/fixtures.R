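## Deterministic toy fixtures with known ground truth.
##
## The generator builds small networks in which every consistency condition of
## the workflow holds *exactly by construction*, not by fitting:
##   - ln keq = -N_int' mu from chemical potentials of the internal species,
##     so the Wegscheider conditions K' ln(keq) = 0 are exact and transport
##     reactions (whose potential sums are constrained to zero) have keq = 1;
##   - chemical potentials and internal concentrations are found jointly by a
##     small feasibility LP that gives every reaction a positive thermodynamic
##     force with a randomised margin, the drive coming from the fixed
##     boundary concentrations (substrate-rich medium in, product-poor out);
##   - Michaelis and catalytic constants are drawn from the balancing priors
##     with the backward kcat fixed by the Haldane relationship;
##   - target fluxes are exact rational routings through the topology, and the
##     enzyme scalings u are chosen so the true model actualises them.
## The data bundle is the truth after masking and multiplicative log-normal
## noise.  Measured keq data are generated from noisy potentials, so they stay
## mutually Wegscheider-consistent and direction-consistent, as curated
## equilibrium data would be (the pipeline treats them as hard constraints).

FIXTURE_SCENARIOS <- c("linear_chain", "diamond", "cycle", "transporter",
                       "moiety", "regulated")

#' Generate a toy fixture with known ground truth
#'
#' @param scenario one of `"linear_chain"`, `"diamond"`, `"cycle"`,
#'   `"transporter"`, `"moiety"`, `"regulated"`.
#' @param size total species count, boundary species included (scenario
#'   minima: chain 4, cycle/regulated/transporter 5, diamond 6, moiety 8;
#'   maximum 50).
#' @param seed integer RNG seed; the fixture is reproducible from it.
#' @param mask_fraction fraction of kinetic/thermodynamic constants removed
#'   from the data bundle.
#' @param noise_sd_factor geometric SD of the multiplicative log-normal noise
#'   applied to bundle values (1 = no noise).
#' @param biomass_objective give the export reaction a biomass flag (it then
#'   receives a clamped linlog law during assembly).
#' @param pathway_flux flux through the main route (mM/s).
#' @return object of class `toy_fixture`: `network`, `truth` (concentrations,
#'   keq, kinetics, target fluxes and the true `kinetic_model`), `bundle`,
#'   `objective`, `regulation`, `scenario`, `seed`.
#' @export
make_fixture <- function(scenario = FIXTURE_SCENARIOS, size = 8, seed = 1,
                         mask_fraction = 0, noise_sd_factor = 1,
                         biomass_objective = FALSE, pathway_flux = 1) {
  scenario <- match.arg(scenario)
  if (mask_fraction < 0 || mask_fraction > 1) stop("mask_fraction must be in [0, 1]")
  if (noise_sd_factor < 1) stop("noise_sd_factor must be >= 1")
  if (size > 50) stop("impossible scenario/size combination: size > 50")
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(seed)

  topo <- switch(scenario,
                 linear_chain = topo_chain(size),
                 diamond = topo_diamond(size),
                 cycle = topo_cycle(size),
                 transporter = topo_transporter(size),
                 moiety = topo_moiety(size),
                 regulated = topo_chain(size, min_internal = 3))
  if (biomass_objective) {
    i <- which(vapply(topo$reactions, function(r) r$id == topo$objective, TRUE))
    topo$reactions[[i]]$biomass <- TRUE
  }
  net <- stoichiometric_network(topo$species, topo$reactions)
  v <- topo$v * pathway_flux

  th <- fixture_thermo(net, topo$boundary_conc, v)
  conc <- th$conc
  keq <- th$keq
  gam <- mass_action_ratios(net, conc)

  ## ground-truth kinetics: priors + exact Haldane
  laws <- list()
  for (r in net$reactions) {
    if (isTRUE(r$biomass)) {
      st <- r$stoich
      laws[[r$id]] <- list(kind = "linlog_clamped", u = 1, vref = unname(v[[r$id]]),
                           eps = setNames(ifelse(st < 0, abs(st), 0), names(st)),
                           cref = conc[names(st)], regulation = NULL)
      next
    }
    st <- r$stoich
    km <- setNames(rlnorm(length(st), log(conc[names(st)]), log(2)), names(st))
    kcatf <- rlnorm(1, log(10), log(3))
    kcatr <- exp(log(kcatf) - log(keq[[r$id]]) + sum(st * log(km)))
    laws[[r$id]] <- list(kind = "common_modular", u = 1, kcatf = kcatf,
                         kcatr = kcatr, km = km, regulation = NULL)
  }

  regulation <- NULL
  if (scenario == "regulated") {
    internal <- internal_species_ids(net)
    inhib <- internal[length(internal)]
    target <- "R1"
    regulation <- data.frame(reaction = target, species = inhib,
                             mode = "inhibitor",
                             constant = unname(conc[[inhib]]),
                             stringsAsFactors = FALSE)
    laws[[target]]$regulation <- regulation[, c("species", "mode", "constant")]
    i <- which(vapply(net$reactions, function(r) r$id == target, TRUE))
    net$reactions[[i]]$modifiers <- data.frame(species = inhib, mode = "inhibitor",
                                               stringsAsFactors = FALSE)
  }

  fixed <- setNames(net$species$boundary, net$species$id)
  truth_model <- structure(list(network = net, conc = conc, fixed = fixed,
                                laws = laws, target_flux = v,
                                thermo = NULL, posteriors = NULL,
                                rescaled = FALSE),
                           class = "kinetic_model")
  truth_model <- rescale_vmax(truth_model, v)

  cm_laws <- laws[vapply(laws, `[[`, "", "kind") == "common_modular"]
  truth <- list(conc = conc, keq = keq, gamma = gam, v = v,
                km = lapply(cm_laws, `[[`, "km"),
                kcatf = vapply(laws, function(l) l$kcatf %||% NA_real_, 0),
                kcatr = vapply(laws, function(l) l$kcatr %||% NA_real_, 0),
                u = vapply(truth_model$laws, `[[`, 0, "u"),
                potentials = th$mu,
                model = truth_model)

  bundle <- fixture_bundle(net, truth, regulation, mask_fraction, noise_sd_factor)

  structure(list(network = net, truth = truth, bundle = bundle,
                 objective = topo$objective, regulation = regulation,
                 scenario = scenario, size = size, seed = seed,
                 mask_fraction = mask_fraction,
                 noise_sd_factor = noise_sd_factor),
            class = "toy_fixture")
}

#' @export
print.toy_fixture <- function(x, ...) {
  cat(sprintf("Toy fixture '%s' (size %d, seed %d): %d reactions, mask %.2f, noise gsd %.2f\n",
              x$scenario, x$size, x$seed, length(x$network$reactions),
              x$mask_fraction, x$noise_sd_factor))
  invisible(x)
}

## ---------------------------------------------------------------------------
## scenario topologies; each returns species df, reaction list, exact flux
## routing v (unit pathway flux), objective id, boundary concentrations

chain_reactions <- function(ids, from, to) {
  mapply(function(id, a, b) list(id = id, stoich = setNames(c(-1, 1), c(a, b))),
         ids, from, to, SIMPLIFY = FALSE, USE.NAMES = FALSE)
}

topo_chain <- function(size, min_internal = 2L) {
  ni <- size - 2L
  if (ni < min_internal) stop("impossible scenario/size combination (need size >= ",
                              min_internal + 2L, ")")
  A <- paste0("A", seq_len(ni))
  species <- data.frame(id = c("Sx", A, "Px"),
                        compartment = c("extracellular", rep("cytosol", ni),
                                        "extracellular"),
                        boundary = c(TRUE, rep(FALSE, ni), TRUE))
  rx <- c(list(list(id = "T_in", stoich = c(Sx = -1, A1 = 1))),
          if (ni > 1) chain_reactions(paste0("R", seq_len(ni - 1)),
                                      A[-ni], A[-1]),
          list(list(id = "R_out", stoich = setNames(c(-1, 1), c(A[ni], "Px")))))
  v <- setNames(rep(1, length(rx)), vapply(rx, `[[`, "", "id"))
  list(species = species, reactions = rx, v = v, objective = "R_out",
       boundary_conc = c(Sx = 24.5, Px = 0.0245))
}

topo_diamond <- function(size) {
  ni <- size - 2L
  if (ni < 4L) stop("impossible scenario/size combination (need size >= 6)")
  nb <- ni - 2L
  l1 <- ceiling(nb / 2); l2 <- nb - l1
  B <- paste0("B", seq_len(l1)); C <- if (l2 > 0) paste0("C", seq_len(l2)) else character(0)
  species <- data.frame(id = c("Sx", "A", B, C, "D", "Px"),
                        compartment = c("extracellular", rep("cytosol", ni),
                                        "extracellular"),
                        boundary = c(TRUE, rep(FALSE, ni), TRUE))
  p1 <- c("A", B, "D"); p2 <- c("A", C, "D")
  rb <- chain_reactions(paste0("Rb", seq_len(length(p1) - 1)), p1[-length(p1)], p1[-1])
  rc <- chain_reactions(paste0("Rc", seq_len(length(p2) - 1)), p2[-length(p2)], p2[-1])
  rx <- c(list(list(id = "T_in", stoich = c(Sx = -1, A = 1))), rb, rc,
          list(list(id = "R_out", stoich = c(D = -1, Px = 1))))
  v <- setNames(c(1, rep(0.5, length(rb)), rep(0.5, length(rc)), 1),
                vapply(rx, `[[`, "", "id"))
  list(species = species, reactions = rx, v = v, objective = "R_out",
       boundary_conc = c(Sx = 24.5, Px = 0.0245))
}

topo_cycle <- function(size) {
  ## a shortcut A -> D in parallel with a path A -> C1 .. Ck -> D: the null
  ## space contains a loop vector, exercising the Wegscheider constraints
  ni <- size - 2L
  if (ni < 3L) stop("impossible scenario/size combination (need size >= 5)")
  k <- ni - 2L
  C <- paste0("C", seq_len(k))
  species <- data.frame(id = c("Sx", "A", C, "D", "Px"),
                        compartment = c("extracellular", rep("cytosol", ni),
                                        "extracellular"),
                        boundary = c(TRUE, rep(FALSE, ni), TRUE))
  path <- c("A", C, "D")
  rp <- chain_reactions(paste0("Rp", seq_len(length(path) - 1)),
                        path[-length(path)], path[-1])
  rx <- c(list(list(id = "T_in", stoich = c(Sx = -1, A = 1)),
               list(id = "R_short", stoich = c(A = -1, D = 1))), rp,
          list(list(id = "R_out", stoich = c(D = -1, Px = 1))))
  v <- setNames(c(1, 0.5, rep(0.5, length(rp)), 1), vapply(rx, `[[`, "", "id"))
  list(species = species, reactions = rx, v = v, objective = "R_out",
       boundary_conc = c(Sx = 24.5, Px = 0.0245))
}

topo_transporter <- function(size) {
  ni <- size - 2L
  if (ni < 3L) stop("impossible scenario/size combination (need size >= 5)")
  A <- paste0("A", seq_len(ni))
  half <- ceiling(ni / 2)
  comp <- c(rep("cytosol", half), rep("mitochondrion", ni - half))
  species <- data.frame(id = c("Sx", A, "Px"),
                        compartment = c("extracellular", comp, "extracellular"),
                        boundary = c(TRUE, rep(FALSE, ni), TRUE))
  rx <- c(list(list(id = "T_in", stoich = c(Sx = -1, A1 = 1))),
          if (ni > 1) chain_reactions(paste0("R", seq_len(ni - 1)), A[-ni], A[-1]),
          list(list(id = "R_out", stoich = setNames(c(-1, 1), c(A[ni], "Px")))))
  v <- setNames(rep(1, length(rx)), vapply(rx, `[[`, "", "id"))
  list(species = species, reactions = rx, v = v, objective = "R_out",
       boundary_conc = c(Sx = 24.5, Px = 0.0245))
}

topo_moiety <- function(size) {
  ## chain whose first step consumes ATP (regenerated from a boundary fuel):
  ## ATP + ADP is a conserved moiety
  ni <- size - 4L        # boundary: Sx, Px, Fx (fuel), Wx (waste)
  if (ni < 4L) stop("impossible scenario/size combination (need size >= 8)")
  k <- ni - 2L           # chain species besides ATP/ADP
  A <- paste0("A", seq_len(k))
  species <- data.frame(id = c("Sx", A, "ATP", "ADP", "Px", "Fx", "Wx"),
                        compartment = c("extracellular", rep("cytosol", k + 2),
                                        rep("extracellular", 3)),
                        boundary = c(TRUE, rep(FALSE, k + 2), TRUE, TRUE, TRUE))
  rx <- c(list(list(id = "T_in", stoich = c(Sx = -1, A1 = 1)),
               list(id = "R1", stoich = c(A1 = -1, ATP = -1, A2 = 1, ADP = 1))),
          if (k > 2) chain_reactions(paste0("R", seq(2, k - 1)), A[2:(k - 1)], A[3:k]),
          list(list(id = "R_regen", stoich = c(ADP = -1, Fx = -1, ATP = 1, Wx = 1)),
               list(id = "R_out", stoich = setNames(c(-1, 1), c(A[k], "Px")))))
  v <- setNames(rep(1, length(rx)), vapply(rx, `[[`, "", "id"))
  list(species = species, reactions = rx, v = v, objective = "R_out",
       boundary_conc = c(Sx = 24.5, Px = 0.0245, Fx = 100, Wx = 0.01))
}

## ---------------------------------------------------------------------------
## joint chemical potentials + internal concentrations by feasibility LP

fixture_thermo <- function(net, boundary_conc, v, base_margin = log(1.1) + 0.05) {
  Nint <- net$N
  Nfull <- stoich_matrix(net, internal_only = FALSE)
  ints <- rownames(Nint)
  bnds <- setdiff(rownames(Nfull), ints)
  m1 <- length(ints); n <- ncol(Nint)
  lcb <- log(boundary_conc[bnds])
  if (anyNA(lcb)) stop("missing boundary concentration")

  transport <- which(vapply(net$reactions, `[[`, TRUE, "transport"))
  ## margin jitter scaled to the available boundary drive
  drive <- -sum(v * as.vector(t(Nfull[bnds, , drop = FALSE]) %*% lcb)) / sum(v)
  jmax <- max(0.02, min(1, 0.8 * drive - base_margin))
  margins <- base_margin + runif(n, 0, jmax) * 0.5
  u_target <- rnorm(m1, log(0.549), 0.7)
  mu_target <- rnorm(m1, 0, 1.5)

  ## vars: mu (m1), u (m1), s (n slack), du+/- (m1), dm+/- (m1)
  nv <- 2 * m1 + n + 4 * m1
  iu <- m1 + seq_len(m1); is <- 2 * m1 + seq_len(n)
  idup <- 2 * m1 + n + seq_len(m1); idun <- idup + m1
  idmp <- idun + m1; idmn <- idmp + m1
  rows <- list(); rhs <- c()
  ## force rows: -(Nint' (mu + u))_j - s_j = margin_j + (Nbnd' lcb)_j
  Bc <- as.vector(t(Nfull[bnds, , drop = FALSE]) %*% lcb)
  for (j in seq_len(n)) {
    a <- rep(0, nv)
    a[seq_len(m1)] <- -Nint[, j]
    a[iu] <- -Nint[, j]
    a[is[j]] <- -1
    rows[[length(rows) + 1L]] <- a
    rhs <- c(rhs, margins[j] + Bc[j])
  }
  ## transport rows: (Nint' mu)_j = 0  (keq = 1)
  for (j in transport) {
    a <- rep(0, nv); a[seq_len(m1)] <- Nint[, j]
    rows[[length(rows) + 1L]] <- a
    rhs <- c(rhs, 0)
  }
  ## deviation rows
  for (i in seq_len(m1)) {
    a <- rep(0, nv); a[iu[i]] <- 1; a[idup[i]] <- -1; a[idun[i]] <- 1
    rows[[length(rows) + 1L]] <- a; rhs <- c(rhs, u_target[i])
    a <- rep(0, nv); a[i] <- 1; a[idmp[i]] <- -1; a[idmn[i]] <- 1
    rows[[length(rows) + 1L]] <- a; rhs <- c(rhs, mu_target[i])
  }
  A <- do.call(rbind, rows)
  lb <- c(rep(-50, m1), rep(log(1e-3), m1), rep(0, n), rep(0, 4 * m1))
  ub <- c(rep(50, m1), rep(log(100), m1), rep(100, n), rep(200, 4 * m1))
  cost <- rep(0, nv); cost[c(idup, idun)] <- 1; cost[c(idmp, idmn)] <- 0.1
  r <- lp_solve(cost, A, rhs, lb, ub)
  if (r$status != "optimal")
    stop("fixture thermodynamics LP infeasible for this scenario/size")
  mu <- setNames(r$x[seq_len(m1)], ints)
  cint <- setNames(exp(r$x[iu]), ints)
  conc <- c(cint, boundary_conc[bnds])[rownames(Nfull)]
  keq <- setNames(exp(-as.vector(t(Nint) %*% mu)), colnames(Nint))
  keq[transport] <- 1    # exact, not merely to LP tolerance
  force <- log(keq) - log(mass_action_ratios(net, conc))
  stopifnot(all(force >= log(1.1) - 1e-9))
  list(mu = mu, conc = conc, keq = keq)
}

## ---------------------------------------------------------------------------
## bundle = truth, masked and noised

fixture_bundle <- function(net, truth, regulation, mask_fraction, noise) {
  sdlog <- log(noise)
  noisy <- function(x) if (sdlog == 0) x else x * rlnorm(length(x), 0, sdlog)
  keep <- function(k) if (mask_fraction == 0) rep(TRUE, k)
          else runif(k) >= mask_fraction

  rids <- reaction_ids(net)
  ## keq data from noisy potentials: stays Wegscheider-consistent; shrink the
  ## potential noise until every measured keq remains direction-consistent
  mu <- truth$potentials
  Nint <- net$N
  lgam <- log(truth$gamma)
  eps <- rnorm(length(mu), 0, sdlog)
  transport <- vapply(net$reactions, `[[`, TRUE, "transport")
  if (any(transport)) {
    ## keep measured transporter keq exactly at 1: remove the noise component
    ## that the transport columns would see
    Nt <- Nint[, transport, drop = FALSE]
    eps <- eps - as.vector(Nt %*% qr.solve(crossprod(Nt), crossprod(Nt, eps)))
  }
  lkq <- NULL
  for (shrink in 0:30) {
    lkq <- -as.vector(t(Nint) %*% (mu + eps))
    lkq[transport] <- log(truth$keq[transport])  # snap to exact 1
    if (all(lkq >= log(1.1) + lgam - 1e-9)) break
    eps <- eps / 2
  }
  keq_df <- data.frame(reaction = rids, value = exp(lkq), gsd = max(noise, 1.0),
                       stringsAsFactors = FALSE)[keep(length(rids)), , drop = FALSE]

  km_rows <- do.call(rbind, lapply(names(truth$km), function(rid) {
    km <- truth$km[[rid]]
    data.frame(reaction = rid, species = names(km), value = unname(km),
               stringsAsFactors = FALSE)
  }))
  if (!is.null(km_rows) && nrow(km_rows)) {
    km_rows$value <- noisy(km_rows$value)
    km_rows$gsd <- max(noise, 1.2)
    km_rows <- km_rows[keep(nrow(km_rows)), , drop = FALSE]
  }

  kc_ids <- names(truth$kcatf)[!is.na(truth$kcatf)]
  kcat_rows <- rbind(
    data.frame(reaction = kc_ids, direction = "forward",
               value = noisy(truth$kcatf[kc_ids]), stringsAsFactors = FALSE),
    data.frame(reaction = kc_ids, direction = "backward",
               value = noisy(truth$kcatr[kc_ids]), stringsAsFactors = FALSE))
  kcat_rows$gsd <- max(noise, 1.2)
  kcat_rows <- kcat_rows[keep(nrow(kcat_rows)), , drop = FALSE]

  conc_df <- data.frame(species = names(truth$conc), value = unname(truth$conc),
                        fixed = setNames(net$species$boundary, net$species$id)[names(truth$conc)],
                        stringsAsFactors = FALSE)

  mod_df <- NULL
  if (!is.null(regulation)) {
    mod_df <- data.frame(reaction = regulation$reaction,
                         species = regulation$species,
                         value = noisy(regulation$constant),
                         gsd = max(noise, 1.2), stringsAsFactors = FALSE)
  }
  flux_conf <- if (sdlog == 0) 0 else 0.1
  data_bundle(flux = data.frame(reaction = names(truth$v), value = unname(truth$v)),
              conc = conc_df,
              keq = if (nrow(keq_df)) keq_df,
              km = if (!is.null(km_rows) && nrow(km_rows)) km_rows,
              kcat = if (nrow(kcat_rows)) kcat_rows,
              modifiers = mod_df,
              flux_confidence = flux_conf)
}

#' Run the full pipeline on a fixture and report recovery
#'
#' Executes geometric FBA, subnetwork extraction, concentration assignment,
#' equilibrium-constant balancing, parameter balancing, assembly and Vmax
#' rescaling on the fixture's data bundle, then compares the result against
#' the fixture's ground truth.
#'
#' @param fixture a [make_fixture()] object.
#' @param priors a [balancing_priors()] object.
#' @param include_regulation apply the fixture's regulation table (with the
#'   bundle's noisy modifier constants) before rescaling.
#' @return list of class `recovery_report`: the fitted `model`, steady-state
#'   residuals, Wegscheider/Haldane residuals, flux and keq errors, and
#'   log10 parameter errors of balanced modes vs. raw data.
#' @export
end_to_end_recovery <- function(fixture, priors = balancing_priors(),
                                include_regulation = TRUE) {
  net <- fixture$network
  bundle <- fixture$bundle
  fd <- geometric_fba(net, bundle, fixture$objective)
  ex <- extract_active_subnetwork(net, fd, cutoff = 0)
  conc <- assign_concentrations(ex$network, bundle)
  ts <- balance_equilibrium_constants(ex$network, conc, bundle$keq,
                                      flux = ex$flux$v)
  ps <- balance_all(ex$network, ts, bundle, priors)
  reg <- NULL
  if (include_regulation && !is.null(fixture$regulation)) {
    reg <- fixture$regulation
    for (i in seq_len(nrow(reg))) {
      hit <- bundle$modifiers$reaction == reg$reaction[i] &
        bundle$modifiers$species == reg$species[i]
      if (any(hit)) reg$constant[i] <- bundle$modifiers$value[which(hit)[1]]
    }
  }
  model <- assemble_kinetic_model(ex$network, ts, ps, ex$flux, regulation = reg)
  model <- rescale_vmax(model)
  ss_res <- max(abs(dyn_stoich(model) %*% model_rates(model)))
  st <- stability(model)

  K <- ex$network$K
  weg <- if (ncol(K) > 0) max(abs(t(K) %*% log(ts$keq))) else 0
  hal <- max(abs(vapply(ps, `[[`, 0, "haldane_residual")))

  tv <- fixture$truth$v[names(ex$flux$v)]
  flux_err <- max(abs(ex$flux$v - tv) / pmax(abs(tv), 1e-12))
  keq_err <- max(abs(log10(ts$keq / fixture$truth$keq[names(ts$keq)])))

  ## parameter errors: balanced modes vs truth, raw data vs truth (only for
  ## quantities with a datum)
  errs <- param_errors(fixture, ps)

  structure(list(model = model, flux = ex$flux, thermo = ts, posteriors = ps,
                 steady_state_residual = ss_res,
                 rate_match_error = max(abs(model_rates(model) - model$target_flux) /
                                          model$target_flux),
                 wegscheider_residual = weg, haldane_residual = hal,
                 flux_error = flux_err, keq_log10_error = keq_err,
                 stable = st$is_stable, eigenvalues = st$eigenvalues,
                 balanced_log10_errors = errs$balanced,
                 raw_log10_errors = errs$raw),
            class = "recovery_report")
}

param_errors <- function(fixture, ps) {
  truth <- fixture$truth
  bundle <- fixture$bundle
  bal <- c(); raw <- c()
  for (i in seq_len(nrow(bundle$km))) {
    rid <- bundle$km$reaction[i]; s <- bundle$km$species[i]
    tv <- truth$km[[rid]][[s]]
    if (is.null(tv) || is.null(ps[[rid]])) next
    bal <- c(bal, abs(log10(ps[[rid]]$km[[s]] / tv)))
    raw <- c(raw, abs(log10(bundle$km$value[i] / tv)))
  }
  for (i in seq_len(nrow(bundle$kcat))) {
    rid <- bundle$kcat$reaction[i]
    if (is.null(ps[[rid]])) next
    fw <- bundle$kcat$direction[i] == "forward"
    tv <- if (fw) truth$kcatf[[rid]] else truth$kcatr[[rid]]
    if (is.na(tv)) next
    bal <- c(bal, abs(log10((if (fw) ps[[rid]]$kcatf else ps[[rid]]$kcatr) / tv)))
    raw <- c(raw, abs(log10(bundle$kcat$value[i] / tv)))
  }
  list(balanced = bal, raw = raw)
}

#' @export
print.recovery_report <- function(x, ...) {
  cat("End-to-end recovery report:\n")
  cat(sprintf("  steady-state residual |N v(c*)|: %.3g mM/s\n", x$steady_state_residual))
  cat(sprintf("  max relative rate/target mismatch: %.3g\n", x$rate_match_error))
  cat(sprintf("  Wegscheider residual: %.3g, Haldane residual: %.3g\n",
              x$wegscheider_residual, x$haldane_residual))
  cat(sprintf("  flux error vs truth: %.3g, keq |log10| error: %.3g\n",
              x$flux_error, x$keq_log10_error))
  if (length(x$balanced_log10_errors))
    cat(sprintf("  median |log10| parameter error: balanced %.3g vs raw data %.3g\n",
                median(x$balanced_log10_errors), median(x$raw_log10_errors)))
  cat(sprintf("  stable steady state: %s\n", x$stable))
  invisible(x)
}
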