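## Step 3: a complete, thermodynamically consistent set of metabolite
## concentrations and equilibrium constants.  Concentrations are pragmatic:
## known values are held fixed and gaps are filled with compartment-class
## medians.  Equilibrium constants are then adjusted in log-space by
## constrained least squares so that the Wegscheider loop conditions
## K' ln(keq) = 0 hold exactly, transport reactions have keq = 1, measured
## keq are honoured as hard data, and every flux-carrying reaction keeps
## keq >= 1.1 * Gamma (its mass-action ratio plus the 10% margin), i.e. a
## positive thermodynamic force.

#' Assign a complete concentration vector
#'
#' Known concentrations are copied from the data bundle.  Unknown
#' intracellular species receive the median of the known intracellular
#' values, unknown extracellular species the median of the known
#' extracellular values (R's usual median convention: the mean of the central
#' pair for even counts).  Protons and inorganic phosphate are flagged as
#' fixed, as are boundary species.  Manual overrides are applied last.
#'
#' @param network a [stoichiometric_network()].
#' @param data_bundle a [data_bundle()] whose `conc` table holds the known
#'   values (mM).
#' @param extracellular_patterns regexes on compartment names identifying the
#'   extracellular class; boundary species always count as extracellular.
#' @param fixed_patterns regexes on species ids/names for species held at
#'   fixed concentration (default: protons, inorganic phosphate).
#' @param overrides named numeric vector of manual concentration overrides.
#' @param default_intracellular,default_extracellular fall-back values used
#'   when a class has unknowns but no known member at all.
#' @return data frame `species`, `conc` (mM), `fixed`, `known`.
#' @export
assign_concentrations <- function(network, data_bundle,
                                  extracellular_patterns = c("^e($|_)", "ext", "external", "out", "medium"),
                                  fixed_patterns = c("^h($|_|\\+)", "^proton", "^pi($|_)", "phosphate"),
                                  overrides = NULL,
                                  default_intracellular = NA_real_,
                                  default_extracellular = NA_real_) {
  sp <- network$species
  known <- setNames(data_bundle$conc$value, data_bundle$conc$species)
  known <- known[names(known) %in% sp$id]
  fixed_data <- data_bundle$conc$species[data_bundle$conc$fixed]

  is_extra <- sp$boundary |
    Reduce(`|`, lapply(extracellular_patterns, grepl, x = sp$compartment,
                       ignore.case = TRUE))
  conc <- setNames(rep(NA_real_, nrow(sp)), sp$id)
  conc[names(known)] <- known
  for (cls in c(FALSE, TRUE)) {
    idx <- which(is_extra == cls)
    miss <- idx[is.na(conc[idx])]
    if (!length(miss)) next
    have <- conc[idx][!is.na(conc[idx])]
    fill <- if (length(have)) median(have)
            else if (cls) default_extracellular else default_intracellular
    if (is.na(fill))
      stop("configuration error: no known ", if (cls) "extracellular" else "intracellular",
           " concentration and no default supplied")
    conc[miss] <- fill
  }
  fixed <- sp$boundary |
    sp$id %in% fixed_data |
    Reduce(`|`, lapply(fixed_patterns, function(p)
      grepl(p, sp$id, ignore.case = TRUE) | grepl(p, sp$name, ignore.case = TRUE)))
  if (!is.null(overrides)) {
    unknown <- setdiff(names(overrides), sp$id)
    if (length(unknown)) stop("override for unknown species: ",
                              paste(unknown, collapse = ", "))
    conc[names(overrides)] <- overrides
  }
  if (any(conc <= 0)) stop("validation error: non-positive concentration for ",
                           paste(names(conc)[conc <= 0], collapse = ", "))
  data.frame(species = sp$id, conc = unname(conc), fixed = fixed,
             known = sp$id %in% names(known), stringsAsFactors = FALSE)
}

#' Mass-action ratio of a reaction
#'
#' `Gamma = prod(products c^|n|) / prod(substrates c^|n|)` in the reaction's
#' current orientation; boundary species enter at their fixed concentrations.
#'
#' @param reaction a reaction element of a [stoichiometric_network()] (or any
#'   list with a named signed `stoich` vector).
#' @param concentrations named concentration vector (mM) covering every
#'   participant.
#' @return dimensionless scalar.
#' @export
mass_action_ratio <- function(reaction, concentrations) {
  st <- reaction$stoich
  missing <- setdiff(names(st), names(concentrations))
  if (length(missing))
    stop("data error: missing concentration for species: ",
         paste(missing, collapse = ", "))
  cc <- concentrations[names(st)]
  if (any(!is.finite(cc) | cc <= 0))
    stop("data error: non-positive concentration among participants of '",
         reaction$id, "'")
  exp(sum(st * log(cc)))
}

mass_action_ratios <- function(network, concentrations) {
  vapply(network$reactions, mass_action_ratio, 0, concentrations = concentrations)
}

#' Balance equilibrium constants under the Wegscheider conditions
#'
#' Produces a complete `keq` vector such that `t(K) %*% log(keq) = 0` (loop
#' products of equilibrium constants equal one), transport reactions have
#' `keq = 1`, reactions with measured values keep them exactly, and every
#' flux-carrying reaction retains `keq >= margin * Gamma` so that its
#' thermodynamic force is positive in the direction of flux.  Unknown
#' constants are found by least squares in log-space towards the target
#' `10 * Gamma` (one order of magnitude above the mass-action ratio), boxed
#' between `margin * Gamma` and `keq_max`.
#'
#' @param network oriented [stoichiometric_network()] (all fluxes positive,
#'   i.e. after [extract_active_subnetwork()]).
#' @param concentrations result of [assign_concentrations()] (or a named
#'   vector).
#' @param keq_data named vector of measured equilibrium constants (fixed data
#'   points), or the `keq` table of a [data_bundle()].
#' @param flux optional named flux vector; reactions with zero flux are
#'   exempt from the force bound.  Default: all reactions carry flux.
#' @param margin force margin (default 1.1: mass-action ratio + 10%).
#' @param keq_max upper bound for unknown equilibrium constants.
#' @return object of class `thermo_state`: `conc` data frame, named `keq`,
#'   named `gamma`, and the Wegscheider residual.
#' @export
balance_equilibrium_constants <- function(network, concentrations, keq_data = NULL,
                                          flux = NULL, margin = 1.1, keq_max = 1e6) {
  rids <- reaction_ids(network)
  n <- length(rids)
  conc_df <- if (is.data.frame(concentrations)) concentrations
             else data.frame(species = names(concentrations),
                             conc = unname(concentrations), fixed = FALSE)
  cvec <- setNames(conc_df$conc, conc_df$species)
  gam <- mass_action_ratios(network, cvec)
  lg <- log(gam)

  if (is.data.frame(keq_data)) keq_data <- setNames(keq_data$value, keq_data$reaction)
  keq_data <- keq_data[names(keq_data) %in% rids]
  if (length(keq_data) && any(keq_data <= 0)) stop("keq data must be positive")

  carrying <- if (is.null(flux)) setNames(rep(TRUE, n), rids)
              else setNames(abs(flux[rids]) > 0, rids)

  transport <- vapply(network$reactions, `[[`, TRUE, "transport")
  x <- setNames(rep(NA_real_, n), rids)      # ln keq
  ## measured data are hard constraints; the transport rule fills the rest
  x[rids[transport]] <- 0
  if (length(keq_data)) x[names(keq_data)] <- log(keq_data)
  fix <- !is.na(x)

  ## a fixed keq below the force bound contradicts the flux direction
  bad <- fix & carrying & (x < log(margin * gam) - 1e-9)
  if (any(bad))
    stop("thermodynamic conflict: fixed keq below ", margin, "*Gamma for ",
         paste(rids[bad], collapse = ", "),
         " (datum contradicts the flux direction)")

  K <- network$K
  lo <- ifelse(carrying, log(margin) + lg, -log(keq_max))
  hi <- rep(log(keq_max), n)
  hi <- pmax(hi, lo + 1e-9)
  target <- pmin(pmax(log(10) + lg, lo), hi)

  if (any(!fix)) {
    free <- which(!fix)
    if (ncol(K) > 0) {
      Aeq <- t(K[free, , drop = FALSE])
      beq <- -as.vector(t(K[fix, , drop = FALSE]) %*% x[fix])
      ## drop dependent rows
      keep <- independent_rows(Aeq)
      resid_chk <- if (length(keep) < nrow(Aeq)) {
        sol <- qr.solve(qr(Aeq[keep, , drop = FALSE], LAPACK = TRUE), beq[keep])
        max(abs(Aeq %*% sol - beq))
      } else 0
      Aeq <- Aeq[keep, , drop = FALSE]; beq <- beq[keep]
    } else { Aeq <- NULL; beq <- NULL }
    r <- qp_solve(diag(1, length(free)), -target[free], Aeq, beq,
                  lo[free], hi[free])
    if (!identical(r$status, "optimal"))
      stop("thermodynamic conflict: fixed equilibrium constants are ",
           "incompatible with the Wegscheider conditions and force bounds")
    x[free] <- r$x
  }
  ## verify the loop conditions over the full vector (fixed values included)
  wres <- if (ncol(K) > 0) max(abs(t(K) %*% x)) else 0
  if (wres > 1e-8)
    stop("thermodynamic conflict: fixed equilibrium constants violate the ",
         "Wegscheider conditions (residual ", format(wres), ")")
  keq <- exp(x)
  structure(list(conc = conc_df, keq = keq, gamma = gam,
                 wegscheider_residual = wres, margin = margin),
            class = "thermo_state")
}

independent_rows <- function(A, tol = 1e-10) {
  if (nrow(A) == 0L) return(integer(0))
  q <- qr(t(A), tol = tol)
  sort(q$pivot[seq_len(q$rank)])
}

#' @export
print.thermo_state <- function(x, ...) {
  cat(sprintf("Thermo state: %d concentrations, %d equilibrium constants\n",
              nrow(x$conc), length(x$keq)))
  cat(sprintf("  Wegscheider residual: %.3g; min keq/Gamma: %.4g\n",
              x$wegscheider_residual, min(x$keq / x$gamma)))
  invisible(x)
}
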