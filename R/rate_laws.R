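## Step 5: standard rate laws.
##
## The common modular rate law is a generalised reversible Michaelis-Menten
## kinetics valid for any stoichiometry,
##
##   v = u * reg(c) * [ kcat+ prod_sub (c/KM)^m  -  kcat- prod_prod (c/KM)^m ]
##       / [ prod_sub (1 + c/KM)^m + prod_prod (1 + c/KM)^m - 1 ]
##
## with molecularities m_i = |n_i|; the expanded denominator terms enumerate
## the binding states of a random-order enzyme mechanism.  reg(c) collects
## hyperbolic prefactors c/(c+KA) (activators) and KI/(c+KI) (inhibitors).
## Biomass/growth/lipid-production reactions instead use a linlog law clamped
## at zero: v = u * max(0, v_ref (1 + sum_i eps_i ln(c_i/c_ref,i))).

regulation_factor <- function(regulation, conc) {
  if (is.null(regulation) || nrow(regulation) == 0L) return(1)
  f <- 1
  for (i in seq_len(nrow(regulation))) {
    s <- regulation$species[i]; k <- regulation$constant[i]
    cs <- conc[[s]]
    if (is.null(cs) || is.na(cs)) stop("missing concentration for modifier '", s, "'")
    f <- f * if (regulation$mode[i] == "activator") cs / (cs + k) else k / (cs + k)
  }
  f
}

## d log(reg)/d c_s summed over rows for species s
regulation_dlog <- function(regulation, conc, s) {
  if (is.null(regulation) || nrow(regulation) == 0L) return(0)
  out <- 0
  for (i in seq_len(nrow(regulation))) {
    if (regulation$species[i] != s) next
    k <- regulation$constant[i]; cs <- conc[[s]]
    out <- out + if (regulation$mode[i] == "activator") k / (cs * (cs + k))
                 else -1 / (cs + k)
  }
  out
}

#' Common modular rate law
#'
#' @param reaction a reaction (named signed `stoich`, products positive).
#' @param params list with `u` (mM/s scale), `kcatf`, `kcatr` (1/s), `km`
#'   (named, mM, one per participant) and optional `regulation` data frame
#'   (`species`, `mode`, `constant`).
#' @param concentrations named vector (mM) covering all participants and
#'   modifiers.
#' @return rate in mM/s (positive in the direction of the products).
#' @export
common_modular_rate <- function(reaction, params, concentrations) {
  st <- reaction$stoich
  km <- params$km[names(st)]
  if (any(is.na(km) | km <= 0))
    stop("parameter error: missing or non-positive KM for reaction '",
         reaction$id, "'")
  cc <- concentrations[names(st)]
  if (any(is.na(cc) | cc < 0))
    stop("data error: missing concentration for participants of '", reaction$id, "'")
  m <- abs(st)
  r <- cc / km
  sub <- st < 0
  ps <- prod(r[sub]^m[sub]); pp <- prod(r[!sub]^m[!sub])
  ds <- prod((1 + r[sub])^m[sub]); dp <- prod((1 + r[!sub])^m[!sub])
  num <- params$kcatf * ps - params$kcatr * pp
  params$u * regulation_factor(params$regulation, concentrations) *
    num / (ds + dp - 1)
}

## analytic d rate / d conc for every species (participants + modifiers)
common_modular_drate <- function(reaction, params, concentrations, species) {
  st <- reaction$stoich
  km <- params$km[names(st)]
  cc <- concentrations[names(st)]
  m <- abs(st)
  r <- cc / km
  sub <- st < 0
  ps <- prod(r[sub]^m[sub]); pp <- prod(r[!sub]^m[!sub])
  ds <- prod((1 + r[sub])^m[sub]); dp <- prod((1 + r[!sub])^m[!sub])
  den <- ds + dp - 1
  reg <- regulation_factor(params$regulation, concentrations)
  num <- params$kcatf * ps - params$kcatr * pp
  rate <- params$u * reg * num / den
  vapply(species, function(s) {
    d <- 0
    if (s %in% names(st)) {
      i <- match(s, names(st))
      dnum <- if (sub[i]) params$kcatf * ps * m[i] / cc[i]
              else -params$kcatr * pp * m[i] / cc[i]
      dden <- if (sub[i]) ds * m[i] / (km[i] + cc[i]) else dp * m[i] / (km[i] + cc[i])
      d <- params$u * reg * (dnum * den - num * dden) / den^2
    }
    d + rate * regulation_dlog(params$regulation, concentrations, s)
  }, 0)
}

#' Linlog rate law with zero clamp
#'
#' `rate = u * max(0, v_ref * (1 + sum_i eps_i * ln(c_i / c_ref_i)))`; at the
#' reference state the rate equals `u * v_ref`.  Used for biomass, growth and
#' lipid-production reactions, where a saturable mechanistic law is not
#' meaningful and negative rates are clamped to zero.
#'
#' @param reaction a reaction (for its participant names).
#' @param params list with `u`, `vref` (mM/s), `eps` (named elasticities),
#'   `cref` (named reference concentrations, mM), optional `regulation`.
#' @param concentrations named vector (mM).
#' @return rate in mM/s.
#' @export
linlog_clamped_rate <- function(reaction, params, concentrations) {
  eps <- params$eps
  eps <- eps[eps != 0]
  if (length(eps)) {
    cref <- params$cref[names(eps)]
    cc <- concentrations[names(eps)]
    if (any(is.na(cref) | cref <= 0))
      stop("parameter error: non-positive reference concentration in linlog law")
    if (any(is.na(cc) | cc <= 0))
      stop("data error: non-positive concentration in linlog law for '",
           reaction$id, "'")
    lin <- 1 + sum(eps * log(cc / cref))
  } else lin <- 1
  params$u * regulation_factor(params$regulation, concentrations) *
    max(0, params$vref * lin)
}

linlog_drate <- function(reaction, params, concentrations, species) {
  eps <- params$eps; eps <- eps[eps != 0]
  lin <- if (length(eps))
    1 + sum(eps * log(concentrations[names(eps)] / params$cref[names(eps)]))
  else 1
  reg <- regulation_factor(params$regulation, concentrations)
  rate <- params$u * reg * max(0, params$vref * lin)
  vapply(species, function(s) {
    d <- 0
    if (params$vref * lin > 0 && s %in% names(eps))
      d <- params$u * reg * params$vref * eps[[s]] / concentrations[[s]]
    d + rate * regulation_dlog(params$regulation, concentrations, s)
  }, 0)
}

eval_rate <- function(reaction, law, concentrations) {
  if (law$kind == "common_modular") common_modular_rate(reaction, law, concentrations)
  else linlog_clamped_rate(reaction, law, concentrations)
}

eval_drate <- function(reaction, law, concentrations, species) {
  if (law$kind == "common_modular")
    common_modular_drate(reaction, law, concentrations, species)
  else linlog_drate(reaction, law, concentrations, species)
}
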