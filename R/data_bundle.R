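## The data bundle: sparse observed fluxes, concentrations, equilibrium and
## kinetic constants with multiplicative (geometric-SD) uncertainties, all in
## the package's canonical units mM, s, mM/s.

DEFAULT_GSD <- c(conc = 1.5, km = 1.5, kcat = 2.0, keq = 2.0, modifier = 1.5)

empty_df <- function(...) {
  cols <- list(...)
  as.data.frame(lapply(cols, function(cl) vector(cl, 0L)), stringsAsFactors = FALSE)
}

#' Construct a data bundle programmatically
#'
#' @param flux data frame `reaction`, `value` (mM/s) and optional
#'   `lower`/`upper` bounds; missing bounds default to
#'   `value*(1 -/+ flux_confidence)` (ordered so `lower <= upper` for negative
#'   values).
#' @param conc data frame `species`, `value` (mM), optional `gsd`, `fixed`.
#' @param keq data frame `reaction`, `value`, optional `gsd`.
#' @param km data frame `reaction`, `species`, `value` (mM), optional `gsd`.
#' @param kcat data frame `reaction`, `direction` ("forward"/"backward"),
#'   `value` (1/s), optional `gsd`.
#' @param modifiers data frame `reaction`, `species`, `value` (mM), optional
#'   `gsd` -- activation/inhibition constants of allosteric regulators.
#' @param flux_confidence relative half-width used for flux bounds when no
#'   explicit bounds are given (default 0.1).
#' @return object of class `data_bundle`.
#' @details Entries lacking an uncertainty receive the default geometric
#'   standard deviations 1.5 (concentrations, Michaelis and modifier
#'   constants) and 2.0 (catalytic and equilibrium constants).
#' @export
data_bundle <- function(flux = NULL, conc = NULL, keq = NULL, km = NULL,
                        kcat = NULL, modifiers = NULL, flux_confidence = 0.1) {
  fill_gsd <- function(df, def) {
    if (is.null(df$gsd)) df$gsd <- NA_real_
    df$gsd[is.na(df$gsd)] <- def
    if (nrow(df) && any(df$gsd < 1)) stop("geometric SDs must be >= 1")
    df
  }
  flux <- flux %||% empty_df(reaction = "character", value = "numeric",
                             lower = "numeric", upper = "numeric")
  flux <- as.data.frame(flux, stringsAsFactors = FALSE)
  if (nrow(flux)) {
    if (is.null(flux$lower)) flux$lower <- NA_real_
    if (is.null(flux$upper)) flux$upper <- NA_real_
    lo <- pmin(flux$value * (1 - flux_confidence), flux$value * (1 + flux_confidence))
    hi <- pmax(flux$value * (1 - flux_confidence), flux$value * (1 + flux_confidence))
    flux$lower[is.na(flux$lower)] <- lo[is.na(flux$lower)]
    flux$upper[is.na(flux$upper)] <- hi[is.na(flux$upper)]
    bad <- flux$lower > flux$value + 1e-12 | flux$upper < flux$value - 1e-12
    if (any(bad))
      stop("flux bounds must satisfy lower <= value <= upper; offending reactions: ",
           paste(flux$reaction[bad], collapse = ", "))
  }
  conc <- as.data.frame(conc %||% empty_df(species = "character", value = "numeric",
                                           gsd = "numeric", fixed = "logical"),
                        stringsAsFactors = FALSE)
  if (nrow(conc) && is.null(conc$fixed)) conc$fixed <- FALSE
  keq <- as.data.frame(keq %||% empty_df(reaction = "character", value = "numeric",
                                         gsd = "numeric"), stringsAsFactors = FALSE)
  km <- as.data.frame(km %||% empty_df(reaction = "character", species = "character",
                                       value = "numeric", gsd = "numeric"),
                      stringsAsFactors = FALSE)
  kcat <- as.data.frame(kcat %||% empty_df(reaction = "character",
                                           direction = "character",
                                           value = "numeric", gsd = "numeric"),
                        stringsAsFactors = FALSE)
  modifiers <- as.data.frame(modifiers %||% empty_df(reaction = "character",
                                                     species = "character",
                                                     value = "numeric", gsd = "numeric"),
                             stringsAsFactors = FALSE)
  for (nm in c("conc", "km", "modifiers")) {
    df <- get(nm)
    if (nrow(df) && any(!is.finite(df$value) | df$value <= 0)) {
      bad <- which(!is.finite(df$value) | df$value <= 0)
      stop("validation error: non-positive ", nm, " values in rows ",
           paste(bad, collapse = ", "))
    }
  }
  for (nm in c("keq", "kcat")) {
    df <- get(nm)
    if (nrow(df) && any(!is.finite(df$value) | df$value <= 0))
      stop("validation error: non-positive ", nm, " values")
  }
  if (nrow(kcat) && !all(kcat$direction %in% c("forward", "backward")))
    stop("kcat direction must be 'forward' or 'backward'")
  structure(list(flux = flux,
                 conc = fill_gsd(conc, DEFAULT_GSD[["conc"]]),
                 keq = fill_gsd(keq, DEFAULT_GSD[["keq"]]),
                 km = fill_gsd(km, DEFAULT_GSD[["km"]]),
                 kcat = fill_gsd(kcat, DEFAULT_GSD[["kcat"]]),
                 modifiers = fill_gsd(modifiers, DEFAULT_GSD[["modifier"]])),
            class = "data_bundle")
}

#' Read a data bundle from SBtab-like quantity tables
#'
#' Accepts one or several delimited text files (or data frames).  Each table
#' must have a header naming a `QuantityType` column plus `Reaction`,
#' `Compound` (or `Species`), `Value`, and optionally `Unit`, `Uncertainty`
#' (geometric SD), `Mode`/`Direction` (for catalytic constants), `Lower`,
#' `Upper` (for fluxes) and `IsFixed` (for concentrations).  Both tab- and
#' comma-separated files are accepted; the delimiter is sniffed from the
#' header line.
#'
#' Recognised quantity types (case-insensitive): `equilibrium constant`/`keq`,
#' `Michaelis constant`/`km`, `catalytic constant`/`kcat` (with direction, or
#' the shorthands `kcat+`/`kcat-`), `concentration`, `flux`/`rate`,
#' `activation constant`/`ka`, `inhibition constant`/`ki`.  Values are
#' unit-normalised to mM, 1/s and mM/s.
#'
#' @param x path(s) to delimited files, a data frame, or a list of data frames.
#' @param network optional [stoichiometric_network()]; when given, rows whose
#'   reaction or species ids are unknown are reported via a warning (they are
#'   kept in the bundle, not silently dropped).
#' @param flux_confidence see [data_bundle()].
#' @return a [data_bundle()].
#' @export
read_data_bundle <- function(x, network = NULL, flux_confidence = 0.1) {
  tabs <- if (is.data.frame(x)) list(x)
  else if (is.character(x)) lapply(x, read_sbtab_file)
  else if (is.list(x)) lapply(x, as.data.frame)
  else stop("x must be file path(s) or data frame(s)")

  rows <- do.call(rbind, lapply(tabs, normalise_sbtab))
  pick <- function(kind) rows[rows$kind == kind, , drop = FALSE]

  cv <- function(df) { # unit conversion to mM / 1/s / mM/s
    if (!nrow(df)) return(df)
    u <- tolower(trimws(df$unit)); u[is.na(u) | u == ""] <- "default"
    fac <- rep(1, nrow(df))
    fac[u %in% c("m", "mol/l", "mol/litre", "molar")] <- 1e3
    fac[u %in% c("um", "\u00b5m", "micromolar", "umol/l")] <- 1e-3
    fac[u %in% c("nm", "nanomolar")] <- 1e-6
    fac[u %in% c("1/min", "min-1", "per minute")] <- 1 / 60
    fac[u %in% c("m/s", "mol/l/s")] <- 1e3
    fac[u %in% c("mm/min", "mm min-1")] <- 1 / 60
    fac[u %in% c("mm/h", "mm/hr")] <- 1 / 3600
    known <- u %in% c("default", "mm", "mmol/l", "1/s", "s-1", "per second",
                      "mm/s", "dimensionless", "1", "m", "mol/l", "mol/litre",
                      "molar", "um", "\u00b5m", "micromolar", "umol/l", "nm",
                      "nanomolar", "1/min", "min-1", "per minute", "m/s",
                      "mol/l/s", "mm/min", "mm min-1", "mm/h", "mm/hr")
    if (any(!known))
      stop("unknown unit(s): ", paste(unique(df$unit[!known]), collapse = ", "))
    df$value <- df$value * fac
    df$lower <- df$lower * fac
    df$upper <- df$upper * fac
    df
  }
  rows <- cv(rows)

  neg <- rows$kind %in% c("conc", "km", "ka", "ki") & rows$value <= 0
  if (any(neg))
    stop("validation error: non-positive concentration/Michaelis/modifier constants in rows: ",
         paste(which(neg), collapse = ", "))

  fx <- pick("flux"); cc <- pick("conc"); ke <- pick("keq"); kmm <- pick("km")
  kc <- pick("kcat"); mod <- rbind(pick("ka"), pick("ki"))

  bundle <- data_bundle(
    flux = if (nrow(fx)) data.frame(reaction = fx$reaction, value = fx$value,
                                    lower = fx$lower, upper = fx$upper),
    conc = if (nrow(cc)) data.frame(species = cc$species, value = cc$value,
                                    gsd = cc$gsd, fixed = cc$fixed),
    keq = if (nrow(ke)) data.frame(reaction = ke$reaction, value = ke$value, gsd = ke$gsd),
    km = if (nrow(kmm)) data.frame(reaction = kmm$reaction, species = kmm$species,
                                   value = kmm$value, gsd = kmm$gsd),
    kcat = if (nrow(kc)) data.frame(reaction = kc$reaction, direction = kc$direction,
                                    value = kc$value, gsd = kc$gsd),
    modifiers = if (nrow(mod)) data.frame(reaction = mod$reaction, species = mod$species,
                                          value = mod$value, gsd = mod$gsd),
    flux_confidence = flux_confidence)

  if (!is.null(network)) {
    unk_r <- setdiff(c(bundle$flux$reaction, bundle$keq$reaction, bundle$km$reaction,
                       bundle$kcat$reaction, bundle$modifiers$reaction),
                     reaction_ids(network))
    unk_s <- setdiff(c(bundle$conc$species, bundle$km$species, bundle$modifiers$species),
                     network$species$id)
    if (length(unk_r) || length(unk_s)) {
      warning("data bundle references ids not in the network - reactions: [",
              paste(unk_r, collapse = ", "), "], species: [",
              paste(unk_s, collapse = ", "), "]")
      attr(bundle, "unknown_ids") <- list(reactions = unk_r, species = unk_s)
    }
  }
  bundle
}

read_sbtab_file <- function(path) {
  first <- readLines(path, n = 2L)
  first <- first[!startsWith(first, "!!")]  # SBtab declaration line
  sep <- if (grepl("\t", first[1])) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep, comment.char = "",
                          stringsAsFactors = FALSE, check.names = FALSE,
                          skip = if (length(readLines(path, n = 1L)) &&
                                     startsWith(readLines(path, n = 1L), "!!")) 1L else 0L)
  names(df) <- sub("^!", "", names(df))
  df
}

normalise_sbtab <- function(df) {
  nm <- tolower(gsub("[ _]", "", names(df)))
  col <- function(keys) {
    i <- which(nm %in% keys)
    if (length(i)) df[[i[1]]] else rep(NA, nrow(df))
  }
  qt <- tolower(trimws(as.character(col(c("quantitytype", "quantity", "type")))))
  if (all(is.na(qt))) stop("table lacks a QuantityType column")
  kind <- rep(NA_character_, length(qt))
  kind[grepl("^(keq|equilibriumconstant|equilibrium constant)$", qt)] <- "keq"
  kind[grepl("^(km|michaelisconstant|michaelis constant)$", qt)] <- "km"
  kind[grepl("^(kcat|catalyticconstant|catalytic constant|turnovernumber)", qt)] <- "kcat"
  kind[qt %in% c("kcat+", "kcatf", "forward catalytic constant")] <- "kcat"
  kind[qt %in% c("kcat-", "kcatr", "backward catalytic constant")] <- "kcat"
  kind[grepl("^(conc|concentration)$", qt)] <- "conc"
  kind[grepl("^(flux|rate|rateofreaction|rate of reaction)$", qt)] <- "flux"
  kind[grepl("^(ka|activationconstant|activation constant)$", qt)] <- "ka"
  kind[grepl("^(ki|inhibitionconstant|inhibition constant|inhibitoryconstant|inhibitory constant)$", qt)] <- "ki"
  if (anyNA(kind))
    stop("unrecognised quantity type(s): ", paste(unique(qt[is.na(kind)]), collapse = ", "))

  dir <- tolower(trimws(as.character(col(c("mode", "direction")))))
  dir[dir %in% c("fwd", "forward", "+", "f")] <- "forward"
  dir[dir %in% c("rev", "reverse", "backward", "-", "b", "r")] <- "backward"
  dir[qt %in% c("kcat+", "kcatf", "forward catalytic constant")] <- "forward"
  dir[qt %in% c("kcat-", "kcatr", "backward catalytic constant")] <- "backward"
  dir[kind == "kcat" & (is.na(dir) | dir == "")] <- "forward"

  rxn <- as.character(col(c("reaction", "reactionid", "reactionsbmlid")))
  spc <- as.character(col(c("compound", "species", "compoundid", "speciesid", "metabolite")))
  ## ids written as "R1:A" split into reaction and compound
  both <- grepl(":", rxn, fixed = TRUE) & (is.na(spc) | spc == "")
  spc[both] <- sub("^[^:]*:", "", rxn[both])
  rxn[both] <- sub(":.*$", "", rxn[both])

  fixed <- tolower(as.character(col(c("isfixed", "fixed")))) %in% c("true", "1", "yes")
  data.frame(kind = kind, reaction = rxn, species = spc,
             value = as.numeric(col("value")),
             unit = as.character(col("unit")),
             gsd = suppressWarnings(as.numeric(col(c("uncertainty", "geometricsd",
                                                     "geomsd", "gsd")))),
             direction = dir,
             lower = suppressWarnings(as.numeric(col(c("lower", "lowerbound", "min")))),
             upper = suppressWarnings(as.numeric(col(c("upper", "upperbound", "max")))),
             fixed = fixed, stringsAsFactors = FALSE)
}

#' @export
print.data_bundle <- function(x, ...) {
  cat("Data bundle:\n")
  for (nm in c("flux", "conc", "keq", "km", "kcat", "modifiers"))
    cat(sprintf("  %-10s %d entries\n", nm, nrow(x[[nm]])))
  invisible(x)
}
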