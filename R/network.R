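#' Construct a stoichiometric network
#'
#' The central structural container: species (internal or boundary), reactions
#' with signed stoichiometries (products positive), the stoichiometric matrix
#' `N` over internal species, and a null-space matrix `K` whose columns span
#' all stationary flux vectors \{v : N v = 0\}.
#'
#' @param species data frame with columns `id`, `name` (optional),
#'   `compartment` (optional, default "cell"), `boundary` (logical, optional).
#' @param reactions list; each element a list with `id`, `stoich` (named
#'   numeric vector of signed stoichiometric coefficients, products positive),
#'   and optionally `name`, `reversible` (default `TRUE`), `biomass`,
#'   `modifiers` (data frame with columns `species`, `mode` in
#'   `"activator"`/`"inhibitor"`).
#' @return object of class `sto_network` with elements `species`, `reactions`,
#'   `N` (internal species x reactions) and `K` (null-space matrix of `N`).
#' @details Transport reactions are flagged automatically as those whose
#'   participants span more than one compartment. Boundary species are kept in
#'   the species table (their concentrations are model parameters) but do not
#'   contribute rows to `N`.
#' @export
stoichiometric_network <- function(species, reactions) {
  species <- as.data.frame(species, stringsAsFactors = FALSE)
  if (is.null(species$name)) species$name <- species$id
  if (is.null(species$compartment)) species$compartment <- "cell"
  if (is.null(species$boundary)) species$boundary <- FALSE
  species$boundary <- as.logical(species$boundary)
  if (anyDuplicated(species$id))
    stop("duplicate species ids: ", paste(unique(species$id[duplicated(species$id)]), collapse = ", "))

  comp_of <- setNames(species$compartment, species$id)
  rids <- vapply(reactions, function(r) r$id, "")
  if (anyDuplicated(rids))
    stop("duplicate reaction ids: ", paste(unique(rids[duplicated(rids)]), collapse = ", "))

  reactions <- lapply(reactions, function(r) {
    st <- r$stoich
    st <- st[st != 0]
    if (length(st) == 0L) stop("reaction '", r$id, "' has an empty stoichiometry")
    unknown <- setdiff(names(st), species$id)
    if (length(unknown))
      stop("reaction '", r$id, "' references unknown species: ",
           paste(unknown, collapse = ", "))
    mods <- r$modifiers
    if (!is.null(mods) && nrow(mods)) {
      unknown <- setdiff(mods$species, species$id)
      if (length(unknown))
        stop("reaction '", r$id, "' has unknown modifier species: ",
             paste(unknown, collapse = ", "))
      if (!all(mods$mode %in% c("activator", "inhibitor")))
        stop("modifier mode must be 'activator' or 'inhibitor'")
    } else mods <- data.frame(species = character(0), mode = character(0))
    list(id = r$id,
         name = r$name %||% r$id,
         stoich = st,
         reversible = isTRUE(r$reversible %||% TRUE),
         transport = isTRUE(r$transport %||%
                              (length(unique(comp_of[names(st)])) > 1L)),
         biomass = isTRUE(r$biomass %||% FALSE),
         modifiers = mods)
  })
  names(reactions) <- rids

  net <- structure(list(species = species, reactions = reactions),
                   class = "sto_network")
  net$N <- stoich_matrix(net)
  net$K <- null_space(net$N)
  net
}

#' Stoichiometric matrix over internal species
#'
#' @param net a `sto_network`.
#' @param internal_only drop boundary species rows (the default; `FALSE` gives
#'   the full matrix over all species).
#' @return numeric matrix, rows named by species id, columns by reaction id.
#' @export
stoich_matrix <- function(net, internal_only = TRUE) {
  sp <- if (internal_only) net$species$id[!net$species$boundary] else net$species$id
  N <- matrix(0, length(sp), length(net$reactions),
              dimnames = list(sp, names(net$reactions)))
  for (r in net$reactions) {
    keep <- intersect(names(r$stoich), sp)
    N[keep, r$id] <- r$stoich[keep]
  }
  N
}

reaction_ids <- function(net) names(net$reactions)
internal_species_ids <- function(net) net$species$id[!net$species$boundary]

#' @export
print.sto_network <- function(x, ...) {
  nb <- sum(x$species$boundary)
  cat(sprintf("Stoichiometric network: %d species (%d boundary), %d reactions\n",
              nrow(x$species), nb, length(x$reactions)))
  cat(sprintf("  rank(N) = %d, dim null space = %d\n",
              matrix_rank(x$N), ncol(x$K)))
  tr <- sum(vapply(x$reactions, `[[`, TRUE, "transport"))
  if (tr) cat(sprintf("  %d transport reaction(s)\n", tr))
  invisible(x)
}

## rebuild a network from a species table + reaction list after edits
rebuild_network <- function(species, reactions) {
  stoichiometric_network(species, unname(reactions))
}
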