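# shared builders and independent oracles

chain_net <- function(ni = 2) {
  A <- paste0("A", seq_len(ni))
  sp <- data.frame(id = c("Sx", A, "Px"),
                   compartment = c("extracellular", rep("cytosol", ni), "extracellular"),
                   boundary = c(TRUE, rep(FALSE, ni), TRUE))
  rx <- c(list(list(id = "T_in", stoich = c(Sx = -1, A1 = 1))),
          if (ni > 1) lapply(seq_len(ni - 1), function(k)
            list(id = paste0("R", k),
                 stoich = setNames(c(-1, 1), c(A[k], A[k + 1])))),
          list(list(id = "R_out", stoich = setNames(c(-1, 1), c(A[ni], "Px")))))
  stoichiometric_network(sp, rx)
}

cycle3_net <- function() {
  stoichiometric_network(
    data.frame(id = c("A", "B", "C"), boundary = FALSE),
    list(list(id = "R1", stoich = c(A = -1, B = 1)),
         list(id = "R2", stoich = c(B = -1, C = 1)),
         list(id = "R3", stoich = c(C = -1, A = 1))))
}

# brute-force LP oracle: enumerate all basic solutions (vertices)
lp_bruteforce <- function(cvec, A, b, lb, ub) {
  n <- length(cvec); m <- nrow(A)
  best <- Inf
  for (k in seq_len(ncol(utils::combn(n, m)))) {
    B <- utils::combn(n, m)[, k]
    Nn <- setdiff(seq_len(n), B)
    grid <- as.matrix(expand.grid(rep(list(c(TRUE, FALSE)), length(Nn))))
    if (length(Nn) == 0L) grid <- matrix(TRUE, 1, 0)
    for (g in seq_len(nrow(grid))) {
      x <- numeric(n)
      x[Nn] <- ifelse(grid[g, ], lb[Nn], ub[Nn])
      xb <- tryCatch(solve(A[, B, drop = FALSE],
                           b - A[, Nn, drop = FALSE] %*% x[Nn]),
                     error = function(e) NULL)
      if (is.null(xb)) next
      x[B] <- xb
      if (all(x >= lb - 1e-9) && all(x <= ub + 1e-9))
        best <- min(best, sum(cvec * x))
    }
  }
  best
}

# directed-cycle oracle for sign feasibility on uni-uni networks whose
# boundary species each appear in at most one reaction: decreasing potentials
# exist iff the internal-species digraph is acyclic
has_internal_cycle <- function(net) {
  ints <- net$species$id[!net$species$boundary]
  edges <- list()
  for (r in net$reactions) {
    s <- names(r$stoich)[r$stoich < 0]; p <- names(r$stoich)[r$stoich > 0]
    if (length(s) == 1 && length(p) == 1 && s %in% ints && p %in% ints)
      edges[[length(edges) + 1L]] <- c(s, p)
  }
  adj <- split(vapply(edges, `[`, "", 2), vapply(edges, `[`, "", 1))
  state <- setNames(rep(0L, length(ints)), ints)  # 0 new, 1 open, 2 done
  dfs <- function(v) {
    state[v] <<- 1L
    for (w in adj[[v]] %||% character(0)) {
      if (state[w] == 1L) return(TRUE)
      if (state[w] == 0L && dfs(w)) return(TRUE)
    }
    state[v] <<- 2L
    FALSE
  }
  any(vapply(ints, function(v) state[v] == 0L && dfs(v), TRUE))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# a tiny hand-built, already-rescaled kinetic model around one reaction
single_reaction_model <- function(kcatf = 2, kcatr = 1, km = c(A = 1, B = 1),
                                  conc = c(Sx = 10, A = 2, B = 1, Px = 0.1),
                                  u = 1) {
  sp <- data.frame(id = c("Sx", "A", "B", "Px"),
                   compartment = c("extracellular", "cytosol", "cytosol", "extracellular"),
                   boundary = c(TRUE, FALSE, FALSE, TRUE))
  rx <- list(list(id = "T_in", stoich = c(Sx = -1, A = 1)),
             list(id = "R1", stoich = c(A = -1, B = 1)),
             list(id = "R_out", stoich = c(B = -1, Px = 1)))
  net <- stoichiometric_network(sp, rx)
  laws <- list(
    T_in = list(kind = "common_modular", u = 1, kcatf = 1, kcatr = 0.01,
                km = c(Sx = 5, A = 1), regulation = NULL),
    R1 = list(kind = "common_modular", u = u, kcatf = kcatf, kcatr = kcatr,
              km = km, regulation = NULL),
    R_out = list(kind = "common_modular", u = 1, kcatf = 1, kcatr = 0.01,
                 km = c(B = 1, Px = 5), regulation = NULL))
  structure(list(network = net, conc = conc,
                 fixed = setNames(net$species$boundary, net$species$id),
                 laws = laws, target_flux = NULL, thermo = NULL,
                 posteriors = NULL, rescaled = FALSE),
            class = "kinetic_model")
}
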