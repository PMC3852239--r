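# geometric FBA, subnetwork extraction and sign feasibility

test_that("a constrained linear chain carries the inflow everywhere", {
  net <- chain_net(2)
  b <- data_bundle(flux = data.frame(reaction = "T_in", value = 1,
                                     lower = 1, upper = 1))
  fd <- geometric_fba(net, b, objective = "R_out")
  expect_lt(max(abs(fd$v - 1)), 1e-9)
  expect_lt(max(abs(net$N %*% fd$v)), 1e-9)
})

test_that("a symmetric diamond splits its flux centrally", {
  sp <- data.frame(id = c("Sx", "A", "B", "C", "D", "Px"),
                   boundary = c(TRUE, rep(FALSE, 4), TRUE))
  rx <- list(list(id = "T_in", stoich = c(Sx = -1, A = 1)),
             list(id = "Rb1", stoich = c(A = -1, B = 1)),
             list(id = "Rb2", stoich = c(B = -1, D = 1)),
             list(id = "Rc1", stoich = c(A = -1, C = 1)),
             list(id = "Rc2", stoich = c(C = -1, D = 1)),
             list(id = "R_out", stoich = c(D = -1, Px = 1)))
  net <- stoichiometric_network(sp, rx)
  b <- data_bundle(flux = data.frame(reaction = "T_in", value = 1,
                                     lower = 1, upper = 1))
  fd <- geometric_fba(net, b, objective = "R_out")
  expect_equal(unname(fd$v[c("Rb1", "Rb2", "Rc1", "Rc2")]), rep(0.5, 4),
               tolerance = 1e-8)
})

test_that("a detached internal cycle carries zero flux (L1 oracle)", {
  sp <- data.frame(id = c("Sx", "A", "Px", "X", "Y", "Z"),
                   boundary = c(TRUE, FALSE, TRUE, FALSE, FALSE, FALSE))
  rx <- list(list(id = "T_in", stoich = c(Sx = -1, A = 1)),
             list(id = "R_out", stoich = c(A = -1, Px = 1)),
             list(id = "C1", stoich = c(X = -1, Y = 1)),
             list(id = "C2", stoich = c(Y = -1, Z = 1)),
             list(id = "C3", stoich = c(Z = -1, X = 1)))
  net <- stoichiometric_network(sp, rx)
  b <- data_bundle(flux = data.frame(reaction = "T_in", value = 1,
                                     lower = 1, upper = 1))
  fd <- geometric_fba(net, b, objective = "R_out")
  ## oracle: any solution is (1, 1, t, t, t); sum|v| = 2 + 3|t|, minimal at 0
  expect_lt(max(abs(fd$v[c("C1", "C2", "C3")])), 1e-9)
  expect_equal(fd$l1_norm, 2, tolerance = 1e-9)
})

test_that("geometric FBA attains the plain-FBA optimum with minimal L1 norm", {
  set.seed(31)
  for (seed in c(2, 5, 9)) {
    fx <- make_fixture(c("diamond", "cycle", "moiety")[(seed %% 3) + 1],
                       size = 9, seed = seed, noise_sd_factor = 1.5,
                       mask_fraction = 0.5)
    net <- fx$network
    ## plain FBA optimum, solved directly
    lbub <- local({
      rids <- kineticizer:::reaction_ids(net)
      lb <- rep(-1000, length(rids)); ub <- rep(1000, length(rids))
      names(lb) <- names(ub) <- rids
      fxd <- fx$bundle$flux
      lb[fxd$reaction] <- fxd$lower; ub[fxd$reaction] <- fxd$upper
      list(lb = lb, ub = ub)
    })
    cobj <- -(kineticizer:::reaction_ids(net) == fx$objective)
    plain <- kineticizer:::lp_solve(cobj, net$N, rep(0, nrow(net$N)),
                                    lbub$lb, lbub$ub)
    fd <- geometric_fba(net, fx$bundle, fx$objective)
    expect_equal(fd$objective_value, -plain$objective,
                 tolerance = 1e-9 * max(1, abs(plain$objective)))
    ## the geometric point has minimal sum(|v|) among sampled optima
    face_lb <- lbub$lb; face_ub <- lbub$ub
    face_lb[fx$objective] <- face_ub[fx$objective] <- fd$objective_value
    verts <- replicate(15, {
      r <- kineticizer:::lp_solve(rnorm(length(cobj)), net$N,
                                  rep(0, nrow(net$N)), face_lb, face_ub)
      r$x
    })
    for (k in 1:100) {
      w <- runif(ncol(verts)); w <- w / sum(w)
      smp <- verts %*% w
      expect_gte(sum(abs(smp)) + 1e-9, fd$l1_norm)
    }
  }
})

test_that("infeasible bound sets are reported with the conflicting reactions", {
  net <- chain_net(2)
  b <- data_bundle(flux = data.frame(reaction = c("T_in", "R_out"),
                                     value = c(1, 3), lower = c(1, 3),
                                     upper = c(1, 3)))
  expect_error(geometric_fba(net, b, objective = "R_out"),
               "irreducible conflicting bound set")
})

test_that("extraction removes zero fluxes, reverses negative ones, drops orphans", {
  sp <- data.frame(id = c("A", "B", "X"), boundary = FALSE)
  rx <- list(list(id = "R1", stoich = c(A = -1, B = 1)),
             list(id = "R2", stoich = c(X = -1, A = 1)))
  net <- stoichiometric_network(sp, rx)
  fd <- structure(list(v = c(R1 = -2, R2 = 0)), class = "flux_distribution")
  ex <- extract_active_subnetwork(net, fd)
  expect_identical(names(ex$network$reactions), "R1")
  expect_equal(ex$network$reactions$R1$stoich, c(A = 1, B = -1))  # B -> A now
  expect_equal(unname(ex$flux$v), 2)
  expect_false("X" %in% ex$network$species$id)
  ## stationarity is preserved on the reduced network
  fx <- make_fixture("diamond", size = 8, seed = 33)
  fd2 <- geometric_fba(fx$network, fx$bundle, fx$objective)
  ex2 <- extract_active_subnetwork(fx$network, fd2)
  expect_lt(max(abs(ex2$network$N %*% ex2$flux$v)), 1e-9)
  ## argument handling
  expect_error(extract_active_subnetwork(net, fd, cutoff = -1), "non-negative")
  expect_warning(extract_active_subnetwork(fx$network, fd2, cutoff = 1e-6),
                 "re-run")
})

test_that("sign feasibility: chains pass, flux-carrying loops fail", {
  net <- chain_net(3)
  fd <- structure(list(v = setNames(rep(1, 4),
                                    kineticizer:::reaction_ids(net))),
                  class = "flux_distribution")
  rep1 <- check_sign_feasibility(net, fd)
  expect_true(rep1$feasible)
  cyc <- cycle3_net()
  fd2 <- structure(list(v = c(R1 = 1, R2 = 1, R3 = 1)),
                   class = "flux_distribution")
  rep2 <- check_sign_feasibility(cyc, fd2)
  expect_false(rep2$feasible)
  expect_setequal(rep2$violating_cycle, c("R1", "R2", "R3"))
})

test_that("sign feasibility agrees with the directed-cycle oracle", {
  set.seed(34)
  for (trial in 1:12) {
    n_sp <- sample(4:7, 1)
    ids <- paste0("S", seq_len(n_sp))
    sp <- data.frame(id = c(ids, "Bx"), boundary = c(rep(FALSE, n_sp), TRUE))
    n_rx <- sample(3:8, 1)
    rx <- lapply(seq_len(n_rx), function(k) {
      pair <- sample(ids, 2)
      list(id = paste0("R", k), stoich = setNames(c(-1, 1), pair))
    })
    rx[[length(rx) + 1L]] <- list(id = "Rb", stoich = setNames(c(-1, 1), c("Bx", ids[1])))
    net <- tryCatch(stoichiometric_network(sp, rx), error = function(e) NULL)
    if (is.null(net)) next   # duplicate reaction stoichiometries are fine; ids unique
    v <- setNames(rep(1, length(rx)), vapply(rx, `[[`, "", "id"))
    fd <- structure(list(v = v), class = "flux_distribution")
    expect_identical(check_sign_feasibility(net, fd)$feasible,
                     !has_internal_cycle(net),
                     info = paste("trial", trial))
  }
})
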