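# steady states, stability, MCA and perturbations

test_that("a single irreversible consumer gives the analytic decay eigenvalue", {
  ## one dynamic species A fed at constant rate, consumed by a saturable step:
  ## J = -u kcat km / (km + c)^2
  sp <- data.frame(id = c("Sx", "A", "Px"),
                   compartment = c("e", "c", "e"),
                   boundary = c(TRUE, FALSE, TRUE))
  rx <- list(list(id = "T_in", stoich = c(Sx = -1, A = 1)),
             list(id = "R_out", stoich = c(A = -1, Px = 1)))
  net <- stoichiometric_network(sp, rx)
  u <- 2; kcat <- 3; km <- 1.5; cA <- 0.8
  laws <- list(T_in = list(kind = "linlog_clamped", u = 1, vref = 1,
                           eps = c(Sx = 0, A = 0), cref = c(Sx = 10, A = cA)),
               R_out = list(kind = "common_modular", u = u, kcatf = kcat,
                            kcatr = 0, km = c(A = km, Px = 1e6)))
  m <- structure(list(network = net, conc = c(Sx = 10, A = cA, Px = 1e-6),
                      fixed = c(Sx = TRUE, A = FALSE, Px = TRUE),
                      laws = laws, target_flux = NULL, rescaled = FALSE),
                 class = "kinetic_model")
  st <- stability(m)
  lam_expected <- -u * kcat * km / (km + cA)^2 *
    1 / (1 + cA / km + 1e-6 / 1e6)  # denominator of the modular law
  ## analytic derivative of the modular law for the uni-uni irreversible case
  num_d <- (model_rates(m, c(Sx = 10, A = cA + 1e-7, Px = 1e-6))[["R_out"]] -
            model_rates(m, c(Sx = 10, A = cA - 1e-7, Px = 1e-6))[["R_out"]]) / 2e-7
  expect_equal(Re(st$eigenvalues[1]), -num_d, tolerance = 1e-6)
  expect_true(st$is_stable)
})

test_that("summation theorems hold on every fixture scenario", {
  for (seed in seq_along(FIXTURE_SCENARIOS)) {
    fx <- make_fixture(FIXTURE_SCENARIOS[seed], size = 9, seed = 80 + seed,
                       mask_fraction = 0.3, noise_sd_factor = 1.3)
    m <- end_to_end_recovery(fx)$model
    mca <- control_coefficients(m)
    expect_lt(max(abs(rowSums(mca$C_J_scaled) - 1)), 1e-6)
    expect_lt(max(abs(rowSums(mca$C_S_scaled))), 1e-6)
    ## connectivity theorem: C_J E = 0 and C_S E = -I on the reduced system
    red <- kineticizer:::link_matrix(kineticizer:::dyn_stoich(m))
    expect_lt(max(abs(mca$C_J %*% mca$E %*% red$L)), 1e-6)
    expect_lt(max(abs(mca$C_S %*% mca$E %*% red$L + red$L)), 1e-6)
  }
})

test_that("matrix-identity control coefficients match finite differences", {
  fx <- make_fixture("diamond", size = 7, seed = 85, mask_fraction = 0.2,
                     noise_sd_factor = 1.2)
  m <- end_to_end_recovery(fx)$model
  mca <- control_coefficients(m)
  fd <- control_coefficients_fd(m, rel_step = 1e-6)
  expect_lt(max(abs(mca$C_J_scaled - fd$C_J_scaled)), 1e-4)
  expect_lt(max(abs(mca$C_S_scaled - fd$C_S_scaled)), 1e-4)
})

test_that("overall control is the column root sum of squares, top 5% flagged", {
  CJ <- matrix(c(3, 4, 0, 0), 2, 2, dimnames = list(c("x", "y"), c("a", "b")))
  oc <- overall_flux_control(list(C_J_scaled = CJ))
  expect_equal(unname(oc$overall), c(5, 0))
  expect_identical(oc$high_control, "a")
  ## 20 reactions -> exactly ceiling(1) = 1 flagged; ties broken by id
  CJ20 <- matrix(1, 1, 20, dimnames = list("f", paste0("r", sprintf("%02d", 20:1))))
  oc20 <- overall_flux_control(list(C_J_scaled = CJ20))
  expect_length(oc20$high_control, 1L)
  expect_identical(oc20$high_control, "r01")
})

test_that("an engineered positive-feedback loop is flagged unstable", {
  ## linlog laws with chosen elasticities: production of A responds twice as
  ## strongly to A as its consumption does -> Jacobian = +v/c > 0
  sp <- data.frame(id = c("Sx", "A", "Px"), compartment = c("e", "c", "e"),
                   boundary = c(TRUE, FALSE, TRUE))
  rx <- list(list(id = "R_in", stoich = c(Sx = -1, A = 1),
                  modifiers = data.frame(species = "A", mode = "activator")),
             list(id = "R_out", stoich = c(A = -1, Px = 1)))
  net <- stoichiometric_network(sp, rx)
  laws <- list(R_in = list(kind = "linlog_clamped", u = 1, vref = 1,
                           eps = c(Sx = 0, A = 2), cref = c(Sx = 10, A = 1)),
               R_out = list(kind = "linlog_clamped", u = 1, vref = 1,
                            eps = c(A = 1, Px = 0), cref = c(A = 1, Px = 1)))
  m <- structure(list(network = net, conc = c(Sx = 10, A = 1, Px = 1),
                      fixed = c(Sx = TRUE, A = FALSE, Px = TRUE),
                      laws = laws, target_flux = NULL, rescaled = FALSE),
                 class = "kinetic_model")
  st <- stability(m)
  expect_false(st$is_stable)
  expect_equal(Re(st$eigenvalues[1]), 1, tolerance = 1e-9)  # (2 - 1) * v/c
})

test_that("identity perturbations stay put; pulses relax back; uptake responds", {
  fx <- make_fixture("linear_chain", size = 6, seed = 86, mask_fraction = 0.3,
                     noise_sd_factor = 1.3)
  m <- end_to_end_recovery(fx)$model
  dyn <- kineticizer:::dynamic_species(m)
  ps1 <- simulate_perturbation(m, "Sx", 1, duration = 5, n_out = 9)
  expect_lt(max(abs(sweep(ps1$conc, 2, m$conc[dyn]))), 1e-9)
  ## ten-fold pulse, restored: the system returns to the original state
  st <- stability(m)
  expect_true(st$is_stable)
  t_relax <- 80 / abs(st$max_re)
  ps2 <- simulate_perturbation(m, "Sx", 10, duration = t_relax,
                               restore_at = t_relax / 40, n_out = 40)
  expect_true(ps2$returned_to_reference)
  expect_lt(ps2$final_distance, 1e-6)
  ## a 30% substrate increase raises the uptake flux (elasticity sign check)
  ps3 <- simulate_perturbation(m, "Sx", 1.3, duration = 2, n_out = 5)
  expect_true(all(ps3$flux[-1, "T_in"] > m$target_flux[["T_in"]]))
  ## argument validation
  expect_error(simulate_perturbation(m, "A1", 2, 1), "not a boundary")
  expect_error(simulate_perturbation(m, "Sx", -1, 1), "positive")
})

test_that("moiety totals are conserved through integration and steady states", {
  fx <- make_fixture("moiety", size = 9, seed = 87, mask_fraction = 0.3,
                     noise_sd_factor = 1.3)
  m <- end_to_end_recovery(fx)$model
  tot0 <- m$conc[["ATP"]] + m$conc[["ADP"]]
  ps <- simulate_perturbation(m, "Sx", 3, duration = 10, n_out = 11)
  expect_lt(max(abs(ps$conc[, "ATP"] + ps$conc[, "ADP"] - tot0)), 1e-9)
  ## conservation is respected by the Newton steady-state search as well
  m2 <- m; m2$laws[["R1"]]$u <- m2$laws[["R1"]]$u * 1.2
  ss <- find_steady_state(m2)
  expect_true(ss$converged)
  expect_equal(ss$conc[["ATP"]] + ss$conc[["ADP"]], tot0, tolerance = 1e-9)
})

test_that("Newton steady states agree with long ODE relaxation", {
  fx <- make_fixture("cycle", size = 7, seed = 88, mask_fraction = 0.3,
                     noise_sd_factor = 1.3)
  m <- end_to_end_recovery(fx)$model
  m$laws[["R_short"]]$u <- m$laws[["R_short"]]$u * 1.3   # nudge off c*
  ss <- find_steady_state(m)
  expect_true(ss$converged)
  od <- kineticizer:::model_odes(m)
  st <- stability(m, ss$conc)
  sim <- kineticizer:::ode_integrate(od$f, od$jac,
                                     m$conc[kineticizer:::dynamic_species(m)],
                                     t_end = 60 / abs(st$max_re), n_out = 3)
  final <- sim$y[3, ]
  expect_lt(max(abs(final - ss$conc[names(final)]) / pmax(abs(final), 1e-12)),
            1e-6)
})
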