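# concentrations and Wegscheider-consistent equilibrium constants

test_that("unknown concentrations get the class median", {
  sp <- data.frame(id = c("G", "A", "B", "C", "U", "Xe"),
                   compartment = c(rep("cytosol", 5), "extracellular"),
                   boundary = c(rep(FALSE, 5), TRUE))
  rx <- list(list(id = "R1", stoich = c(G = -1, A = 1)),
             list(id = "R2", stoich = c(A = -1, B = 1)),
             list(id = "R3", stoich = c(B = -1, C = 1)),
             list(id = "R4", stoich = c(C = -1, U = 1)),
             list(id = "T", stoich = c(U = -1, Xe = 1)))
  net <- stoichiometric_network(sp, rx)
  b <- data_bundle(conc = data.frame(species = c("G", "A", "B", "Xe"),
                                     value = c(0.1, 0.549, 10, 24.5)))
  cc <- assign_concentrations(net, b)
  expect_equal(cc$conc[cc$species == "C"], 0.549)     # median of {0.1, 0.549, 10}
  expect_equal(cc$conc[cc$species == "U"], 0.549)
  expect_true(cc$fixed[cc$species == "Xe"])           # boundary species fixed

  ## median of a single known value, and the even-count convention
  b1 <- data_bundle(conc = data.frame(species = c("G", "Xe"), value = c(3, 24.5)))
  cc1 <- assign_concentrations(net, b1)
  expect_true(all(cc1$conc[cc1$species %in% c("A", "B", "C", "U")] == 3))
  b2 <- data_bundle(conc = data.frame(species = c("G", "A", "Xe"),
                                      value = c(1, 3, 24.5)))
  cc2 <- assign_concentrations(net, b2)
  expect_equal(cc2$conc[cc2$species == "B"], 2)       # mean of the central pair
})

test_that("protons/phosphate are fixed; overrides and errors behave", {
  sp <- data.frame(id = c("h_c", "pi_c", "glc"), compartment = "cytosol",
                   boundary = FALSE)
  rx <- list(list(id = "R", stoich = c(glc = -1, h_c = 1, pi_c = 1)))
  net <- stoichiometric_network(sp, rx)
  b <- data_bundle(conc = data.frame(species = "glc", value = 1))
  cc <- assign_concentrations(net, b, overrides = c(h_c = 1e-4))
  expect_true(all(cc$fixed[cc$species %in% c("h_c", "pi_c")]))
  expect_equal(cc$conc[cc$species == "h_c"], 1e-4)
  expect_error(assign_concentrations(net, data_bundle()),
               "configuration error")
})

test_that("mass-action ratios follow the stoichiometry", {
  expect_equal(mass_action_ratio(list(id = "r", stoich = c(A = -1, B = 1)),
                                 c(A = 1, B = 1)), 1)
  expect_equal(mass_action_ratio(list(id = "r", stoich = c(A = -2, B = 1)),
                                 c(A = 2, B = 1)), 0.25)
  expect_equal(mass_action_ratio(list(id = "r", stoich = c(A = -1, B = -1, C = 1, D = 1)),
                                 c(A = 1, B = 2, C = 3, D = 4)), 6)
  expect_error(mass_action_ratio(list(id = "r", stoich = c(A = -1, B = 1)),
                                 c(A = 1)), "missing concentration.*B")
})

test_that("Wegscheider closure determines the third keq of a cycle", {
  ts <- balance_equilibrium_constants(cycle3_net(), c(A = 1, B = 1, C = 1),
                                      keq_data = c(R1 = 2, R2 = 5),
                                      flux = c(R1 = 0, R2 = 0, R3 = 0))
  expect_equal(unname(ts$keq[["R3"]]), 0.1, tolerance = 1e-9)
})

test_that("constrained least squares matches a parameterised analytic oracle", {
  ## 3-cycle with one fixed keq: the loop condition x1 + x2 + x3 = 0 leaves
  ## two free coordinates; min ||x - t||^2 on that line has the closed form
  ## x_i = t_i + (d - t2 - t3)/2 with d = -ln(keq_fixed), boxes inactive
  net <- cycle3_net()
  conc <- c(A = 0.9, B = 1.4, C = 0.6)
  ts <- balance_equilibrium_constants(net, conc, keq_data = c(R1 = 2),
                                      flux = c(R1 = 0, R2 = 0, R3 = 0))
  g <- ts$gamma
  t2 <- log(10 * g[["R2"]]); t3 <- log(10 * g[["R3"]])
  lam <- (-log(2) - t2 - t3) / 2
  expect_equal(log(ts$keq[["R2"]]), t2 + lam, tolerance = 1e-8)
  expect_equal(log(ts$keq[["R3"]]), t3 + lam, tolerance = 1e-8)
  expect_lt(max(abs(t(net$K) %*% log(ts$keq))), 1e-8)
})

test_that("transport keq = 1 and the 10% force margin are enforced", {
  sp <- data.frame(id = c("Se", "A", "B", "Pe"), boundary = c(TRUE, FALSE, FALSE, TRUE),
                   compartment = c("e", "c", "c", "e"))
  rx <- list(list(id = "T1", stoich = c(Se = -1, A = 1)),
             list(id = "R1", stoich = c(A = -1, B = 1)),
             list(id = "T2", stoich = c(B = -1, Pe = 1)))
  net <- stoichiometric_network(sp, rx)
  ts <- balance_equilibrium_constants(net, c(Se = 24.5, A = 1, B = 0.5, Pe = 0.01))
  expect_identical(unname(ts$keq[c("T1", "T2")]), c(1, 1))
  expect_true(all(ts$keq / ts$gamma >= 1.1 - 1e-12))

  ## a single reaction at Gamma = 1 must come out at keq >= 1.1
  net1 <- stoichiometric_network(data.frame(id = c("A", "B"), boundary = FALSE),
                                 list(list(id = "R", stoich = c(A = -1, B = 1))))
  ts1 <- balance_equilibrium_constants(net1, c(A = 1, B = 1))
  expect_gte(unname(ts1$keq[["R"]]), 1.1 - 1e-12)
})

test_that("conflicting fixed keq raise typed errors instead of being relaxed", {
  net1 <- stoichiometric_network(data.frame(id = c("A", "B"), boundary = FALSE),
                                 list(list(id = "R", stoich = c(A = -1, B = 1))))
  expect_error(balance_equilibrium_constants(net1, c(A = 1, B = 1),
                                             keq_data = c(R = 0.5)),
               "thermodynamic conflict.*R")
  expect_error(balance_equilibrium_constants(cycle3_net(), c(A = 1, B = 1, C = 1),
                                             keq_data = c(R1 = 2, R2 = 5, R3 = 7),
                                             flux = c(R1 = 0, R2 = 0, R3 = 0)),
               "Wegscheider")
})

test_that("re-balancing an already consistent keq set is idempotent", {
  fx <- make_fixture("cycle", size = 8, seed = 41)
  net <- fx$network
  ts1 <- balance_equilibrium_constants(net, fx$truth$conc, fx$truth$keq,
                                       flux = fx$truth$v)
  expect_lt(max(abs(log(ts1$keq) - log(fx$truth$keq))), 1e-10)
})

test_that("pipeline keq are Wegscheider-consistent with positive forces", {
  for (seed in c(3, 7)) {
    fx <- make_fixture(c("diamond", "moiety")[(seed %% 2) + 1], size = 10,
                       seed = seed, mask_fraction = 0.5, noise_sd_factor = 1.5)
    rep <- end_to_end_recovery(fx)
    expect_lt(rep$wegscheider_residual, 1e-8)
    expect_true(all(rep$thermo$keq / rep$thermo$gamma >= 1.1 - 1e-12))
  }
})
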