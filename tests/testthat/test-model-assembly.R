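# rate laws, regulation and Vmax rescaling

test_that("the common modular rate law evaluates to its hand value", {
  rxn <- list(id = "R", stoich = c(A = -1, B = 1))
  law <- list(kind = "common_modular", u = 1, kcatf = 2, kcatr = 1,
              km = c(A = 1, B = 1))
  ## (2*2 - 1*1) / ((1+2) + (1+1) - 1) = 3/4
  expect_equal(common_modular_rate(rxn, law, c(A = 2, B = 1)), 0.75)
})

test_that("the rate vanishes at equilibrium and saturates when irreversible", {
  rxn <- list(id = "R", stoich = c(A = -2, B = 1))
  km <- c(A = 0.7, B = 1.9); kcatf <- 5; keq <- 4
  kcatr <- exp(log(kcatf) - log(keq) + sum(rxn$stoich * log(km)))
  law <- list(kind = "common_modular", u = 3, kcatf = kcatf, kcatr = kcatr, km = km)
  cA <- 0.9; cB <- keq * cA^2                       # Gamma = keq
  expect_lt(abs(common_modular_rate(rxn, law, c(A = cA, B = cB))),
            1e-12 * 3 * kcatf)
  ## irreversible saturation bound
  rxn2 <- list(id = "R2", stoich = c(A = -1, B = 1))
  law2 <- list(kind = "common_modular", u = 1, kcatf = 2, kcatr = 0,
               km = c(A = 1, B = 1))
  for (cA in c(0.1, 1, 100, 1e4)) {
    r <- common_modular_rate(rxn2, law2, c(A = cA, B = 7))
    expect_true(r > 0 && r <= 2)
  }
  expect_error(common_modular_rate(rxn2, list(kind = "common_modular", u = 1,
                                              kcatf = 1, kcatr = 0,
                                              km = c(A = 0, B = 1)),
                                   c(A = 1, B = 1)),
               "parameter error")
})

test_that("linlog laws hit the reference, clamp at zero, and follow ln c", {
  rxn <- list(id = "B", stoich = c(A = -1, X = 1))
  law <- list(kind = "linlog_clamped", u = 1, vref = 1,
              eps = c(A = 1, X = 0), cref = c(A = 2, X = 1))
  expect_equal(linlog_clamped_rate(rxn, law, c(A = 2, X = 5)), 1)
  expect_equal(linlog_clamped_rate(rxn, law, c(A = 4, X = 5)), 1 + log(2))
  expect_equal(linlog_clamped_rate(rxn, law, c(A = 2 * exp(-5), X = 5)), 0)
})

test_that("regulation prefactors are hyperbolic and order-preserving", {
  rxn <- list(id = "R", stoich = c(A = -1, B = 1))
  base <- list(kind = "common_modular", u = 1, kcatf = 2, kcatr = 0,
               km = c(A = 1, B = 1))
  r0 <- common_modular_rate(rxn, base, c(A = 1, B = 1, I = 3, X = 3))
  inh <- base; inh$regulation <- data.frame(species = "I", mode = "inhibitor",
                                            constant = 3)
  expect_equal(common_modular_rate(rxn, inh, c(A = 1, B = 1, I = 3, X = 3)),
               r0 / 2)                               # c = K_I -> 1/2
  act <- base; act$regulation <- data.frame(species = "X", mode = "activator",
                                            constant = 1e-9)
  expect_equal(common_modular_rate(rxn, act, c(A = 1, B = 1, I = 3, X = 3)),
               r0, tolerance = 1e-8)                 # c >> K_A -> 1
})

test_that("apply_regulation validates and rescaling restores the steady state", {
  fx <- make_fixture("linear_chain", size = 6, seed = 61)
  model <- end_to_end_recovery(fx)$model
  expect_identical(apply_regulation(model, NULL), model)
  expect_error(apply_regulation(model, data.frame(reaction = "nope",
                                                  species = "A1",
                                                  mode = "inhibitor",
                                                  constant = 1)),
               "validation error")
  reg <- data.frame(reaction = "R1", species = "A2", mode = "inhibitor",
                    constant = unname(model$conc[["A2"]]))
  m2 <- apply_regulation(model, reg)
  expect_false(m2$rescaled)
  m2 <- rescale_vmax(m2)
  ## regulated and unregulated models share the same v* and c*
  expect_lt(max(abs(model_rates(m2) - model$target_flux) / model$target_flux),
            1e-9)
  expect_lt(max(abs(kineticizer:::dyn_stoich(m2) %*% model_rates(m2))), 1e-9)
})

test_that("rescale_vmax multiplies u by v/rate and guards signs", {
  m <- single_reaction_model()
  rates <- model_rates(m)
  target <- rates * c(1, 3, 1)                       # triple only R1's target
  names(target) <- names(rates)
  m$target_flux <- target
  m2 <- rescale_vmax(m)
  expect_equal(m2$laws$R1$u, 3 * m$laws$R1$u)
  expect_equal(unname(model_rates(m2)), unname(target), tolerance = 1e-12)
  ## fixed point: rescaling again changes nothing
  m3 <- rescale_vmax(m2)
  expect_equal(m3$laws$R1$u, m2$laws$R1$u)
  ## sign guard
  m$target_flux <- -target
  expect_error(rescale_vmax(m), "scaling error")
})

test_that("rate signs follow the thermodynamic force before rescaling", {
  set.seed(62)
  for (seed in 1:5) {
    fx <- make_fixture("diamond", size = 8, seed = 70 + seed)
    net <- fx$network
    for (rid in kineticizer:::reaction_ids(net)) {
      law <- fx$truth$model$laws[[rid]]
      if (law$kind != "common_modular") next
      rxn <- net$reactions[[rid]]
      cc <- fx$truth$conc * rlnorm(length(fx$truth$conc), 0, 0.8)
      names(cc) <- names(fx$truth$conc)
      gam <- mass_action_ratio(rxn, cc)
      force <- log(fx$truth$keq[[rid]] / gam)
      rate <- common_modular_rate(rxn, law, cc)
      if (abs(force) > 1e-9)
        expect_identical(sign(rate), sign(force), info = paste(seed, rid))
    }
  }
})

test_that("assembled pipeline models actualise the predefined steady state", {
  for (seed in c(4, 8)) {
    fx <- make_fixture(c("moiety", "transporter")[(seed %% 2) + 1], size = 10,
                       seed = seed, mask_fraction = 0.5, noise_sd_factor = 1.5)
    rep <- end_to_end_recovery(fx)
    expect_lt(rep$rate_match_error, 1e-9)
    expect_lt(rep$steady_state_residual, 1e-9)
  }
})
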