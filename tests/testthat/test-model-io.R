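# SBML and tabular input/output

sbml_wrap <- function(species, reactions) {
  paste0('<?xml version="1.0" encoding="UTF-8"?>',
         '<sbml xmlns="http://www.sbml.org/sbml/level3/version1/core" level="3" version="1">',
         '<model id="m"><listOfCompartments>',
         '<compartment id="cytosol" constant="true"/>',
         '<compartment id="external" constant="true"/>',
         '</listOfCompartments><listOfSpecies>', species,
         '</listOfSpecies><listOfReactions>', reactions,
         '</listOfReactions></model></sbml>')
}

test_that("a single reaction A->B yields N = [[-1],[1]]", {
  doc <- sbml_wrap(
    '<species id="A" compartment="cytosol" boundaryCondition="false" constant="false"/>
     <species id="B" compartment="cytosol" boundaryCondition="false" constant="false"/>',
    '<reaction id="R1" reversible="true" fast="false">
       <listOfReactants><speciesReference species="A" stoichiometry="1" constant="true"/></listOfReactants>
       <listOfProducts><speciesReference species="B" stoichiometry="1" constant="true"/></listOfProducts>
     </reaction>')
  net <- read_network(doc)
  expect_equal(unname(net$N), matrix(c(-1, 1), 2, 1))
  expect_false(net$reactions$R1$transport)
})

test_that("a two-compartment reaction is flagged as transport", {
  doc <- sbml_wrap(
    '<species id="A_c" compartment="cytosol"/>
     <species id="A_e" compartment="external"/>',
    '<reaction id="T1" reversible="true" fast="false">
       <listOfReactants><speciesReference species="A_e"/></listOfReactants>
       <listOfProducts><speciesReference species="A_c"/></listOfProducts>
     </reaction>')
  net <- read_network(doc)
  expect_true(net$reactions$T1$transport)
})

test_that("the null space of a 3-reaction cycle is proportional to (1,1,1)", {
  net <- cycle3_net()
  expect_equal(ncol(net$K), 1L)
  k <- net$K[, 1]
  expect_lt(max(abs(k - mean(k))), 1e-12)       # all components equal
  expect_lt(max(abs(net$N %*% net$K)), 1e-10)
})

test_that("modifier SBO terms map to modes, with inhibitor as logged default", {
  doc <- sbml_wrap(
    '<species id="A" compartment="cytosol"/><species id="B" compartment="cytosol"/>
     <species id="X" compartment="cytosol"/><species id="Y" compartment="cytosol"/>',
    '<reaction id="R1" reversible="true" fast="false">
       <listOfReactants><speciesReference species="A"/></listOfReactants>
       <listOfProducts><speciesReference species="B"/></listOfProducts>
       <listOfModifiers>
         <modifierSpeciesReference species="X" sboTerm="SBO:0000459"/>
         <modifierSpeciesReference species="Y"/>
       </listOfModifiers>
     </reaction>')
  expect_message(net <- read_network(doc), "defaulting to mode 'inhibitor'")
  mods <- net$reactions$R1$modifiers
  expect_equal(mods$mode[mods$species == "X"], "activator")
  expect_equal(mods$mode[mods$species == "Y"], "inhibitor")
})

test_that("malformed documents and unknown species raise typed errors", {
  expect_error(read_network("<sbml><model></sbml>"), "SBML format error")
  doc <- sbml_wrap('<species id="A" compartment="cytosol"/>',
                   '<reaction id="R1" reversible="true" fast="false">
                      <listOfReactants><speciesReference species="ZZ"/></listOfReactants>
                    </reaction>')
  expect_error(read_network(doc), "structural error.*ZZ")
})

test_that("data bundle parsing: pass-through, unit conversion, validation", {
  tab <- data.frame(QuantityType = c("keq", "km", "concentration"),
                    Reaction = c("R1", "R1", NA),
                    Compound = c(NA, "A", "A"),
                    Value = c(2.0, 549, 1.2),
                    Unit = c("dimensionless", "uM", "mM"))
  b <- read_data_bundle(tab)
  expect_equal(b$keq$value, 2.0)
  expect_equal(b$km$value, 0.549)          # 549 uM -> mM
  expect_equal(b$conc$value, 1.2)
  expect_equal(b$keq$gsd, 2.0)             # default geometric SDs
  expect_equal(b$km$gsd, 1.5)

  bad <- data.frame(QuantityType = "concentration", Reaction = NA,
                    Compound = "A", Value = -1, Unit = "mM")
  expect_error(read_data_bundle(bad), "validation error")
})

test_that("tab- and comma-delimited SBtab files parse identically", {
  df <- data.frame(QuantityType = c("kcat+", "flux"), Reaction = c("R1", "R1"),
                   Compound = NA, Value = c(30, 2), Unit = c("1/min", "mM/s"))
  f1 <- tempfile(fileext = ".tsv"); f2 <- tempfile(fileext = ".csv")
  utils::write.table(df, f1, sep = "\t", row.names = FALSE, quote = FALSE)
  utils::write.table(df, f2, sep = ",", row.names = FALSE, quote = FALSE)
  b1 <- read_data_bundle(f1); b2 <- read_data_bundle(f2)
  expect_equal(b1$kcat$value, 0.5)         # 30/min -> 0.5/s
  expect_equal(b1$kcat$direction, "forward")
  expect_equal(b1, b2)
  unlink(c(f1, f2))
})

test_that("unknown ids are reported, not dropped", {
  net <- chain_net(2)
  tab <- data.frame(QuantityType = "keq", Reaction = c("R1", "Rghost"),
                    Compound = NA, Value = c(2, 3), Unit = NA)
  expect_warning(b <- read_data_bundle(tab, network = net), "Rghost")
  expect_equal(nrow(b$keq), 2L)
})

test_that("kinetic models round-trip through SBML with identical rates", {
  fx <- make_fixture("moiety", size = 9, seed = 21, mask_fraction = 0.2,
                     noise_sd_factor = 1.4)
  model <- end_to_end_recovery(fx)$model
  path <- tempfile(fileext = ".xml")
  write_kinetic_model(model, path)
  skm <- read_kinetic_model(path)
  r0 <- model_rates(model)
  r1 <- sbml_rates(skm)
  expect_lt(max(abs(r0 - r1[names(r0)]) / abs(r0)), 1e-9)
  ## stoichiometry, flags and parameters preserved
  for (rid in names(model$network$reactions)) {
    st0 <- model$network$reactions[[rid]]$stoich
    st1 <- skm$network$reactions[[rid]]$stoich[names(st0)]
    expect_identical(unname(st1), unname(st0))
  }
  expect_identical(skm$network$species$boundary[match("Fx", skm$network$species$id)], TRUE)
  expect_equal(sort(skm$conc[names(model$conc)]), sort(model$conc), tolerance = 1e-12)
  ## the structured model survives the round trip as well
  m2 <- as_kinetic_model(skm)
  expect_equal(model_rates(m2)[names(r0)], r0, tolerance = 1e-9)
  mca2 <- control_coefficients(m2)
  expect_lt(max(abs(rowSums(mca2$C_J_scaled) - 1)), 1e-6)
  unlink(path)
})

test_that("a clamped linlog law serialises with a piecewise zero clamp", {
  fx <- make_fixture("linear_chain", size = 6, seed = 22, biomass_objective = TRUE)
  txt <- write_kinetic_model(fx$truth$model)
  expect_match(txt, "piecewise")
  skm <- read_kinetic_model(txt)
  r0 <- model_rates(fx$truth$model)
  expect_lt(max(abs(r0 - sbml_rates(skm)[names(r0)]) / abs(r0)), 1e-9)
})

test_that("serialising an incomplete model fails", {
  fx <- make_fixture("linear_chain", size = 5, seed = 23)
  broken <- fx$truth$model
  broken$laws[["R1"]] <- list(kind = NULL)
  expect_error(write_kinetic_model(broken), "assembly-incomplete")
})

test_that("N K = 0 and dim(K) = n - rank(N) on random fixtures", {
  for (seed in 1:6) {
    fx <- make_fixture(FIXTURE_SCENARIOS[(seed %% 6) + 1],
                       size = 8 + seed, seed = seed)
    N <- fx$network$N; K <- fx$network$K
    if (ncol(K) > 0) expect_lt(max(abs(N %*% K)), 1e-10)
    expect_equal(ncol(K), ncol(N) - qr(N)$rank)
  }
})
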