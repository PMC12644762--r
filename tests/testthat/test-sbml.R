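test_that("SBML round trip preserves the model exactly", {
  net <- default_network()
  path <- tempfile(fileext = ".xml")
  init <- round_state(net, initial_state(net, NFKB = 100, RNA_p50 = 7))
  write_sbml(net, path, initial = init)
  rt <- read_sbml(path)
  expect_equal(rt$network$stoich, net$stoich, ignore_attr = TRUE)
  expect_equal(rt$network$reactions$rate, net$reactions$rate,
               tolerance = 1e-15)
  expect_equal(unname(rt$initial[net$species$name]), unname(init))
  # species set covers the subunits, dimer, and all five RNAs
  expect_true(all(c("P_p50", "P_p65", "NFKB",
                    paste0("RNA_", c("p50", "p65", "TWIST1", "SLUG",
                                     "SIP1"))) %in% rt$network$species$name))
  # the parameter set is reconstructed from the rate-constant names
  expect_s3_class(rt$params, "grn_params")
  expect_equal(rt$params$genes$kon, grn_params()$genes$kon,
               tolerance = 1e-15)
  # conservation laws are re-detected after the round trip
  expect_length(rt$network$conservation, 5)
})

test_that("round-tripped models simulate identically", {
  net <- default_network()
  path <- tempfile(fileext = ".xml")
  write_sbml(net, path)
  net2 <- read_sbml(path)$network
  rep <- default_report()
  init <- round_state(net, unlist(rep$states[1, net$species$name]))
  a <- tau_leap(net, init, horizon = 20, seed = 5, record_interval = 5)
  b <- tau_leap(net2, init[net2$species$name], horizon = 20, seed = 5,
                record_interval = 5)
  expect_equal(as.data.frame(a[, names(b)]), as.data.frame(b))
})

test_that("the shipped calibrated model file loads with the full species
           set and the default rate constants", {
  path <- system.file("extdata", "nfkb_grn_calibrated.xml",
                      package = "nfkbgrn")
  expect_true(nzchar(path))
  m <- read_sbml(path)
  expect_true(all(c("P_p50", "P_p65", "NFKB",
                    paste0("RNA_", c("p50", "p65", "TWIST1", "SLUG",
                                     "SIP1"))) %in% m$network$species$name))
  expect_equal(sort(m$network$reactions$rate),
               sort(default_network()$reactions$rate), tolerance = 1e-14)
  # the stored initial state is the HER2 stationary state, rounded
  expect_equal(unname(m$initial[["P_p65"]]),
               round(default_report()$states$P_p65[1]))
})

test_that("malformed and non-mass-action files are rejected cleanly", {
  bad <- tempfile(fileext = ".xml")
  writeLines("<sbml><model></sbml>", bad)  # not well-formed XML
  expect_error(read_sbml(bad))
  # valid XML but a non-mass-action kinetic law (contains a <plus/>)
  nonma <- tempfile(fileext = ".xml")
  writeLines(c(
    '<sbml xmlns="http://www.sbml.org/sbml/level3/version1/core" level="3" version="1">',
    '<model id="m"><listOfCompartments><compartment id="cell" size="1" constant="true"/></listOfCompartments>',
    '<listOfSpecies><species id="A" compartment="cell" initialAmount="5" hasOnlySubstanceUnits="true" boundaryCondition="false" constant="false"/></listOfSpecies>',
    '<listOfParameters><parameter id="k1" value="2" constant="true"/></listOfParameters>',
    '<listOfReactions><reaction id="decay" reversible="false">',
    '<listOfReactants><speciesReference species="A" stoichiometry="1" constant="true"/></listOfReactants>',
    '<kineticLaw><math xmlns="http://www.w3.org/1998/Math/MathML">',
    '<apply><plus/><ci>k1</ci><ci>A</ci></apply>',
    '</math></kineticLaw></reaction></listOfReactions></model></sbml>'
  ), nonma)
  expect_error(read_sbml(nonma), "non-mass-action.*decay|decay")
})
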