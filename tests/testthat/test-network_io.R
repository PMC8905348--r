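test_that("a minimal hand-written SBML L2 file parses into a 2x1 network", {
  f <- withr::local_tempfile(fileext = ".xml")
  writeLines(c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    '<sbml xmlns="http://www.sbml.org/sbml/level2/version4" level="2" version="4">',
    ' <model id="mini">',
    '  <listOfCompartments><compartment id="c"/></listOfCompartments>',
    '  <listOfSpecies>',
    '   <species id="A" compartment="c"/>',
    '   <species id="B" compartment="c"/>',
    '  </listOfSpecies>',
    '  <listOfReactions>',
    '   <reaction id="r1" reversible="false">',
    '    <listOfReactants><speciesReference species="A"/></listOfReactants>',
    '    <listOfProducts><speciesReference species="B"/></listOfProducts>',
    '   </reaction>',
    '  </listOfReactions>',
    ' </model>',
    '</sbml>'), f)
  net <- readSBML(f)
  expect_equal(nMetabolites(net), 2L)
  expect_equal(nReactions(net), 1L)
  expect_equal(as.vector(stoichiometry(net)), c(-1, 1))
  expect_false(net@reactions$reversible)     # explicit attribute wins
  expect_equal(net@reactions$lower_bound, 0) # irreversible default
})

test_that("SBML round-trips through both dialects with bounds intact", {
  net <- makeToyNetwork("branch", 4)@network
  net@reactions$reversible[2] <- TRUE
  net@reactions$lower_bound[2] <- -500
  for (dialect in c("L3", "L2")) {
    f <- withr::local_tempfile(fileext = ".xml")
    writeSBML(net, f, dialect)
    back <- readSBML(f)
    expect_identical(as.matrix(stoichiometry(back)),
                     as.matrix(stoichiometry(net)))
    expect_identical(back@reactions$reversible, net@reactions$reversible)
    expect_equal(back@reactions$lower_bound, net@reactions$lower_bound)
    expect_equal(back@reactions$upper_bound, net@reactions$upper_bound)
    expect_identical(metaboliteIds(back), metaboliteIds(net))
  }
})

test_that("boundary species are recognised by attribute and by suffix", {
  net <- networkFromReactions(
    list(list(id = "ex", substrates = c(glc_b = 1), products = c(glc = 1))),
    boundary = "glc_b")
  f <- withr::local_tempfile(fileext = ".xml")
  writeSBML(net, f)
  back <- readSBML(f)
  expect_identical(back@metabolites$boundary, c(TRUE, FALSE))
  # suffix rule alone also catches it
  back2 <- readSBML(f, boundary_rules = "suffix")
  expect_identical(back2@metabolites$boundary, c(TRUE, FALSE))
  back3 <- readSBML(f, boundary_rules = "attribute")
  expect_identical(back3@metabolites$boundary, c(TRUE, FALSE))
})

test_that("malformed or empty models are rejected with a named error", {
  f <- withr::local_tempfile(fileext = ".xml")
  writeLines("<notsbml/>", f)
  expect_error(readSBML(f), "model")
  writeLines(c(
    '<sbml xmlns="http://www.sbml.org/sbml/level2/version4" level="2" version="4">',
    '<model><listOfSpecies><species id="A"/></listOfSpecies></model></sbml>'), f)
  expect_error(readSBML(f), "no reactions")
  expect_error(readSBML(file.path(tempdir(), "absent.xml")), "not found")
})

test_that("splitting reversible reactions creates exact negated pairs", {
  # 3 reversible + 2 irreversible -> 8 columns, 3 registered pairs
  rxns <- list(
    list(id = "v1", substrates = c(A = 1), products = c(B = 1), reversible = TRUE),
    list(id = "v2", substrates = c(B = 1), products = c(C = 2), reversible = TRUE),
    list(id = "v3", substrates = c(C = 1), products = c(D = 1), reversible = TRUE),
    list(id = "w1", substrates = c(A = 1), products = c(D = 1)),
    list(id = "w2", substrates = c(D = 2), products = c(B = 1)))
  base <- networkFromReactions(rxns, u_default = 800)
  sn <- splitReversible(base, u_default = 800)
  expect_equal(nReactions(sn), 8L)
  expect_equal(nrow(pairMap(sn)), 3L)
  S <- as.matrix(stoichiometry(sn))
  for (q in seq_len(nrow(pairMap(sn))))
    expect_identical(S[, pairMap(sn)[q, 1]], -S[, pairMap(sn)[q, 2]])
  expect_identical(reactionIds(sn)[pairMap(sn)[, 2]],
                   c("v1_R", "v2_R", "v3_R"))
  org <- originMap(sn)
  expect_identical(org$origin[org$id == "v2_R"], "v2")
  expect_identical(org$direction[org$id == "v2_R"], "reverse")
  # forward bound from ub, backward from |lb|
  expect_equal(unname(upperBounds(sn)[c("v1", "v1_R")]), c(800, 800))
})

test_that("splitting an already-irreversible network is the identity", {
  net <- makeToyNetwork("chain", 4)
  again <- splitReversible(net@network)
  expect_equal(nrow(pairMap(again)), 0L)
  expect_identical(as.matrix(stoichiometry(again)),
                   as.matrix(stoichiometry(net)))
  expect_identical(reactionIds(again), reactionIds(net))
})

test_that("asymmetric flux bounds map to asymmetric split caps", {
  base <- networkFromReactions(list(
    list(id = "v", substrates = c(A = 1), products = c(B = 1),
         reversible = TRUE, lower_bound = -3, upper_bound = 7)))
  sn <- splitReversible(base)
  expect_equal(unname(upperBounds(sn)[c("v", "v_R")]), c(7, 3))
})

test_that("an _R id collision is refused with both ids reported", {
  base <- networkFromReactions(list(
    list(id = "v", substrates = c(A = 1), products = c(B = 1),
         reversible = TRUE),
    list(id = "v_R", substrates = c(B = 1), products = c(A = 1))))
  expect_error(splitReversible(base), "v_R")
})

test_that("boundary reactions are found by empty sides and boundary species", {
  rxns <- list(
    list(id = "src", substrates = stats::setNames(numeric(0), character(0)),
         products = c(A = 1)),
    list(id = "r1", substrates = c(A = 1), products = c(B = 1)),
    list(id = "snk", substrates = c(B = 1),
         products = stats::setNames(numeric(0), character(0))),
    list(id = "exb", substrates = c(X_b = 1), products = c(A = 1)))
  net <- splitReversible(networkFromReactions(rxns, boundary = "X_b"))
  expect_setequal(findBoundaryReactions(net), c("src", "snk", "exb"))
})

test_that("blocking sets caps to zero except for exempted reactions", {
  rxns <- list(
    list(id = "src", substrates = stats::setNames(numeric(0), character(0)),
         products = c(A = 1)),
    list(id = "r1", substrates = c(A = 1), products = c(B = 1)),
    list(id = "snk", substrates = c(B = 1),
         products = stats::setNames(numeric(0), character(0))))
  net <- splitReversible(networkFromReactions(rxns))
  blocked <- blockBoundary(net, exempt = "snk")
  expect_equal(unname(upperBounds(blocked)[c("src", "r1", "snk")]),
               c(0, 1000, 1000))
  expect_identical(attr(blocked, "blocked"), "src")
  # exempting everything is a no-op
  all_ex <- blockBoundary(net, exempt = c("src", "snk"))
  expect_equal(upperBounds(all_ex), upperBounds(net))
  # empty exemptions leave no open source or sink
  none <- blockBoundary(net)
  expect_equal(unname(upperBounds(none)[c("src", "snk")]), c(0, 0))
  expect_error(blockBoundary(net, exempt = "nope"), "nope")
})

test_that("the network table reports origin, direction and caps", {
  base <- networkFromReactions(list(
    list(id = "v", substrates = c(A = 1), products = c(B = 1),
         reversible = TRUE, lower_bound = -2, upper_bound = 5)))
  sn <- splitReversible(base)
  f <- withr::local_tempfile(fileext = ".tsv")
  tbl <- networkTable(sn, f)
  expect_identical(tbl$reaction, c("v", "v_R"))
  expect_identical(tbl$direction, c("forward", "reverse"))
  expect_equal(tbl$upper_bound, c(5, 2))
  expect_identical(utils::read.delim(f)$reaction, c("v", "v_R"))
})
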