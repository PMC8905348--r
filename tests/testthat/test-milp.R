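test_that("the chain instance solves to the hand-computed optimum", {
  ci <- chainInstance(lambda = 0.1)
  s <- solveOnce(ci$problem)
  expect_s4_class(s, "ShiftSolution")
  expect_equal(s@objective, -3.4, tolerance = 1e-6)
  expect_equal(unname(s@phi), c(2, 2), tolerance = 1e-6)
  expect_setequal(activeReactions(s), c("r1", "r2"))
  expect_equal(unname(s@predictedVariation), c(-2, 0, 2), tolerance = 1e-6)
  expect_identical(s@status, "optimal")
  # independent re-evaluation agrees with the solver objective
  expect_equal(evaluateObjective(ci$problem, s), s@objective,
               tolerance = 1e-6)
})

test_that("cardinality-only mode (lambda = 1) counts reactions", {
  ci <- chainInstance(lambda = 1)
  s <- solveOnce(ci$problem)
  expect_equal(s@objective, 2, tolerance = 1e-6)
  expect_setequal(activeReactions(s), c("r1", "r2"))
})

test_that("no measurements and epsilon 0 yield the empty solution", {
  net <- makeToyNetwork("chain", 3)
  ms <- MeasurementSet(data.frame(metabolite_id = character(),
                                  delta_min = numeric(),
                                  delta_max = numeric()))
  p <- buildProblem(net, buildBoundVectors(net, ms), lambda = 0.1)
  s <- solveOnce(p)
  expect_equal(s@objective, 0, tolerance = 1e-9)
  expect_length(activeReactions(s), 0)
  expect_equal(evaluateObjective(p, s), 0)
})

test_that("lambda outside (0, 1] and misaligned bounds are rejected", {
  ci <- chainInstance()
  bv <- buildBoundVectors(ci$net, ci$ms)
  expect_error(buildProblem(ci$net, bv, lambda = 0), "lambda")
  expect_error(buildProblem(ci$net, bv, lambda = 1.2), "lambda")
  short <- new("BoundVectors", deltaMin = c(A = -1), deltaMax = c(A = 1),
               measured = c(A = FALSE), sign = c(A = 0))
  expect_error(buildProblem(ci$net, short, lambda = 0.5), "aligned")
})

test_that("forward and reverse of a split pair never co-occur", {
  net <- makeToyNetwork("reversible_pair", 2)
  ms <- MeasurementSet(data.frame(metabolite_id = c("A", "B"),
                                  delta_min = c(-1, 1), delta_max = c(-1, 1)))
  p <- buildProblem(net, buildBoundVectors(net, ms), lambda = 0.1)
  s <- solveOnce(p)
  expect_identical(activeReactions(s), "r1")
  pm <- pairMap(net)
  expect_lte(sum(s@support[pm[1, ]]), 1L)
  # the reverse direction is picked when the signs flip
  ms2 <- MeasurementSet(data.frame(metabolite_id = c("A", "B"),
                                   delta_min = c(1, -1), delta_max = c(1, -1)))
  s2 <- solveOnce(buildProblem(net, buildBoundVectors(net, ms2), lambda = 0.1))
  expect_identical(activeReactions(s2), "r1_R")
})

test_that("an unsatisfiable instance reports the binding metabolites", {
  net <- makeToyNetwork("chain", 3)
  # A can release at most 2 moles but C demands at least 3
  ms <- MeasurementSet(data.frame(metabolite_id = c("A", "C"),
                                  delta_min = c(-2, 3), delta_max = c(-1, 4)))
  p <- buildProblem(net, buildBoundVectors(net, ms), lambda = 0.1)
  expect_error(solveOnce(p), "infeasible")
  expect_error(solveOnce(p), "A|C")  # at least one binding metabolite named
})

test_that("epsilon slack appears in the objective at its (1 - lambda) price", {
  # same chain but C demands one mole more than A supplies: with epsilon = 1
  # the extra mole must come out of B's relaxation
  net <- makeToyNetwork("chain", 3)
  ms <- MeasurementSet(data.frame(metabolite_id = c("A", "C"),
                                  delta_min = c(-2, 3), delta_max = c(-2, 3)),
                       epsilon = 1)
  p <- buildProblem(net, buildBoundVectors(net, ms), lambda = 0.1)
  s <- solveOnce(p)
  expect_equal(unname(abs(s@predictedVariation["B"])), 1, tolerance = 1e-6)
  # objective = 0.2 - 0.9 * (2 + 3) + 0.9 * 1
  expect_equal(s@objective, 0.2 - 0.9 * 5 + 0.9, tolerance = 1e-6)
  expect_equal(evaluateObjective(p, s), s@objective, tolerance = 1e-6)
})

test_that("feasibility checking flags planted violations and only those", {
  ci <- chainInstance()
  s <- solveOnce(ci$problem)
  expect_identical(nrow(checkFeasibility(ci$problem, s)), 0L)

  s_phi <- s
  s_phi@phi["r1"] <- s_phi@phi["r1"] + 1    # breaks A's row and B's balance
  v1 <- checkFeasibility(ci$problem, s_phi)
  expect_gt(nrow(v1), 0)
  expect_true(all(grepl("row", v1$constraint)))

  s_y <- s
  s_y@support["r1"] <- FALSE                # phi > 0 with y = 0
  v2 <- checkFeasibility(ci$problem, s_y)
  expect_true("link_zero" %in% v2$constraint)

  s_t <- s
  s_t@phi["r2"] <- 1e-6                     # y = 1 with phi below theta
  v3 <- checkFeasibility(ci$problem, s_t)
  expect_true("link_theta" %in% v3$constraint)
})

test_that("scaling data by c > 0 scales the continuous objective part", {
  base <- samplePlantedProblem(11)
  expect_false(is.null(base))
  s1 <- solveOnce(base$problem)
  for (c_scale in c(0.5, 3)) {
    ms2 <- base$measurements
    ms2@intervals$delta_min <- ms2@intervals$delta_min * c_scale
    ms2@intervals$delta_max <- ms2@intervals$delta_max * c_scale
    ms2@epsilon <- ms2@epsilon * c_scale
    net2 <- base$network
    net2@network@reactions$upper_bound <-
      net2@network@reactions$upper_bound * c_scale
    p2 <- buildProblem(net2, buildBoundVectors(net2, ms2), lambda = 0.1)
    s2 <- solveOnce(p2)
    lam <- 0.1
    cont1 <- s1@objective - lam * sum(s1@support)
    cont2 <- s2@objective - lam * sum(s2@support)
    expect_equal(cont2, c_scale * cont1, tolerance = 1e-5)
    expect_setequal(activeReactions(s2), activeReactions(s1))
  }
})

test_that("gap and time limits are honoured and reported in the status", {
  sp <- samplePlantedProblem(17)
  expect_false(is.null(sp))
  pg <- buildProblem(sp$network, buildBoundVectors(sp$network,
                                                   sp$measurements),
                     lambda = 0.1, mip_gap = 0.25)
  sg <- solveOnce(pg)
  expect_true(sg@status %in% c("optimal", "gap_limit"))
  exact <- solveOnce(sp$problem)
  expect_lte(exact@objective, sg@objective + 1e-9)
  if (sg@status == "gap_limit")
    expect_lte(sg@objective,
               exact@objective + 0.25 * abs(exact@objective) + 1e-6)
})
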