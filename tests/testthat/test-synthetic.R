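test_that("toy topologies have the documented shapes", {
  ch <- makeToyNetwork("chain", 3)
  expect_identical(metaboliteIds(ch), c("A", "B", "C"))
  expect_identical(reactionIds(ch), c("r1", "r2"))
  expect_equal(as.vector(stoichiometry(ch)[, "r1"]), c(-1, 1, 0))

  br <- makeToyNetwork("branch", 3)
  expect_identical(reactionIds(br), c("r1", "r2", "r3"))
  expect_equal(as.vector(stoichiometry(br)[, "r2"]), c(-1, 0, 1)) # A -> C
  expect_equal(as.vector(stoichiometry(br)[, "r3"]), c(0, 1, -1)) # C -> B

  cy <- makeToyNetwork("cycle", 4)
  expect_equal(nReactions(cy), 4L)
  expect_equal(as.vector(Matrix::rowSums(stoichiometry(cy))), rep(0, 4))

  rp <- makeToyNetwork("reversible_pair", 2)
  expect_identical(reactionIds(rp), c("r1", "r1_R"))
  expect_equal(nrow(pairMap(rp)), 1L)

  expect_error(makeToyNetwork("chain", 1), "at least 2")
})

test_that("random toy networks are connected and reproducible", {
  a <- makeToyNetwork("random", 7, seed = 3)
  b <- makeToyNetwork("random", 7, seed = 3)
  expect_identical(as.matrix(stoichiometry(a)), as.matrix(stoichiometry(b)))
  # connectivity: every metabolite touches at least one reaction, and a walk
  # over undirected adjacency reaches every node
  S <- as.matrix(stoichiometry(a))
  adj <- abs(S) %*% t(abs(S)) > 0
  reach <- c(1L); repeat {
    nxt <- unique(c(reach, which(colSums(adj[reach, , drop = FALSE]) > 0)))
    if (length(nxt) == length(reach)) break
    reach <- nxt
  }
  expect_length(reach, nMetabolites(a))
})

test_that("planted instances derive one-signed intervals from S phi*", {
  net <- makeToyNetwork("chain", 3)
  inst <- makePlantedInstance(net, c("r1", "r2"), magnitudes = 2)
  expect_equal(unname(inst@phiStar[c("r1", "r2")]), c(2, 2))
  # noise 0: point intervals, only A and C qualify (B balances)
  expect_setequal(inst@measuredIds, c("A", "C"))
  expect_equal(inst@deltas$delta_min, inst@deltas$delta_max)
  expect_equal(inst@epsilonRequired, 0)
  # with noise, intervals widen and remain one-signed
  instn <- makePlantedInstance(net, c("r1", "r2"), magnitudes = 2,
                               noise_halfwidth = 0.5)
  expect_true(all(instn@deltas$delta_max - instn@deltas$delta_min == 1))
  expect_true(all(instn@deltas$delta_min * instn@deltas$delta_max > 0))
  # phi* is feasible for its own instance
  ms <- MeasurementSet(inst@deltas, epsilon = inst@epsilonRequired)
  p <- buildProblem(net, buildBoundVectors(net, ms), lambda = 0.1)
  s_manual <- new("ShiftSolution", phi = inst@phiStar,
                  support = inst@phiStar > 0,
                  objective = 0,
                  predictedVariation = as.vector(stoichiometry(net) %*%
                                                   inst@phiStar),
                  status = "optimal", gap = 0)
  expect_identical(nrow(checkFeasibility(p, s_manual)), 0L)
})

test_that("degenerate planted supports are rejected", {
  rp <- makeToyNetwork("reversible_pair", 2)
  expect_error(makePlantedInstance(rp, c("r1", "r1_R")), "pair exclusivity")
  cy <- makeToyNetwork("cycle", 3)
  # a full unit cycle moves no net mass: nothing to measure
  expect_error(makePlantedInstance(cy, reactionIds(cy), magnitudes = 1),
               "rejected")
  expect_error(makePlantedInstance(cy, "nope"), "nope")
  expect_error(makePlantedInstance(cy, "r1", magnitudes = -1), "positive")
})

test_that("the exhaustive oracle reproduces the hand-computed optima", {
  ci <- chainInstance(lambda = 0.1)
  bf <- bruteForceSolve(ci$problem)
  expect_identical(bf$status, "optimal")
  expect_equal(bf$objective, -3.4, tolerance = 1e-6)
  expect_length(bf$supports, 1L)
  expect_setequal(bf$supports[[1]], c("r1", "r2"))

  bi <- branchInstance(lambda = 0.1)
  bfb <- bruteForceSolve(bi$problem)
  expect_equal(bfb$objective, -1.7, tolerance = 1e-6)
  expect_identical(bfb$supports[[1]], "r1")

  # infeasible instance: empty support list and the flag
  net <- makeToyNetwork("chain", 3)
  ms <- MeasurementSet(data.frame(metabolite_id = c("A", "C"),
                                  delta_min = c(-2, 3), delta_max = c(-1, 4)))
  pinf <- buildProblem(net, buildBoundVectors(net, ms), lambda = 0.1)
  bfi <- bruteForceSolve(pinf)
  expect_identical(bfi$status, "infeasible")
  expect_length(bfi$supports, 0L)
})

test_that("the oracle refuses instances beyond its size guard", {
  net <- makeToyNetwork("cycle", 15)
  ms <- MeasurementSet(data.frame(metabolite_id = "A",
                                  delta_min = -1, delta_max = -1))
  p <- buildProblem(net, buildBoundVectors(net, ms), lambda = 0.1)
  expect_error(bruteForceSolve(p), "too large")
  expect_error(bruteForceEnumerate(p, 2), "too large")
})

test_that("the oracle enumeration loop matches the derived sequences", {
  bi <- branchInstance(lambda = 0.1)
  be <- bruteForceEnumerate(bi$problem, 10)
  expect_identical(supportKeys(be$supports), supportKeys(list("r1", c("r2", "r3"))))
  expect_identical(be$supports[[1]], "r1")
  expect_identical(be$termination, "infeasible")
  expect_false(any(be$tied))
  b1 <- bruteForceEnumerate(bi$problem, 1)
  expect_length(b1$supports, 1L)

  ci <- chainInstance(lambda = 0.1)
  bc <- bruteForceEnumerate(ci$problem, 5)
  expect_length(bc$supports, 1L)
  expect_setequal(bc$supports[[1]], c("r1", "r2"))
})

test_that("toy fixtures round-trip through the SBML reader end-to-end", {
  net <- makeToyNetwork("branch", 4)
  f <- withr::local_tempfile(fileext = ".xml")
  writeSBML(net, f)
  reread <- splitReversible(readSBML(f))
  expect_identical(as.matrix(stoichiometry(reread)),
                   as.matrix(stoichiometry(net)))
  inst <- makePlantedInstance(net, c("r2", "r3", "r4"), magnitudes = 1.5)
  ms <- MeasurementSet(inst@deltas, epsilon = 0)
  p <- buildProblem(reread, buildBoundVectors(reread, ms), lambda = 0.1)
  ss <- enumerateSolutions(p, n_max = 10)
  expect_true(any(vapply(supportSet(ss), function(s)
    setequal(s, c("r2", "r3", "r4")), logical(1))))
})
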