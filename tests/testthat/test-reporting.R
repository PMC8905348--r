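test_that("occurrence percentages follow the enumerated solutions", {
  bi <- branchInstance()
  ss <- enumerateSolutions(bi$problem, n_max = 10)
  tbl <- occurrenceTable(ss, bi$net)
  expect_setequal(tbl$reaction, c("r1", "r2", "r3"))
  expect_true(all(tbl$occurrence_pct == 50))
  expect_true(all(tbl$occurrence_count == 1L))
  expect_true(all(tbl$direction == "forward"))
  # a single-solution set puts every active reaction at 100%
  s1 <- enumerateSolutions(bi$problem, n_max = 1)
  t1 <- occurrenceTable(s1, bi$net)
  expect_identical(t1$reaction, "r1")
  expect_equal(t1$occurrence_pct, 100)
  expect_equal(t1$mean_phi, 1, tolerance = 1e-6)
  # never-active reactions are absent
  expect_false("r2" %in% t1$reaction)
  expect_error(occurrenceTable(new("SolutionSet", solutions = list(),
                                   cuts = list(), termination = "infeasible"),
                               bi$net), "empty")
})

test_that("occurrence counts equal the sum of per-solution activity", {
  sp <- samplePlantedProblem(6)
  expect_false(is.null(sp))
  ss <- enumerateSolutions(sp$problem, n_max = 3)
  tbl <- occurrenceTable(ss, sp$network)
  org <- originMap(sp$network)
  for (i in seq_len(nrow(tbl))) {
    rid <- org$id[org$origin == tbl$reaction[i] &
                  org$direction == tbl$direction[i]]
    manual <- sum(vapply(ss@solutions, function(s) s@support[[rid]],
                         logical(1)))
    expect_identical(tbl$occurrence_count[i], as.integer(manual))
    expect_equal(tbl$occurrence_pct[i],
                 100 * manual / length(ss@solutions))
  }
})

test_that("predicted variations carry the solved S phi per solution", {
  ci <- chainInstance()
  ss <- enumerateSolutions(ci$problem, n_max = 1)
  pv <- predictedVariations(ss, ci$net,
                            buildBoundVectors(ci$net, ci$ms))
  expect_equal(pv$variation, c(-2, 0, 2), tolerance = 1e-6)
  expect_identical(pv$change, c("depletion", "none", "accumulation"))
  expect_identical(pv$measured, c(TRUE, FALSE, TRUE))
})

test_that("pathway-map export signs reverse directions and suffixes clashes", {
  tbl <- data.frame(reaction = c("r1", "FBA"),
                    direction = c("forward", "reverse"),
                    occurrence_count = c(1L, 2L),
                    occurrence_pct = c(50, 100),
                    mean_phi = c(1, 2), stringsAsFactors = FALSE)
  f <- withr::local_tempfile(fileext = ".json")
  mapping <- exportEscher(tbl, f)
  expect_equal(mapping[["r1"]], 50)
  expect_equal(mapping[["FBA"]], -100)
  parsed <- jsonlite::read_json(f)
  expect_equal(parsed$FBA, -100)
  # both directions across solutions: suffixed entries plus a warning
  tbl2 <- data.frame(reaction = c("v", "v"),
                     direction = c("forward", "reverse"),
                     occurrence_count = c(1L, 1L),
                     occurrence_pct = c(60, 40),
                     mean_phi = c(1, 1), stringsAsFactors = FALSE)
  expect_warning(m2 <- exportEscher(tbl2, f), "both directions")
  expect_equal(m2[["v_fwd"]], 60)
  expect_equal(m2[["v_rev"]], -40)
  # empty table -> empty but valid mapping file
  empty <- tbl[integer(0), ]
  exportEscher(empty, f)
  expect_length(jsonlite::read_json(f), 0)
})

test_that("occurrence distance is symmetric and zero only on agreement", {
  a <- data.frame(reaction = c("r1", "r2"), direction = "forward",
                  occurrence_pct = c(100, 50))
  b <- data.frame(reaction = c("r1", "r3"), direction = "forward",
                  occurrence_pct = c(80, 30))
  expect_equal(occurrenceDistance(a, b), occurrenceDistance(b, a))
  expect_equal(occurrenceDistance(a, b), mean(c(20, 50, 30)))
  expect_equal(occurrenceDistance(a, a), 0)
  expect_equal(occurrenceDistance(a, b, aggregate = "max"), 50)
})

test_that("excluding a decisive metabolite moves the robustness distance", {
  bi <- branchInstance()
  out <- robustnessAnalysis(bi$net, bi$ms,
                            exclusions = list(character(0), "B"),
                            lambda = 0.1, n_max = 10)
  expect_equal(out$distance, c(0, 50))
  expect_equal(out$n_solutions, c(2L, 0L))
  expect_error(robustnessAnalysis(bi$net, bi$ms,
                                  exclusions = list(c("A", "B")),
                                  lambda = 0.1, n_max = 2),
               "every measured")
  expect_error(robustnessAnalysis(bi$net, bi$ms, exclusions = list("Q"),
                                  lambda = 0.1, n_max = 2), "Q")
})

test_that("random exclusion sets are reproducible under a seed", {
  ms <- MeasurementSet(data.frame(metabolite_id = letters[1:6],
                                  delta_min = 1:6, delta_max = 2:7))
  a <- randomExclusionSets(ms, k = 3, size = 2, seed = 42)
  b <- randomExclusionSets(ms, k = 3, size = 2, seed = 42)
  expect_identical(a, b)
  expect_true(all(vapply(a, length, integer(1)) == 2))
  expect_error(randomExclusionSets(ms, 2, 6, 1), "at least one")
})

test_that("a run directory contains all per-solution and aggregate files", {
  bi <- branchInstance()
  ss <- enumerateSolutions(bi$problem, n_max = 10)
  d <- withr::local_tempdir()
  writeRunDirectory(ss, bi$problem, d)
  expect_true(file.exists(file.path(d, "occurrence.tsv")))
  expect_true(file.exists(file.path(d, "escher_data.json")))
  expect_true(file.exists(file.path(d, "run_log.txt")))
  expect_length(list.files(file.path(d, "solutions")), 2L)
  expect_length(list.files(file.path(d, "variations")), 2L)
  occ <- utils::read.delim(file.path(d, "occurrence.tsv"))
  expect_setequal(occ$reaction, c("r1", "r2", "r3"))
  sol1 <- utils::read.delim(file.path(d, "solutions", "solution_1.tsv"))
  expect_identical(sol1$reaction, "r1")
  expect_equal(sol1$phi, 1, tolerance = 1e-6)
})
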