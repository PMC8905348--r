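# Shared toy instances.
#
# The chain instance: A -> B -> C with A depleted by [1, 2] moles and C
# accumulated by [1, 2]; with epsilon = 0, B must balance, so the only
# feasible support is {r1, r2} with phi1 = phi2 in [1, 2]. At lambda = 0.1
# the objective 0.1 * 2 - 0.9 * (t + t) is minimised at t = 2: -3.4.
chainInstance <- function(lambda = 0.1, epsilon = 0, ...) {
  net <- makeToyNetwork("chain", 3)
  ms <- MeasurementSet(data.frame(metabolite_id = c("A", "C"),
                                  delta_min = c(-2, 1), delta_max = c(-1, 2)),
                       epsilon = epsilon)
  list(net = net, ms = ms,
       problem = buildProblem(net, buildBoundVectors(net, ms),
                              lambda = lambda, ...))
}

# The branch instance: r1: A -> B and r2: A -> C, r3: C -> B, with A -> -1
# and B -> +1 exactly; {r1} (objective 0.1 - 0.9 * 2 = -1.7) beats {r2, r3}
# (0.2 - 0.9 * 2 = -1.6); nothing else is feasible at epsilon = 0.
branchInstance <- function(lambda = 0.1, epsilon = 0, ...) {
  net <- makeToyNetwork("branch", 3)
  ms <- MeasurementSet(data.frame(metabolite_id = c("A", "B"),
                                  delta_min = c(-1, 1), delta_max = c(-1, 1)),
                       epsilon = epsilon)
  list(net = net, ms = ms,
       problem = buildProblem(net, buildBoundVectors(net, ms),
                              lambda = lambda, ...))
}

supportSet <- function(ss) lapply(ss@solutions, function(s)
  sort(activeReactions(s)))

supportKeys <- function(supports) sort(vapply(supports, function(s)
  paste(sort(s), collapse = "+"), character(1)))
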