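#' @import methods
#' @importFrom Matrix Matrix sparseMatrix
NULL

setClassUnion("numericOrNULL", c("numeric", "NULL"))

#' MetabolicNetwork: a stoichiometric model
#'
#' Container for a metabolic network viewed as a weighted directed hypergraph:
#' metabolites are vertices, reactions are hyperarcs connecting a substrate set
#' to a disjoint product set, and the m x n stoichiometric matrix S carries the
#' coefficients (negative for consumption, positive for production).
#'
#' @slot metabolites data.frame with columns \code{id}, \code{name},
#'   \code{compartment}, \code{boundary} (logical: species outside the
#'   modelled system).
#' @slot reactions data.frame with columns \code{id}, \code{name},
#'   \code{reversible} (logical), \code{lower_bound}, \code{upper_bound}.
#' @slot stoich sparse m x n matrix (rows = metabolites, columns = reactions),
#'   dimnames set to the metabolite and reaction ids.
#'
#' @details Metabolite and reaction order is the document order of the source
#' SBML (or the construction order for synthetic networks); every matrix and
#' report in the package follows it, so output is stable across runs.
#'
#' @export
setClass("MetabolicNetwork",
  representation(
    metabolites = "data.frame",
    reactions   = "data.frame",
    stoich      = "Matrix"
  )
)

setValidity("MetabolicNetwork", function(object) {
  msgs <- character()
  met <- object@metabolites
  rxn <- object@reactions
  S <- object@stoich
  need_met <- c("id", "name", "compartment", "boundary")
  need_rxn <- c("id", "name", "reversible", "lower_bound", "upper_bound")
  if (!all(need_met %in% names(met)))
    msgs <- c(msgs, paste("metabolites must have columns:",
                          paste(need_met, collapse = ", ")))
  if (!all(need_rxn %in% names(rxn)))
    msgs <- c(msgs, paste("reactions must have columns:",
                          paste(need_rxn, collapse = ", ")))
  if (length(msgs)) return(msgs)
  if (anyDuplicated(met$id)) msgs <- c(msgs, "duplicate metabolite ids")
  if (anyDuplicated(rxn$id)) msgs <- c(msgs, "duplicate reaction ids")
  if (any(!nzchar(met$id))) msgs <- c(msgs, "empty metabolite id")
  if (nrow(S) != nrow(met) || ncol(S) != nrow(rxn))
    msgs <- c(msgs, "stoichiometric matrix dimensions disagree with tables")
  if (nrow(met) > 0L && !identical(rownames(S), met$id))
    msgs <- c(msgs, "stoich rownames must equal metabolite ids")
  if (nrow(rxn) > 0L && !identical(colnames(S), rxn$id))
    msgs <- c(msgs, "stoich colnames must equal reaction ids")
  if (any(rxn$upper_bound < rxn$lower_bound))
    msgs <- c(msgs, "reaction lower_bound exceeds upper_bound")
  if (length(msgs)) msgs else TRUE
})

#' SplitNetwork: an irreversible network with registered forward/backward pairs
#'
#' Result of splitting every reversible reaction into a forward and a backward
#' copy. All member reactions run forward only (moles passed phi_j >= 0); the
#' pair map records which columns originate from one reversible reaction so
#' that mutual exclusion (at most one direction active per solution) can be
#' enforced downstream.
#'
#' @slot network a \linkS4class{MetabolicNetwork} in which every reaction is
#'   irreversible; \code{upper_bound} is the moles-passed cap u_j and
#'   \code{lower_bound} is 0.
#' @slot pairs integer matrix with columns \code{fwd}, \code{rev}: column
#'   indices of each split couple.
#' @slot origin data.frame with columns \code{id}, \code{origin},
#'   \code{direction} mapping each split reaction to its source reaction and
#'   sense (\code{"forward"} or \code{"reverse"}).
#'
#' @export
setClass("SplitNetwork",
  representation(
    network = "MetabolicNetwork",
    pairs   = "matrix",
    origin  = "data.frame"
  )
)

setValidity("SplitNetwork", function(object) {
  msgs <- character()
  net <- object@network
  if (any(net@reactions$reversible))
    msgs <- c(msgs, "split network still contains reversible reactions")
  if (any(net@reactions$lower_bound != 0))
    msgs <- c(msgs, "split reactions must have lower_bound 0")
  if (any(net@reactions$upper_bound < 0))
    msgs <- c(msgs, "negative upper bound")
  p <- object@pairs
  if (ncol(p) != 2L || !identical(colnames(p), c("fwd", "rev")))
    msgs <- c(msgs, "pairs must be an integer matrix with columns fwd, rev")
  n <- nrow(net@reactions)
  if (nrow(p) > 0L) {
    if (any(p < 1L) || any(p > n))
      msgs <- c(msgs, "pair index out of range")
    if (anyDuplicated(as.vector(p)))
      msgs <- c(msgs, "a reaction appears in more than one pair slot")
    # backward column must be the exact negation of the forward column
    S <- net@stoich
    for (k in seq_len(nrow(p))) {
      if (!isTRUE(all(S[, p[k, 1L]] == -S[, p[k, 2L]]))) {
        msgs <- c(msgs, sprintf("pair %d: columns are not exact negations", k))
        break
      }
    }
  }
  if (nrow(object@origin) != n)
    msgs <- c(msgs, "origin map must have one row per reaction")
  if (length(msgs)) msgs else TRUE
})

#' MeasurementSet: measured concentration-change intervals
#'
#' The measured metabolite set X with a strictly one-signed interval
#' [delta_min, delta_max] of moles accumulated (positive) or depleted
#' (negative) per metabolite, the relaxation epsilon granted to non-measured
#' metabolites, and optional virtual source/sink declarations.
#'
#' @slot intervals data.frame with columns \code{metabolite_id},
#'   \code{delta_min}, \code{delta_max}, \code{sign}.
#' @slot epsilon non-negative scalar: non-measured metabolites may vary within
#'   [-epsilon, +epsilon] unless overridden.
#' @slot epsilonOverrides data.frame with columns \code{metabolite_id},
#'   \code{eps_min}, \code{eps_max} for per-metabolite relaxation bounds.
#' @slot sources data.frame (\code{metabolite_id}, \code{magnitude}): the
#'   metabolite may be drawn from an external pool, i.e. its delta_min is
#'   lowered to -magnitude.
#' @slot sinks data.frame (\code{metabolite_id}, \code{magnitude}): delta_max
#'   is raised to +magnitude.
#'
#' @export
setClass("MeasurementSet",
  representation(
    intervals        = "data.frame",
    epsilon          = "numeric",
    epsilonOverrides = "data.frame",
    sources          = "data.frame",
    sinks            = "data.frame"
  ),
  prototype(
    intervals        = data.frame(metabolite_id = character(),
                                  delta_min = numeric(),
                                  delta_max = numeric(),
                                  sign = numeric()),
    epsilon          = 0,
    epsilonOverrides = data.frame(metabolite_id = character(),
                                  eps_min = numeric(), eps_max = numeric()),
    sources          = data.frame(metabolite_id = character(),
                                  magnitude = numeric()),
    sinks            = data.frame(metabolite_id = character(),
                                  magnitude = numeric())
  )
)

setValidity("MeasurementSet", function(object) {
  msgs <- character()
  iv <- object@intervals
  if (anyDuplicated(iv$metabolite_id))
    msgs <- c(msgs, "duplicate measured metabolite")
  if (any(iv$delta_min > iv$delta_max))
    msgs <- c(msgs, "delta_min > delta_max")
  spans <- iv$delta_min <= 0 & iv$delta_max >= 0
  if (any(spans))
    msgs <- c(msgs, paste("interval spans zero for:",
                          paste(iv$metabolite_id[spans], collapse = ", ")))
  if (any(sign(iv$delta_min) != iv$sign))
    msgs <- c(msgs, "sign column disagrees with interval sign")
  if (length(object@epsilon) != 1L || object@epsilon < 0)
    msgs <- c(msgs, "epsilon must be a single non-negative number")
  if (any(object@epsilonOverrides$metabolite_id %in% iv$metabolite_id))
    msgs <- c(msgs, "a metabolite cannot be both measured and epsilon-overridden")
  if (any(object@sources$magnitude <= 0) || any(object@sinks$magnitude <= 0))
    msgs <- c(msgs, "source/sink magnitudes must be positive")
  if (length(msgs)) msgs else TRUE
})

#' BoundVectors: assembled per-metabolite variation bounds
#'
#' The vectors Delta_min and Delta_max over all metabolites of a network, in
#' network order: measured entries carry their intervals, non-measured entries
#' the epsilon relaxation, with source/sink declarations widening individual
#' components.
#'
#' @slot deltaMin named numeric vector over metabolites.
#' @slot deltaMax named numeric vector.
#' @slot measured named logical vector (membership in X).
#' @slot sign named numeric vector: +1/-1 on measured entries, 0 elsewhere.
#'
#' @export
setClass("BoundVectors",
  representation(
    deltaMin = "numeric",
    deltaMax = "numeric",
    measured = "logical",
    sign     = "numeric"
  )
)

setValidity("BoundVectors", function(object) {
  msgs <- character()
  if (length(object@deltaMin) != length(object@deltaMax) ||
      length(object@deltaMin) != length(object@measured) ||
      length(object@deltaMin) != length(object@sign))
    msgs <- c(msgs, "component vectors must have equal length")
  else {
    if (any(object@deltaMin > object@deltaMax))
      msgs <- c(msgs, "deltaMin > deltaMax componentwise")
    if (any(object@sign[!object@measured] != 0))
      msgs <- c(msgs, "sign must be 0 on non-measured entries")
    if (any(object@sign[object@measured] == 0))
      msgs <- c(msgs, "sign must be +/-1 on measured entries")
  }
  if (length(msgs)) msgs else TRUE
})

#' ShiftProblem: the assembled mixed-integer program
#'
#' One solver-ready instance: the split network, the variation bounds, the
#' parsimony weight lambda, the activity threshold theta linking the binary
#' support variables to the moles-passed variables, and any exclusion cuts
#' accumulated during enumeration.
#'
#' @slot network a \linkS4class{SplitNetwork}.
#' @slot bounds a \linkS4class{BoundVectors} aligned to the network.
#' @slot lambda weight in (0, 1]: lambda scales the reaction-count term,
#'   (1 - lambda) the concentration-variation terms. lambda = 1 is the
#'   cardinality-only mode (the continuous terms vanish).
#' @slot theta minimum moles passed through an active reaction (> 0); links
#'   y_j = 1 to phi_j >= theta.
#' @slot cuts list of integer vectors: reaction-index supports excluded by
#'   earlier enumeration iterations.
#' @slot opts list of solver options: \code{mip_gap}, \code{time_limit_s},
#'   \code{seed}, \code{threads} (recorded for provenance; the bundled
#'   branch-and-bound is single-threaded and deterministic).
#'
#' @export
setClass("ShiftProblem",
  representation(
    network = "SplitNetwork",
    bounds  = "BoundVectors",
    lambda  = "numeric",
    theta   = "numeric",
    cuts    = "list",
    opts    = "list"
  )
)

setValidity("ShiftProblem", function(object) {
  msgs <- character()
  if (length(object@lambda) != 1L || object@lambda <= 0 || object@lambda > 1)
    msgs <- c(msgs, "lambda must lie in (0, 1]")
  if (length(object@theta) != 1L || object@theta <= 0)
    msgs <- c(msgs, "theta must be positive")
  n <- nrow(object@network@network@reactions)
  m <- nrow(object@network@network@metabolites)
  if (length(object@bounds@deltaMin) != m)
    msgs <- c(msgs, "bounds length disagrees with metabolite count")
  bad <- vapply(object@cuts, function(cut)
    length(cut) == 0L || any(cut < 1L | cut > n), logical(1))
  if (any(bad)) msgs <- c(msgs, "invalid exclusion cut")
  if (length(msgs)) msgs else TRUE
})

#' ShiftSolution: one answer of the mixed-integer program
#'
#' @slot phi named non-negative numeric: moles passed through each split
#'   reaction over the transition interval.
#' @slot support named logical: the active set y.
#' @slot objective objective value as returned by the solver.
#' @slot predictedVariation named numeric: S phi, the net production (+) or
#'   consumption (-) of every metabolite.
#' @slot status one of \code{"optimal"}, \code{"gap_limit"},
#'   \code{"time_limit"}.
#' @slot gap achieved relative optimality gap (0 when proven optimal).
#'
#' @export
setClass("ShiftSolution",
  representation(
    phi                = "numeric",
    support            = "logical",
    objective          = "numeric",
    predictedVariation = "numeric",
    status             = "character",
    gap                = "numeric"
  )
)

setValidity("ShiftSolution", function(object) {
  msgs <- character()
  if (length(object@phi) != length(object@support))
    msgs <- c(msgs, "phi and support lengths differ")
  if (!object@status %in% c("optimal", "gap_limit", "time_limit"))
    msgs <- c(msgs, "unknown status")
  if (length(msgs)) msgs else TRUE
})

#' SolutionSet: enumerated alternate optima
#'
#' Ordered list of solutions produced by iterative exclusion-cut enumeration,
#' together with the cuts applied and the reason enumeration stopped.
#'
#' @slot solutions list of \linkS4class{ShiftSolution}.
#' @slot cuts list of character vectors: the excluded supports (reaction ids).
#' @slot termination one of \code{"count_reached"}, \code{"infeasible"},
#'   \code{"empty_support"}, \code{"degradation"}, \code{"time_budget"}.
#'
#' @export
setClass("SolutionSet",
  representation(
    solutions   = "list",
    cuts        = "list",
    termination = "character"
  )
)

setValidity("SolutionSet", function(object) {
  ok <- vapply(object@solutions, is, logical(1), class2 = "ShiftSolution")
  if (!all(ok)) return("solutions must be ShiftSolution objects")
  supports <- lapply(object@solutions, function(s) sort(names(which(s@support))))
  if (anyDuplicated(vapply(supports, paste, character(1), collapse = "\r")))
    return("duplicate supports in solution set")
  TRUE
})
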