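#' @include milp.R
NULL

#' Build an exclusion cut from a support
#'
#' Returns the linear constraint sum over the support of y_j <= |support| - 1,
#' which forbids the exact support and every superset of it in later
#' iterations.
#'
#' @param support character vector of active reaction ids, or a named logical
#'   vector (a solution's support slot).
#' @param net the \linkS4class{SplitNetwork} the ids refer to.
#' @return list with elements \code{idx} (integer reaction indices),
#'   \code{rhs} (= length(idx) - 1) and \code{ids}.
#' @export
exclusionCut <- function(support, net) {
  if (is.logical(support)) support <- names(which(support))
  if (length(support) == 0L)
    stop("degenerate cut: the empty support cannot be excluded ",
         "(an empty optimum terminates enumeration instead)")
  idx <- match(support, reactionIds(net))
  if (anyNA(idx))
    stop("unknown reaction id(s) in support: ",
         paste(support[is.na(idx)], collapse = ", "))
  list(idx = as.integer(idx), rhs = length(idx) - 1L, ids = support)
}

#' Enumerate alternate solutions with exclusion cuts
#'
#' Solves the program, records the solution, excludes its support (and all
#' supersets) with an integer cut, and re-solves, until \code{n_max} solutions
#' are found, the program becomes infeasible, the empty support is optimal, or
#' an optional objective-degradation budget is exhausted. The objective value
#' is deliberately not fixed after the first solution, so later solutions may
#' be slightly suboptimal; with a zero MIP gap the objective sequence is
#' non-decreasing because the feasible region only shrinks. Iterations that
#' stop at the gap or time limit still record and cut their (possibly
#' suboptimal) solution.
#'
#' @param p a \linkS4class{ShiftProblem}.
#' @param n_max maximum number of solutions (>= 1).
#' @param max_degradation optional fraction: stop once the objective worsens
#'   by more than this fraction of |first objective| relative to the first
#'   solution (NULL = no limit).
#' @param verify when TRUE (default) each recorded solution is checked with
#'   \code{\link{checkFeasibility}} and a violation raises an error.
#' @return a \linkS4class{SolutionSet}.
#' @examples
#' net <- makeToyNetwork("branch", 3)
#' ms <- MeasurementSet(data.frame(metabolite_id = c("A", "B"),
#'                                 delta_min = c(-1, 1), delta_max = c(-1, 1)))
#' ss <- enumerateSolutions(buildProblem(net, buildBoundVectors(net, ms),
#'                                       lambda = 0.1), n_max = 10)
#' ss
#' @export
enumerateSolutions <- function(p, n_max, max_degradation = NULL,
                               verify = TRUE) {
  stopifnot(is(p, "ShiftProblem"), n_max >= 1)
  sols <- list(); cut_ids <- list()
  termination <- "count_reached"
  firstObj <- NULL
  for (k in seq_len(n_max)) {
    s <- tryCatch(solveOnce(p), error = function(e) e)
    if (inherits(s, "error")) {
      if (k == 1L) stop(s)
      termination <- "infeasible"
      break
    }
    if (verify) {
      bad <- checkFeasibility(p, s)
      if (nrow(bad))
        stop("solver returned an infeasible solution (",
             paste(unique(bad$constraint), collapse = ", "), ")")
    }
    if (is.null(firstObj)) firstObj <- s@objective
    if (!is.null(max_degradation) &&
        s@objective > firstObj + max_degradation * abs(firstObj) + 1e-9) {
      termination <- "degradation"
      break
    }
    sols[[k]] <- s
    act <- activeReactions(s)
    if (length(act) == 0L) {
      termination <- "empty_support"
      break
    }
    cut <- exclusionCut(act, p@network)
    cut_ids[[length(cut_ids) + 1L]] <- cut$ids
    p@cuts[[length(p@cuts) + 1L]] <- cut$idx
  }
  new("SolutionSet", solutions = sols, cuts = cut_ids,
      termination = termination)
}
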