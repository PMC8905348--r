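#' @include AllGenerics.R
NULL

#' @rdname nMetabolites
#' @export
setMethod("nMetabolites", "MetabolicNetwork", function(x) nrow(x@metabolites))

#' @rdname nMetabolites
#' @export
setMethod("nMetabolites", "SplitNetwork", function(x) nMetabolites(x@network))

#' @rdname nReactions
#' @export
setMethod("nReactions", "MetabolicNetwork", function(x) nrow(x@reactions))

#' @rdname nReactions
#' @export
setMethod("nReactions", "SplitNetwork", function(x) nReactions(x@network))

#' @rdname stoichiometry
#' @export
setMethod("stoichiometry", "MetabolicNetwork", function(x) x@stoich)

#' @rdname stoichiometry
#' @export
setMethod("stoichiometry", "SplitNetwork", function(x) x@network@stoich)

#' @rdname metaboliteIds
#' @export
setMethod("metaboliteIds", "MetabolicNetwork", function(x) x@metabolites$id)

#' @rdname metaboliteIds
#' @export
setMethod("metaboliteIds", "SplitNetwork", function(x) metaboliteIds(x@network))

#' @rdname reactionIds
#' @export
setMethod("reactionIds", "MetabolicNetwork", function(x) x@reactions$id)

#' @rdname reactionIds
#' @export
setMethod("reactionIds", "SplitNetwork", function(x) reactionIds(x@network))

#' @rdname pairMap
#' @export
setMethod("pairMap", "SplitNetwork", function(x) x@pairs)

#' @rdname pairMap
#' @export
setMethod("pairMap", "ShiftProblem", function(x) x@network@pairs)

#' @rdname originMap
#' @export
setMethod("originMap", "SplitNetwork", function(x) x@origin)

#' @rdname upperBounds
#' @export
setMethod("upperBounds", "MetabolicNetwork", function(x) {
  stats::setNames(x@reactions$upper_bound, x@reactions$id)
})

#' @rdname upperBounds
#' @export
setMethod("upperBounds", "SplitNetwork", function(x) upperBounds(x@network))

#' @rdname activeReactions
#' @export
setMethod("activeReactions", "ShiftSolution", function(x, ...) {
  names(which(x@support))
})

setMethod("show", "MetabolicNetwork", function(object) {
  cat(sprintf("MetabolicNetwork: %d metabolites x %d reactions (%d reversible, %d boundary species)\n",
              nMetabolites(object), nReactions(object),
              sum(object@reactions$reversible),
              sum(object@metabolites$boundary)))
})

setMethod("show", "SplitNetwork", function(object) {
  cat(sprintf("SplitNetwork: %d metabolites x %d irreversible reactions, %d split pairs\n",
              nMetabolites(object), nReactions(object), nrow(object@pairs)))
  blocked <- sum(object@network@reactions$upper_bound == 0)
  if (blocked > 0) cat(sprintf("  %d reactions blocked (upper bound 0)\n", blocked))
})

setMethod("show", "MeasurementSet", function(object) {
  cat(sprintf("MeasurementSet: %d measured metabolites (%d accumulated, %d depleted), epsilon = %g\n",
              nrow(object@intervals), sum(object@intervals$sign > 0),
              sum(object@intervals$sign < 0), object@epsilon))
  if (nrow(object@sources)) cat("  sources:", paste(object@sources$metabolite_id, collapse = ", "), "\n")
  if (nrow(object@sinks)) cat("  sinks:  ", paste(object@sinks$metabolite_id, collapse = ", "), "\n")
})

setMethod("show", "ShiftProblem", function(object) {
  cat(sprintf("ShiftProblem: %d reactions, %d metabolites, lambda = %g, theta = %g, %d exclusion cuts\n",
              nReactions(object@network), nMetabolites(object@network),
              object@lambda, object@theta, length(object@cuts)))
})

setMethod("show", "ShiftSolution", function(object) {
  act <- activeReactions(object)
  cat(sprintf("ShiftSolution (%s): %d active reactions, objective %.6g\n",
              object@status, length(act), object@objective))
  if (length(act)) cat("  support:", paste(act, collapse = ", "), "\n")
})

setMethod("show", "SolutionSet", function(object) {
  objs <- vapply(object@solutions, function(s) s@objective, numeric(1))
  cat(sprintf("SolutionSet: %d solutions (termination: %s)\n",
              length(objs), object@termination))
  if (length(objs))
    cat(sprintf("  objective range [%.6g, %.6g]\n", min(objs), max(objs)))
})
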