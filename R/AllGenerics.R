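#' @include AllClasses.R
NULL

#' Number of metabolites
#' @param x a network object
#' @return integer count
#' @export
setGeneric("nMetabolites", function(x) standardGeneric("nMetabolites"))

#' Number of reactions
#' @param x a network object
#' @return integer count
#' @export
setGeneric("nReactions", function(x) standardGeneric("nReactions"))

#' Stoichiometric matrix
#' @param x a network object
#' @return sparse m x n matrix with metabolite/reaction dimnames
#' @export
setGeneric("stoichiometry", function(x) standardGeneric("stoichiometry"))

#' Metabolite identifiers, in network order
#' @param x a network object
#' @return character vector
#' @export
setGeneric("metaboliteIds", function(x) standardGeneric("metaboliteIds"))

#' Reaction identifiers, in network order
#' @param x a network object
#' @return character vector
#' @export
setGeneric("reactionIds", function(x) standardGeneric("reactionIds"))

#' Forward/backward split pairs
#' @param x a SplitNetwork (or object containing one)
#' @return integer matrix with columns fwd, rev
#' @export
setGeneric("pairMap", function(x) standardGeneric("pairMap"))

#' Origin of each split reaction
#' @param x a SplitNetwork (or object containing one)
#' @return data.frame with columns id, origin, direction
#' @export
setGeneric("originMap", function(x) standardGeneric("originMap"))

#' Per-reaction upper bounds on moles passed
#' @param x a network object
#' @return named numeric vector u
#' @export
setGeneric("upperBounds", function(x) standardGeneric("upperBounds"))

#' Active set of a solution
#' @param x a ShiftSolution
#' @param ... further arguments
#' @return character vector of active reaction ids
#' @export
setGeneric("activeReactions", function(x, ...) standardGeneric("activeReactions"))
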