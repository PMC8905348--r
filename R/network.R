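#' @include sbml.R
NULL

#' Build a MetabolicNetwork from a reaction list
#'
#' Convenience constructor used by the synthetic generators and tests.
#'
#' @param reactions list of reaction descriptions; each element is a list with
#'   entries \code{id}, \code{substrates} (named numeric vector of positive
#'   coefficients), \code{products} (likewise), \code{reversible} (logical,
#'   default FALSE), and optional \code{lower_bound}/\code{upper_bound}.
#' @param metabolites optional character vector fixing metabolite order;
#'   defaults to first appearance order.
#' @param boundary character vector of metabolite ids flagged as outside the
#'   modelled system.
#' @param u_default default bound magnitude.
#' @return a \linkS4class{MetabolicNetwork}.
#' @export
networkFromReactions <- function(reactions, metabolites = NULL,
                                 boundary = character(), u_default = 1000) {
  seen <- character(0)
  for (r in reactions)
    seen <- union(seen, c(names(r$substrates), names(r$products)))
  if (is.null(metabolites)) metabolites <- seen
  extra <- setdiff(seen, metabolites)
  if (length(extra))
    stop("reactions reference metabolites not listed: ",
         paste(extra, collapse = ", "))
  m <- length(metabolites); n <- length(reactions)
  ids <- vapply(reactions, function(r) r$id, character(1))
  if (anyDuplicated(ids)) stop("duplicate reaction ids")
  rev <- vapply(reactions, function(r) isTRUE(r$reversible), logical(1))
  lb <- vapply(reactions, function(r)
    if (!is.null(r$lower_bound)) r$lower_bound
    else if (isTRUE(r$reversible)) -u_default else 0, numeric(1))
  ub <- vapply(reactions, function(r)
    if (!is.null(r$upper_bound)) r$upper_bound else u_default, numeric(1))
  tri_i <- integer(0); tri_j <- integer(0); tri_x <- numeric(0)
  midx <- stats::setNames(seq_len(m), metabolites)
  for (j in seq_len(n)) {
    r <- reactions[[j]]
    if (length(intersect(names(r$substrates), names(r$products))))
      stop("reaction '", r$id, "': substrate and product sets overlap")
    if (any(c(r$substrates, r$products) <= 0))
      stop("reaction '", r$id, "': coefficients must be strictly positive")
    idx <- c(midx[names(r$substrates)], midx[names(r$products)])
    val <- c(-unname(r$substrates), unname(r$products))
    tri_i <- c(tri_i, unname(idx)); tri_j <- c(tri_j, rep(j, length(idx)))
    tri_x <- c(tri_x, val)
  }
  S <- Matrix::sparseMatrix(i = tri_i, j = tri_j, x = tri_x, dims = c(m, n),
                            dimnames = list(metabolites, ids))
  new("MetabolicNetwork",
      metabolites = data.frame(id = metabolites, name = metabolites,
                               compartment = "c",
                               boundary = metabolites %in% boundary,
                               stringsAsFactors = FALSE),
      reactions = data.frame(id = ids, name = ids, reversible = rev,
                             lower_bound = lb, upper_bound = ub,
                             stringsAsFactors = FALSE),
      stoich = S)
}

#' Split reversible reactions into forward/backward pairs
#'
#' Every reversible reaction j becomes a forward copy (same id) and a backward
#' copy with id \code{<id>_R} whose substrates and products are swapped. Both
#' copies run forward only. When the original flux bounds are
#' \code{[lb, ub]} with \code{lb < 0 < ub}, the forward copy receives upper
#' bound \code{ub} and the backward copy \code{|lb|}; non-finite bounds fall
#' back to \code{u_default}. Irreversible reactions pass through unchanged
#' (their moles-passed cap is their upper bound, floored at 0).
#'
#' @param net a \linkS4class{MetabolicNetwork}.
#' @param u_default bound magnitude used where the model gives no finite
#'   bound.
#' @param suffix suffix appended to the backward copy's id.
#' @return a \linkS4class{SplitNetwork}.
#' @examples
#' net <- makeToyNetwork("reversible_pair", 2)
#' pairMap(net)
#' @export
splitReversible <- function(net, u_default = 1000, suffix = "_R") {
  stopifnot(is(net, "MetabolicNetwork"))
  rxn <- net@reactions
  S <- net@stoich
  rev_idx <- which(rxn$reversible)
  rev_ids <- if (length(rev_idx)) paste0(rxn$id[rev_idx], suffix)
             else character(0)
  clash <- intersect(rev_ids, rxn$id)
  if (length(clash))
    stop("cannot split: backward ids collide with existing reactions: ",
         paste(sprintf("%s (from %s)", clash, sub(paste0(suffix, "$"), "", clash)),
               collapse = ", "))

  cap <- function(x) {
    x[!is.finite(x)] <- u_default
    pmax(x, 0)
  }
  n0 <- nrow(rxn)
  ids <- c(rxn$id, rev_ids)
  nms <- c(rxn$name, if (length(rev_idx)) paste0(rxn$name[rev_idx], " (reverse)")
                     else character(0))
  u_fwd <- cap(rxn$upper_bound)
  u_rev <- cap(-rxn$lower_bound[rev_idx])
  S_new <- cbind(S, -S[, rev_idx, drop = FALSE])
  colnames(S_new) <- ids
  base <- new("MetabolicNetwork",
    metabolites = net@metabolites,
    reactions = data.frame(id = ids, name = nms,
                           reversible = FALSE,
                           lower_bound = 0,
                           upper_bound = c(u_fwd, u_rev),
                           stringsAsFactors = FALSE),
    stoich = S_new)
  pairs <- cbind(fwd = rev_idx, rev = n0 + seq_along(rev_idx))
  storage.mode(pairs) <- "integer"
  origin <- data.frame(
    id = ids,
    origin = c(rxn$id, rxn$id[rev_idx]),
    direction = c(rep("forward", n0), rep("reverse", length(rev_idx))),
    stringsAsFactors = FALSE)
  new("SplitNetwork", network = base, pairs = pairs, origin = origin)
}

#' Find source and sink reactions
#'
#' A reaction is a boundary reaction when its substrate set is empty (a pure
#' source), its product set is empty (a pure sink), or every substrate --
#' or every product -- is a species flagged as outside the modelled system.
#' Such reactions move matter across the system boundary, where changes in
#' concentration escape the objective.
#'
#' @param net a \linkS4class{SplitNetwork}.
#' @return character vector of boundary reaction ids.
#' @export
findBoundaryReactions <- function(net) {
  stopifnot(is(net, "SplitNetwork"))
  S <- net@network@stoich
  bnd <- net@network@metabolites$boundary
  ids <- reactionIds(net)
  out <- character(0)
  for (j in seq_along(ids)) {
    col <- S[, j]
    subs <- which(col < 0); prods <- which(col > 0)
    if (length(subs) == 0L || length(prods) == 0L ||
        all(bnd[subs]) || all(bnd[prods]))
      out <- c(out, ids[j])
  }
  out
}

#' Block boundary reactions
#'
#' Sets the moles-passed cap of every boundary reaction not listed in
#' \code{exempt} to zero, so concentration changes cannot simply be pushed
#' outside the network. Blocking keeps the column in place (bound 0, not
#' removal) so indices and reports stay stable. Use \code{exempt} to keep,
#' e.g., a biomass sink open.
#'
#' @param net a \linkS4class{SplitNetwork}.
#' @param exempt character vector of reaction ids to leave untouched.
#' @return the modified \linkS4class{SplitNetwork}; the ids actually blocked
#'   are attached as attribute \code{"blocked"}.
#' @export
blockBoundary <- function(net, exempt = character()) {
  stopifnot(is(net, "SplitNetwork"))
  unknown <- setdiff(exempt, reactionIds(net))
  if (length(unknown))
    stop("unknown reaction id(s) in exempt: ", paste(unknown, collapse = ", "))
  to_block <- setdiff(findBoundaryReactions(net), exempt)
  idx <- match(to_block, reactionIds(net))
  net@network@reactions$upper_bound[idx] <- 0
  attr(net, "blocked") <- to_block
  net
}

#' Tabulate a split network
#'
#' Debug/report view: one row per split reaction with its origin, direction
#' and moles-passed cap. Written as TSV when \code{path} is given.
#'
#' @param net a \linkS4class{SplitNetwork}.
#' @param path optional output TSV path.
#' @return data.frame with columns reaction, origin, direction, upper_bound.
#' @export
networkTable <- function(net, path = NULL) {
  stopifnot(is(net, "SplitNetwork"))
  tbl <- data.frame(
    reaction = net@origin$id,
    origin = net@origin$origin,
    direction = net@origin$direction,
    upper_bound = net@network@reactions$upper_bound,
    stringsAsFactors = FALSE)
  if (!is.null(path))
    utils::write.table(tbl, path, sep = "\t", quote = FALSE, row.names = FALSE)
  tbl
}
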