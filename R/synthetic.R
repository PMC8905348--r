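#' @include report.R
NULL

#' PlantedInstance: a synthetic perturbation with known ground truth
#'
#' @slot network the \linkS4class{SplitNetwork}.
#' @slot phiStar named non-negative ground-truth moles-passed vector.
#' @slot measuredIds metabolites whose variation is reported.
#' @slot deltas data.frame of measured intervals derived from S phiStar.
#' @slot noiseHalfwidth half-width added around each true variation.
#' @slot epsilonRequired smallest epsilon at which phiStar itself is feasible
#'   (the largest |variation| among non-measured metabolites).
#'
#' @export
setClass("PlantedInstance",
  representation(
    network        = "SplitNetwork",
    phiStar        = "numeric",
    measuredIds    = "character",
    deltas         = "data.frame",
    noiseHalfwidth = "numeric",
    epsilonRequired = "numeric"
  )
)

setMethod("show", "PlantedInstance", function(object) {
  cat(sprintf("PlantedInstance: support {%s}, %d measured metabolites, noise %g, epsilon required %g\n",
              paste(names(which(object@phiStar > 0)), collapse = ", "),
              length(object@measuredIds), object@noiseHalfwidth,
              object@epsilonRequired))
})

#' Generate a toy split network
#'
#' Named small topologies used for testing and illustration, plus a seeded
#' random generator. All reactions have unit stoichiometry.
#'
#' \describe{
#'   \item{chain}{M1 -> M2 -> ... -> Msize (size - 1 irreversible reactions).}
#'   \item{branch}{a direct reaction A -> B plus a parallel path
#'     A -> C -> ... -> B through size - 2 intermediates.}
#'   \item{cycle}{M1 -> M2 -> ... -> Msize -> M1.}
#'   \item{reversible_pair}{A <-> B, split into r1 and r1_R.}
#'   \item{random}{a connected network on \code{size} metabolites: a random
#'     spanning tree plus extra arcs, each reaction reversible with
#'     probability \code{reversible_fraction}.}
#' }
#'
#' @param kind one of \code{"chain"}, \code{"branch"}, \code{"cycle"},
#'   \code{"reversible_pair"}, \code{"random"}.
#' @param size number of metabolites (>= 2; branch needs >= 3).
#' @param seed RNG seed (random kind only).
#' @param reversible_fraction probability that a random-kind reaction is
#'   reversible.
#' @param extra_arcs number of arcs added beyond the spanning tree (random
#'   kind); defaults to about half the size.
#' @param u_default moles-passed cap on every reaction.
#' @return a \linkS4class{SplitNetwork}.
#' @export
makeToyNetwork <- function(kind = c("chain", "branch", "cycle",
                                    "reversible_pair", "random"),
                           size, seed = 1L, reversible_fraction = 0.3,
                           extra_arcs = NULL, u_default = 1000) {
  kind <- match.arg(kind)
  if (size < 2) stop("size must be at least 2")
  met_names <- function(k) if (k <= 26) LETTERS[seq_len(k)]
                           else sprintf("M%03d", seq_len(k))
  rx <- function(id, from, to, reversible = FALSE)
    list(id = id, substrates = stats::setNames(1, from),
         products = stats::setNames(1, to), reversible = reversible,
         upper_bound = u_default,
         lower_bound = if (reversible) -u_default else 0)
  mets <- met_names(size)
  reactions <- switch(kind,
    chain = lapply(seq_len(size - 1L), function(i)
      rx(paste0("r", i), mets[i], mets[i + 1L])),
    branch = {
      if (size < 3) stop("branch needs size >= 3")
      # r1: direct A -> B; r2..: A -> C -> ... -> B
      path <- c(mets[1L], mets[3:size], mets[2L])
      c(list(rx("r1", mets[1L], mets[2L])),
        lapply(seq_len(length(path) - 1L), function(i)
          rx(paste0("r", i + 1L), path[i], path[i + 1L])))
    },
    cycle = lapply(seq_len(size), function(i)
      rx(paste0("r", i), mets[i], mets[if (i == size) 1L else i + 1L])),
    reversible_pair = list(rx("r1", mets[1L], mets[2L], reversible = TRUE)),
    random = {
      old <- if (exists(".Random.seed", globalenv()))
        get(".Random.seed", globalenv())
      on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
      set.seed(seed)
      if (is.null(extra_arcs)) extra_arcs <- max(1L, size %/% 2L)
      edges <- lapply(2:size, function(i) {
        j <- if (i == 2L) 1L else sample.int(i - 1L, 1L)
        if (stats::runif(1) < 0.5) c(j, i) else c(i, j)
      })
      for (e in seq_len(extra_arcs)) {
        repeat {
          ft <- sample.int(size, 2L)
          dup <- any(vapply(edges, function(x) all(x == ft), logical(1)))
          if (!dup) break
        }
        edges[[length(edges) + 1L]] <- ft
      }
      lapply(seq_along(edges), function(i)
        rx(paste0("r", i), mets[edges[[i]][1L]], mets[edges[[i]][2L]],
           reversible = stats::runif(1) < reversible_fraction))
    })
  net <- networkFromReactions(reactions, metabolites = mets,
                              u_default = u_default)
  splitReversible(net, u_default = u_default)
}

#' Plant a ground-truth perturbation in a network
#'
#' Builds phiStar with the given magnitudes on \code{active_support} and
#' zero elsewhere, computes the true variation S phiStar, and derives
#' measured intervals [v - noise, v + noise] for a seeded sample of the
#' metabolites whose true variation exceeds the noise half-width (so every
#' interval is strictly one-signed).
#'
#' @param net a \linkS4class{SplitNetwork}.
#' @param active_support character vector of split-reaction ids; must respect
#'   pair exclusivity.
#' @param magnitudes positive scalar or vector (recycled over the support).
#' @param measured_fraction fraction of qualifying metabolites measured.
#' @param noise_halfwidth half-width of the measured intervals.
#' @param seed RNG seed for the measured-metabolite sample.
#' @return a \linkS4class{PlantedInstance}.
#' @export
makePlantedInstance <- function(net, active_support, magnitudes = 1,
                                measured_fraction = 1, noise_halfwidth = 0,
                                seed = 1L) {
  stopifnot(is(net, "SplitNetwork"), noise_halfwidth >= 0,
            measured_fraction > 0, measured_fraction <= 1)
  ids <- reactionIds(net)
  idx <- match(active_support, ids)
  if (anyNA(idx))
    stop("unknown reaction(s): ",
         paste(active_support[is.na(idx)], collapse = ", "))
  if (any(magnitudes <= 0)) stop("magnitudes must be positive")
  pairs <- net@pairs
  if (nrow(pairs)) {
    for (q in seq_len(nrow(pairs)))
      if (all(pairs[q, ] %in% idx))
        stop("support violates pair exclusivity: ",
             paste(ids[pairs[q, ]], collapse = " and "))
  }
  u <- net@network@reactions$upper_bound
  phi <- stats::setNames(numeric(length(ids)), ids)
  phi[idx] <- rep_len(magnitudes, length(idx))
  if (any(phi[idx] > u[idx]))
    stop("planted magnitude exceeds a reaction's upper bound")
  v <- as.vector(net@network@stoich %*% phi)
  names(v) <- metaboliteIds(net)
  qualify <- names(v)[abs(v) > noise_halfwidth]
  if (length(qualify) == 0L)
    stop("instance rejected: the planted support produces no measurable ",
         "one-signed variation")
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  n_meas <- max(1L, ceiling(measured_fraction * length(qualify)))
  measured <- sort(sample(qualify, n_meas))
  deltas <- data.frame(metabolite_id = measured,
                       delta_min = v[measured] - noise_halfwidth,
                       delta_max = v[measured] + noise_halfwidth,
                       sign = sign(v[measured]),
                       stringsAsFactors = FALSE)
  rownames(deltas) <- NULL
  nonmeas <- setdiff(names(v), measured)
  eps_req <- if (length(nonmeas)) max(abs(v[nonmeas])) else 0
  new("PlantedInstance", network = net, phiStar = phi,
      measuredIds = measured, deltas = deltas,
      noiseHalfwidth = noise_halfwidth, epsilonRequired = eps_req)
}

#' Draw one random planted benchmark problem
#'
#' Convenience wrapper tying the generators together: a seeded random
#' network, a random planted support respecting pair exclusivity, measured
#' intervals from a subsample of the affected metabolites, and the assembled
#' problem with epsilon just above the spill the unmeasured metabolites need.
#' Instances whose split network exceeds \code{max_split} reactions (too
#' large for the exhaustive oracle) or whose planted support produces no
#' measurable variation are rejected (returns NULL), so callers can walk a
#' seed sequence until enough instances are collected.
#'
#' @param seed RNG seed driving every random choice.
#' @param size number of metabolites.
#' @param lambda parsimony weight of the assembled problem.
#' @param support_size planted support size.
#' @param measured_fraction fraction of affected metabolites measured.
#' @param noise_halfwidth measured-interval half-width.
#' @param reversible_fraction passed to \code{\link{makeToyNetwork}}.
#' @param epsilon_margin slack added to the minimum feasible epsilon.
#' @param max_split reject networks with more split reactions than this.
#' @return list with \code{problem}, \code{instance}, \code{network},
#'   \code{measurements}, or NULL when the seed is rejected.
#' @export
samplePlantedProblem <- function(seed, size = 5 + (seed %% 3), lambda = 0.1,
                                 support_size = 3, measured_fraction = 0.7,
                                 noise_halfwidth = 0.05,
                                 reversible_fraction = 0.35,
                                 epsilon_margin = 0.1, max_split = 12) {
  net <- makeToyNetwork("random", size = size, seed = seed,
                        reversible_fraction = reversible_fraction)
  n <- nReactions(net)
  if (n > max_split) return(NULL)
  ids <- reactionIds(net)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  set.seed(seed + 1000L)
  pairs <- pairMap(net)
  cand <- seq_len(n)
  if (nrow(pairs)) for (q in seq_len(nrow(pairs)))
    cand <- setdiff(cand, pairs[q, if (stats::runif(1) < 0.5) 1L else 2L])
  supp <- sort(sample(cand, min(support_size, length(cand))))
  mags <- stats::runif(length(supp), 0.5, 2)
  if (!is.null(old)) assign(".Random.seed", old, globalenv())
  inst <- tryCatch(
    makePlantedInstance(net, ids[supp], magnitudes = mags,
                        measured_fraction = measured_fraction,
                        noise_halfwidth = noise_halfwidth, seed = seed),
    error = function(e) NULL)
  if (is.null(inst)) return(NULL)
  ms <- MeasurementSet(inst@deltas,
                       epsilon = inst@epsilonRequired + epsilon_margin)
  p <- buildProblem(net, buildBoundVectors(net, ms), lambda = lambda)
  list(problem = p, instance = inst, network = net, measurements = ms)
}

# All supports respecting pair exclusivity and zero-capacity blocks,
# as a list of integer index vectors (the empty support included).
.allSupports <- function(p) {
  n <- nReactions(p@network)
  u <- p@network@network@reactions$upper_bound
  usable <- which(u >= p@theta)
  pairs <- p@network@pairs
  paired <- as.vector(pairs)
  singles <- setdiff(usable, paired)
  supports <- list(integer(0))
  extend <- function(supports, choices) {
    out <- list()
    for (s in supports) for (ch in choices)
      out[[length(out) + 1L]] <- c(s, ch)
    out
  }
  for (q in seq_len(nrow(pairs))) {
    choices <- list(integer(0))
    if (pairs[q, 1L] %in% usable) choices <- c(choices, list(pairs[q, 1L]))
    if (pairs[q, 2L] %in% usable) choices <- c(choices, list(pairs[q, 2L]))
    supports <- extend(supports, choices)
  }
  for (j in singles)
    supports <- extend(supports, list(integer(0), j))
  lapply(supports, sort)
}

#' Exhaustive solve by support enumeration
#'
#' Independent oracle for the mixed-integer program: enumerates every support
#' respecting pair exclusivity (at most 14 split reactions), solves the
#' continuous subproblem restricted to each support, and returns the global
#' minimum together with every support attaining it within \code{tie_tol}.
#'
#' @param p a \linkS4class{ShiftProblem}; exclusion cuts present in \code{p}
#'   are honoured (cut-violating supports are skipped).
#' @param tie_tol two supports are co-optimal when their objectives differ by
#'   at most this.
#' @return list with \code{status} ("optimal" or "infeasible"),
#'   \code{objective}, \code{supports} (list of character vectors), and
#'   \code{values} (objective per feasible support, named by a support key).
#' @export
bruteForceSolve <- function(p, tie_tol = 1e-6) {
  stopifnot(is(p, "ShiftProblem"))
  n <- nReactions(p@network)
  if (n > 14L)
    stop("instance too large for exhaustive enumeration (", n,
         " split reactions > 14)")
  ids <- reactionIds(p@network)
  supports <- .allSupports(p)
  ctx <- .milpContext(p)
  cut_ok <- function(s) !any(vapply(p@cuts, function(cut)
    all(cut %in% s), logical(1)))
  vals <- vapply(supports, function(s) {
    if (!cut_ok(s)) return(NA_real_)
    v <- .supportValue(p, s, ctx)
    if (is.finite(v)) v else NA_real_
  }, numeric(1))
  feas <- which(!is.na(vals))
  if (length(feas) == 0L)
    return(list(status = "infeasible", objective = NA_real_,
                supports = list(), values = numeric(0)))
  best <- min(vals[feas])
  opt <- feas[vals[feas] <= best + tie_tol]
  keys <- vapply(supports, function(s) paste(s, collapse = ","), character(1))
  list(status = "optimal", objective = best,
       supports = lapply(opt, function(t) ids[supports[[t]]]),
       values = stats::setNames(vals[feas], keys[feas]))
}

#' Exhaustive enumeration with exclusion cuts
#'
#' Runs the same cut-and-resolve loop as \code{\link{enumerateSolutions}} but
#' with exhaustive search in place of the branch-and-bound: at each iteration
#' the feasible support with the smallest objective is recorded and every
#' superset of it is excluded. Ties are broken by lexicographically smallest
#' support (by reaction index), a deterministic test-only convention.
#'
#' @param p a \linkS4class{ShiftProblem}.
#' @param n_max maximum number of solutions.
#' @return list with \code{supports} (list of character vectors),
#'   \code{objectives}, \code{tied} (whether several supports attained the
#'   iteration's optimum, i.e. the recorded choice is convention-dependent),
#'   and \code{termination}.
#' @export
bruteForceEnumerate <- function(p, n_max) {
  stopifnot(is(p, "ShiftProblem"), n_max >= 1)
  n <- nReactions(p@network)
  if (n > 14L)
    stop("instance too large for exhaustive enumeration (", n,
         " split reactions > 14)")
  ids <- reactionIds(p@network)
  supports <- .allSupports(p)
  ctx <- .milpContext(p)
  cut_ok <- function(s) !any(vapply(p@cuts, function(cut)
    all(cut %in% s), logical(1)))
  vals <- vapply(supports, function(s) {
    if (!cut_ok(s)) return(NA_real_)
    v <- .supportValue(p, s, ctx)
    if (is.finite(v)) v else NA_real_
  }, numeric(1))
  alive <- !is.na(vals)
  out_supports <- list(); out_obj <- numeric(0)
  termination <- "count_reached"
  lex_before <- function(a, b) {  # a, b sorted integer vectors
    k <- min(length(a), length(b))
    if (k > 0) for (i in seq_len(k)) {
      if (a[i] < b[i]) return(TRUE)
      if (a[i] > b[i]) return(FALSE)
    }
    length(a) < length(b)
  }
  out_tied <- logical(0)
  for (iter in seq_len(n_max)) {
    cand <- which(alive)
    if (length(cand) == 0L) { termination <- "infeasible"; break }
    best <- min(vals[cand])
    tied <- cand[vals[cand] <= best + 1e-6]
    pick <- tied[1L]
    if (length(tied) > 1L)
      for (t in tied[-1L])
        if (lex_before(supports[[t]], supports[[pick]])) pick <- t
    chosen <- supports[[pick]]
    out_supports[[length(out_supports) + 1L]] <- ids[chosen]
    out_obj <- c(out_obj, vals[pick])
    out_tied <- c(out_tied, length(tied) > 1L)
    if (length(chosen) == 0L) { termination <- "empty_support"; break }
    # exclusion constraint: remove the chosen support and all supersets
    for (t in which(alive))
      if (all(chosen %in% supports[[t]])) alive[t] <- FALSE
  }
  list(supports = out_supports, objectives = out_obj, tied = out_tied,
       termination = termination)
}
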