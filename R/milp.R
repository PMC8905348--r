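#' @include lp.R
NULL

#' Assemble the mixed-integer program for one transient-state instance
#'
#' Creates the solver-ready problem: continuous moles-passed variables
#' phi_j in [0, u_j], binary support variables y_j, the indicator link
#' (phi_j <= u_j y_j and phi_j >= theta y_j), mutual exclusion of
#' forward/backward split pairs (y_j + y_jbar <= 1), the row constraints
#' Delta_min <= S phi <= Delta_max, and the objective
#' lambda * sum(y) + (1 - lambda) * sum over non-measured |S phi|
#' - (1 - lambda) * sum over measured |S phi|. The maximised measured term is
#' linear because measured intervals are strictly one-signed; the minimised
#' non-measured term uses epigraph auxiliaries.
#'
#' @param net a \linkS4class{SplitNetwork}.
#' @param bounds a \linkS4class{BoundVectors} aligned to \code{net} (from
#'   \code{\link{buildBoundVectors}}).
#' @param lambda weight in (0, 1]; 1 selects the cardinality-only mode in
#'   which only the number of active reactions is minimised.
#' @param theta minimum moles passed through an active reaction (> 0).
#' @param mip_gap relative optimality gap at which the branch-and-bound may
#'   stop (0 = prove optimality).
#' @param time_limit_s wall-clock limit per solve, seconds.
#' @param seed,threads recorded in the problem for provenance; the bundled
#'   solver is deterministic and single-threaded.
#' @return a \linkS4class{ShiftProblem}.
#' @examples
#' net <- makeToyNetwork("chain", 3)
#' ms <- MeasurementSet(data.frame(metabolite_id = c("A", "C"),
#'                                 delta_min = c(-2, 1), delta_max = c(-1, 2)))
#' p <- buildProblem(net, buildBoundVectors(net, ms), lambda = 0.1)
#' solveOnce(p)
#' @export
buildProblem <- function(net, bounds, lambda, theta = 1e-4,
                         mip_gap = 0, time_limit_s = Inf,
                         seed = 1L, threads = 1L) {
  stopifnot(is(net, "SplitNetwork"), is(bounds, "BoundVectors"))
  if (!is.numeric(lambda) || length(lambda) != 1L || lambda <= 0 || lambda > 1)
    stop("lambda must lie in (0, 1]; got ", lambda)
  if (length(bounds@deltaMin) != nMetabolites(net))
    stop("bounds are not aligned to the network (", length(bounds@deltaMin),
         " components vs ", nMetabolites(net), " metabolites)")
  if (any(bounds@deltaMin > bounds@deltaMax))
    stop("assembly error: deltaMin exceeds deltaMax")
  new("ShiftProblem", network = net, bounds = bounds,
      lambda = lambda, theta = theta, cuts = list(),
      opts = list(mip_gap = mip_gap, time_limit_s = time_limit_s,
                  seed = as.integer(seed), threads = as.integer(threads)))
}

# Fixpoint propagation of a partial assignment of the binary supports.
# fixed: integer vector over reactions with NA = free, 0L, 1L.
# Applies: pair exclusivity, zero-capacity reactions, and exclusion cuts
# whose slack has run out. Returns NULL when the node is infeasible.
.propagateFixed <- function(p, fixed) {
  u <- p@network@network@reactions$upper_bound
  fixed[is.na(fixed) & u < p@theta] <- 0L
  if (any(fixed == 1L & u < p@theta, na.rm = TRUE)) return(NULL)
  pairs <- p@network@pairs
  repeat {
    changed <- FALSE
    if (nrow(pairs)) {
      f1 <- fixed[pairs[, 1L]]; f2 <- fixed[pairs[, 2L]]
      if (any(f1 == 1L & f2 == 1L, na.rm = TRUE)) return(NULL)
      sel <- which(f1 == 1L & is.na(f2))
      if (length(sel)) { fixed[pairs[sel, 2L]] <- 0L; changed <- TRUE }
      sel <- which(f2 == 1L & is.na(f1))
      if (length(sel)) { fixed[pairs[sel, 1L]] <- 0L; changed <- TRUE }
    }
    for (cut in p@cuts) {
      n1 <- sum(fixed[cut] == 1L, na.rm = TRUE)
      freeIdx <- cut[is.na(fixed[cut])]
      rhs <- length(cut) - 1L - n1
      if (rhs < 0L) return(NULL)
      if (rhs == 0L && length(freeIdx)) {
        fixed[freeIdx] <- 0L
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  fixed
}

# Precomputed dense pieces shared by every node of one solve.
.milpContext <- function(p, u = NULL) {
  net <- p@network@network
  S <- as.matrix(net@stoich)
  list(S = S, u = if (is.null(u)) net@reactions$upper_bound else u)
}

# Tighten the per-reaction moles-passed caps: for each reaction, the maximum
# phi_j over the polytope {Delta_min <= S phi <= Delta_max, 0 <= phi <= u} is
# a valid cap, usually far below a generic default, and it sharpens the
# big-M indicator link phi_j <= u_j y_j considerably. Returns the tightened
# cap vector, or NULL when the polytope is empty.
.tightenBounds <- function(p, ctx) {
  S <- ctx$S; u <- ctx$u
  n <- ncol(S); m <- nrow(S)
  dmin <- p@bounds@deltaMin; dmax <- p@bounds@deltaMax
  Arows <- list(); brhs <- numeric(0)
  Erows <- list(); erhs <- numeric(0)
  for (i in seq_len(m)) {
    srow <- S[i, ]
    if (all(srow == 0)) {
      if (dmin[i] > 0 || dmax[i] < 0) return(NULL)
      next
    }
    if (dmin[i] == dmax[i]) {
      Erows[[length(Erows) + 1L]] <- srow; erhs <- c(erhs, dmin[i])
    } else {
      if (is.finite(dmax[i])) {
        Arows[[length(Arows) + 1L]] <- srow; brhs <- c(brhs, dmax[i])
      }
      if (is.finite(dmin[i])) {
        Arows[[length(Arows) + 1L]] <- -srow; brhs <- c(brhs, -dmin[i])
      }
    }
  }
  A <- if (length(Arows)) do.call(rbind, Arows) else NULL
  Aeq <- if (length(Erows)) do.call(rbind, Erows) else NULL
  beq <- if (length(erhs)) erhs else NULL
  ut <- u
  for (j in seq_len(n)) {
    if (u[j] <= 0) next
    cc <- numeric(n); cc[j] <- -1
    r <- solveLP(cc, A = A, b = brhs, Aeq = Aeq, beq = beq, ub = u)
    if (r$status == "infeasible") return(NULL)
    if (r$status == "optimal") ut[j] <- min(u[j], -r$value + 1e-9)
  }
  ut
}

# Assemble and solve the LP relaxation at a node of the branch-and-bound.
# Free binaries are relaxed to [0, 1]. Returns list(status, bound, phi, yfree,
# freeIdx) where bound includes the constant objective parts.
.solveNode <- function(p, fixed, ctx = NULL) {
  net <- p@network@network
  if (is.null(ctx)) ctx <- .milpContext(p)
  S <- ctx$S
  n <- ncol(S); m <- nrow(S)
  u <- ctx$u
  lam <- p@lambda; theta <- p@theta
  dmin <- p@bounds@deltaMin; dmax <- p@bounds@deltaMax
  measured <- p@bounds@measured; sgn <- p@bounds@sign

  freeIdx <- which(is.na(fixed))
  f1 <- which(fixed == 1L)
  pinned <- dmin == dmax
  auxRows <- if (lam < 1) which(!measured & !pinned) else integer(0)
  k <- length(auxRows); f <- length(freeIdx)

  nv <- n + k + f
  iPhi <- seq_len(n)
  iA <- n + seq_len(k)
  iY <- n + k + seq_len(f)

  cc <- numeric(nv)
  if (lam < 1 && any(measured))
    cc[iPhi] <- -(1 - lam) * colSums(S[measured, , drop = FALSE] *
                                       sgn[measured])
  if (k) cc[iA] <- (1 - lam)
  if (f) cc[iY] <- lam
  const <- lam * length(f1) +
    if (lam < 1) (1 - lam) * sum(abs(dmin[!measured & pinned])) else 0

  ub <- numeric(nv)
  ub[iPhi] <- ifelse(fixed == 0L & !is.na(fixed), 0, u)
  if (k) {
    capS <- as.vector(abs(S[auxRows, , drop = FALSE]) %*% ub[iPhi])
    ub[iA] <- pmin(pmax(abs(dmin[auxRows]), abs(dmax[auxRows])), capS)
  }
  if (f) ub[iY] <- 1

  Arows <- list(); brhs <- numeric(0)
  Erows <- list(); erhs <- numeric(0)
  add_le <- function(row, rhs) { Arows[[length(Arows) + 1L]] <<- row
                                 brhs[length(brhs) + 1L] <<- rhs }
  add_eq <- function(row, rhs) { Erows[[length(Erows) + 1L]] <<- row
                                 erhs[length(erhs) + 1L] <<- rhs }

  for (i in seq_len(m)) {
    srow <- S[i, ]
    if (all(srow == 0)) {
      if (dmin[i] > 0 || dmax[i] < 0) return(list(status = "infeasible"))
      next
    }
    row <- numeric(nv); row[iPhi] <- srow
    if (pinned[i]) add_eq(row, dmin[i])
    else {
      if (is.finite(dmax[i])) add_le(row, dmax[i])
      if (is.finite(dmin[i])) add_le(-row, -dmin[i])
    }
  }
  for (t in seq_len(k)) {
    i <- auxRows[t]
    row <- numeric(nv); row[iPhi] <- S[i, ]; row[iA[t]] <- -1
    add_le(row, 0)
    row[iPhi] <- -S[i, ]
    add_le(row, 0)
  }
  for (t in seq_len(f)) {
    j <- freeIdx[t]
    row <- numeric(nv); row[j] <- 1; row[iY[t]] <- -u[j]
    add_le(row, 0)
    row <- numeric(nv); row[j] <- -1; row[iY[t]] <- theta
    add_le(row, 0)
  }
  for (j in f1) {
    row <- numeric(nv); row[j] <- -1
    add_le(row, -theta)
  }
  pairs <- p@network@pairs
  if (nrow(pairs)) for (q in seq_len(nrow(pairs))) {
    t1 <- match(pairs[q, 1L], freeIdx); t2 <- match(pairs[q, 2L], freeIdx)
    if (!is.na(t1) && !is.na(t2)) {
      row <- numeric(nv); row[iY[t1]] <- 1; row[iY[t2]] <- 1
      add_le(row, 1)
    }
  }
  for (cut in p@cuts) {
    n1 <- sum(fixed[cut] == 1L, na.rm = TRUE)
    tFree <- match(cut[is.na(fixed[cut])], freeIdx)
    rhs <- length(cut) - 1L - n1
    if (rhs < 0L) return(list(status = "infeasible"))
    if (length(tFree) == 0L || rhs >= length(tFree)) next
    row <- numeric(nv); row[iY[tFree]] <- 1
    add_le(row, rhs)
  }

  A <- if (length(Arows)) do.call(rbind, Arows) else NULL
  Aeq <- if (length(Erows)) do.call(rbind, Erows) else NULL
  r <- solveLP(cc, A = A, b = brhs, Aeq = Aeq,
               beq = if (length(erhs)) erhs else NULL, ub = ub)
  if (r$status != "optimal") return(list(status = r$status))
  list(status = "optimal", bound = r$value + const,
       phi = r$x[iPhi], yfree = if (f) r$x[iY] else numeric(0),
       freeIdx = freeIdx)
}

#' Solve the mixed-integer program for one solution
#'
#' Runs a deterministic single-threaded branch-and-bound over the binary
#' support variables, bounding each node with the LP relaxation (free binaries
#' relaxed to [0, 1]). Branching picks the most fractional support variable
#' and explores the branch nearest the relaxation value first.
#'
#' @param p a \linkS4class{ShiftProblem}.
#' @return a \linkS4class{ShiftSolution}; \code{status} records whether the
#'   search proved optimality, stopped at the relative gap target, or hit the
#'   time limit.
#' @seealso \code{\link{buildProblem}}, \code{\link{enumerateSolutions}}
#' @export
solveOnce <- function(p) {
  stopifnot(is(p, "ShiftProblem"))
  n <- nReactions(p@network)
  mip_gap <- p@opts$mip_gap %||% 0
  tlim <- p@opts$time_limit_s %||% Inf
  t0 <- Sys.time()
  intTol <- 1e-6

  ctx <- .milpContext(p)
  ut <- .tightenBounds(p, ctx)
  if (is.null(ut)) stop(.infeasibilityReport(p), call. = FALSE)
  ctx$u <- ut
  pw <- p  # working copy with tightened caps (a valid reformulation)
  pw@network@network@reactions$upper_bound <- ut

  root <- rep(NA_integer_, n)
  stack <- list(list(fixed = root, pbound = -Inf))
  inc <- NULL; incObj <- Inf
  gapPruned <- FALSE; timedOut <- FALSE
  minOpenBound <- Inf   # best bound among gap-pruned / abandoned nodes

  # rounding heuristic: support of the root relaxation, largest pair member
  # kept, solved as a fixed support for an early incumbent
  rootSol <- .solveNode(pw, .propagateFixed(pw, root) %||% root, ctx)
  if (identical(rootSol$status, "optimal") && length(rootSol$freeIdx)) {
    tau <- p@theta / 2
    supp <- which(rootSol$phi > tau)
    pairs <- pw@network@pairs
    if (nrow(pairs)) for (q in seq_len(nrow(pairs))) {
      jf <- pairs[q, 1L]; jr <- pairs[q, 2L]
      if (jf %in% supp && jr %in% supp) {
        drop <- if (rootSol$phi[jf] >= rootSol$phi[jr]) jr else jf
        supp <- setdiff(supp, drop)
      }
    }
    fx <- rep(0L, n); fx[supp] <- 1L
    fx2 <- .propagateFixed(pw, fx)
    if (!is.null(fx2)) {
      h <- .solveNode(pw, fx2, ctx)
      if (identical(h$status, "optimal")) {
        inc <- list(phi = h$phi, y = fx2, obj = h$bound)
        incObj <- h$bound
      }
    }
  }

  while (length(stack)) {
    if (as.numeric(Sys.time() - t0, units = "secs") > tlim) {
      timedOut <- TRUE
      minOpenBound <- min(minOpenBound,
                          vapply(stack, function(nd) nd$pbound, numeric(1)))
      break
    }
    node <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    fixed <- .propagateFixed(pw, node$fixed)
    if (is.null(fixed)) next
    sol <- .solveNode(pw, fixed, ctx)
    if (sol$status == "unbounded")
      stop("internal error: relaxation unbounded despite finite bounds")
    if (sol$status != "optimal") next
    if (sol$bound >= incObj - 1e-9) next
    if (mip_gap > 0 && sol$bound >= incObj - mip_gap * abs(incObj)) {
      gapPruned <- TRUE
      minOpenBound <- min(minOpenBound, sol$bound)
      next
    }
    yf <- sol$yfree
    fracs <- pmin(yf, 1 - yf)
    if (length(yf) == 0L || max(fracs) <= intTol) {
      # integral relaxation: optimum of this subtree
      yfull <- fixed
      if (length(yf)) yfull[sol$freeIdx] <- as.integer(round(yf))
      inc <- list(phi = sol$phi, y = yfull, obj = sol$bound)
      incObj <- sol$bound
      next
    }
    t <- which.max(fracs)
    j <- sol$freeIdx[t]
    first <- as.integer(round(yf[t]))          # explored first (pushed last)
    for (v in c(1L - first, first)) {
      child <- fixed; child[j] <- v
      stack[[length(stack) + 1L]] <- list(fixed = child, pbound = sol$bound)
    }
  }

  if (is.null(inc)) {
    if (timedOut)
      stop("time limit reached before any feasible solution was found")
    stop(.infeasibilityReport(p), call. = FALSE)
  }

  status <- if (timedOut) "time_limit"
            else if (gapPruned) "gap_limit"
            else "optimal"
  lb <- min(incObj, minOpenBound)
  gap <- if (status == "optimal") 0
         else max(0, (incObj - lb) / max(1e-12, abs(incObj)))

  ids <- reactionIds(p@network)
  phi <- stats::setNames(pmax(inc$phi, 0), ids)
  support <- stats::setNames(inc$y == 1L, ids)
  phi[!support] <- 0
  pv <- as.vector(p@network@network@stoich %*% phi)
  names(pv) <- metaboliteIds(p@network)
  new("ShiftSolution", phi = phi, support = support,
      objective = inc$obj, predictedVariation = pv,
      status = status, gap = gap)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Objective value of the continuous subproblem restricted to one support
# (phi = 0 off the support, phi >= theta on it), in variables limited to the
# support plus the needed epigraph auxiliaries. Returns +Inf when infeasible.
.supportValue <- function(p, suppIdx, ctx = NULL) {
  if (is.null(ctx)) ctx <- .milpContext(p)
  S <- ctx$S; u <- ctx$u
  m <- nrow(S)
  lam <- p@lambda; theta <- p@theta
  dmin <- p@bounds@deltaMin; dmax <- p@bounds@deltaMax
  measured <- p@bounds@measured; sgn <- p@bounds@sign
  t <- length(suppIdx)
  if (t && any(u[suppIdx] < theta)) return(Inf)
  ST <- S[, suppIdx, drop = FALSE]
  pinned <- dmin == dmax
  livRow <- if (t) rowSums(ST != 0) > 0 else rep(FALSE, m)
  # rows untouched by the support must admit zero variation
  off <- !livRow
  if (any(dmin[off] > 1e-12) || any(dmax[off] < -1e-12)) return(Inf)
  auxRows <- which(livRow & !measured & !pinned)
  k <- if (lam < 1) length(auxRows) else 0L
  if (lam == 1) auxRows <- integer(0)
  nv <- t + k
  const <- lam * t +
    if (lam < 1) (1 - lam) * sum(abs(dmin[!measured & pinned])) else 0
  if (nv == 0L) return(const)
  cc <- numeric(nv)
  if (lam < 1 && any(measured & livRow)) {
    mi <- which(measured & livRow)
    cc[seq_len(t)] <- -(1 - lam) *
      colSums(ST[mi, , drop = FALSE] * sgn[mi])
  }
  if (k) cc[t + seq_len(k)] <- (1 - lam)
  ub <- numeric(nv)
  ub[seq_len(t)] <- u[suppIdx]
  if (k) {
    capS <- as.vector(abs(ST[auxRows, , drop = FALSE]) %*% u[suppIdx])
    ub[t + seq_len(k)] <- pmin(pmax(abs(dmin[auxRows]), abs(dmax[auxRows])),
                               capS)
  }
  Arows <- list(); brhs <- numeric(0)
  Erows <- list(); erhs <- numeric(0)
  for (i in which(livRow)) {
    row <- numeric(nv); row[seq_len(t)] <- ST[i, ]
    if (pinned[i]) {
      Erows[[length(Erows) + 1L]] <- row; erhs <- c(erhs, dmin[i])
    } else {
      if (is.finite(dmax[i])) {
        Arows[[length(Arows) + 1L]] <- row; brhs <- c(brhs, dmax[i])
      }
      if (is.finite(dmin[i])) {
        Arows[[length(Arows) + 1L]] <- -row; brhs <- c(brhs, -dmin[i])
      }
    }
  }
  for (q in seq_len(k)) {
    i <- auxRows[q]
    row <- numeric(nv); row[seq_len(t)] <- ST[i, ]; row[t + q] <- -1
    Arows[[length(Arows) + 1L]] <- row; brhs <- c(brhs, 0)
    row[seq_len(t)] <- -ST[i, ]
    Arows[[length(Arows) + 1L]] <- row; brhs <- c(brhs, 0)
  }
  for (q in seq_len(t)) {
    row <- numeric(nv); row[q] <- -1
    Arows[[length(Arows) + 1L]] <- row; brhs <- c(brhs, -theta)
  }
  r <- solveLP(cc,
               A = if (length(Arows)) do.call(rbind, Arows) else NULL,
               b = brhs,
               Aeq = if (length(Erows)) do.call(rbind, Erows) else NULL,
               beq = if (length(erhs)) erhs else NULL, ub = ub)
  if (r$status != "optimal") return(Inf)
  r$value + const
}

# Build the infeasibility message: relax each measured metabolite's row in
# turn and report those whose relaxation restores LP feasibility.
.infeasibilityReport <- function(p) {
  msg <- "problem infeasible: no moles-passed vector satisfies the variation bounds"
  midx <- which(p@bounds@measured)
  if (length(midx) == 0L || length(midx) > 60L)
    return(msg)
  big <- 10 * max(1, abs(p@bounds@deltaMin[is.finite(p@bounds@deltaMin)]),
                  abs(p@bounds@deltaMax[is.finite(p@bounds@deltaMax)]),
                  p@network@network@reactions$upper_bound)
  binding <- character(0)
  for (i in midx) {
    q <- p
    q@bounds@deltaMin[i] <- -big
    q@bounds@deltaMax[i] <- big
    q@bounds@measured[i] <- FALSE
    q@bounds@sign[i] <- 0
    r <- .solveNode(q, rep(NA_integer_, nReactions(p@network)))
    if (identical(r$status, "optimal"))
      binding <- c(binding, metaboliteIds(p@network)[i])
  }
  if (length(binding))
    msg <- paste0(msg, "; binding measured metabolites: ",
                  paste(binding, collapse = ", "))
  msg
}

#' Re-evaluate the objective of a solution from first principles
#'
#' Recomputes lambda * sum(y) + (1 - lambda) * sum over non-measured
#' |S phi|_i - (1 - lambda) * sum over measured |S phi|_i directly with true
#' absolute values (no epigraph auxiliaries), independently of the solver's
#' internal linearisation.
#'
#' @param p a \linkS4class{ShiftProblem}.
#' @param s a \linkS4class{ShiftSolution} for \code{p}.
#' @return the objective value.
#' @export
evaluateObjective <- function(p, s) {
  stopifnot(is(p, "ShiftProblem"), is(s, "ShiftSolution"))
  v <- as.vector(p@network@network@stoich %*% s@phi)
  lam <- p@lambda
  meas <- p@bounds@measured
  lam * sum(s@support) +
    (1 - lam) * sum(abs(v[!meas])) -
    (1 - lam) * sum(abs(v[meas]))
}

#' Verify every constraint of a solution
#'
#' Checks the variation bounds, the moles-passed bounds, the indicator link,
#' split-pair mutual exclusion and any exclusion cuts, each within \code{tol}.
#' Violations are returned as data, not raised.
#'
#' @param p a \linkS4class{ShiftProblem}.
#' @param s a \linkS4class{ShiftSolution}.
#' @param tol feasibility tolerance.
#' @return data.frame with columns \code{constraint}, \code{id},
#'   \code{violation}; zero rows means feasible.
#' @export
checkFeasibility <- function(p, s, tol = 1e-6) {
  stopifnot(is(p, "ShiftProblem"), is(s, "ShiftSolution"))
  viol <- list()
  add <- function(constraint, id, amount)
    viol[[length(viol) + 1L]] <<- data.frame(constraint = constraint, id = id,
                                             violation = amount,
                                             stringsAsFactors = FALSE)
  ids <- reactionIds(p@network)
  mids <- metaboliteIds(p@network)
  u <- p@network@network@reactions$upper_bound
  phi <- s@phi; y <- s@support
  for (j in seq_along(phi)) {
    if (phi[j] < -tol) add("phi_nonneg", ids[j], -phi[j])
    if (phi[j] > u[j] + tol) add("phi_upper", ids[j], phi[j] - u[j])
    if (!y[j] && phi[j] > tol) add("link_zero", ids[j], phi[j])
    if (y[j] && phi[j] < p@theta - tol) add("link_theta", ids[j],
                                            p@theta - phi[j])
  }
  v <- as.vector(p@network@network@stoich %*% phi)
  for (i in seq_along(v)) {
    if (v[i] < p@bounds@deltaMin[i] - tol)
      add("row_lower", mids[i], p@bounds@deltaMin[i] - v[i])
    if (v[i] > p@bounds@deltaMax[i] + tol)
      add("row_upper", mids[i], v[i] - p@bounds@deltaMax[i])
  }
  pairs <- p@network@pairs
  if (nrow(pairs)) for (q in seq_len(nrow(pairs))) {
    if (y[pairs[q, 1L]] && y[pairs[q, 2L]])
      add("pair_exclusion", paste(ids[pairs[q, ]], collapse = "+"), 1)
  }
  for (ci in seq_along(p@cuts)) {
    cut <- p@cuts[[ci]]
    if (sum(y[cut]) > length(cut) - 1L)
      add("exclusion_cut", paste0("cut_", ci),
          sum(y[cut]) - (length(cut) - 1L))
  }
  if (length(viol)) do.call(rbind, viol)
  else data.frame(constraint = character(), id = character(),
                  violation = numeric(), stringsAsFactors = FALSE)
}
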