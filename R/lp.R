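#' @include measurements.R
NULL

# Dense two-phase primal simplex with Bland's anti-cycling rule.
#
# Minimizes cc'x subject to A x <= b, Aeq x = beq, 0 <= x <= ub.
# Written for the small, dense linear programs that arise as relaxations and
# support-restricted subproblems of the transient-state program (tens of
# variables); determinism and a trustworthy infeasibility verdict matter more
# here than large-scale speed, which is why the classic tableau method with
# Bland's rule is used (finite termination, no big-M constants).
#
# Returns list(status, x, value) with status "optimal", "infeasible" or
# "unbounded".
solveLP <- function(cc, A = NULL, b = NULL, Aeq = NULL, beq = NULL, ub = NULL) {
  nv <- length(cc)
  if (nv == 0L)
    return(list(status = "optimal", x = numeric(0), value = 0))

  # fold finite upper bounds in as inequality rows
  if (!is.null(ub)) {
    fin <- which(is.finite(ub))
    if (length(fin)) {
      Ub <- matrix(0, length(fin), nv)
      Ub[cbind(seq_along(fin), fin)] <- 1
      A <- rbind(A, Ub)
      b <- c(b, ub[fin])
    }
  }
  m1 <- NROW(A); m2 <- NROW(Aeq)
  G <- rbind(if (m1) A, if (m2) Aeq)
  h <- c(if (m1) b, if (m2) beq)
  eqrow <- c(rep(FALSE, m1), rep(TRUE, m2))
  m <- length(h)
  if (m == 0L) {
    # no constraints: minimum at x = 0 unless a negative cost is unbounded
    if (any(cc < 0)) return(list(status = "unbounded", x = NULL, value = -Inf))
    return(list(status = "optimal", x = numeric(nv), value = 0))
  }

  # row equilibration for numerical balance
  rs <- apply(abs(G), 1L, max)
  rs[rs == 0] <- 1
  G <- G / rs
  h <- h / rs

  # orient rows so every right-hand side is non-negative
  neg <- h < 0
  G[neg, ] <- -G[neg, , drop = FALSE]
  h[neg] <- -h[neg]
  ge <- neg & !eqrow       # were <=, now >= : surplus + artificial
  le <- !neg & !eqrow      # <= : slack only

  nslack <- sum(le) + sum(ge)               # slack (+1) or surplus (-1)
  artrows <- which(eqrow | ge)
  nart <- length(artrows)
  N <- nv + nslack + nart
  Tm <- matrix(0, m, N + 1L)
  Tm[, seq_len(nv)] <- G
  Tm[, N + 1L] <- h
  basis <- integer(m)
  scol <- nv
  for (i in seq_len(m)) {
    if (le[i]) {
      scol <- scol + 1L
      Tm[i, scol] <- 1
      basis[i] <- scol
    } else if (ge[i]) {
      scol <- scol + 1L
      Tm[i, scol] <- -1
    }
  }
  acol <- nv + nslack
  for (i in artrows) {
    acol <- acol + 1L
    Tm[i, acol] <- 1
    basis[i] <- acol
  }
  art <- seq.int(nv + nslack + 1L, length.out = nart)
  tol <- 1e-9 * max(1, abs(h), abs(cc))

  run_phase <- function(Tm, basis, cost, allowed, maxit = 20000L) {
    for (it in seq_len(maxit)) {
      cB <- cost[basis]
      red <- cost - as.vector(crossprod(Tm[, seq_len(N), drop = FALSE], cB))
      red[!allowed] <- 0
      ent <- which(red < -tol)
      if (length(ent) == 0L)
        return(list(Tm = Tm, basis = basis, status = "optimal"))
      j <- ent[1L]                               # Bland: smallest index
      colj <- Tm[, j]
      pos <- which(colj > tol)
      if (length(pos) == 0L)
        return(list(Tm = Tm, basis = basis, status = "unbounded"))
      ratio <- Tm[pos, N + 1L] / colj[pos]
      rmin <- min(ratio)
      cand <- pos[ratio <= rmin + tol]
      r <- cand[which.min(basis[cand])]          # Bland on leaving variable
      piv <- Tm[r, j]
      Tm[r, ] <- Tm[r, ] / piv
      other <- setdiff(seq_len(m), r)
      Tm[other, ] <- Tm[other, , drop = FALSE] -
        outer(Tm[other, j], Tm[r, ])
      basis[r] <- j
    }
    list(Tm = Tm, basis = basis, status = "maxit")
  }

  if (nart) {
    cost1 <- numeric(N); cost1[art] <- 1
    ph1 <- run_phase(Tm, basis, cost1, allowed = rep(TRUE, N))
    if (ph1$status != "optimal")
      return(list(status = "infeasible", x = NULL, value = Inf))
    Tm <- ph1$Tm; basis <- ph1$basis
    obj1 <- sum(Tm[basis %in% art, N + 1L])
    if (obj1 > 1e-7 * max(1, max(abs(h))))
      return(list(status = "infeasible", x = NULL, value = Inf))
    # pivot lingering zero-level artificials out of the basis when possible
    for (r in which(basis %in% art)) {
      row <- Tm[r, seq_len(nv + nslack)]
      j <- which(abs(row) > tol)
      if (length(j)) {
        j <- j[1L]
        piv <- Tm[r, j]
        Tm[r, ] <- Tm[r, ] / piv
        other <- setdiff(seq_len(m), r)
        Tm[other, ] <- Tm[other, , drop = FALSE] -
          outer(Tm[other, j], Tm[r, ])
        basis[r] <- j
      }
    }
  }

  cost2 <- numeric(N); cost2[seq_len(nv)] <- cc
  allowed <- rep(TRUE, N)
  if (nart) allowed[art] <- FALSE
  ph2 <- run_phase(Tm, basis, cost2, allowed)
  if (ph2$status == "unbounded")
    return(list(status = "unbounded", x = NULL, value = -Inf))
  if (ph2$status != "optimal")
    return(list(status = "infeasible", x = NULL, value = Inf))
  Tm <- ph2$Tm; basis <- ph2$basis
  x <- numeric(N)
  x[basis] <- Tm[, N + 1L]
  xv <- pmax(x[seq_len(nv)], 0)
  list(status = "optimal", x = xv, value = sum(cc * xv))
}
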