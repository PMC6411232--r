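# Dense two-phase primal simplex (Bland's rule), standard form:
#   min c'x  s.t.  A x = b, x >= 0.
# Written for desk-scale problems (toy network, random fixtures, constructed
# tie-break cases); no sparse machinery, no revised simplex. Bland's rule
# guarantees termination under degeneracy at the price of speed.

simplex_solve <- function(cvec, A, b, tol = 1e-9) {
  A <- as.matrix(A)
  m <- nrow(A); n <- ncol(A)
  stopifnot(length(cvec) == n, length(b) == m)
  neg <- b < 0
  A[neg, ] <- -A[neg, , drop = FALSE]
  b[neg] <- -b[neg]

  pivot <- function(Tb, r, basis, pr, pc) {
    piv <- Tb[pr, pc]
    Tb[pr, ] <- Tb[pr, ] / piv
    for (i in seq_len(nrow(Tb))) {
      if (i != pr && abs(Tb[i, pc]) > 0) Tb[i, ] <- Tb[i, ] - Tb[i, pc] * Tb[pr, ]
    }
    r <- r - r[pc] * Tb[pr, ]
    basis[pr] <- pc
    list(Tb = Tb, r = r, basis = basis)
  }

  iterate <- function(Tb, r, basis, ncols) {
    repeat {
      enter <- which(r[seq_len(ncols)] < -tol)
      if (!length(enter)) return(list(Tb = Tb, r = r, basis = basis, status = "optimal"))
      j <- min(enter)                       # Bland: smallest index enters
      col <- Tb[, j]
      rows <- which(col > tol)
      if (!length(rows)) return(list(Tb = Tb, r = r, basis = basis, status = "unbounded"))
      ratio <- Tb[rows, ncols + 1L] / col[rows]
      cand <- rows[ratio <= min(ratio) + tol]
      i <- cand[which.min(basis[cand])]     # Bland: smallest basis index leaves
      st <- pivot(Tb, r, basis, i, j)
      Tb <- st$Tb; r <- st$r; basis <- st$basis
    }
  }

  # Phase 1
  ntot <- n + m
  Tb <- cbind(A, diag(m), b)
  basis <- n + seq_len(m)
  c1 <- c(rep(0, n), rep(1, m))
  r <- c(c1, 0) - colSums(Tb)               # reduced costs w.r.t. artificial basis
  st <- iterate(Tb, r, basis, ntot)
  if (st$status == "unbounded") stop2("phase-1 simplex unbounded (internal error)")
  Tb <- st$Tb; basis <- st$basis
  phase1_obj <- -st$r[ntot + 1L]
  if (phase1_obj > 1e-7 * max(1, max(abs(b))))
    return(list(status = "infeasible", x = NULL, obj = NA_real_))

  # Drive artificials out of the basis; drop redundant rows.
  keep <- rep(TRUE, m)
  for (i in seq_len(m)) {
    if (basis[i] > n) {
      j <- which(abs(Tb[i, seq_len(n)]) > tol)
      if (length(j)) {
        st2 <- pivot(Tb, st$r, basis, i, min(j))
        Tb <- st2$Tb; st$r <- st2$r; basis <- st2$basis
      } else keep[i] <- FALSE
    }
  }
  Tb <- Tb[keep, , drop = FALSE]; basis <- basis[keep]
  m2 <- nrow(Tb)
  Tb <- Tb[, c(seq_len(n), ntot + 1L), drop = FALSE]

  # Phase 2: reduced costs from original objective over the reduced tableau
  cB <- cvec[basis]
  r <- c(cvec, 0) - as.numeric(cB %*% Tb)
  st <- iterate(Tb, r, basis, n)
  if (st$status == "unbounded")
    return(list(status = "unbounded", x = NULL, obj = -Inf))
  Tb <- st$Tb; basis <- st$basis
  x <- numeric(n)
  x[basis] <- Tb[, n + 1L]
  x[x < 0 & x > -1e-9] <- 0
  list(status = "optimal", x = x, obj = sum(cvec * x))
}

# LP over a flux polytope in its native variables:
#   optimize obj'v  s.t.  E v = d, l <= v <= u, plus optional extra
#   inequalities list(a=, rhs=, sense="<="/">=").
# Requires finite lower bounds (split form). Returns list(status, v, obj).
lp_over_polytope <- function(P, obj, maximize = TRUE, extra_ineq = NULL,
                             tol = 1e-9) {
  n <- length(P$l)
  if (any(!is.finite(P$l))) stop2("polytope has infinite lower bounds; split first")
  obj <- rep_len(as.numeric(obj), n)
  # shift x = v - l
  E <- if (nrow(P$E)) as.matrix(P$E) else matrix(0, 0, n)
  d <- P$d - if (nrow(E)) as.numeric(E %*% P$l) else numeric(0)
  rows <- list(); rhs <- numeric()
  slack_cols <- 0L
  width <- P$u - P$l
  fin <- which(is.finite(width))
  n_slack <- length(fin)
  extra <- extra_ineq %||% list()
  n_extra <- length(extra)
  ntot <- n + n_slack + n_extra
  Amat <- matrix(0, nrow(E) + n_slack + n_extra, ntot)
  bvec <- numeric(nrow(Amat))
  if (nrow(E)) {
    Amat[seq_len(nrow(E)), seq_len(n)] <- E
    bvec[seq_len(nrow(E))] <- d
  }
  ri <- nrow(E)
  for (k in seq_along(fin)) {
    ri <- ri + 1L
    Amat[ri, fin[k]] <- 1
    Amat[ri, n + k] <- 1
    bvec[ri] <- width[fin[k]]
  }
  for (k in seq_along(extra)) {
    ri <- ri + 1L
    a <- rep_len(as.numeric(extra[[k]]$a), n)
    sgn <- if (identical(extra[[k]]$sense, ">=")) -1 else 1
    Amat[ri, seq_len(n)] <- sgn * a
    Amat[ri, n + n_slack + k] <- 1
    bvec[ri] <- sgn * (extra[[k]]$rhs - sum(a * P$l))
  }
  cvec <- c(if (maximize) -obj else obj, rep(0, n_slack + n_extra))
  sol <- simplex_solve(cvec, Amat, bvec, tol = tol)
  if (sol$status != "optimal")
    return(list(status = sol$status, v = NULL, obj = NA_real_))
  v <- sol$x[seq_len(n)] + P$l
  names(v) <- P$var_names
  list(status = "optimal", v = v, obj = sum(obj * v))
}

#' Test whether a flux polytope is empty
#'
#' Runs a phase-1 feasibility LP. Infeasibility (for example a maintenance
#' demand exceeding the maximal attainable supply) is reported as `TRUE`
#' rather than an error.
#'
#' @param polytope a [flux_polytope] object.
#' @return logical scalar.
#' @export
polytope_is_empty <- function(polytope) {
  sol <- lp_over_polytope(polytope, numeric(length(polytope$l)))
  sol$status == "infeasible"
}
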