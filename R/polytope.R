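#' Flux polytope container
#'
#' The xi-dependent feasible set \{v : E v = d, l <= v <= u\} in split
#' (non-negative, except paired exchange variables) coordinates, together with
#' the affine growth functional z(v) = w'v + z0, the enzymatic cost vector and
#' a provenance map back to net reaction fluxes and exchange uptakes.
#'
#' @param E equality matrix (rows = balanced metabolites + optional crowding).
#' @param d equality right-hand side.
#' @param l,u variable bounds.
#' @param w,z0 tilt vector and offset of z(v) = w'v + z0 (1/h).
#' @param cost enzymatic cost per variable (mg.h/mmol; 0 for exchanges/slack).
#' @param var_names variable names.
#' @param provenance list with elements `reactions` (split map) and
#'   `exchanges` (data frame met/upt/exc/closed), or NULL.
#' @param xi the xi at which the polytope was built (gDW.h/L), or NA.
#' @return an object of class `flux_polytope`.
#' @export
flux_polytope <- function(E, d, l, u, w, z0 = 0, cost = NULL,
                          var_names = NULL, provenance = NULL, xi = NA_real_) {
  E <- as.matrix(E)
  n <- ncol(E)
  if (n == 0 && length(l)) { E <- matrix(0, 0, length(l)); n <- length(l) }
  var_names <- var_names %||% paste0("v", seq_len(n))
  stopifnot(length(d) == nrow(E), length(l) == n, length(u) == n,
            length(w) == n)
  if (any(l > u + .tol)) stop2("flux_polytope: l > u")
  if (any(!is.finite(w))) stop2("z must have finite coefficients")
  cost <- cost %||% numeric(n)
  colnames(E) <- var_names
  structure(list(E = E, d = as.numeric(d),
                 l = setNames(as.numeric(l), var_names),
                 u = setNames(as.numeric(u), var_names),
                 w = setNames(as.numeric(w), var_names), z0 = z0,
                 cost = setNames(rep_len(as.numeric(cost), n), var_names),
                 var_names = var_names, provenance = provenance, xi = xi),
            class = "flux_polytope")
}

#' @export
print.flux_polytope <- function(x, ...) {
  cat(sprintf("<flux_polytope> %d variables, %d equality rows (xi = %s)\n",
              length(x$l), nrow(x$E), format(x$xi)))
  invisible(x)
}

#' Evaluate the growth functional z(v) on a flux vector
#' @param polytope a [flux_polytope].
#' @param v flux vector (polytope variable order or named).
#' @return z in 1/h.
#' @export
polytope_z <- function(polytope, v) {
  if (!is.null(names(v))) v <- v[polytope$var_names]
  sum(polytope$w * v) + polytope$z0
}

#' Build the xi-dependent flux polytope of a network in a medium
#'
#' Encodes, for every balanced metabolite i, the stationary balance
#' sum_k N_ik r_k + u_i = e_i + y_i z (z substituted by its affine
#' definition), the uptake bounds u_i in \[-L_i, U_i\] with
#' U_i = min(V_i, c_i/xi), and the enzyme-crowding budget
#' sum_k alpha_k r_k + slack = C with slack in \[0, C\] when C < Inf.
#' Excretable exchanges are represented as uptake-minus-excretion variable
#' pairs so every variable is non-negative.
#'
#' Metabolites listed as exchanges but absent from the medium default to
#' c_i = 0, V_i = Inf (so U_i = 0 for xi > 0); metabolites with infinite feed
#' concentration (water, protons, oxygen) get U_i = V_i and are flagged as not
#' closed (excluded from mass-balance bookkeeping downstream).
#'
#' An infeasible combination (for example maintenance demand exceeding
#' attainable supply) yields an empty polytope, detectable via
#' [polytope_is_empty()]; construction never fails on that account.
#'
#' @param network a split `metabolic_network` (see [split_reversible()]).
#' @param medium a [medium()] table.
#' @param xi cell density over dilution rate (gDW.h/L, >= 0).
#' @param excretion_cap finite cap substituted for L_i = Inf when a bounded
#'   box is required (default `Inf`, i.e. uncapped; see [box_polytope()]).
#' @return a [flux_polytope].
#' @export
build_polytope <- function(network, medium, xi, excretion_cap = Inf) {
  if (!network$split) stop2("network must be split to irreversible form first")
  if (!is_scalar_num(xi) || xi < 0) stop2("xi must be a non-negative scalar")
  rxn <- network$reaction_ids
  nr <- length(rxn)
  bf <- biomass_functional(network)
  ex <- network$exchange_ids
  med_c <- setNames(rep(0, length(ex)), ex)
  med_V <- setNames(rep(Inf, length(ex)), ex)
  known <- intersect(medium$met, ex)
  med_c[known] <- medium$c[match(known, medium$met)]
  med_V[known] <- medium$V[match(known, medium$met)]

  Umax <- uptake_bound(ifelse(is.infinite(med_c), Inf, med_c), med_V, xi)
  Umax[is.infinite(med_c)] <- med_V[is.infinite(med_c)]

  upt_names <- if (length(ex)) paste0("upt__", ex) else character(0)
  excr <- network$excretable[ex]
  exc_names <- if (length(ex)) ifelse(excr, paste0("exc__", ex),
                                      NA_character_) else character(0)

  var_names <- c(rxn, upt_names, exc_names[excr])
  n <- length(var_names)
  l <- setNames(numeric(n), var_names)
  u <- setNames(rep(Inf, n), var_names)
  u[rxn] <- network$ub
  l[rxn] <- network$lb
  u[upt_names] <- Umax
  u[exc_names[excr]] <- excretion_cap

  crowd <- is.finite(network$budget)
  if (crowd) {
    var_names <- c(var_names, "crowding_slack")
    l <- c(l, crowding_slack = 0)
    u <- c(u, crowding_slack = network$budget)
    n <- n + 1L
  }

  mets <- network$metabolite_ids
  E <- matrix(0, length(mets) + crowd, n, dimnames = list(NULL, var_names))
  d <- numeric(nrow(E))
  S <- as.matrix(network$stoich)
  yv <- network$biomass_coeff
  E[seq_along(mets), rxn] <- S - outer(yv, bf$w)
  for (k in seq_along(ex)) {
    i <- match(ex[k], mets)
    E[i, upt_names[k]] <- 1
    if (excr[k]) E[i, exc_names[k]] <- -1
  }
  d[seq_along(mets)] <- network$maintenance + yv * bf$z0
  if (crowd) {
    E[nrow(E), rxn] <- network$cost
    E[nrow(E), "crowding_slack"] <- 1
    d[nrow(E)] <- network$budget
  }

  w <- setNames(numeric(n), var_names)
  w[rxn] <- bf$w
  cost <- setNames(numeric(n), var_names)
  cost[rxn] <- network$cost

  prov <- list(
    reactions = network$split_map,
    exchanges = data.frame(met = ex, upt = upt_names,
                           exc = exc_names,
                           c = as.numeric(med_c), V = as.numeric(med_V),
                           closed = is.finite(med_c),
                           stringsAsFactors = FALSE))
  flux_polytope(E, d, l, u, w, bf$z0, cost, var_names, prov, xi)
}

#' Tighten infinite bounds of a polytope by flux-variability LPs
#'
#' Rejection sampling and Expectation Propagation require a bounded box. Each
#' variable with an infinite upper bound is maximized by LP; an unbounded LP
#' raises an error (the network genuinely lacks a bound).
#'
#' @param polytope a [flux_polytope].
#' @param pad relative padding added to the computed bound (default 0, the
#'   exact implied bound).
#' @return the polytope with finite bounds.
#' @export
box_polytope <- function(polytope, pad = 0) {
  P <- polytope
  for (j in which(!is.finite(P$u))) {
    obj <- numeric(length(P$l)); obj[j] <- 1
    sol <- lp_over_polytope(P, obj, maximize = TRUE)
    if (sol$status == "unbounded")
      stop2("variable ", P$var_names[j], " is unbounded; add bounds")
    if (sol$status == "infeasible") stop2("polytope is empty")
    P$u[j] <- sol$obj * (1 + pad) + .tol
  }
  P
}

# Affine parametrization of {v : Ev = d} restricted to free (l < u) variables:
# v_free = x0 + B t with B orthonormal null-space basis. Fixed variables are
# folded into d. Returns NULL-dimension k = 0 polytopes as a single point.
polytope_nullspace <- function(polytope, tol = 1e-10) {
  l <- polytope$l; u <- polytope$u
  fixed <- which(u - l < .tol)
  free <- setdiff(seq_along(l), fixed)
  E <- polytope$E
  d <- polytope$d
  if (length(fixed) && nrow(E))
    d <- d - as.numeric(E[, fixed, drop = FALSE] %*% l[fixed])
  Ef <- E[, free, drop = FALSE]
  nf <- length(free)
  if (nrow(Ef) == 0) {
    return(list(free = free, fixed = fixed, fixed_val = l[fixed],
                B = diag(nf), x0 = numeric(nf), k = nf, resid = 0))
  }
  sv <- svd(Ef, nu = nrow(Ef), nv = nf)
  rk <- sum(sv$d > tol * max(sv$d, 1))
  B <- if (rk < nf) sv$v[, (rk + 1):nf, drop = FALSE] else matrix(0, nf, 0)
  x0 <- if (rk > 0) {
    sv$v[, seq_len(rk), drop = FALSE] %*%
      ((t(sv$u[, seq_len(rk), drop = FALSE]) %*% d) / sv$d[seq_len(rk)])
  } else matrix(0, nf, 1)
  x0 <- as.numeric(x0)
  resid <- sqrt(sum((as.numeric(Ef %*% x0) - d)^2))
  list(free = free, fixed = fixed, fixed_val = l[fixed],
       B = B, x0 = x0, k = ncol(B), resid = resid)
}

# Net uptake per exchange metabolite from a full variable vector.
polytope_net_uptake <- function(polytope, v) {
  exch <- polytope$provenance$exchanges
  if (is.null(exch)) return(setNames(numeric(0), character(0)))
  out <- setNames(numeric(nrow(exch)), exch$met)
  for (i in seq_len(nrow(exch))) {
    upt <- v[[exch$upt[i]]]
    exc <- if (!is.na(exch$exc[i])) v[[exch$exc[i]]] else 0
    out[i] <- upt - exc
  }
  out
}
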