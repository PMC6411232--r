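#' Construct a metabolic network
#'
#' The static description of a cell's metabolism: stoichiometry, reaction
#' reversibility and bounds, which metabolites are exchangeable with the
#' medium, per-metabolite maintenance demands and biomass requirements, the
#' enzymatic flux costs and the crowding budget, and the definition of the
#' biomass synthesis rate `z`.
#'
#' Units follow the conventions of mammalian-cell constraint-based models:
#' fluxes in mmol/gDW/h, costs `alpha` in mg.h/mmol, budget `C` in mg/mgDW,
#' maintenance `e_i` in mmol/gDW/h and biomass coefficients `y_i` in mmol/gDW.
#'
#' @param metabolite_ids character vector of metabolite identifiers.
#' @param reaction_ids character vector of reaction identifiers.
#' @param stoich stoichiometric matrix (metabolites x reactions); dense or
#'   sparse, coerced to [Matrix::Matrix] sparse.
#' @param lb,ub flux bounds per reaction (mmol/gDW/h); `-Inf`/`Inf` allowed.
#' @param reversible logical per reaction; defaults to `lb < 0`.
#' @param exchange_ids metabolites exchangeable with the medium.
#' @param excretable named logical over `exchange_ids`; `FALSE` encodes an
#'   excretion bound L_i = 0, `TRUE` encodes L_i = Inf.
#' @param maintenance named non-negative vector e_i (growth-independent
#'   demand); missing metabolites default to 0.
#' @param biomass_coeff named non-negative vector y_i; missing default 0.
#' @param cost non-negative enzymatic cost alpha_k per reaction; default 0.
#' @param budget crowding budget `C` (> 0, `Inf` disables the constraint).
#' @param biomass definition of z: either
#'   `list(kind = "reaction", reaction = <id>)` for a biomass reaction flux, or
#'   `list(kind = "affine", weights = <named coefficients>, e = <maintenance>,
#'   y = <yield>)` for z = (sum w_k v_k - e)/y.
#' @return an object of class `metabolic_network`.
#' @export
metabolic_network <- function(metabolite_ids, reaction_ids, stoich,
                              lb, ub, reversible = NULL,
                              exchange_ids = character(),
                              excretable = NULL,
                              maintenance = NULL, biomass_coeff = NULL,
                              cost = NULL, budget = Inf,
                              biomass = NULL) {
  m <- length(metabolite_ids); n <- length(reaction_ids)
  stoich <- Matrix::Matrix(stoich, sparse = TRUE)
  if (!all(dim(stoich) == c(m, n)))
    stop2("stoich must be ", m, " x ", n, ", got ", nrow(stoich), " x ", ncol(stoich))
  dimnames(stoich) <- list(metabolite_ids, reaction_ids)
  lb <- rep_len(as.numeric(lb), n); ub <- rep_len(as.numeric(ub), n)
  if (any(lb > ub)) {
    bad <- reaction_ids[lb > ub]
    stop2("lb > ub for reaction(s): ", paste(bad, collapse = ", "))
  }
  if (is.null(reversible)) reversible <- lb < 0
  reversible <- rep_len(as.logical(reversible), n)
  if (any(!reversible & lb < 0))
    stop2("irreversible reactions must have lb = 0: ",
          paste(reaction_ids[!reversible & lb < 0], collapse = ", "))
  if (!all(exchange_ids %in% metabolite_ids))
    stop2("unknown exchange metabolite(s): ",
          paste(setdiff(exchange_ids, metabolite_ids), collapse = ", "))
  fill <- function(x, ids, default = 0) {
    out <- setNames(rep(default, length(ids)), ids)
    if (!is.null(x)) {
      if (is.null(names(x))) stop2("named vector required")
      unknown <- setdiff(names(x), ids)
      if (length(unknown)) stop2("unknown id(s): ", paste(unknown, collapse = ", "))
      out[names(x)] <- x
    }
    out
  }
  maintenance <- fill(maintenance, metabolite_ids)
  biomass_coeff <- fill(biomass_coeff, metabolite_ids)
  if (any(maintenance < 0) || any(biomass_coeff < 0))
    stop2("maintenance and biomass_coeff must be non-negative")
  if (is.null(cost)) cost <- rep(0, n)
  if (!is.null(names(cost))) cost <- fill(cost, reaction_ids)
  cost <- rep_len(as.numeric(cost), n)
  if (any(cost < 0)) stop2("costs alpha_k must be non-negative")
  if (!is_scalar_num(budget) || budget <= 0) stop2("budget C must be > 0")
  excr <- setNames(rep(TRUE, length(exchange_ids)), exchange_ids)
  if (!is.null(excretable)) {
    if (is.null(names(excretable))) stop2("excretable must be named")
    excr[names(excretable)] <- as.logical(excretable)
  }
  if (is.null(biomass)) stop2("a biomass definition is required")
  if (identical(biomass$kind, "reaction")) {
    if (!biomass$reaction %in% reaction_ids)
      stop2("biomass reaction not found: ", biomass$reaction)
  } else if (identical(biomass$kind, "affine")) {
    if (is.null(names(biomass$weights)) ||
        !all(names(biomass$weights) %in% reaction_ids))
      stop2("biomass weights must be named by reaction id")
    if (!is_scalar_num(biomass$y) || biomass$y <= 0) stop2("biomass yield y must be > 0")
    if (!is_scalar_num(biomass$e) || biomass$e < 0) stop2("biomass maintenance e must be >= 0")
  } else stop2("biomass$kind must be 'reaction' or 'affine'")

  structure(list(
    metabolite_ids = metabolite_ids, reaction_ids = reaction_ids,
    stoich = stoich, reversible = reversible,
    lb = setNames(lb, reaction_ids), ub = setNames(ub, reaction_ids),
    exchange_ids = exchange_ids, excretable = excr,
    maintenance = maintenance, biomass_coeff = biomass_coeff,
    cost = setNames(cost, reaction_ids), budget = budget,
    biomass = biomass, split = FALSE, split_map = NULL
  ), class = "metabolic_network")
}

#' @export
print.metabolic_network <- function(x, ...) {
  cat(sprintf("<metabolic_network> %d metabolites x %d reactions%s\n",
              length(x$metabolite_ids), length(x$reaction_ids),
              if (x$split) " (split to irreversible form)" else ""))
  cat(sprintf("  exchanges: %s\n", paste(x$exchange_ids, collapse = ", ")))
  cat(sprintf("  crowding budget C = %s, z defined via %s\n",
              format(x$budget), x$biomass$kind))
  invisible(x)
}

#' Tilt vector of the biomass rate z over reaction fluxes
#'
#' Returns `list(w, z0)` such that z = sum(w_k v_k) + z0 on the (possibly
#' split) reaction flux vector.
#' @keywords internal
biomass_functional <- function(network) {
  n <- length(network$reaction_ids)
  w <- setNames(numeric(n), network$reaction_ids)
  if (network$biomass$kind == "reaction") {
    w[network$biomass$reaction] <- 1
    z0 <- 0
  } else {
    w[names(network$biomass$weights)] <- network$biomass$weights / network$biomass$y
    z0 <- -network$biomass$e / network$biomass$y
  }
  list(w = w, z0 = z0)
}

#' Split reversible reactions into irreversible forward/backward pairs
#'
#' The crowding constraint sum(alpha_k |r_k|) <= C is nonlinear in signed
#' fluxes; splitting makes every flux non-negative so the constraint becomes
#' linear. Reverse-only reactions (ub <= 0) are flipped into a single
#' non-negative variable rather than a pair.
#'
#' @param network a `metabolic_network`.
#' @return the split network, with `$split_map` holding for each original
#'   reaction the forward/backward variable names (NA when absent) so that
#'   net flux = v\[fwd\] - v\[bwd\]; see [reassemble_fluxes()].
#' @export
split_reversible <- function(network) {
  if (network$split) return(network)
  ids <- network$reaction_ids
  cols <- list(); newid <- character(); lb <- numeric(); ub <- numeric()
  cost <- numeric()
  map <- data.frame(orig = ids, fwd = NA_character_, bwd = NA_character_,
                    stringsAsFactors = FALSE)
  S <- network$stoich
  bf <- biomass_functional(network)
  w <- numeric(); wnames <- character()
  add <- function(col, id, l, u, a, wt) {
    cols[[length(cols) + 1L]] <<- col
    newid <<- c(newid, id)
    lb <<- c(lb, unname(l)); ub <<- c(ub, unname(u))
    cost <<- c(cost, unname(a)); w <<- c(w, unname(wt))
  }
  for (j in seq_along(ids)) {
    l <- network$lb[j]; u <- network$ub[j]; a <- network$cost[j]
    wt <- bf$w[j]
    if (l >= 0) {
      add(S[, j], ids[j], l, u, a, wt)
      map$fwd[j] <- ids[j]
    } else if (u <= 0) {
      nid <- paste0(ids[j], "__rev")
      add(-S[, j], nid, -u, -l, a, -wt)
      map$bwd[j] <- nid
    } else {
      fid <- paste0(ids[j], "__fwd"); bid <- paste0(ids[j], "__bwd")
      add(S[, j], fid, 0, u, a, wt)
      add(-S[, j], bid, 0, -l, a, -wt)
      map$fwd[j] <- fid; map$bwd[j] <- bid
    }
  }
  S2 <- do.call(cbind, lapply(cols, as.numeric))
  out <- metabolic_network(
    metabolite_ids = network$metabolite_ids, reaction_ids = newid,
    stoich = S2, lb = lb, ub = ub, reversible = rep(FALSE, length(newid)),
    exchange_ids = network$exchange_ids, excretable = network$excretable,
    maintenance = network$maintenance, biomass_coeff = network$biomass_coeff,
    cost = cost, budget = network$budget,
    # the original functional carried over exactly: weights are already scaled
    # by the yield, so the split network uses y = 1 and e = -z0
    biomass = list(kind = "affine", weights = setNames(w, newid),
                   e = -bf$z0, y = 1))
  out$split <- TRUE
  out$split_map <- map
  out$parent <- list(reaction_ids = ids)
  out
}

#' Reassemble net fluxes of the original reactions from split variables
#'
#' @param network a split `metabolic_network` (output of [split_reversible()]).
#' @param v named flux vector over the split variable names.
#' @return named net flux vector over the original reaction ids.
#' @export
reassemble_fluxes <- function(network, v) {
  if (!network$split) stop2("network is not split")
  map <- network$split_map
  out <- setNames(numeric(nrow(map)), map$orig)
  for (j in seq_len(nrow(map))) {
    f <- if (!is.na(map$fwd[j])) v[[map$fwd[j]]] else 0
    b <- if (!is.na(map$bwd[j])) v[[map$bwd[j]]] else 0
    out[j] <- f - b
  }
  out
}

#' Medium definition
#'
#' @param metabolite_ids exchanged metabolites.
#' @param conc feed concentrations c_i (mM); `Inf` allowed (e.g. water).
#' @param vmax maximal uptake rates V_i (mmol/gDW/h); `Inf` allowed.
#' @return a `medium` object (data frame with columns met, c, V).
#' @export
medium <- function(metabolite_ids, conc, vmax) {
  conc <- rep_len(as.numeric(conc), length(metabolite_ids))
  vmax <- rep_len(as.numeric(vmax), length(metabolite_ids))
  if (any(conc < 0)) stop2("feed concentrations c_i must be >= 0")
  if (any(vmax < 0)) stop2("maximal uptakes V_i must be >= 0")
  structure(data.frame(met = metabolite_ids, c = conc, V = vmax,
                       stringsAsFactors = FALSE),
            class = c("medium", "data.frame"))
}

#' Toxicity model: multiplicative growth inhibition and linear death
#'
#' @param K_inhib named inhibition constants K_i (mM, > 0); the inhibition
#'   factor is K(s) = prod_i (1 + s_i/K_i)^-1.
#' @param tau named linear death coefficients tau_i (1/h/mM, >= 0); the death
#'   rate is sigma(s) = sum_i tau_i s_i.
#' @return a `toxicity_model` object.
#' @export
toxicity_model <- function(K_inhib = NULL, tau = NULL) {
  if (!is.null(K_inhib)) {
    if (is.null(names(K_inhib))) stop2("K_inhib must be named by metabolite")
    if (any(K_inhib <= 0)) stop2("inhibition constants K_i must be > 0")
  }
  if (!is.null(tau)) {
    if (is.null(names(tau))) stop2("tau must be named by metabolite")
    if (any(tau < 0)) stop2("death coefficients tau_i must be >= 0")
  }
  structure(list(K_inhib = K_inhib, tau = tau), class = "toxicity_model")
}

check_conc <- function(s) {
  if (is.null(names(s)) && length(s)) stop2("concentration vector must be named")
  if (any(s < 0)) stop2("negative concentration(s): ",
                        paste(names(s)[s < 0], collapse = ", "))
  s
}

#' Growth inhibition factor K(s)
#'
#' K(s) = prod_i (1 + s_i/K_i)^-1 over the inhibiting metabolites; always in
#' (0, 1]. Metabolites absent from `s` contribute s_i = 0.
#'
#' @param s named concentration vector (mM, >= 0).
#' @param tox a [toxicity_model()].
#' @return dimensionless scalar in (0, 1].
#' @export
growth_inhibition <- function(s, tox) {
  check_conc(s)
  if (is.null(tox$K_inhib)) return(1)
  si <- ifelse(names(tox$K_inhib) %in% names(s), s[names(tox$K_inhib)], 0)
  prod(1 / (1 + si / tox$K_inhib))
}

#' Death rate sigma(s) = sum_i tau_i s_i
#'
#' @inheritParams growth_inhibition
#' @return death rate in 1/h (>= 0).
#' @export
death_rate <- function(s, tox) {
  check_conc(s)
  if (is.null(tox$tau)) return(0)
  si <- ifelse(names(tox$tau) %in% names(s), s[names(tox$tau)], 0)
  sum(tox$tau * si)
}

#' Net growth rate lambda = z K(s) - sigma(s)
#'
#' @param z biomass synthesis rate (1/h).
#' @inheritParams growth_inhibition
#' @return net growth rate (1/h); can be negative.
#' @export
net_growth <- function(z, s, tox) {
  z * growth_inhibition(s, tox) - death_rate(s, tox)
}

#' Maximum uptake bound U_i = min(V_i, c_i / xi)
#'
#' The supply limit follows from non-negativity of the steady-state
#' concentration s_i = c_i - <u_i> xi: uptake cannot exceed c_i/xi. At xi = 0
#' there is no supply limitation and U_i = V_i.
#'
#' @param c_i feed concentration (mM, >= 0).
#' @param V_i kinetic maximal uptake (mmol/gDW/h, >= 0).
#' @param xi cell density over dilution rate, X/D (gDW.h/L, >= 0).
#' @return uptake bound (mmol/gDW/h). Vectorized over inputs.
#' @export
uptake_bound <- function(c_i, V_i, xi) {
  if (any(c_i < 0) || any(V_i < 0) || any(xi < 0))
    stop2("uptake_bound: inputs must be non-negative")
  n <- max(length(c_i), length(V_i), length(xi))
  c_i <- rep_len(c_i, n); V_i <- rep_len(V_i, n); xi <- rep_len(xi, n)
  supply <- rep(Inf, n)
  pos <- xi > 0 & is.finite(c_i)
  supply[pos] <- c_i[pos] / xi[pos]
  setNames(pmin(V_i, supply), names(c_i))
}
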