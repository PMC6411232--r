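#' Lexicographic flux balance analysis on a polytope
#'
#' Stage 1 maximizes the growth functional z; stage 2 minimizes the total
#' enzymatic cost sum(alpha_k r_k) subject to z staying at its optimum within
#' a relative tolerance. The cost tie-break makes the optimum unique whenever
#' the cost coefficients are heterogeneous enough that constant-cost contours
#' are not parallel to constant-z contours.
#'
#' @param polytope a [flux_polytope].
#' @param z_tol relative tolerance pinning stage-2 z to the stage-1 optimum.
#' @return named optimal flux vector with attributes `z` and `cost`.
#'   Errors with message containing "infeasible" on an empty polytope and
#'   "unbounded" when bounds are missing.
#' @export
fba_solve <- function(polytope, z_tol = 1e-9) {
  s1 <- lp_over_polytope(polytope, polytope$w, maximize = TRUE)
  if (s1$status == "infeasible") stop2("fba_solve: polytope is infeasible")
  if (s1$status == "unbounded")
    stop2("fba_solve: z is unbounded (missing bounds)")
  zopt <- s1$obj
  if (all(polytope$cost == 0)) {
    # nothing to tie-break on; keep the stage-1 vertex (exact z optimum)
    v <- s1$v
  } else {
    floor_z <- zopt - z_tol * max(1, abs(zopt))
    s2 <- lp_over_polytope(polytope, polytope$cost, maximize = FALSE,
                           extra_ineq = list(list(a = polytope$w, rhs = floor_z,
                                                  sense = ">=")))
    if (s2$status == "unbounded")
      stop2("fba_solve: cost is unbounded (missing bounds)")
    v <- if (s2$status == "optimal") s2$v else s1$v
  }
  attr(v, "z") <- polytope_z(polytope, v)
  attr(v, "cost") <- sum(polytope$cost * v)
  v
}

#' Remove reactions carrying no flux anywhere on a xi grid
#'
#' Runs lexicographic FBA at every xi of the grid and drops the original
#' reactions whose net flux stays below `tol` at all feasible grid points,
#' then prunes metabolites that no longer participate in any reaction (unless
#' they carry a maintenance or biomass demand). Infeasible grid points are
#' reported in the removal report, never silently dropped.
#'
#' @param network a `metabolic_network` (split or not; splitting is applied
#'   internally and the reduction is reported on the original reactions).
#' @param medium a [medium()].
#' @param xi_grid xi values to probe; default 30 log-spaced points in
#'   \[1e-2, 1e3\].
#' @param tol zero-flux tolerance (mmol/gDW/h).
#' @return the reduced network (same split state as the input), with
#'   attribute `reduction_report`: list(removed_reactions, removed_metabolites,
#'   skipped_xi, max_flux).
#' @export
reduce_network <- function(network, medium,
                           xi_grid = exp(seq(log(1e-2), log(1e3),
                                             length.out = 30)),
                           tol = 1e-8) {
  was_split <- network$split
  orig <- network
  split <- if (was_split) network else split_reversible(network)
  orig_ids <- split$split_map$orig
  maxflux <- setNames(numeric(length(orig_ids)), orig_ids)
  skipped <- numeric(0)
  for (xi in xi_grid) {
    P <- build_polytope(split, medium, xi)
    v <- tryCatch(fba_solve(P), error = function(e) e)
    if (inherits(v, "error")) {
      skipped <- c(skipped, xi)
      next
    }
    nets <- abs(reassemble_fluxes(split, v))
    maxflux <- pmax(maxflux, nets[orig_ids])
  }
  drop_rxn <- orig_ids[maxflux < tol]
  base <- if (was_split) split else orig
  keep_r <- setdiff(base$reaction_ids, if (was_split) {
    # map original drops to split variable names
    mm <- split$split_map[split$split_map$orig %in% drop_rxn, ]
    c(mm$fwd[!is.na(mm$fwd)], mm$bwd[!is.na(mm$bwd)])
  } else drop_rxn)
  ri <- match(keep_r, base$reaction_ids)
  S <- as.matrix(base$stoich)[, ri, drop = FALSE]
  used <- rowSums(S != 0) > 0 | base$maintenance > 0 | base$biomass_coeff > 0
  keep_m <- base$metabolite_ids[used]
  S <- S[used, , drop = FALSE]
  bw <- base$biomass
  if (bw$kind == "affine") bw$weights <- bw$weights[names(bw$weights) %in% keep_r]
  out <- metabolic_network(
    metabolite_ids = keep_m, reaction_ids = keep_r, stoich = S,
    lb = base$lb[ri], ub = base$ub[ri], reversible = base$reversible[ri],
    exchange_ids = intersect(base$exchange_ids, keep_m),
    excretable = base$excretable[intersect(base$exchange_ids, keep_m)],
    maintenance = base$maintenance[keep_m],
    biomass_coeff = base$biomass_coeff[keep_m],
    cost = base$cost[ri], budget = base$budget, biomass = bw)
  if (was_split) {
    out$split <- TRUE
    out$split_map <- split$split_map[!(split$split_map$orig %in% drop_rxn), ,
                                     drop = FALSE]
  }
  attr(out, "reduction_report") <- list(
    removed_reactions = drop_rxn,
    removed_metabolites = setdiff(base$metabolite_ids, keep_m),
    skipped_xi = skipped, max_flux = maxflux)
  out
}

#' Random multiplicative perturbation of enzymatic cost coefficients
#'
#' Each alpha_k is multiplied by an independent uniform factor in
#' \[1 - max_rel, 1 + max_rel\]; used to probe robustness of sweep features
#' to poorly annotated costs.
#'
#' @param network a `metabolic_network`.
#' @param max_rel maximal relative perturbation, in \[0, 1).
#' @param seed integer seed (RNG state of the caller is preserved).
#' @return the perturbed network.
#' @export
perturb_costs <- function(network, max_rel = 0.25, seed = 1) {
  stopifnot(max_rel >= 0, max_rel < 1)
  f <- with_seed(seed, function()
    runif(length(network$cost), 1 - max_rel, 1 + max_rel))
  network$cost <- network$cost * f
  network
}
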