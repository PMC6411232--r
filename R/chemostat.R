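#' One self-consistent chemostat steady state
#'
#' Constructor used by [solve_at()]; rarely called directly.
#'
#' @param xi,beta_prime,beta control parameters.
#' @param s named concentrations (mM).
#' @param u named net uptakes (mmol/gDW/h).
#' @param z_mean,K,sigma,lambda,D,X derived quantities.
#' @param stability one of "stable", "unstable", "boundary", "unknown".
#' @param feasible logical; FALSE flags washout or a failed computation.
#' @param engine,converged,note moment-engine metadata.
#' @return a `steady_state` object.
#' @export
steady_state <- function(xi, beta_prime, beta = NA_real_, s = NULL, u = NULL,
                         z_mean = NA_real_, K = NA_real_, sigma = NA_real_,
                         lambda = NA_real_, D = NA_real_, X = NA_real_,
                         stability = "unknown", feasible = FALSE,
                         engine = NA_character_, converged = NA,
                         note = NULL) {
  structure(list(xi = xi, beta_prime = beta_prime, beta = beta,
                 s = s, u = u, z_mean = z_mean, K = K, sigma = sigma,
                 lambda = lambda, D = D, X = X, stability = stability,
                 feasible = feasible, engine = engine, converged = converged,
                 note = note),
            class = "steady_state")
}

#' @export
print.steady_state <- function(x, ...) {
  cat(sprintf(
    "<steady_state> xi=%.4g beta'=%s D=%.6g X=%.6g feasible=%s (%s)\n",
    x$xi, format(x$beta_prime), x$D, x$X, x$feasible, x$engine))
  if (length(x$s))
    cat("  s:", paste(sprintf("%s=%.4g", names(x$s), x$s), collapse = ", "), "\n")
  invisible(x)
}

resolve_engine <- function(engine, beta_prime, ep_opts) {
  if (is.function(engine)) return(engine)
  engine <- match.arg(engine, c("ep", "fba"))
  if (engine == "fba" || is.infinite(beta_prime)) {
    function(P, bp) {
      v <- fba_solve(P)
      moment_result(mean = v, var = setNames(numeric(length(v)), names(v)),
                    z_mean = attr(v, "z"), z_var = 0, method = "fba",
                    u_mean = polytope_net_uptake(P, v))
    }
  } else {
    function(P, bp) ep_moments(P, bp, ep_opts)
  }
}

#' Solve the chemostat at given (xi, beta')
#'
#' The formal solution sequence: build the xi-dependent polytope; compute the
#' moments of the tilted distribution with the chosen engine; set
#' s_i = c_i - <u_i> xi for every closed exchange; then K(s), sigma(s),
#' beta = beta'/K, <lambda> = <z> K - sigma, D = <lambda> and X = xi D.
#' A negative D means washout: the state is flagged infeasible, never clamped.
#' An empty polytope or non-converged moments yield a flagged state, never
#' fabricated numbers.
#'
#' @param xi gDW.h/L (>= 0).
#' @param beta_prime effective tilt (h; \[0, Inf\]).
#' @param network a `metabolic_network` (split automatically if needed).
#' @param med a [medium()].
#' @param tox a [toxicity_model()] (default: no toxicity).
#' @param engine "ep", "fba", or a function(polytope, beta_prime) returning a
#'   [moment_result()] (e.g. [toy_quadrature_engine()]).
#' @param ep_opts an [ep_options()] list for the EP engine.
#' @param excretion_cap passed to [build_polytope()].
#' @param s_tol negative concentrations above `-s_tol` are clamped to zero;
#'   larger negativity errors (it signals a violated uptake bound).
#' @return a [steady_state()].
#' @export
solve_at <- function(xi, beta_prime, network, med, tox = toxicity_model(),
                     engine = "ep", ep_opts = ep_options(),
                     excretion_cap = Inf, s_tol = 1e-8) {
  stopifnot(xi >= 0, beta_prime >= 0)
  net <- if (network$split) network else split_reversible(network)
  P <- build_polytope(net, med, xi, excretion_cap)
  eng_name <- if (is.function(engine)) "custom" else engine
  if (polytope_is_empty(P))
    return(steady_state(xi, beta_prime, engine = eng_name,
                        note = "empty polytope"))
  fn <- resolve_engine(engine, beta_prime, ep_opts)
  mom <- tryCatch(fn(P, beta_prime), error = function(e) e)
  if (inherits(mom, "error"))
    return(steady_state(xi, beta_prime, engine = eng_name,
                        note = conditionMessage(mom)))
  if (!isTRUE(mom$converged))
    return(steady_state(xi, beta_prime, engine = mom$method,
                        converged = FALSE, note = "moments did not converge"))
  exch <- P$provenance$exchanges
  closed <- exch$met[exch$closed]
  u <- mom$u_mean[closed]
  cvec <- setNames(exch$c[exch$closed], closed)
  s <- cvec - u * xi
  bad <- s < -s_tol * pmax(1, cvec)
  if (any(bad))
    stop2("negative steady-state concentration for ",
          paste(closed[bad], collapse = ", "),
          " (uptake bound violated?)")
  if (any(s < 0)) {
    message("clamping tiny negative concentration(s): ",
            paste(closed[s < 0], collapse = ", "))
    s[s < 0] <- 0
  }
  K <- growth_inhibition(s, tox)
  sig <- death_rate(s, tox)
  lambda <- mom$z_mean * K - sig
  D <- lambda
  X <- xi * D
  beta <- if (is.infinite(beta_prime)) Inf else beta_prime / K
  steady_state(xi, beta_prime, beta = beta, s = s, u = mom$u_mean,
               z_mean = mom$z_mean, K = K, sigma = sig, lambda = lambda,
               D = D, X = X, feasible = D >= 0,
               engine = mom$method, converged = mom$converged)
}

#' Solve the chemostat at fixed heterogeneity beta
#'
#' Finds beta' such that beta'/K(s(xi, beta')) = beta by bisection on
#' beta' in \[0, beta\] (K <= 1 guarantees the bracket). With no inhibiting
#' metabolites K = 1 identically and beta' = beta without iteration.
#'
#' @inheritParams solve_at
#' @param beta heterogeneity parameter (h; \[0, Inf\]).
#' @param rel_tol relative tolerance on beta'.
#' @return a [steady_state()] with `beta` set; a bracket without sign change
#'   is flagged with stability "unknown" and a note.
#' @export
solve_fixed_beta <- function(xi, beta, network, med, tox = toxicity_model(),
                             engine = "ep", ep_opts = ep_options(),
                             excretion_cap = Inf, rel_tol = 1e-8) {
  stopifnot(beta >= 0)
  at <- function(bp) solve_at(xi, bp, network, med, tox, engine, ep_opts,
                              excretion_cap)
  if (beta == 0 || is.infinite(beta) || is.null(tox$K_inhib)) {
    st <- at(beta)
    st$beta <- beta
    return(st)
  }
  f <- function(bp) {
    st <- at(bp)
    if (!isTRUE(st$feasible) && is.null(st$s)) return(list(val = NA, st = st))
    list(val = bp - beta * st$K, st = st)
  }
  lo <- 0; hi <- beta
  flo <- f(lo); fhi <- f(hi)
  if (is.na(flo$val) || is.na(fhi$val) || flo$val > 0 || fhi$val < 0) {
    st <- fhi$st
    st$stability <- "unknown"
    st$note <- "no sign change in beta' bracket"
    return(st)
  }
  st <- fhi$st
  for (it in 1:200) {
    mid <- 0.5 * (lo + hi)
    fm <- f(mid)
    if (is.na(fm$val)) break
    st <- fm$st
    if (fm$val > 0) hi <- mid else lo <- mid
    if ((hi - lo) <= rel_tol * max(beta, 1e-12)) break
  }
  st$beta <- beta
  st
}

#' Sweep steady states over a xi grid for each beta
#'
#' @inheritParams solve_fixed_beta
#' @param xi_grid strictly increasing xi values.
#' @param beta_list heterogeneity values (may include `Inf`).
#' @return a `sweep_result`: a data frame with one row per (beta, xi) and
#'   columns xi, beta, beta_prime, D, X, K, sigma, z, s_/u_ per exchange,
#'   stability, feasible, engine, converged; the full `steady_state` objects
#'   are kept in attribute `states`.
#' @export
chemostat_sweep <- function(xi_grid, beta_list, network, med,
                            tox = toxicity_model(), engine = "ep",
                            ep_opts = ep_options(), excretion_cap = Inf) {
  if (is.unsorted(xi_grid, strictly = TRUE))
    stop2("xi_grid must be strictly increasing")
  states <- list()
  rows <- list()
  for (beta in beta_list) {
    curve <- lapply(xi_grid, function(xi)
      solve_fixed_beta(xi, beta, network, med, tox, engine, ep_opts,
                       excretion_cap))
    stab <- classify_stability(xi_grid, vapply(curve, function(s)
      ifelse(is.na(s$D), -Inf, s$D), numeric(1)),
      feasible = vapply(curve, function(s) isTRUE(s$feasible), logical(1)))
    for (i in seq_along(curve)) curve[[i]]$stability <- stab[i]
    states <- c(states, curve)
    rows[[length(rows) + 1L]] <- do.call(rbind, lapply(curve, function(st) {
      base <- data.frame(xi = st$xi, beta = beta, beta_prime = st$beta_prime,
                         D = st$D, X = st$X, K = st$K, sigma = st$sigma,
                         z = st$z_mean, stability = st$stability,
                         feasible = st$feasible, engine = st$engine,
                         converged = isTRUE(st$converged))
      for (m in names(st$s)) base[[paste0("s_", m)]] <- st$s[[m]]
      for (m in names(st$u)) base[[paste0("u_", m)]] <- st$u[[m]]
      base
    }))
  }
  if (!length(rows)) {
    out <- data.frame()
  } else {
    cols <- unique(unlist(lapply(rows, names)))
    rows <- lapply(rows, function(r) {
      for (cc in setdiff(cols, names(r))) r[[cc]] <- NA
      r[cols]
    })
    out <- do.call(rbind, rows)
  }
  attr(out, "states") <- states
  class(out) <- c("sweep_result", "data.frame")
  out
}

#' Classify stability of steady states along a D(xi) curve
#'
#' A steady state is stable where D(xi) is decreasing. Interior points use a
#' central finite difference; when that vanishes (a local extremum on the
#' grid) the backward difference decides, so a washed-out peak classifies as
#' unstable. Endpoints use one-sided differences and may only be "stable" or
#' "unknown". Points flagged infeasible are labelled "infeasible".
#'
#' @param xi,D numeric vectors (>= 3 points).
#' @param feasible optional logical vector.
#' @param tol slope magnitude below which a point is "boundary".
#' @return character vector of flags.
#' @export
classify_stability <- function(xi, D, feasible = NULL, tol = 1e-12) {
  n <- length(xi)
  if (n < 3) stop2("need at least 3 points to classify stability")
  feasible <- feasible %||% rep(TRUE, n)
  out <- character(n)
  slope_ok <- function(s) if (s < -tol) "stable" else if (s > tol) "unstable" else "boundary"
  for (i in seq_len(n)) {
    if (!feasible[i]) { out[i] <- "infeasible"; next }
    if (i == 1) {
      s <- (D[2] - D[1]) / (xi[2] - xi[1])
      out[i] <- if (s < -tol) "stable" else "unknown"
    } else if (i == n) {
      s <- (D[n] - D[n - 1]) / (xi[n] - xi[n - 1])
      out[i] <- if (s < -tol) "stable" else "unknown"
    } else {
      s <- (D[i + 1] - D[i - 1]) / (xi[i + 1] - xi[i - 1])
      if (abs(s) <= tol) s <- (D[i] - D[i - 1]) / (xi[i] - xi[i - 1])
      out[i] <- slope_ok(s)
    }
  }
  out
}

#' Medium depth: the largest xi with a non-negative steady-state growth
#'
#' Scans D(xi) on a log grid, takes the last feasible point and bisects
#' against the next grid point. If D >= 0 at the top of the search range the
#' result is `Inf` with attribute `open_ended = TRUE`.
#'
#' @param D_fun function(xi) returning the steady-state D (NA allowed).
#' @param xi_range search interval.
#' @param n_grid number of log-spaced scan points.
#' @param rel_tol relative bisection tolerance.
#' @return xi_m (gDW.h/L).
#' @export
medium_depth <- function(D_fun, xi_range = c(1e-2, 5e3), n_grid = 60,
                         rel_tol = 1e-6) {
  xs <- exp(seq(log(xi_range[1]), log(xi_range[2]), length.out = n_grid))
  Ds <- vapply(xs, function(x) {
    d <- D_fun(x)
    if (is.null(d) || is.na(d)) -Inf else d
  }, numeric(1))
  pos <- which(Ds >= 0)
  if (!length(pos)) return(0)
  i <- max(pos)
  if (i == length(xs)) return(structure(Inf, open_ended = TRUE))
  lo <- xs[i]; hi <- xs[i + 1]
  repeat {
    mid <- 0.5 * (lo + hi)
    d <- D_fun(mid)
    if (!is.null(d) && !is.na(d) && d >= 0) lo <- mid else hi <- mid
    if ((hi - lo) <= rel_tol * hi) break
  }
  0.5 * (lo + hi)
}

#' Phase diagram over a (beta, xi) grid
#'
#' Labels each cell infeasible / stable / unstable from per-beta D(xi) curves
#' and extracts the region boundaries: the medium depth xi_m(beta) (largest
#' feasible xi on the grid) and the endpoints of the unstable window.
#'
#' @param beta_grid,xi_grid non-empty grids (xi strictly increasing).
#' @param solve_fun function(xi, beta) returning a [steady_state()] (or any
#'   list with elements D and feasible).
#' @return list with `table` (data frame beta, xi, region, X) and `boundaries`
#'   (data frame beta, xi_m, unstable_lo, unstable_hi).
#' @export
phase_diagram <- function(beta_grid, xi_grid, solve_fun) {
  if (!length(beta_grid) || !length(xi_grid)) stop2("grids must be non-empty")
  tabs <- list(); bounds <- list()
  for (beta in beta_grid) {
    curve <- lapply(xi_grid, function(xi) solve_fun(xi, beta))
    D <- vapply(curve, function(s) ifelse(is.na(s$D), -Inf, s$D), numeric(1))
    feas <- vapply(curve, function(s) isTRUE(s$feasible), logical(1))
    stab <- classify_stability(xi_grid, D, feasible = feas)
    region <- ifelse(!feas, "infeasible",
                     ifelse(stab == "unstable", "unstable", "stable"))
    X <- vapply(curve, function(s) ifelse(isTRUE(s$feasible), s$X, NA_real_),
                numeric(1))
    tabs[[length(tabs) + 1L]] <-
      data.frame(beta = beta, xi = xi_grid, region = region, X = X)
    un <- which(region == "unstable")
    bounds[[length(bounds) + 1L]] <- data.frame(
      beta = beta,
      xi_m = if (any(feas)) max(xi_grid[feas]) else NA_real_,
      unstable_lo = if (length(un)) xi_grid[min(un)] else NA_real_,
      unstable_hi = if (length(un)) xi_grid[max(un)] else NA_real_)
  }
  list(table = do.call(rbind, tabs), boundaries = do.call(rbind, bounds))
}

# ---- toy-model conveniences -------------------------------------------------

#' Quadrature moment engine for the toy network
#'
#' Returns an engine closure for [solve_at()] that computes exact moments by
#' the toy quadrature instead of EP. With no inhibiting metabolites in the toy
#' toxicity model, K = 1 and beta' = beta.
#'
#' @param params a [toy_params()].
#' @return function(polytope, beta_prime) -> [moment_result()].
#' @export
toy_quadrature_engine <- function(params = toy_params()) {
  function(P, bp) toy_moments(P$xi, bp, params)
}

#' Toy chemostat solved by exact quadrature
#'
#' @param xi gDW.h/L.
#' @param beta heterogeneity (h; Inf for the homogeneous/FBA limit). Equal to
#'   beta' here because the toy toxicity is purely additive (K = 1).
#' @param params a [toy_params()].
#' @return a [steady_state()].
#' @export
toy_solve_at <- function(xi, beta, params = toy_params()) {
  st <- solve_at(xi, beta, toy_network(params), toy_medium(params),
                 toy_toxicity(params), engine = toy_quadrature_engine(params))
  st$beta <- beta
  st
}

#' Toy steady-state sweep by exact quadrature
#'
#' @param xi_grid strictly increasing xi values.
#' @param beta_list heterogeneity values (h; Inf allowed).
#' @param params a [toy_params()].
#' @return a `sweep_result` (see [chemostat_sweep()]).
#' @export
toy_sweep <- function(xi_grid, beta_list, params = toy_params()) {
  chemostat_sweep(xi_grid, beta_list, toy_network(params), toy_medium(params),
                  toy_toxicity(params),
                  engine = toy_quadrature_engine(params))
}

#' Toy medium depth at fixed beta
#'
#' @inheritParams toy_solve_at
#' @param xi_range,rel_tol passed to [medium_depth()].
#' @return xi_m (gDW.h/L).
#' @export
toy_medium_depth <- function(beta, params = toy_params(),
                             xi_range = c(1e-2, 5e3), rel_tol = 1e-6) {
  medium_depth(function(xi) {
    st <- toy_solve_at(xi, beta, params)
    st$D
  }, xi_range = xi_range, rel_tol = rel_tol)
}
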