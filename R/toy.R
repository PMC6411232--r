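#' Parameters of the exactly solvable overflow-metabolism network
#'
#' A minimal network capturing the switch from oxidative to fermentative
#' metabolism: glucose consumed at rate v_g yields an intermediate that is
#' either respired (v_o, capped by mitochondrial capacity R) or excreted as
#' lactate (-v_l), with ATP synthesized at v_atp = 2 v_g + 18 v_o. Biomass
#' synthesis is z = (v_atp - e)/y. Secreted lactate is toxic with a linear
#' death rate sigma = tau * w.
#'
#' Defaults are literature-calibrated mammalian-cell values: V_g = 0.5 and
#' R = 0.45 mmol/gDW/h, maintenance e = 1 mmol/gDW/h, yield y = 348 mmol/gDW
#' (calibrated so the maximum growth rate is about 1/day), tau = 0.0022
#' 1/h/mM and feed glucose c_g = 15 mM.
#'
#' @param V_g maximal glucose uptake (mmol/gDW/h).
#' @param R respiratory (oxidative phosphorylation) capacity (mmol/gDW/h).
#' @param e ATP maintenance demand (mmol/gDW/h).
#' @param y biomass yield on ATP (mmol/gDW).
#' @param tau death rate per unit lactate (1/h/mM).
#' @param c_g feed glucose concentration (mM).
#' @return a `toy_params` list with derived element `lambda_m`, the maximum
#'   growth rate at xi = 0 in the homogeneous limit.
#' @export
toy_params <- function(V_g = 0.5, R = 0.45, e = 1, y = 348,
                       tau = 0.0022, c_g = 15) {
  stopifnot(V_g >= 0, R >= 0, e >= 0, y > 0, tau >= 0, c_g >= 0)
  p <- list(V_g = V_g, R = R, e = e, y = y, tau = tau, c_g = c_g)
  p$lambda_m <- (2 * V_g + 18 * min(R, 2 * V_g) - e) / y
  structure(p, class = "toy_params")
}

#' The toy network as a `metabolic_network`
#'
#' Encodes the balances 2 v_g + v_l - v_o = 0 (intermediate) and
#' 2 v_g + 18 v_o = v_atp (ATP), with v_l <= 0 (lactate excretion only),
#' 0 <= v_o <= R, and glucose/lactate as exchanges. The uptake cap
#' v_g <= min(V_g, c_g/xi) is applied at polytope build time through the
#' medium.
#'
#' @param params a [toy_params()] object.
#' @return an (unsplit) `metabolic_network`.
#' @export
toy_network <- function(params = toy_params()) {
  mets <- c("glc", "lac", "intermediate", "atp")
  rxns <- c("v_g", "v_l", "v_o", "v_atp")
  S <- matrix(0, 4, 4, dimnames = list(mets, rxns))
  S["glc", "v_g"] <- -1; S["intermediate", "v_g"] <- 2; S["atp", "v_g"] <- 2
  S["lac", "v_l"] <- -1; S["intermediate", "v_l"] <- 1
  S["intermediate", "v_o"] <- -1; S["atp", "v_o"] <- 18
  S["atp", "v_atp"] <- -1
  metabolic_network(
    metabolite_ids = mets, reaction_ids = rxns, stoich = S,
    lb = c(0, -Inf, 0, 0), ub = c(params$V_g, 0, params$R, Inf),
    exchange_ids = c("glc", "lac"),
    excretable = c(glc = FALSE, lac = TRUE),
    biomass = list(kind = "affine", weights = c(v_atp = 1),
                   e = params$e, y = params$y))
}

#' Medium and toxicity companions of the toy network
#' @param params a [toy_params()] object.
#' @return [toy_medium()]: a [medium()]; [toy_toxicity()]: a [toxicity_model()].
#' @export
toy_medium <- function(params = toy_params()) {
  medium(c("glc", "lac"), conc = c(params$c_g, 0), vmax = c(params$V_g, 0))
}

#' @rdname toy_medium
#' @export
toy_toxicity <- function(params = toy_params()) {
  toxicity_model(tau = c(lac = params$tau))
}

#' Closed-form FBA vertex of the toy model
#'
#' The growth-maximizing (beta = Inf) flux vector: glucose uptake saturates
#' its bound U = min(V_g, c_g/xi), respiration takes min(R, 2U), the excess
#' intermediate is excreted as lactate.
#'
#' @param xi gDW.h/L (>= 0).
#' @param params a [toy_params()].
#' @return named vector (v_g, v_o, v_l, v_atp, z).
#' @export
toy_fba_vertex <- function(xi, params = toy_params()) {
  stopifnot(xi >= 0)
  U <- uptake_bound(params$c_g, params$V_g, xi)
  v_g <- U
  v_o <- min(params$R, 2 * U)
  v_l <- v_o - 2 * U
  v_atp <- 2 * U + 18 * v_o
  c(v_g = v_g, v_o = v_o, v_l = v_l, v_atp = v_atp,
    z = (v_atp - params$e) / params$y)
}

# integral J_q(delta, b) = int_0^delta s^q e^(b s) ds, stable for small b*delta
int_exp_poly <- function(q, delta, b) {
  if (delta <= 0) return(0)
  x <- b * delta
  if (abs(x) < 1e-4) {
    # series: sum_k b^k delta^(q+k+1) / (k! (q+k+1))
    term <- delta^(q + 1) / (q + 1)
    tot <- term
    bk <- 1
    for (k in 1:12) {
      bk <- bk * b / k
      term <- bk * delta^(q + k + 1) / (q + k + 1)
      tot <- tot + term
      if (abs(term) < 1e-17 * abs(tot)) break
    }
    return(tot)
  }
  ebd <- exp(x)
  J0 <- expm1(x) / b
  if (q == 0) return(J0)
  J1 <- (delta * ebd - J0) / b
  if (q == 1) return(J1)
  (delta^2 * ebd - 2 * J1) / b
}

# int_{t0}^{t1} t^q e^{b (t - A)} dt via binomial shift to J integrals,
# anchored at the upper limit so exp() never overflows for large b (t1 <= A
# on the toy polytope, hence the prefactor is <= 1)
int_tq <- function(q, t0, t1, b, A) {
  if (t1 <= t0) return(0)
  delta <- t1 - t0
  pre <- exp(b * (t1 - A))
  tot <- 0
  for (j in 0:q)
    tot <- tot + choose(q, j) * t1^(q - j) * (-1)^j * int_exp_poly(j, delta, -b)
  pre * tot
}

#' Exact moments of the tilted distribution on the toy polytope
#'
#' The maximum-entropy density P(v_atp, v_g) proportional to
#' exp(+beta v_atp / y) on the two-dimensional region
#' \{0 <= v_g <= U, 2 v_g <= v_atp <= min(38 v_g, 2 v_g + 18 R)\},
#' U = min(V_g, c_g/xi). The inner integral over v_atp is analytic; the outer
#' integral over v_g is adaptive quadrature split at the respiration kink
#' v_g = R/2 and (for large beta) at the exponential boundary layer near
#' v_g = U, achieving near machine precision. At beta = Inf the FBA vertex is
#' returned with zero variances.
#'
#' Note the sign convention: the tilt rewards high ATP synthesis, consistent
#' with the maximum-entropy statement P proportional to exp(beta' z); additive
#' constants (maintenance, death rate) cancel upon normalization.
#'
#' @param xi gDW.h/L (>= 0).
#' @param beta heterogeneity parameter in h (>= 0, or Inf for the
#'   homogeneous/FBA limit).
#' @param params a [toy_params()].
#' @param rel_tol relative tolerance of the outer quadrature.
#' @return a [moment_result()] over (v_g, v_o, v_l, v_atp), with `logZ`
#'   and net-uptake means (glc, lac).
#' @export
toy_moments <- function(xi, beta, params = toy_params(), rel_tol = 1e-10) {
  stopifnot(xi >= 0, beta >= 0)
  U <- uptake_bound(params$c_g, params$V_g, xi)
  nm <- c("v_g", "v_o", "v_l", "v_atp")
  point_result <- function(v, method) {
    moment_result(mean = v[nm], var = setNames(numeric(4), nm),
                  z_mean = v[["z"]], z_var = 0, logZ = NA_real_,
                  method = method,
                  u_mean = c(glc = v[["v_g"]], lac = v[["v_l"]]))
  }
  if (is.infinite(beta)) return(point_result(toy_fba_vertex(xi, params), "fba"))
  if (U <= 0 || params$R < 0) {
    v <- c(v_g = 0, v_o = 0, v_l = 0, v_atp = 0, z = -params$e / params$y)
    return(point_result(v, "point"))
  }
  R <- params$R
  b <- beta / params$y
  Tfun_hi <- function(x) pmin(38 * x, 2 * x + 18 * R)
  A <- Tfun_hi(U)

  inner <- function(q) function(x) {
    vapply(x, function(xx) int_tq(q, 2 * xx, Tfun_hi(xx), b, A), numeric(1))
  }
  # breakpoints: respiration kink, and boundary-layer scales near x = U
  brk <- c(0, min(U, R / 2), U)
  if (b * 38 * U > 30) {
    sc <- U - c(1, 3, 10, 30, 100, 300) / (38 * b)
    brk <- c(brk, sc[sc > 0 & sc < U])
  }
  brk <- sort(unique(pmin(pmax(brk, 0), U)))
  quad <- function(f) {
    tot <- 0
    for (i in seq_len(length(brk) - 1)) {
      width <- brk[i + 1] - brk[i]
      if (width < 1e-300) next
      # at large beta the integrand underflows to zero left of the boundary
      # layer; skip pieces whose whole mass is below double precision
      cap <- exp(b * (Tfun_hi(brk[i + 1]) - A))
      if (cap * width * (1 + A)^2 < 1e-280) next
      tot <- tot + integrate(f, brk[i], brk[i + 1], rel.tol = rel_tol,
                             abs.tol = 0, subdivisions = 500L)$value
    }
    tot
  }
  f_pq <- function(p, q) {
    g <- inner(q)
    function(x) x^p * g(x)
  }
  M00 <- quad(f_pq(0, 0))
  if (!is.finite(M00) || M00 <= 0)
    return(moment_result(mean = setNames(rep(NA_real_, 4), nm),
                         var = setNames(numeric(4), nm),
                         z_mean = NA_real_, z_var = NA_real_,
                         method = "quadrature", converged = FALSE))
  M10 <- quad(f_pq(1, 0)); M01 <- quad(f_pq(0, 1))
  M20 <- quad(f_pq(2, 0)); M02 <- quad(f_pq(0, 2)); M11 <- quad(f_pq(1, 1))
  mx <- M10 / M00; mt <- M01 / M00
  vx <- max(M20 / M00 - mx^2, 0)
  vt <- max(M02 / M00 - mt^2, 0)
  cxt <- M11 / M00 - mx * mt

  mean_v <- c(v_g = mx, v_o = (mt - 2 * mx) / 18, v_l = (mt - 38 * mx) / 18,
              v_atp = mt)
  var_v <- c(v_g = vx,
             v_o = (4 * vx + vt - 4 * cxt) / 324,
             v_l = (38^2 * vx + vt - 2 * 38 * cxt) / 324,
             v_atp = vt)
  moment_result(mean = mean_v, var = pmax(var_v, 0),
                z_mean = (mt - params$e) / params$y,
                z_var = vt / params$y^2,
                logZ = log(M00) + b * A,
                method = "quadrature",
                u_mean = c(glc = mx, lac = (mt - 38 * mx) / 18))
}

#' Medium depth of the toy model in the homogeneous (beta = Inf) limit
#'
#' The largest xi with a non-negative net growth rate along the FBA branch.
#' For the default parameters lactate secretion has ceased in that regime, so
#' the closed form xi_m = 38 c_g / e applies; the general case is solved by
#' scanning the FBA chain D(xi) = z(xi) - tau * w(xi) on a log grid and
#' bisecting at the largest sign change.
#'
#' @param params a [toy_params()].
#' @param xi_max upper end of the search range.
#' @return xi_m in gDW.h/L; `Inf` (with attribute `open_ended = TRUE`) when
#'   maintenance e = 0 and D never becomes negative.
#' @export
toy_medium_depth_fba <- function(params = toy_params(), xi_max = 1e9) {
  D_of <- function(xi) {
    v <- toy_fba_vertex(xi, params)
    s_w <- max(0, -v[["v_l"]]) * xi
    v[["z"]] - params$tau * s_w
  }
  if (params$e == 0) {
    # z > 0 whenever any glucose can be taken up and z -> 0+ as xi -> Inf
    if (D_of(xi_max) >= 0) return(structure(Inf, open_ended = TRUE))
  }
  xs <- exp(seq(log(1e-6), log(xi_max), length.out = 6000))
  Ds <- vapply(xs, D_of, numeric(1))
  pos <- which(Ds >= 0)
  if (!length(pos)) return(0)
  i <- max(pos)
  if (i == length(xs)) return(structure(Inf, open_ended = TRUE))
  lo <- xs[i]; hi <- xs[i + 1]
  for (it in 1:200) {
    mid <- 0.5 * (lo + hi)
    if (D_of(mid) >= 0) lo <- mid else hi <- mid
    if ((hi - lo) <= 1e-12 * hi) break
  }
  0.5 * (lo + hi)
}
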