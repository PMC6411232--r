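# Expectation Propagation on box-constrained flux polytopes.
#
# The target P(v) proportional to exp(beta' z(v)) * 1[l <= v <= u] on the
# affine set {E v = d} is approximated by a Gaussian whose univariate
# marginals are iteratively moment-matched against their box-truncated
# versions. z is affine in v, so the tilt is absorbed exactly as a linear
# exponent and introduces no moment-matching error of its own. Equalities are
# eliminated exactly by a null-space parametrization (no soft-delta
# regularizer), so the Gaussian algebra stays well conditioned.

#' Scaled complementary error function erfcx(x) = exp(x^2) erfc(x)
#'
#' Numerically stable for large positive x (no underflow/overflow); used by
#' the truncated-normal moment kernel in far-tail regimes.
#' @param x numeric vector.
#' @return erfcx(x).
#' @export
erfcx <- function(x) {
  out <- numeric(length(x))
  neg <- x < 0
  # erfcx(-x) = 2 exp(x^2) - erfcx(x); overflows for very negative x, as it must
  if (any(neg)) out[neg] <- 2 * exp(x[neg]^2) - erfcx(-x[neg])
  pos <- !neg
  if (any(pos)) {
    xp <- x[pos]
    res <- numeric(length(xp))
    small <- xp < 10
    if (any(small)) {
      xs <- xp[small]
      res[small] <- exp(xs^2 + log(2) +
                          pnorm(xs * sqrt(2), lower.tail = FALSE, log.p = TRUE))
    }
    if (any(!small)) {
      xl <- xp[!small]
      # asymptotic series 1/(x sqrt(pi)) sum (-1)^k (2k-1)!! / (2x^2)^k
      inv2x2 <- 1 / (2 * xl^2)
      s <- rep(1, length(xl)); term <- rep(1, length(xl))
      for (k in 1:10) {
        term <- term * -(2 * k - 1) * inv2x2
        s <- s + term
      }
      res[!small] <- s / (xl * sqrt(pi))
    }
    out[pos] <- res
  }
  out
}

#' First two moments of a truncated Gaussian
#'
#' Exact mean and variance of N(mu, s2) truncated to \[a, b\] (either bound
#' may be infinite), computed through scaled complementary error functions so
#' far-tail truncations (the workhorse regime of EP on tight polytopes) do not
#' lose precision to cancellation.
#'
#' @param mu,s2 mean and variance of the parent Gaussian (s2 > 0).
#' @param a,b truncation bounds, a < b.
#' @return `c(mean, var)`.
#' @export
truncnorm_moments <- function(mu, s2, a, b) {
  if (!(a < b)) stop2("truncation requires a < b")
  if (!(s2 > 0)) stop2("variance must be positive")
  if (a == -Inf && b == Inf) return(c(mean = mu, var = s2))
  s <- sqrt(s2)
  al <- (a - mu) / s; be <- (b - mu) / s
  if (is.finite(al) && is.finite(be) && (be - al) < 1e-8) {
    # vanishing interval: uniform limit
    return(c(mean = 0.5 * (a + b), var = (b - a)^2 / 12))
  }
  flip <- FALSE
  if (is.finite(be) && be <= 0 || (!is.finite(al) && is.finite(be))) {
    # mirror so the truncation lies in the right tail / central region
    tmp <- al; al <- -be; be <- -tmp
    flip <- TRUE
  }
  if (al >= 0) {
    # right-tail regime: work with scaled ratios, Delta <= 1 by construction
    Delta <- if (is.finite(be)) exp((al^2 - be^2) / 2) else 0
    W <- sqrt(pi / 2) * (erfcx(al / sqrt(2)) -
                           if (is.finite(be)) Delta * erfcx(be / sqrt(2)) else 0)
    h1 <- (1 - Delta) / W
    h2 <- (al - if (is.finite(be)) be * Delta else 0) / W
    m <- h1
    v <- 1 + h2 - h1^2
  } else {
    # central regime: direct formulas are safe
    Z <- pnorm(be) - pnorm(al)
    pa <- dnorm(al); pb <- if (is.finite(be)) dnorm(be) else 0
    h1 <- (pa - pb) / Z
    apa <- if (is.finite(al)) al * pa else 0
    bpb <- if (is.finite(be)) be * pb else 0
    m <- h1
    v <- 1 + (apa - bpb) / Z - h1^2
  }
  if (flip) m <- -m
  c(mean = mu + s * m, var = max(s2 * v, 0))
}

# moments of the density proportional to exp(eta * y) on [a, b] (finite):
# the flat-cavity limit of the truncated Gaussian.
texp_moments <- function(eta, a, b) {
  d <- b - a
  t <- eta * d
  if (abs(t) < 1e-8)
    return(c(mean = 0.5 * (a + b) + eta * d^2 / 12, var = d^2 / 12))
  if (t > 0) {
    m0 <- if (t > 40) d - 1 / eta else d / (1 - exp(-t)) - 1 / eta
    m <- a + m0
  } else {
    m0 <- if (t < -40) -1 / eta else d / (1 - exp(-t)) - 1 / eta
    m <- a + m0
  }
  v <- if (abs(t) > 40) 1 / eta^2 else 1 / eta^2 - d^2 / (4 * sinh(t / 2)^2)
  c(mean = m, var = max(v, 0))
}

#' Options for the Expectation Propagation engine
#'
#' @param damping retained fraction of the old site parameters per update
#'   (in \[0, 1)); heavier damping is slower but more robust.
#' @param tol convergence tolerance on the maximum absolute change of the
#'   tilted means and variances (in scaled \[0, 1\] units).
#' @param max_iter maximum number of sweeps.
#' @param var_min,var_max clipping range for tilted variances.
#' @return an `ep_options` list.
#' @export
ep_options <- function(damping = 0.9, tol = 1e-6, max_iter = 2000L,
                       var_min = 1e-50, var_max = 1e50) {
  stopifnot(damping >= 0, damping < 1, tol > 0, max_iter >= 1)
  structure(list(damping = damping, tol = tol, max_iter = as.integer(max_iter),
                 var_min = var_min, var_max = var_max), class = "ep_options")
}

#' Expectation Propagation moments on a flux polytope
#'
#' Approximates the marginals and the moments of z under
#' P(v) proportional to exp(beta' z(v)) on the polytope. All variables must be
#' (or become, via [box_polytope()]) finitely boxed. Variables are rescaled to
#' \[0, 1\] by their bound widths; sites are updated sequentially in fixed
#' variable order, so the algorithm is fully deterministic.
#'
#' @param polytope a [flux_polytope].
#' @param beta_prime effective tilt beta' (h, >= 0, finite).
#' @param options an [ep_options()] list.
#' @return a [moment_result()]; `converged = FALSE` flags non-convergence
#'   within `max_iter` (downstream consumers must refuse such results).
#' @export
ep_moments <- function(polytope, beta_prime = 0, options = ep_options()) {
  stopifnot(beta_prime >= 0, is.finite(beta_prime))
  P <- polytope
  if (any(!is.finite(P$u)) || any(!is.finite(P$l))) P <- box_polytope(P)
  nv <- length(P$l)
  width <- P$u - P$l
  fixed <- which(width < .tol)
  free <- setdiff(seq_len(nv), fixed)
  nf <- length(free)
  d <- P$d
  if (nrow(P$E)) {
    if (length(fixed))
      d <- d - as.numeric(P$E[, fixed, drop = FALSE] %*% P$l[fixed])
    d <- d - as.numeric(P$E[, free, drop = FALSE] %*% P$l[free])
  }
  sfree <- width[free]
  Es <- if (nrow(P$E)) P$E[, free, drop = FALSE] %*% diag(sfree, nf) else
    matrix(0, 0, nf)

  finish <- function(mean_y, var_y, Sig_y, converged, iters, err) {
    mean_v <- setNames(numeric(nv), P$var_names)
    var_v <- setNames(numeric(nv), P$var_names)
    mean_v[fixed] <- P$l[fixed]
    mean_v[free] <- P$l[free] + sfree * mean_y
    var_v[free] <- sfree^2 * var_y
    z_mean <- sum(P$w * mean_v) + P$z0
    ws <- P$w[free] * sfree
    z_var <- if (!is.null(Sig_y)) as.numeric(ws %*% Sig_y %*% ws) else 0
    moment_result(mean = mean_v, var = var_v, z_mean = z_mean,
                  z_var = max(z_var, 0), method = "ep",
                  converged = converged, iterations = iters,
                  error_est = err,
                  u_mean = moments_net_uptake(P, mean_v))
  }
  if (nf == 0) {
    resid <- if (nrow(P$E)) max(abs(as.numeric(P$E %*% P$l) - P$d)) else 0
    if (resid > 1e-6) stop2("infeasible equality system (fully fixed polytope)")
    return(finish(numeric(0), numeric(0), NULL, TRUE, 0L, 0))
  }
  # null space of the scaled equalities
  if (nrow(Es)) {
    sv <- svd(Es, nu = nrow(Es), nv = nf)
    rk <- sum(sv$d > 1e-10 * max(sv$d, 1))
    B <- if (rk < nf) sv$v[, (rk + 1):nf, drop = FALSE] else matrix(0, nf, 0)
    y0 <- if (rk > 0)
      as.numeric(sv$v[, seq_len(rk), drop = FALSE] %*%
                   ((t(sv$u[, seq_len(rk), drop = FALSE]) %*% d) / sv$d[seq_len(rk)]))
    else numeric(nf)
    if (sqrt(sum((as.numeric(Es %*% y0) - d)^2)) > 1e-6 * max(1, max(abs(d))))
      stop2("infeasible equality system")
  } else {
    B <- diag(nf); y0 <- numeric(nf)
  }
  k <- ncol(B)
  if (k == 0) {
    ok <- all(y0 > -1e-7) && all(y0 < 1 + 1e-7)
    if (!ok) stop2("infeasible equality system (point outside box)")
    return(finish(pmin(pmax(y0, 0), 1), numeric(nf), NULL, TRUE, 0L, 0))
  }

  g <- beta_prime * (P$w[free] * sfree)   # exact linear tilt, in y units
  a_site <- rep(1, nf)
  h_site <- rep(0.5, nf)
  tm <- rep(0.5, nf); tv <- rep(1 / 12, nf)
  dm <- options$damping
  err <- Inf
  iters <- 0L
  gauss <- function() {
    Pt <- crossprod(B, a_site * B)
    bt <- as.numeric(crossprod(B, h_site + g - a_site * y0))
    Sig_t <- tryCatch(chol2inv(chol(Pt)),
                      error = function(e) solve(Pt + diag(1e-12, k)))
    mu_t <- as.numeric(Sig_t %*% bt)
    list(Sig = Sig_t, mu = mu_t)
  }
  for (it in seq_len(options$max_iter)) {
    iters <- it
    tm_old <- tm; tv_old <- tv
    for (n in seq_len(nf)) {
      gs <- gauss()
      m_n <- y0[n] + sum(B[n, ] * gs$mu)
      q_n <- as.numeric(B[n, , drop = FALSE] %*% gs$Sig %*% B[n, ])
      q_n <- max(q_n, 1e-300)
      prec_c <- 1 / q_n - a_site[n]
      lin_c <- m_n / q_n - h_site[n]
      mo <- if (prec_c < 1e-12) texp_moments(lin_c, 0, 1) else
        truncnorm_moments(lin_c / prec_c, 1 / prec_c, 0, 1)
      tmn <- mo[[1]]
      tvn <- min(max(mo[[2]], options$var_min), options$var_max)
      a_new <- 1 / tvn - max(prec_c, 0)
      h_new <- tmn / tvn - lin_c
      if (!is.finite(a_new) || a_new < 1e-12) {
        a_new <- 1e-12
        h_new <- tmn * a_new
      }
      a_site[n] <- dm * a_site[n] + (1 - dm) * a_new
      h_site[n] <- dm * h_site[n] + (1 - dm) * h_new
      tm[n] <- tmn; tv[n] <- tvn
    }
    err <- max(abs(tm - tm_old), abs(tv - tv_old))
    if (err < options$tol) break
  }
  gs <- gauss()
  Sig_y <- B %*% gs$Sig %*% t(B)
  finish(tm, tv, Sig_y, err < options$tol, iters, err)
}
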