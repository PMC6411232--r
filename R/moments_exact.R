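# Brute-force oracles for moments of the tilted distribution on small
# polytopes. Not intended for genome-scale networks (the acceptance rate of
# box rejection collapses with dimension); these exist to validate the
# quadrature and EP engines on fixtures.

#' Rejection sampling from the tilted distribution on a polytope
#'
#' Draws i.i.d. samples from P(v) proportional to exp(beta' z(v)) restricted
#' to the polytope. Equality constraints are eliminated once by an affine
#' null-space parametrization; proposals are uniform in the bounding box of
#' the reduced coordinates, accepted on the bound constraints, and thinned by
#' an exponential accept on the tilt (using the polytope's maximal z so the
#' acceptance probability is <= 1).
#'
#' @param polytope a [flux_polytope] with bounded variables (use
#'   [box_polytope()] first if needed).
#' @param beta_prime effective tilt (h, >= 0, finite).
#' @param n number of samples (>= 1).
#' @param seed integer seed; the caller's RNG state is left untouched.
#' @param accept_floor minimal tolerated acceptance rate; below it the
#'   sampler aborts and advises quadrature.
#' @return an `n` x n_vars matrix with variable names as columns and
#'   attributes `seed` and `acceptance_rate`.
#' @export
rejection_sample <- function(polytope, beta_prime = 0, n = 1e5, seed = 1,
                             accept_floor = 1e-4) {
  stopifnot(n >= 1, beta_prime >= 0, is.finite(beta_prime))
  P <- polytope
  if (any(!is.finite(P$u)) || any(!is.finite(P$l))) P <- box_polytope(P)
  if (polytope_is_empty(P)) stop2("polytope is empty")
  ns <- polytope_nullspace(P)
  nv <- length(P$l)
  full <- matrix(NA_real_, n, nv, dimnames = list(NULL, P$var_names))
  if (length(ns$fixed))
    full[, ns$fixed] <- matrix(ns$fixed_val, n, length(ns$fixed), byrow = TRUE)
  if (ns$k == 0) {
    full[, ns$free] <- matrix(ns$x0, n, length(ns$free), byrow = TRUE)
    attr(full, "seed") <- seed; attr(full, "acceptance_rate") <- 1
    return(full)
  }
  # bounding box of the reduced coordinates t_j = B_j' (v_free - x0), by LP
  tlo <- thi <- numeric(ns$k)
  for (j in seq_len(ns$k)) {
    obj <- numeric(nv); obj[ns$free] <- ns$B[, j]
    off <- sum(ns$B[, j] * ns$x0)
    lo <- lp_over_polytope(P, obj, maximize = FALSE)
    hi <- lp_over_polytope(P, obj, maximize = TRUE)
    if (lo$status != "optimal" || hi$status != "optimal")
      stop2("failed to bound reduced coordinate ", j)
    tlo[j] <- lo$obj - off; thi[j] <- hi$obj - off
  }
  zmax <- if (beta_prime > 0) {
    sol <- lp_over_polytope(P, P$w, maximize = TRUE)
    if (sol$status != "optimal") stop2("cannot bound z for tilted sampling")
    sol$obj + P$z0
  } else NA_real_
  lf <- P$l[ns$free]; uf <- P$u[ns$free]
  wf <- P$w[ns$free]
  z_fixed <- if (length(ns$fixed)) sum(P$w[ns$fixed] * ns$fixed_val) else 0

  got <- 0L; tried <- 0L
  out_free <- matrix(NA_real_, n, length(ns$free))
  with_seed(seed, function() {
    batch <- max(2048L, min(65536L, as.integer(n)))
    while (got < n) {
      Tm <- matrix(runif(batch * ns$k, rep(tlo, each = batch),
                         rep(thi, each = batch)), batch, ns$k)
      V <- matrix(ns$x0, batch, length(ns$free), byrow = TRUE) +
        Tm %*% t(ns$B)
      ok <- rowSums(V < rep(lf - 1e-9, each = batch) |
                    V > rep(uf + 1e-9, each = batch)) == 0
      if (beta_prime > 0 && any(ok)) {
        z <- as.numeric(V[ok, , drop = FALSE] %*% wf) + z_fixed + P$z0
        keep <- runif(sum(ok)) < exp(beta_prime * (z - zmax))
        idx <- which(ok); ok[idx[!keep]] <- FALSE
      }
      tried <<- tried + batch
      nk <- sum(ok)
      if (nk) {
        take <- min(nk, n - got)
        out_free[got + seq_len(take), ] <<-
          V[which(ok)[seq_len(take)], , drop = FALSE]
        got <<- got + take
      }
      if (tried >= 2e5 && got / tried < accept_floor)
        stop2("rejection acceptance rate ", signif(got / tried, 2),
              " below floor; use quadrature or EP instead")
    }
  })
  full[, ns$free] <- out_free
  attr(full, "seed") <- seed
  attr(full, "acceptance_rate") <- got / tried
  full
}

#' Weighted sample moments
#'
#' @param samples matrix of samples (columns = variables).
#' @param weights optional non-negative weights.
#' @param polytope optional [flux_polytope]; when given, moments of z and
#'   net-uptake means are included.
#' @return a [moment_result()] with standard-error estimates in `error_est`.
#' @export
sample_moments <- function(samples, weights = NULL, polytope = NULL) {
  samples <- as.matrix(samples)
  n <- nrow(samples)
  if (n < 2) stop2("need at least 2 samples")
  w <- weights %||% rep(1, n)
  if (length(w) != n || any(w < 0) || !any(w > 0) || any(!is.finite(w)))
    stop2("degenerate weights")
  w <- w / sum(w)
  neff <- 1 / sum(w^2)
  mu <- as.numeric(crossprod(w, samples))
  cent <- sweep(samples, 2, mu)
  v <- as.numeric(crossprod(w, cent^2)) * neff / max(neff - 1, 1)
  se <- sqrt(v / neff)
  names(mu) <- names(v) <- names(se) <- colnames(samples)
  z_mean <- z_var <- NA_real_
  u_mean <- NULL
  if (!is.null(polytope)) {
    zs <- as.numeric(samples[, polytope$var_names, drop = FALSE] %*%
                       polytope$w) + polytope$z0
    z_mean <- sum(w * zs)
    z_var <- sum(w * (zs - z_mean)^2) * neff / max(neff - 1, 1)
    u_mean <- moments_net_uptake(polytope, mu)
  }
  moment_result(mean = mu, var = v, z_mean = z_mean, z_var = z_var,
                method = "rejection", iterations = n,
                error_est = se, u_mean = u_mean)
}

#' One-call sampling oracle
#'
#' Convenience wrapper: [rejection_sample()] then [sample_moments()].
#' @inheritParams rejection_sample
#' @return a [moment_result()].
#' @export
exact_moments <- function(polytope, beta_prime = 0, n = 1e5, seed = 1) {
  s <- rejection_sample(polytope, beta_prime, n, seed)
  sample_moments(s, polytope = polytope)
}
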