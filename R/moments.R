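#' Moment result container
#'
#' Means and variances of fluxes and of the growth functional z under the
#' tilted maximum-entropy distribution, with convergence metadata. A result
#' whose `converged` flag is `FALSE` must be refused by downstream consumers
#' (the chemostat solver flags the steady state rather than using it).
#'
#' @param mean,var named vectors over variables (flux units, squared).
#' @param z_mean,z_var moments of z (1/h, 1/h^2).
#' @param logZ log-partition value when available.
#' @param method one of "quadrature", "rejection", "ep", "fba", "point".
#' @param converged logical.
#' @param iterations iteration or sample count.
#' @param error_est optional error estimate (standard errors or max change).
#' @param u_mean optional named net-uptake means per exchange metabolite.
#' @return an object of class `moment_result`.
#' @export
moment_result <- function(mean, var, z_mean, z_var, logZ = NA_real_,
                          method, converged = TRUE, iterations = NA_integer_,
                          error_est = NULL, u_mean = NULL) {
  if (any(var < -.tol)) stop2("negative variance in moment result")
  var <- pmax(var, 0)
  structure(list(mean = mean, var = var, z_mean = z_mean, z_var = z_var,
                 logZ = logZ, method = method, converged = converged,
                 iterations = iterations, error_est = error_est,
                 u_mean = u_mean),
            class = "moment_result")
}

#' @export
print.moment_result <- function(x, ...) {
  cat(sprintf("<moment_result> method=%s converged=%s <z>=%.6g Var(z)=%.3g\n",
              x$method, x$converged, x$z_mean, x$z_var))
  invisible(x)
}

# Map variable-level moments of a polytope to net uptakes per exchange.
moments_net_uptake <- function(polytope, mean) {
  exch <- polytope$provenance$exchanges
  if (is.null(exch)) return(NULL)
  out <- setNames(numeric(nrow(exch)), exch$met)
  for (i in seq_len(nrow(exch))) {
    upt <- mean[[exch$upt[i]]]
    exc <- if (!is.na(exch$exc[i])) mean[[exch$exc[i]]] else 0
    out[i] <- upt - exc
  }
  out
}
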