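# Independent oracles used to cross-check the package's solver and
# marginal-likelihood approximation. These deliberately avoid the package's
# own computational paths: the ODE oracle integrates the differential
# equations with deSolve's adaptive lsoda, and the quadrature oracle
# computes the marginal integral with adaptive Gauss-Hermite quadrature
# whose nodes come from the Golub-Welsch eigendecomposition.

# Gauss-Hermite nodes/weights (physicists' convention, weight exp(-x^2)).
gauss_hermite <- function(n) {
  J <- matrix(0, n, n)
  off <- sqrt(seq_len(n - 1) / 2)
  J[cbind(1:(n - 1), 2:n)] <- off
  J[cbind(2:n, 1:(n - 1))] <- off
  e <- eigen(J, symmetric = TRUE)
  list(nodes = e$values, weights = sqrt(pi) * e$vectors[1, ]^2)
}

# -2 log marginal likelihood of a one-free-eta subject by adaptive
# Gauss-Hermite quadrature: the joint density is evaluated on a grid
# centered at the conditional mode and scaled by the curvature there.
# `joint_fun(eta_scalar)` must return the joint log-density (data + prior).
quadrature_ofv_1d <- function(joint_fun, n_nodes = 64) {
  opt <- optimize(function(e) -joint_fun(e), c(-6, 6))
  m <- opt$minimum
  h <- 1e-4
  H <- -(joint_fun(m + h) - 2 * joint_fun(m) + joint_fun(m - h)) / h^2
  s <- 1 / sqrt(max(H, 1e-8))
  gh <- gauss_hermite(n_nodes)
  eta <- m + sqrt(2) * s * gh$nodes
  lw <- log(gh$weights) + gh$nodes^2 + vapply(eta, joint_fun, numeric(1)) +
    log(sqrt(2) * s)
  M <- max(lw)
  -2 * (M + log(sum(exp(lw - M))))
}

# Laplacian OFV versus the quadrature oracle for a single-subject,
# single-free-eta configuration (the other three IIV variances are pinned
# near zero so the marginal integral is one-dimensional). The data
# likelihood here is recomputed from dnorm/pnorm directly, independent of
# the compiled likelihood path.
laplace_quadrature_case <- function(times, dv_ars, dv_dha, bql, free, om) {
  m <- final_model()
  cov <- list(wt = 52, preg = 0, alt = 20.75, lnpc = 5.88)
  s <- sqrt(unname(m$sigma))
  ds <- tiny_dataset(times = times, dv_ars = dv_ars, dv_dha = dv_dha,
                     bql_ars = bql)
  m1 <- m
  m1$omega[] <- 1e-10
  m1$omega[free] <- om
  lap <- laplacian_ofv(ds, m1)
  data_ll <- function(e) {
    eta <- rep(0, 4)
    eta[free] <- e
    ind <- individual_parameters(m1, cov, eta)
    prof <- solve_profile(ind, 200, times)
    ll <- 0
    for (j in seq_along(times)) {
      ca <- prof$conc_ars[j]
      if (!is.null(bql) && j %in% bql) {
        ll <- ll + log(pnorm((log(1.2) - log(ca)) / s[1]) + 1e-6)
      } else {
        ll <- ll + dnorm(dv_ars[j], log(ca), s[1], log = TRUE)
      }
      ll <- ll + dnorm(dv_dha[j], log(prof$conc_dha[j]), s[2], log = TRUE)
    }
    ll
  }
  joint <- function(e) data_ll(e) + dnorm(e, 0, sqrt(om), log = TRUE)
  c(laplace = lap$ofv, quadrature = quadrature_ofv_1d(joint, 64))
}

# A deterministic rich-sampling toy observation set built from the typical
# profile plus a fixed perturbation sequence.
toy_rich_obs <- function() {
  m <- final_model()
  ind <- individual_parameters(m, list(wt = 52, preg = 0, alt = 20.75,
                                       lnpc = 5.88), rep(0, 4))
  tt <- c(0.25, 0.5, 1, 2, 3, 4, 5, 6)
  pr <- solve_profile(ind, 200, tt)
  list(times = tt,
       dv_ars = log(pr$conc_ars) +
         c(0.3, -0.2, 0.1, 0.4, -0.3, 0.2, -0.1, 0.3),
       dv_dha = log(pr$conc_dha) +
         c(-0.2, 0.1, 0.3, -0.1, 0.2, -0.3, 0.1, 0.2))
}

# Concentrations by adaptive ODE integration of the transit-absorption
# system (single dose at t = 0), independent of the matrix-exponential path.
ode_profile <- function(ind, dose, times, rtol = 1e-11, atol = 1e-16) {
  nn <- ind$nn
  ktr <- ind$ktr
  k23 <- ind$clp / ind$v2
  k30 <- ind$clm / ind$v3
  ns <- nn + 4
  rhs <- function(t, y, p) {
    dy <- numeric(ns)
    dy[1] <- -ktr * y[1]
    for (j in 2:(nn + 1)) dy[j] <- ktr * y[j - 1] - ktr * y[j]
    dy[nn + 2] <- ktr * y[nn + 1] - k23 * y[nn + 2]
    dy[nn + 3] <- k23 * y[nn + 2] - k30 * y[nn + 3]
    dy[nn + 4] <- k30 * y[nn + 3]
    list(dy)
  }
  y0 <- c(ind$f1 * dose, numeric(ns - 1))
  tt <- sort(unique(c(0, times)))
  out <- deSolve::lsoda(y0, tt, rhs, parms = NULL, rtol = rtol, atol = atol)
  idx <- match(times, out[, 1])
  list(conc_ars = 1000 * out[idx, 1 + nn + 2] / ind$v2,
       conc_dha = 1000 * out[idx, 1 + nn + 3] / ind$v3,
       amounts = t(out[idx, -1, drop = FALSE]))
}
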