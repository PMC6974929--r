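test_that("record log-likelihood matches the censored and Gaussian closed forms", {
  # censored record with prediction exactly at the limit: Phi(0) + 1e-6
  ll <- record_loglikelihood(dv = NA, ipred = log(1.2), sigma2 = 0.892,
                             log_lloq = log(1.2), bql = 1)
  expect_equal(exp(ll), 0.500001)
  # prediction far above the limit: probability collapses to the 1e-6 floor
  ll_hi <- record_loglikelihood(dv = NA, ipred = 50, sigma2 = 0.892,
                                log_lloq = log(1.2), bql = 1)
  expect_equal(ll_hi, log(1e-6))
  expect_equal(record_loglikelihood(NA, 50, 0.892, log(1.2), bql = 1,
                                    blq_floor = 0), -Inf)
  # quantifiable record at its prediction: -2 ll = log(2 pi sigma2)
  ll_g <- record_loglikelihood(dv = 2.2, ipred = 2.2, sigma2 = 0.892,
                               log_lloq = log(1.2), bql = 0)
  expect_equal(-2 * ll_g, log(2 * pi * 0.892))
  expect_equal(-2 * ll_g, 1.7236, tolerance = 1e-4)
  expect_error(record_loglikelihood(1, 1, -0.1, 0), "positive")
})

test_that("subject joint log-density matches a term-by-term hand computation", {
  m <- final_model()
  ds <- tiny_dataset(times = c(1, 4), dv_ars = c(3.2, NA), dv_dha = c(5.1, 3.0),
                     bql_ars = 2)
  eta <- c(0.1, -0.2, 0.15, 0.05)
  jl <- subject_joint_loglik(ds, m, eta)
  cov <- list(wt = 52, preg = 0, alt = 20.75, lnpc = 5.88)
  ind <- individual_parameters(m, cov, eta)
  prof <- solve_profile(ind, 200, c(1, 4))
  s <- sqrt(unname(m$sigma))
  hand <- dnorm(3.2, log(prof$conc_ars[1]), s[1], log = TRUE) +
    dnorm(5.1, log(prof$conc_dha[1]), s[2], log = TRUE) +
    log(pnorm((log(1.2) - log(prof$conc_ars[2])) / s[1]) + 1e-6) +
    dnorm(3.0, log(prof$conc_dha[2]), s[2], log = TRUE) +
    sum(dnorm(eta, 0, sqrt(unname(m$omega)), log = TRUE))
  expect_equal(jl, hand, tolerance = 1e-10)
  # prior term decreases monotonically in |eta|
  jl0 <- subject_joint_loglik(ds, m, rep(0, 4))
  prior <- function(e) sum(dnorm(e, 0, sqrt(unname(m$omega)), log = TRUE))
  expect_equal(prior(rep(0, 4)),
               -0.5 * sum(log(2 * pi * unname(m$omega))))
  expect_gt(prior(rep(0, 4)), prior(rep(0.5, 4)))
  expect_gt(prior(rep(0.5, 4)), prior(rep(1, 4)))
})

test_that("Laplacian OFV matches 64-node adaptive Gauss-Hermite quadrature", {
  obs <- toy_rich_obs()
  # censored DHA-clearance eta and a mixed censored/quantifiable F eta
  r1 <- laplace_quadrature_case(obs$times, obs$dv_ars, obs$dv_dha,
                                bql = c(7, 8), free = 2, om = 0.0081)
  expect_lt(abs(r1[["laplace"]] - r1[["quadrature"]]), 0.01)
  r2 <- laplace_quadrature_case(obs$times, obs$dv_ars, obs$dv_dha,
                                bql = c(7, 8), free = 4, om = 0.0887)
  expect_lt(abs(r2[["laplace"]] - r2[["quadrature"]]), 0.01)
})

test_that("vanishing IIV reduces the OFV to -2 times the data log-likelihood at eta 0", {
  m <- final_model()
  m$omega[] <- 1e-8
  ds <- tiny_dataset(times = c(1, 4), dv_ars = c(3.2, NA), dv_dha = c(5.1, 3.0),
                     bql_ars = 2)
  lap <- laplacian_ofv(ds, m)
  jl0 <- subject_joint_loglik(ds, m, rep(0, 4))
  data_ll0 <- jl0 - sum(dnorm(rep(0, 4), 0, sqrt(unname(m$omega)), log = TRUE))
  expect_equal(lap$ofv, -2 * data_ll0, tolerance = 1e-3)
})

test_that("OFV is invariant to subject order and within-time row order", {
  m <- final_model()
  ds <- simulate_study(m, study_design(n_per_group = 4), seed = 31)
  o1 <- laplacian_ofv(ds, m)
  # reverse subject blocks
  r <- ds$records
  ds2 <- ds
  ds2$records <- do.call(rbind, lapply(rev(unique(r$id)),
                                       function(i) r[r$id == i, ]))
  ds2$covariates <- ds$covariates[rev(seq_len(nrow(ds$covariates))), ]
  o2 <- laplacian_ofv(ds2, m)
  expect_equal(o1$ofv, o2$ofv, tolerance = 1e-8)
  # swap analyte order within each time point
  ds3 <- ds
  ds3$records <- do.call(rbind, lapply(split(r, r$id), function(sub) {
    sub[order(sub$time, -sub$cmt), ]
  }))
  o3 <- laplacian_ofv(ds3, m)
  expect_equal(o1$ofv, o3$ofv, tolerance = 1e-8)
})

test_that("M1 and M3 coincide without censored records, and M5 imputes half the LLOQ", {
  m <- final_model()
  ds <- simulate_study(m, study_design(n_per_group = 3), seed = 77,
                       lloq_ars = 1e-30, lloq_dha = 1e-30)  # nothing censored
  expect_false(any(ds$records$bql == 1))
  o3 <- laplacian_ofv(ds, m, likelihood_spec("M3"))
  o1 <- laplacian_ofv(ds, m, likelihood_spec("M1", "laplacian"))
  expect_equal(o3$ofv, o1$ofv, tolerance = 1e-8)

  ds_c <- tiny_dataset(times = c(1, 4), dv_ars = c(3.2, NA),
                       dv_dha = c(5.1, 3.0), bql_ars = 2)
  m5 <- arsdhapk:::apply_blq_method(ds_c, "M5")
  expect_equal(m5$records$dv[m5$records$cmt == 2 & m5$records$time == 4],
               log(0.6))
  expect_error(likelihood_spec("M3", "foce"), "Laplacian")
})

test_that("likelihood-ratio thresholds reproduce the published decision rules", {
  expect_equal(lrt(100, 103.84, df = 1)$p_value, 0.05, tolerance = 1e-3)
  expect_true(lrt(100, 103.85, df = 1)$significant)
  expect_false(lrt(100, 103.83, df = 1)$significant)
  expect_equal(lrt(100, 100, df = 1)$p_value, 1)
  expect_equal(lrt(100, 106.63, df = 1)$p_value, 0.01, tolerance = 1e-2)
  expect_false(lrt(100, 106.63, df = 1, alpha = 0.01)$significant)
  expect_true(lrt(100, 106.64, df = 1, alpha = 0.01)$significant)
  expect_warning(lrt(105, 100, df = 1), "negative")
})
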