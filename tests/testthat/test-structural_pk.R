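test_that("typical individual parameters reproduce the published worked examples", {
  m <- final_model()
  ref_cov <- list(wt = 52, preg = 0, alt = 20.75, lnpc = 5.88)
  ind <- individual_parameters(m, ref_cov, rep(0, 4))
  expect_equal(ind$clm, 190)
  expect_equal(ind$f1, 1)
  expect_equal(ind$ktr, 4 / 0.832)        # (nn+1)/MTT = 4.8077 1/h
  ind_p <- individual_parameters(m, modifyList(ref_cov, list(preg = 1)),
                                 rep(0, 4))
  expect_equal(ind_p$clm, 190 * 1.214)    # 230.66 L/h
  # allometry: clearance ~ (wt/52)^0.75, volume ~ wt/52
  ind_w <- individual_parameters(m, modifyList(ref_cov, list(wt = 65)),
                                 rep(0, 4))
  expect_equal(ind_w$clp, 3570 * (65 / 52)^0.75)
  expect_equal(ind_w$v3, 267 * 65 / 52)
  # etas act exponentially
  ind_e <- individual_parameters(m, ref_cov, c(0.2, -0.1, 0.3, 0.05))
  expect_equal(ind_e$clp, 3570 * exp(0.2))
  expect_equal(ind_e$f1, exp(0.05))
  # extreme covariates driving F non-positive are a domain error
  bad <- population_model(100, 100, 100, 100, 1, effects = list(
    covariate_effect("alt", "f", theta = -0.1, ref = 20)))
  expect_error(individual_parameters(bad, list(wt = 52, alt = 60), rep(0, 4)),
               "non-positive")
})

test_that("no mass has reached the observed compartments at dose time", {
  ind <- random_individuals(1, seed = 1)[[1]]
  p <- solve_profile(ind, 200, c(0, 1e-9))
  expect_equal(p$conc_ars[1], 0)
  expect_equal(p$conc_dha[1], 0)
  expect_lt(p$conc_ars[2], 1e-6)
})

test_that("mass balance holds to 1e-9 relative at every output time", {
  for (ind in random_individuals(20, seed = 2)) {
    tt <- c(0.1, 0.5, 1, 2.7, 6, 12, 24)
    p <- solve_profile(ind, 200, tt)
    total <- colSums(p$amounts)
    expect_lt(max(abs(total - ind$f1 * 200)) / (ind$f1 * 200), 1e-9)
  }
})

test_that("profiles agree with an adaptive ODE oracle to 1e-6 relative", {
  tt <- c(0.25, 0.5, 1, 2, 3, 4, 5, 6, 8, 10, 12)
  for (ind in random_individuals(25, seed = 3)) {
    p <- solve_profile(ind, 200, tt)
    o <- ode_profile(ind, 200, tt)
    relerr <- function(a, b) max(abs(a - b) / pmax(abs(b), 1e-8))
    expect_lt(relerr(p$conc_ars, o$conc_ars), 1e-6)
    expect_lt(relerr(p$conc_dha, o$conc_dha), 1e-6)
  }
})

test_that("the repeated-eigenvalue degeneracy ktr ~ k23 is handled exactly", {
  m <- final_model()
  ind <- individual_parameters(m, list(wt = 52, preg = 0, alt = 20.75,
                                       lnpc = 5.88), rep(0, 4))
  # force k23 equal (and nearly equal) to ktr
  for (eps in c(0, 1e-10, 1e-6)) {
    ind2 <- ind
    ind2$clp <- (ind$ktr + eps) * ind$v2
    tt <- c(0.5, 1, 2, 4, 8)
    p <- solve_profile(ind2, 200, tt)
    o <- ode_profile(ind2, 200, tt)
    expect_lt(max(abs(p$conc_ars - o$conc_ars) / o$conc_ars), 1e-6)
    expect_lt(max(abs(p$conc_dha - o$conc_dha) / o$conc_dha), 1e-6)
  }
})

test_that("multiple doses superpose as shifted single-dose profiles", {
  ind <- random_individuals(1, seed = 4)[[1]]
  doses <- data.frame(time = c(0, 24), amt = c(200, 200))
  tt <- c(1, 6, 23.99, 25, 30, 47.9)
  both <- solve_profile(ind, doses, tt)
  one <- solve_profile(ind, 200, tt)
  shifted <- solve_profile(ind, 200, pmax(tt - 24, 0))
  shifted$conc_ars[tt < 24] <- 0
  shifted$conc_dha[tt < 24] <- 0
  expect_equal(both$conc_ars, one$conc_ars + shifted$conc_ars,
               tolerance = 1e-10)
  expect_equal(both$conc_dha, one$conc_dha + shifted$conc_dha,
               tolerance = 1e-10)
})

test_that("secondary parameters match closed forms and numerical integration", {
  m <- final_model()
  ind <- individual_parameters(m, list(wt = 52, preg = 0, alt = 20.75,
                                       lnpc = 5.88), rep(0, 4))
  sec <- secondary_parameters(ind, 200)
  expect_equal(sec$auc_dha, 200 / 190 * 1000)     # 1052.6 ng h/mL
  expect_equal(sec$auc_ars, 200 / 3570 * 1000)
  # trapezoidal integration of the profile out to long times
  tt <- seq(0, 72, by = 0.02)
  p <- solve_profile(ind, 200, tt)
  trap <- function(y) sum(diff(tt) * (head(y, -1) + y[-1]) / 2)
  expect_lt(abs(trap(p$conc_dha) - sec$auc_dha) / sec$auc_dha, 0.005)
  expect_lt(abs(trap(p$conc_ars) - sec$auc_ars) / sec$auc_ars, 0.005)
  # dose linearity
  sec2 <- secondary_parameters(ind, 400)
  expect_equal(sec2$auc_dha, 2 * sec$auc_dha)
  expect_equal(sec2$cmax_dha, 2 * sec$cmax_dha, tolerance = 1e-6)
  expect_equal(sec2$tmax_dha, sec$tmax_dha, tolerance = 1e-4)
})

test_that("exposure responds monotonically to clearance and pregnancy", {
  m <- final_model()
  cov <- list(wt = 52, preg = 0, alt = 20.75, lnpc = 5.88)
  ind <- individual_parameters(m, cov, rep(0, 4))
  aucs <- vapply(c(100, 190, 300), function(cl) {
    i2 <- ind
    i2$clm <- cl
    secondary_parameters(i2, 200)$auc_dha
  }, numeric(1))
  expect_true(all(diff(aucs) < 0))
  ind_p <- individual_parameters(m, modifyList(cov, list(preg = 1)), rep(0, 4))
  r <- secondary_parameters(ind_p, 200)$auc_dha /
    secondary_parameters(ind, 200)$auc_dha
  expect_equal(r, 1 / 1.214)
})
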