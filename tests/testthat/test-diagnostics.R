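test_that("log-normal CV% conversion reproduces the published variability table", {
  expect_equal(signif(cv_percent(0.0887), 3), 30.5)   # bioavailability
  expect_equal(signif(cv_percent(0.320), 3), 61.4)    # mean transit time
  expect_equal(signif(cv_percent(0.0672), 3), 26.4)   # ARS clearance
  expect_equal(cv_percent(0.00810), 9.02, tolerance = 0.003)  # DHA clearance
  expect_equal(cv_percent(0), 0)
  # strictly increasing and ~ 100*omega for small variances
  expect_true(all(diff(cv_percent(seq(0, 1, 0.05))) > 0))
  expect_equal(cv_percent(1e-4), 100 * sqrt(1e-4), tolerance = 0.01)
  expect_error(cv_percent(-0.1), "negative")
})

fake_fit <- function(model, ds, ebes) {
  rownames(ebes) <- sort(unique(ds$records$id))
  structure(list(estimates = model, dataset = ds, ebes = ebes,
                 converged = TRUE),
            class = "pk_fit")
}

test_that("eta and epsilon shrinkage match their defining limits", {
  m <- final_model()
  ds <- simulate_study(m, study_design(n_per_group = 100), seed = 401)
  # EBEs equal to the true simulated etas: both shrinkages near zero
  f <- fake_fit(m, ds, attr(ds, "eta"))
  sh <- shrinkage(f)
  expect_true(all(abs(sh$eta) < 12))
  expect_true(all(abs(sh$epsilon) < 8))
  # EBEs collapsed to zero: eta shrinkage is exactly 100%
  f0 <- fake_fit(m, ds, matrix(0, 200, 4))
  expect_equal(unname(shrinkage(f0)$eta), rep(100, 4))
})

test_that("CWRES vanish for noise-free data and flag a misspecified absorption model", {
  gen <- final_model()
  gen$omega[] <- 0
  gen$sigma[] <- 0
  design <- study_design(n_per_group = 6)
  ds <- simulate_study(gen, design, seed = 402)
  m_eval <- final_model()
  m_eval$omega[] <- 1e-12
  m_eval$sigma[] <- 1e-6
  f <- fake_fit(m_eval, ds, matrix(0, 12, 4))
  g <- gof_tables(f)
  expect_lt(max(abs(g$cwres)), 1e-3)
  expect_equal(g$ipred, g$pred)

  # well-specified fit: CWRES pass a mean-zero check
  rep1 <- recovery_experiment()[[1]]
  g1 <- gof_tables(rep1$fit)
  expect_lt(abs(mean(g1$cwres)), 3 * sd(g1$cwres) / sqrt(nrow(g1)))

  # absorption misspecification inflates CWRES
  noisy <- simulate_study(final_model(), design, seed = 403)
  good <- fake_fit(final_model(), noisy, matrix(0, 12, 4))
  wrong_model <- final_model()
  wrong_model$mtt <- 0.2
  wrong <- fake_fit(wrong_model, noisy, matrix(0, 12, 4))
  expect_gt(mean(gof_tables(wrong)$cwres^2),
            2 * mean(gof_tables(good)$cwres^2))
})

test_that("fitted synthetic study shows the expected shrinkage pattern", {
  rep1 <- recovery_experiment()[[1]]
  sh <- shrinkage(rep1$fit)
  # clearance etas are poorly individualized at this design (paper: 30-40%)
  expect_gt(sh$eta[["cl_dha"]], 15)
  # epsilon shrinkage stays low (paper: ~10-11%)
  expect_lt(max(abs(sh$epsilon)), 30)
})

test_that("prediction correction is the identity when bin predictions are equal", {
  m <- final_model()
  m$omega[] <- c(0.0672, 0.0081, 0.32, 0.0887)
  design <- study_design(n_per_group = 5)
  ds <- simulate_study(m, design, seed = 404)
  # identical covariates and doses -> identical PRED within every bin
  ds$covariates[, c("wt", "preg", "lnpc", "hb", "ast", "alt", "bil", "ega")] <-
    list(52, 0, 5.88, 11, 20, 20.75, 0.5, 0)
  ds$records$amt[ds$records$evid == 1] <- 200
  v <- suppressWarnings(pc_vpc(m, ds, n_sim = 30, seed = 1))
  obs <- ds$records[arsdhapk:::likelihood_rows(ds$records) &
                      ds$records$bql == 0, ]
  med <- sapply(split(exp(obs$dv[obs$cmt == 3]), obs$time[obs$cmt == 3]),
                median)
  got <- v$percentiles[v$percentiles$analyte == "dha" &
                         v$percentiles$percentile == 50, ]
  common <- intersect(as.numeric(names(med)), got$time)
  expect_gte(length(common), 9)
  expect_equal(got$obs[match(common, got$time)],
               unname(med[as.character(common)]), tolerance = 1e-10)
})

test_that("the BLQ panel is zero when nothing is censored and the output has the contracted shape", {
  m <- final_model()
  ds <- simulate_study(m, study_design(n_per_group = 4), seed = 405,
                       lloq_ars = 1e-30, lloq_dha = 1e-30)
  v <- pc_vpc(m, ds, n_sim = 20, seed = 2)
  expect_true(all(v$blq$obs == 0))
  # one row per analyte x bin x percentile
  expect_equal(nrow(v$percentiles), 2 * 11 * 3)
  expect_equal(nrow(v$blq), 2 * 11)
  expect_true(all(v$percentiles$lo <= v$percentiles$hi))
  expect_true(all(v$blq$lo >= 0 & v$blq$hi <= 1))
})

test_that("degenerate one-subject-per-stratum resampling gives zero-width intervals", {
  m <- final_model()
  ds <- simulate_study(m, study_design(n_per_group = 1), seed = 406)
  fixed <- c("cl_ars", "v_ars", "v_dha", "beta_cl_dha_preg", "beta_f_alt",
             "beta_f_lnpc", "omega_cl_ars", "omega_cl_dha", "omega_mtt",
             "omega_f", "sigma_ars", "sigma_dha")
  b <- bootstrap(ds, m, n = 3, seed = 1, fixed = fixed,
                 control = list(maxit = 60))
  expect_equal(b$n_successful, 3)
  expect_equal(b$summary$sd[b$summary$parameter == "cl_dha"], 0)
  expect_equal(b$summary$ci_lo, b$summary$ci_hi)
  expect_error(bootstrap(ds, m, n = 0), "n >= 1")
})

test_that("full covariate model isolates the pregnancy effect on DHA clearance", {
  design <- study_design(n_per_group = 8)
  gen <- final_model()
  gen$effects <- gen$effects["beta_cl_dha_preg"]
  ds <- simulate_study(gen, design, seed = 407)
  base <- gen
  base$effects <- list()
  res <- full_covariate_model(ds, base, n_boot = 8, seed = 2)
  expect_error(full_covariate_model(ds, base, n_boot = 0), "n_boot")
  pct <- res$percentiles
  get <- function(p, q) pct$effect[pct$parameter == p & pct$percentile == q]
  # percentiles are monotone for every parameter
  for (p in unique(pct$parameter))
    expect_true(all(diff(pct$effect[pct$parameter == p]) >= 0))
  # the generating effect is on DHA clearance only; the others straddle zero
  expect_gt(get("beta_cl_dha_preg", 10), 0)
  expect_lt(get("beta_f_preg", 10), 0)
  expect_gt(get("beta_f_preg", 90), 0)
  expect_gt(res$n_successful, 0)
  expect_equal(res$ref_band, c(-0.2, 0.2))
})
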