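test_that("covariate sampling is reproducible and matches the cohort demographics", {
  d <- study_design()
  a <- sample_covariates(d, 1, 50, seed = 9)
  b <- sample_covariates(d, 1, 50, seed = 9)
  expect_identical(a, b)
  expect_true(all(sample_covariates(d, 0, 50, seed = 9)$ega == 0))
  big <- sample_covariates(d, 1, 4000, seed = 10)
  expect_lt(abs(median(exp(big$lnpc)) - 810) / 810, 0.25)
  expect_lt(abs(median(big$wt) - 52), 2)
  expect_true(all(big$wt > 45 & big$wt < 70))
  expect_true(all(big$ega >= 4 & big$ega <= 8))
  big0 <- sample_covariates(d, 0, 4000, seed = 10)
  expect_lt(abs(median(big0$hb) - 12), 0.5)
  expect_error(sample_covariates(d, 2, 5, seed = 1), "group")
})

test_that("dosing follows the weight bands at 100 mg per tablet", {
  d <- study_design()
  expect_equal(assign_dose(46, d), 150)
  expect_equal(assign_dose(52, d), 200)
  expect_equal(assign_dose(65, d), 250)
  expect_equal(assign_dose(c(49.9, 50, 60, 60.1), d), c(150, 200, 200, 250))
})

test_that("without random effects or noise the simulated data equal the deterministic profile", {
  m <- final_model()
  m$omega[] <- 0
  m$sigma[] <- 0
  design <- study_design(n_per_group = 2)
  ds <- simulate_study(m, design, seed = 20)
  for (i in unique(ds$records$id)) {
    cov <- ds$covariates[ds$covariates$id == i, ]
    ind <- individual_parameters(m, cov, rep(0, 4))
    prof <- solve_profile(ind, assign_dose(cov$wt, design),
                          design$sampling_times)
    lat <- attr(ds, "latent")
    lat <- lat[lat$id == i, ]
    expect_equal(lat$dv[lat$cmt == 2], log(prof$conc_ars), tolerance = 1e-12)
    expect_equal(lat$dv[lat$cmt == 3], log(prof$conc_dha), tolerance = 1e-12)
  }
})

test_that("the same seed gives byte-identical datasets and files", {
  m <- final_model()
  a <- simulate_study(m, study_design(n_per_group = 3), seed = 21)
  b <- simulate_study(m, study_design(n_per_group = 3), seed = 21)
  expect_identical(a$records, b$records)
  fa <- withr::local_tempfile(fileext = ".csv")
  fb <- withr::local_tempfile(fileext = ".csv")
  write_dataset(a, fa)
  write_dataset(b, fb)
  expect_identical(readLines(fa), readLines(fb))
})

test_that("censoring masks dv but keeps the flag, and latent values explain the censoring", {
  ds <- simulate_study(final_model(), study_design(n_per_group = 6),
                       seed = 22)
  r <- ds$records
  cens <- r$evid == 0 & r$bql == 1
  expect_true(any(cens))
  expect_true(all(is.na(r$dv[cens])))
  expect_true(all(r$mdv[cens] == 1))
  lat <- attr(ds, "latent")
  key <- paste(r$id, r$time, r$cmt)
  lkey <- paste(lat$id, lat$time, lat$cmt)
  lloq <- ifelse(r$cmt == 2, ds$lloq_ars, ds$lloq_dha)
  post <- r$evid == 0 & r$time > 0
  expect_true(all(exp(lat$dv[match(key[cens], lkey)]) < lloq[cens]))
  quant <- post & r$bql == 0
  expect_true(all(exp(r$dv[quant]) >= lloq[quant]))
})

test_that("paired exposure simulation isolates the pregnancy effect exactly", {
  m <- final_model()
  ex <- exposure_simulation(m, n_per_group = 60, seed = 23)
  s <- ex$subjects
  mean_rel <- function(g, a, col) mean(s[[col]][s$group == g & s$analyte == a])
  # DHA exposure ratio is the analytic 1/(1 + 0.214) in the paired design
  expect_equal(mean_rel("pregnant", "dha", "rel_auc"), 1 / 1.214,
               tolerance = 1e-12)
  # pregnancy leaves artesunate exposure untouched in the final model
  expect_equal(mean_rel("pregnant", "ars", "rel_auc"), 1, tolerance = 1e-12)
  expect_equal(mean_rel("non-pregnant", "dha", "rel_auc"), 1,
               tolerance = 1e-12)
  expect_equal(mean_rel("non-pregnant", "ars", "rel_cmax"), 1,
               tolerance = 1e-12)
  # percentile table shape and monotonicity; +/-20% reference band recorded
  expect_equal(ex$ref_band, c(0.8, 1.2))
  pct <- ex$percentiles
  expect_equal(nrow(pct), 2 * 2 * 2 * 5)
  for (gg in split(pct, list(pct$group, pct$analyte, pct$metric)))
    expect_true(all(diff(gg$value[order(gg$percentile)]) >= 0))

  # no pregnancy effect -> the two groups are identical subject by subject
  m0 <- m
  m0$effects[["beta_cl_dha_preg"]]$theta <- 0
  ex0 <- exposure_simulation(m0, n_per_group = 20, seed = 24)
  s0 <- ex0$subjects
  expect_equal(s0$auc[s0$group == "pregnant"],
               s0$auc[s0$group == "non-pregnant"], tolerance = 1e-12)
})

test_that("relative exposure comparisons are invariant to dose scaling", {
  m <- final_model()
  d1 <- study_design(n_per_group = 10)
  d2 <- study_design(n_per_group = 10, tablet_strength = 200)
  e1 <- exposure_simulation(m, n_per_group = 10, seed = 25, design = d1)
  e2 <- exposure_simulation(m, n_per_group = 10, seed = 25, design = d2)
  expect_equal(e2$subjects$auc, 2 * e1$subjects$auc, tolerance = 1e-9)
  expect_equal(e2$subjects$rel_auc, e1$subjects$rel_auc, tolerance = 1e-9)
  expect_equal(e2$percentiles$value, e1$percentiles$value, tolerance = 1e-6)
})
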