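# Inverse-CDF draws from truncated normal / log-normal distributions, used
# to match covariate medians and ranges reported for the cohort.
rtnorm <- function(n, mean, sd, lower, upper) {
  plo <- pnorm(lower, mean, sd)
  phi <- pnorm(upper, mean, sd)
  qnorm(plo + runif(n) * (phi - plo), mean, sd)
}
rtlnorm <- function(n, meanlog, sdlog, lower, upper) {
  exp(rtnorm(n, meanlog, sdlog, log(lower), log(upper)))
}

#' Trial design constants for the synthetic study
#'
#' Encodes the study design: two pregnancy groups of `n_per_group` subjects,
#' a single weight-banded oral artesunate dose (100 mg tablets; <50 kg gets
#' 1.5 tablets, 50-60 kg gets 2, >60 kg gets 2.5), plasma samples at 0.25,
#' 0.5, 1, 2, 3, 4, 5, 6, 8, 10 and 12 h post-dose, and per-group covariate
#' distributions (truncated normal / log-normal) parameterized so medians
#' and ranges match the admission demographics of the cohort. Gestational
#' age is uniform over 4-8 months for pregnant subjects, 0 otherwise.
#'
#' @param n_per_group Subjects per pregnancy group.
#' @param sampling_times Post-dose sampling times (h), strictly increasing.
#' @param tablet_strength mg artesunate per tablet.
#' @return A `study_design` object.
#' @export
study_design <- function(n_per_group = 24,
                         sampling_times = c(0.25, 0.5, 1, 2, 3, 4, 5, 6, 8,
                                            10, 12),
                         tablet_strength = 100) {
  stopifnot(n_per_group >= 1, all(diff(sampling_times) > 0),
            all(sampling_times > 0), tablet_strength > 0)
  covariates <- list(
    pregnant = list(
      wt  = list(dist = "tnorm", mean = 52, sd = 5, lower = 46, upper = 70),
      parasites = list(dist = "tlnorm", meanlog = log(810), sdlog = 1.2,
                       lower = 79, upper = 54000),
      hb  = list(dist = "tnorm", mean = 9.1, sd = 1.0, lower = 7.1, upper = 11),
      ast = list(dist = "tlnorm", meanlog = log(20), sdlog = 0.6,
                 lower = 3.2, upper = 84),
      alt = list(dist = "tlnorm", meanlog = log(20.3), sdlog = 0.55,
                 lower = 3.2, upper = 63),
      bil = list(dist = "tlnorm", meanlog = log(0.45), sdlog = 0.5,
                 lower = 0.2, upper = 1.9),
      ega = list(dist = "unif", lower = 4, upper = 8)),
    nonpregnant = list(
      wt  = list(dist = "tnorm", mean = 53, sd = 5, lower = 45, upper = 70),
      parasites = list(dist = "tlnorm", meanlog = log(240), sdlog = 1.0,
                       lower = 18, upper = 2444),
      hb  = list(dist = "tnorm", mean = 12, sd = 1.5, lower = 7.8, upper = 14),
      ast = list(dist = "tlnorm", meanlog = log(27.9), sdlog = 0.45,
                 lower = 8.2, upper = 59.8),
      alt = list(dist = "tlnorm", meanlog = log(21.75), sdlog = 0.45,
                 lower = 9.9, upper = 61.2),
      bil = list(dist = "tlnorm", meanlog = log(0.5), sdlog = 0.5,
                 lower = 0.2, upper = 2),
      ega = NULL))
  structure(list(n_per_group = n_per_group, sampling_times = sampling_times,
                 tablet_strength = tablet_strength,
                 weight_bands = c(50, 60), tablets = c(1.5, 2, 2.5),
                 covariates = covariates),
            class = "study_design")
}

draw_cov <- function(spec, n) {
  switch(spec$dist,
         tnorm = rtnorm(n, spec$mean, spec$sd, spec$lower, spec$upper),
         tlnorm = rtlnorm(n, spec$meanlog, spec$sdlog, spec$lower, spec$upper),
         unif = runif(n, spec$lower, spec$upper),
         stop("unknown distribution"))
}

#' Sample subject covariates for one pregnancy group
#'
#' @param design A [study_design()].
#' @param group 1 for pregnant, 0 for non-pregnant.
#' @param n Number of subjects.
#' @param seed Integer seed (required; no global state is relied upon).
#' @return Data frame with columns `id, wt, preg, lnpc, hb, ast, alt, bil,
#'   ega` (ids 1..n within the draw).
#' @export
sample_covariates <- function(design, group, n, seed) {
  stopifnot(group %in% c(0, 1), n >= 1)
  set.seed(seed)
  g <- if (group == 1) design$covariates$pregnant else
    design$covariates$nonpregnant
  data.frame(id = seq_len(n),
             wt = draw_cov(g$wt, n),
             preg = group,
             lnpc = log(draw_cov(g$parasites, n)),
             hb = draw_cov(g$hb, n),
             ast = draw_cov(g$ast, n),
             alt = draw_cov(g$alt, n),
             bil = draw_cov(g$bil, n),
             ega = if (group == 1) draw_cov(g$ega, n) else rep(0, n))
}

#' Weight-banded artesunate dose
#'
#' @param wt Body weight (kg), vectorized.
#' @param design A [study_design()].
#' @return Dose in mg artesunate (1.5, 2 or 2.5 tablets of
#'   `tablet_strength` mg for <50, 50-60 and >60 kg).
#' @export
assign_dose <- function(wt, design = study_design()) {
  stopifnot(all(wt > 0))
  # bands: < 50 kg | 50-60 kg (inclusive) | > 60 kg
  idx <- 1 + (wt >= design$weight_bands[1]) + (wt > design$weight_bands[2])
  design$tablets[idx] * design$tablet_strength
}

#' Simulate a synthetic study emulating the trial
#'
#' For each subject: covariates are sampled per group, the weight-banded
#' dose is given at time 0, random effects are drawn from `N(0, omega)`,
#' the deterministic profile is solved at the design's sampling times,
#' additive log-scale residual noise is applied per analyte, and observed
#' concentrations below the analyte LLOQ are flagged `bql = 1` with their
#' `dv` masked (the latent values are kept in the `"latent"` attribute for
#' verification). A pre-dose screening record per analyte is emitted with
#' `mdv = 1`; censored rows also carry `mdv = 1` since their `dv` is not a
#' quantified value.
#'
#' @param model A [population_model()].
#' @param design A [study_design()].
#' @param seed Integer seed.
#' @param lloq_ars,lloq_dha Censoring limits (ng/mL).
#' @return A validated `study_dataset` with `2 * n_per_group` subjects
#'   (pregnant subjects first), and attributes `latent` (data frame of
#'   uncensored log concentrations) and `eta` (matrix of the simulated
#'   random effects).
#' @export
simulate_study <- function(model, design = study_design(), seed,
                           lloq_ars = 1.2, lloq_dha = 2.0) {
  if (missing(seed)) stop("an explicit seed is required for reproducibility")
  n <- design$n_per_group
  cov <- rbind(sample_covariates(design, 1, n, seed),
               sample_covariates(design, 0, n, seed + 1))
  cov$id <- seq_len(2 * n)
  set.seed(seed + 2)
  omega <- unname(model$omega)
  eta <- sapply(sqrt(omega), function(s) rnorm(2 * n, 0, s))
  if (all(omega == 0)) eta <- matrix(0, 2 * n, 4)
  tms <- design$sampling_times
  nt <- length(tms)
  sg <- sqrt(unname(model$sigma))
  recs <- vector("list", 2 * n)
  latent <- vector("list", 2 * n)
  for (i in seq_len(2 * n)) {
    dose <- assign_dose(cov$wt[i], design)
    ind <- individual_parameters(model, cov[i, ], eta[i, ])
    prof <- solve_profile(ind, dose, tms)
    dv_ars <- log(prof$conc_ars) + rnorm(nt, 0, sg[1])
    dv_dha <- log(prof$conc_dha) + rnorm(nt, 0, sg[2])
    obs <- data.frame(
      id = cov$id[i],
      time = rep(tms, each = 2),
      dv = as.vector(rbind(dv_ars, dv_dha)),
      evid = 0, mdv = 0, amt = NA_real_,
      cmt = rep(c(2, 3), nt), bql = 0)
    lloq <- ifelse(obs$cmt == 2, lloq_ars, lloq_dha)
    cens <- exp(obs$dv) < lloq
    obs$bql[cens] <- 1
    latent[[i]] <- data.frame(id = cov$id[i], time = obs$time, cmt = obs$cmt,
                              dv = obs$dv)
    obs$dv[cens] <- NA_real_
    obs$mdv[cens] <- 1
    pre <- data.frame(id = cov$id[i], time = 0, dv = NA_real_, evid = 0,
                      mdv = 1, amt = NA_real_, cmt = c(2, 3), bql = 0)
    dz <- data.frame(id = cov$id[i], time = 0, dv = NA_real_, evid = 1,
                     mdv = 1, amt = dose, cmt = 1, bql = 0)
    recs[[i]] <- rbind(pre, dz, obs)
  }
  ds <- study_dataset(do.call(rbind, recs), cov,
                      lloq_ars = lloq_ars, lloq_dha = lloq_dha)
  attr(ds, "latent") <- do.call(rbind, latent)
  rownames(eta) <- cov$id
  colnames(eta) <- names(model$omega)
  attr(ds, "eta") <- eta
  ds
}

#' Paired pregnancy-impact exposure simulation
#'
#' Simulates `n_per_group` pregnant subjects and, for each, an identical
#' non-pregnant twin sharing body weight, all other covariates and the
#' random effects, so the comparison isolates the pregnancy covariate
#' effect. Per-subject AUC (closed form `F1 * dose / CL`) and peak
#' concentration are computed for both analytes and divided by the
#' non-pregnant group mean.
#'
#' @param model A [population_model()]; normally carries a pregnancy effect.
#' @param n_per_group Simulated subjects per group.
#' @param seed Integer seed.
#' @param design A [study_design()] supplying covariate distributions and
#'   the dose bands.
#' @return An `exposure_comparison`: `subjects` (per-subject tidy table with
#'   absolute and relative AUC/CMAX per analyte and group), `percentiles`
#'   (10/25/50/75/90th percentiles of the relative values per group,
#'   analyte and metric) and `ref_band = c(0.8, 1.2)`, the +/-20% band
#'   conventionally taken as the limit of clinical relevance.
#' @export
exposure_simulation <- function(model, n_per_group = 1000, seed,
                                design = study_design()) {
  stopifnot(n_per_group >= 2)
  if (missing(seed)) stop("an explicit seed is required for reproducibility")
  cov <- sample_covariates(design, 1, n_per_group, seed)
  set.seed(seed + 1)
  eta <- sapply(sqrt(unname(model$omega)), function(s)
    rnorm(n_per_group, 0, s))
  if (all(model$omega == 0)) eta <- matrix(0, n_per_group, 4)
  rows <- vector("list", 2 * n_per_group)
  k <- 0
  for (i in seq_len(n_per_group)) {
    dose <- assign_dose(cov$wt[i], design)
    for (g in c(0, 1)) {
      cv <- cov[i, ]
      cv$preg <- g
      if (g == 0) cv$ega <- 0
      ind <- individual_parameters(model, cv, eta[i, ])
      sec <- secondary_parameters(ind, dose)
      k <- k + 1
      rows[[k]] <- data.frame(
        id = i, group = if (g == 1) "pregnant" else "non-pregnant",
        analyte = c("ars", "dha"),
        auc = c(sec$auc_ars, sec$auc_dha),
        cmax = c(sec$cmax_ars, sec$cmax_dha))
    }
  }
  subj <- do.call(rbind, rows)
  for (metric in c("auc", "cmax")) {
    rel <- paste0("rel_", metric)
    subj[[rel]] <- NA_real_
    for (a in c("ars", "dha")) {
      ref <- mean(subj[[metric]][subj$group == "non-pregnant" &
                                   subj$analyte == a])
      sel <- subj$analyte == a
      subj[[rel]][sel] <- subj[[metric]][sel] / ref
    }
  }
  qs <- c(0.1, 0.25, 0.5, 0.75, 0.9)
  pct <- do.call(rbind, lapply(split(
    subj, list(subj$group, subj$analyte)), function(d) {
      data.frame(group = d$group[1], analyte = d$analyte[1],
                 metric = rep(c("auc", "cmax"), each = length(qs)),
                 percentile = rep(100 * qs, 2),
                 value = c(quantile(d$rel_auc, qs), quantile(d$rel_cmax, qs)))
    }))
  rownames(pct) <- NULL
  structure(list(subjects = subj, percentiles = pct, ref_band = c(0.8, 1.2)),
            class = "exposure_comparison")
}
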