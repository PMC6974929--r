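#' Coefficient of variation of a log-normal random effect
#'
#' Converts an inter-individual variance on the log scale to a percent
#' coefficient of variation, `100 * sqrt(exp(omega2) - 1)`.
#'
#' @param omega2 Variance(s) of the log-normal random effect (>= 0).
#' @return CV in percent, vectorized.
#' @examples
#' cv_percent(0.0887)  # 30.5% IIV in relative bioavailability
#' cv_percent(0.320)   # 61.4% IIV in mean transit time
#' @export
cv_percent <- function(omega2) {
  if (any(omega2 < 0)) stop("negative variance")
  100 * sqrt(exp(omega2) - 1)
}

# Log-scale individual predictions and the eta-Jacobian at a given eta,
# for one subject's quantifiable observation rows.
subject_pred <- function(model, cov, obs, eta, jacobian = FALSE) {
  ipred_fun <- function(e) {
    ind <- individual_parameters(model, cov, e)
    prof <- solve_profile(ind, data.frame(time = obs$dose_time,
                                          amt = obs$dose_amt), obs$time)
    log(ifelse(obs$cmt == 2, prof$conc_ars, prof$conc_dha))
  }
  ip <- ipred_fun(eta)
  if (!jacobian) return(list(ipred = ip))
  J <- matrix(0, length(ip), 4)
  for (k in 1:4) {
    h <- 1e-4
    ep <- em <- eta
    ep[k] <- ep[k] + h
    em[k] <- em[k] - h
    J[, k] <- (ipred_fun(ep) - ipred_fun(em)) / (2 * h)
  }
  list(ipred = ip, J = J)
}

#' Goodness-of-fit tables: predictions and conditional weighted residuals
#'
#' Returns, per quantifiable observation, the population prediction
#' (`pred`, at eta = 0), individual prediction (`ipred`, at the
#' empirical-Bayes eta mode), individual weighted residual (`iwres`) and
#' conditional weighted residual (`cwres`) from a first-order linearization
#' of the model about the conditional eta modes:
#' the marginal mean is `f(eta_hat) - J eta_hat` and the marginal
#' covariance `J Omega J' + Sigma`, with `J` the eta-Jacobian of the
#' log-scale predictions. Censored (BLQ) records are excluded.
#'
#' @param fit A `pk_fit`.
#' @param ds Dataset; defaults to the one the fit was run on.
#' @return Data frame with columns `id, time, analyte, dv, pred, ipred,
#'   iwres, cwres` (log scale).
#' @export
gof_tables <- function(fit, ds = fit$dataset) {
  stopifnot(inherits(fit, "pk_fit"))
  model <- fit$estimates
  r <- ds$records
  out <- list()
  for (i in sort(unique(r$id))) {
    sub <- r[r$id == i, , drop = FALSE]
    obs <- sub[likelihood_rows(sub) & sub$bql == 0, , drop = FALSE]
    if (!nrow(obs)) next
    dose <- sub[sub$evid == 1, , drop = FALSE]
    cov <- ds$covariates[ds$covariates$id == i, , drop = FALSE]
    od <- list(time = obs$time, cmt = obs$cmt,
               dose_time = dose$time, dose_amt = dose$amt)
    eb <- fit$ebes[as.character(i), ]
    at_mode <- subject_pred(model, cov, od, eb, jacobian = TRUE)
    pop <- subject_pred(model, cov, od, rep(0, 4))
    s2 <- ifelse(obs$cmt == 2, model$sigma[["ars"]], model$sigma[["dha"]])
    V <- at_mode$J %*% diag(unname(model$omega)) %*% t(at_mode$J) + diag(s2, nrow(obs))
    resid <- obs$dv - (at_mode$ipred - drop(at_mode$J %*% eb))
    cwres <- drop(solve(t(chol(V)), resid))
    out[[length(out) + 1L]] <- data.frame(
      id = i, time = obs$time,
      analyte = ifelse(obs$cmt == 2, "ars", "dha"), dv = obs$dv,
      pred = pop$ipred, ipred = at_mode$ipred,
      iwres = (obs$dv - at_mode$ipred) / sqrt(s2), cwres = cwres)
  }
  do.call(rbind, out)
}

#' Eta and epsilon shrinkage
#'
#' Eta shrinkage per IIV dimension is `100 * (1 - SD(EBE)/omega)`; epsilon
#' shrinkage per analyte is `100 * (1 - SD(IWRES))` over quantifiable
#' observations. High shrinkage warns that empirical Bayes estimates and
#' residual diagnostics are dominated by the priors rather than the data.
#'
#' @param fit A `pk_fit`.
#' @return List with `eta` (named percentages per IIV dimension; dimensions
#'   with zero variance are dropped) and `epsilon` (per analyte).
#' @export
shrinkage <- function(fit) {
  stopifnot(inherits(fit, "pk_fit"))
  om <- fit$estimates$omega
  keep <- om > 0
  eta_shr <- 100 * (1 - apply(fit$ebes[, keep, drop = FALSE], 2, sd) /
                      sqrt(om[keep]))
  g <- gof_tables(fit)
  eps <- vapply(split(g$iwres, g$analyte),
                function(x) 100 * (1 - sd(x)), numeric(1))
  list(eta = eta_shr, epsilon = eps)
}

# Simulate one replicate of the dataset's own design (same subjects, doses,
# sampling times and covariates; new etas and residual noise). Returns the
# observation table with raw-scale concentration and censoring flag.
simulate_replicate <- function(model, ds, obs) {
  n <- length(unique(obs$id))
  ids <- sort(unique(obs$id))
  omega <- unname(model$omega)
  sg <- sqrt(unname(model$sigma))
  sim <- numeric(nrow(obs))
  for (i in ids) {
    sel <- obs$id == i
    o <- obs[sel, , drop = FALSE]
    eta <- rnorm(4, 0, sqrt(omega))
    cov <- ds$covariates[ds$covariates$id == i, , drop = FALSE]
    ind <- individual_parameters(model, cov, eta)
    prof <- solve_profile(ind, data.frame(time = o$dose_time[1],
                                          amt = o$dose_amt[1]),
                          o$time)
    conc <- ifelse(o$cmt == 2, prof$conc_ars, prof$conc_dha)
    noise <- rnorm(nrow(o), 0, ifelse(o$cmt == 2, sg[1], sg[2]))
    sim[sel] <- exp(log(conc) + noise)
  }
  sim
}

#' Prediction-corrected visual predictive check
#'
#' Observations and simulations are normalized per bin by
#' `pcY = Y * median(PRED_bin) / PRED_individual` on the raw concentration
#' scale, where `PRED` is the typical-subject (eta = 0) prediction; 5th,
#' 50th and 95th percentiles of the prediction-corrected quantifiable
#' values are compared with their simulated 95% confidence bands per bin.
#' A separate panel compares, per bin, the observed fraction of samples
#' below the analyte LLOQ (uncorrected values) against its simulated band.
#' Bins default to the nominal sampling times of the fixed-time design.
#'
#' @param fit A `pk_fit`, or a [population_model()] (then `ds` is required).
#' @param ds Dataset; defaults to the fitted one.
#' @param n_sim Number of simulated replicates.
#' @param bins Bin centers (h); observations are assigned to the nearest
#'   center. Default: the distinct post-dose observation times.
#' @param seed Integer seed.
#' @return A `vpc_result`: `percentiles` (analyte, bin time, percentile,
#'   observed value, band lo/hi), `blq` (analyte, bin time, observed BLQ
#'   fraction, band lo/hi) and `n_sim`. Empty bins are dropped with a
#'   warning.
#' @export
pc_vpc <- function(fit, ds = NULL, n_sim = 2000, bins = NULL, seed = 1) {
  if (inherits(fit, "pk_fit")) {
    model <- fit$estimates
    if (is.null(ds)) ds <- fit$dataset
  } else {
    model <- fit
    if (is.null(ds)) stop("ds required when passing a model")
  }
  r <- ds$records
  keep <- likelihood_rows(r)
  doses <- r[r$evid == 1, c("id", "time", "amt")]
  obs <- r[keep, , drop = FALSE]
  obs$dose_time <- doses$time[match(obs$id, doses$id)]
  obs$dose_amt <- doses$amt[match(obs$id, doses$id)]
  if (is.null(bins)) bins <- sort(unique(obs$time))
  obs$bin <- bins[max.col(-abs(outer(obs$time, bins, "-")))]
  # typical predictions per row
  obs$pred <- NA_real_
  for (i in sort(unique(obs$id))) {
    sel <- obs$id == i
    o <- obs[sel, , drop = FALSE]
    cov <- ds$covariates[ds$covariates$id == i, , drop = FALSE]
    ind <- individual_parameters(model, cov, rep(0, 4))
    prof <- solve_profile(ind, data.frame(time = o$dose_time[1],
                                          amt = o$dose_amt[1]), o$time)
    obs$pred[sel] <- ifelse(o$cmt == 2, prof$conc_ars, prof$conc_dha)
  }
  obs$lloq <- ifelse(obs$cmt == 2, ds$lloq_ars, ds$lloq_dha)
  med_pred <- stats::ave(obs$pred, obs$cmt, obs$bin, FUN = median)
  pcfac <- med_pred / obs$pred
  qs <- c(0.05, 0.5, 0.95)
  lev <- unique(paste(obs$cmt, obs$bin, sep = "|"))
  lev <- lev[order(as.numeric(sub("\\|.*", "", lev)),
                   as.numeric(sub(".*\\|", "", lev)))]
  cell <- factor(paste(obs$cmt, obs$bin, sep = "|"), levels = lev)
  pct_of <- function(raw, cens) {
    # percentiles of prediction-corrected quantifiable values per analyte/bin
    pc <- raw * pcfac
    pc[cens] <- NA
    res <- lapply(split(pc, cell), function(x) {
      x <- x[!is.na(x)]
      if (!length(x)) rep(NA_real_, 3) else quantile(x, qs, names = FALSE)
    })
    do.call(rbind, res)
  }
  blq_of <- function(cens) vapply(split(cens, cell), mean, numeric(1))
  obs_raw <- exp(obs$dv)
  obs_cens <- obs$bql == 1
  obs_pct <- pct_of(ifelse(obs_cens, 1, obs_raw), obs_cens)
  obs_blq <- blq_of(obs_cens)
  set.seed(seed)
  sim_pct <- array(NA_real_, c(nrow(obs_pct), 3, n_sim))
  sim_blq <- matrix(NA_real_, length(obs_blq), n_sim)
  for (s in seq_len(n_sim)) {
    y <- simulate_replicate(model, ds, obs)
    cens <- y < obs$lloq
    sim_pct[, , s] <- pct_of(y, cens)
    sim_blq[, s] <- blq_of(cens)
  }
  band <- function(x) quantile(x, c(0.025, 0.975), na.rm = TRUE, names = FALSE)
  lab_cmt <- as.numeric(sub("\\|.*", "", lev))
  lab_time <- as.numeric(sub(".*\\|", "", lev))
  pct <- data.frame(
    analyte = rep(ifelse(lab_cmt == 2, "ars", "dha"), each = 3),
    time = rep(lab_time, each = 3),
    percentile = rep(100 * qs, nrow(obs_pct)),
    obs = as.vector(t(obs_pct)),
    lo = NA_real_, hi = NA_real_)
  k <- 0
  for (b in seq_len(nrow(obs_pct)))
    for (q in 1:3) {
      k <- k + 1
      bd <- band(sim_pct[b, q, ])
      pct$lo[k] <- bd[1]
      pct$hi[k] <- bd[2]
    }
  blq <- data.frame(analyte = ifelse(lab_cmt == 2, "ars", "dha"),
                    time = lab_time, obs = unname(obs_blq),
                    lo = apply(sim_blq, 1, function(x) band(x)[1]),
                    hi = apply(sim_blq, 1, function(x) band(x)[2]))
  if (anyNA(pct$obs)) {
    warning(sum(is.na(pct$obs)) / 3, " empty analyte/bin cell(s) dropped")
    drop_cells <- unique(paste(pct$analyte, pct$time)[is.na(pct$obs)])
    blq <- blq[!paste(blq$analyte, blq$time) %in% drop_cells, ]
    pct <- pct[!is.na(pct$obs), ]
  }
  pct <- pct[order(pct$analyte, pct$time, pct$percentile), ]
  rownames(pct) <- rownames(blq) <- NULL
  structure(list(percentiles = pct,
                 blq = blq[order(blq$analyte, blq$time), ],
                 n_sim = n_sim),
            class = "vpc_result")
}

#' Stratified nonparametric bootstrap of the model fit
#'
#' Subjects are resampled with replacement within pregnancy strata,
#' preserving the stratum sizes; the model is refit to each resampled
#' dataset (warm-started from the supplied estimates) and the summaries are
#' computed over successful fits only.
#'
#' @param ds A `study_dataset` with at least one subject per pregnancy
#'   stratum (a single-subject stratum resamples to itself and contributes
#'   no variability).
#' @param model Starting/reference [population_model()] (typically the
#'   original fit's estimates).
#' @param n Number of bootstrap replicates.
#' @param seed Integer seed.
#' @param spec A [likelihood_spec()].
#' @param fixed,control Passed to [fit()].
#' @return A `bootstrap_result`: `summary` (per parameter: mean, sd,
#'   `rse` = 100 sd/mean, nonparametric 2.5%/97.5% CI), `estimates` (matrix
#'   of per-replicate estimates), `n_requested`, `n_successful`.
#' @export
bootstrap <- function(ds, model, n = 1000, seed = 1,
                      spec = likelihood_spec(), fixed = character(),
                      control = list()) {
  stopifnot(n >= 1)
  cv <- ds$covariates
  strata <- split(cv$id, cv$preg)
  if (!length(strata) || any(lengths(strata) < 1))
    stop("each stratum needs at least one subject")
  set.seed(seed)
  draws <- lapply(seq_len(n), function(b)
    unlist(lapply(strata, function(ids)
      ids[sample.int(length(ids), length(ids), replace = TRUE)])))
  est <- list()
  n_succ <- 0L
  for (b in seq_len(n)) {
    bds <- resample_dataset(ds, draws[[b]])
    fb <- tryCatch(fit(bds, model, spec = spec, fixed = fixed,
                       control = control),
                   error = function(e) NULL)
    if (!is.null(fb) && fb$successful) {
      n_succ <- n_succ + 1L
      est[[length(est) + 1L]] <- fit_coef(fb)
    }
  }
  if (!n_succ) stop("all bootstrap replicates failed")
  em <- do.call(rbind, est)
  summ <- data.frame(
    parameter = colnames(em), mean = colMeans(em),
    sd = apply(em, 2, sd), rse = 100 * apply(em, 2, sd) / colMeans(em),
    ci_lo = apply(em, 2, quantile, 0.025),
    ci_hi = apply(em, 2, quantile, 0.975), row.names = NULL)
  structure(list(summary = summ, estimates = em, n_requested = n,
                 n_successful = n_succ),
            class = "bootstrap_result")
}

# Rebuild a dataset from a vector of (possibly repeated) subject ids,
# assigning fresh ids 1..length(draw).
resample_dataset <- function(ds, draw) {
  recs <- list()
  covs <- list()
  for (j in seq_along(draw)) {
    i <- draw[j]
    rr <- ds$records[ds$records$id == i, , drop = FALSE]
    rr$id <- j
    recs[[j]] <- rr
    cc <- ds$covariates[ds$covariates$id == i, , drop = FALSE]
    cc$id <- j
    covs[[j]] <- cc
  }
  study_dataset(do.call(rbind, recs), do.call(rbind, covs),
                lloq_ars = ds$lloq_ars, lloq_dha = ds$lloq_dha)
}
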