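# Parameter packing for the outer optimization: positive structural thetas
# and all variances on the log scale, covariate-effect thetas (which carry
# sign) on the raw scale with box bounds.

THETA_POS <- c("cl_ars", "v_ars", "cl_dha", "v_dha", "mtt")

pack_parameters <- function(model) {
  p <- c(setNames(log(unlist(model[THETA_POS])), paste0("th_", THETA_POS)),
         setNames(vapply(model$effects, `[[`, numeric(1), "theta"),
                  names(model$effects)),
         setNames(log(model$omega), paste0("om_", names(model$omega))),
         setNames(log(model$sigma), paste0("sg_", names(model$sigma))))
  lower <- rep(-Inf, length(p))
  upper <- rep(Inf, length(p))
  names(lower) <- names(upper) <- names(p)
  for (nm in names(model$effects)) {
    lower[nm] <- model$effects[[nm]]$lower
    upper[nm] <- model$effects[[nm]]$upper
  }
  list(par = p, lower = lower, upper = upper)
}

unpack_parameters <- function(p, template) {
  m <- template
  for (nm in THETA_POS) m[[nm]] <- exp(p[[paste0("th_", nm)]])
  for (nm in names(m$effects)) m$effects[[nm]]$theta <- p[[nm]]
  m$omega[] <- exp(p[paste0("om_", names(m$omega))])
  m$sigma[] <- exp(p[paste0("sg_", names(m$sigma))])
  m
}

#' Fit the population model by marginal-likelihood minimization
#'
#' Minimizes the Laplacian objective function over the fixed effects,
#' covariate-effect thetas, IIV variances and residual variances. Positive
#' parameters and variances are optimized on the log scale; covariate
#' effects on the raw scale under their box bounds. Relative
#' bioavailability is always fixed to 1 for the typical subject (its IIV is
#' estimated). The inner empirical-Bayes problems are warm-started from the
#' previous outer iteration's modes.
#'
#' @param ds A `study_dataset`.
#' @param start A [population_model()] of starting values (all estimated
#'   variances must be positive).
#' @param spec A [likelihood_spec()].
#' @param fixed Character vector of parameter names to hold at their start
#'   values: any of `"cl_ars"`, `"v_ars"`, `"cl_dha"`, `"v_dha"`, `"mtt"`,
#'   effect names (`"beta_<parameter>_<covariate>"`), `"omega_<name>"`,
#'   `"sigma_<name>"`. `"f_pop"` is accepted and always fixed.
#' @param control List overriding `optim` L-BFGS-B control values
#'   (`factr`, `maxit`, `lmm`, `ndeps`).
#' @return A `pk_fit` object: `estimates` (a [population_model()]), `ofv`,
#'   `ofv_nonmem`, `ebes` (per-subject posterior-mode random effects),
#'   `converged`, `boundary`, `successful` (converged, off-boundary,
#'   positive variances; the condition counted in bootstrap summaries),
#'   `n_function_evals`, `start_ofv` and the fitted `spec`.
#' @export
fit <- function(ds, start, spec = likelihood_spec(), fixed = character(),
                control = list()) {
  stopifnot(inherits(ds, "study_dataset"), inherits(start, "population_model"))
  ds_l <- apply_blq_method(ds, spec$blq_method)
  ids <- sort(unique(ds_l$records$id))
  subjects <- prepare_subjects(ds_l, start)
  cov <- ds_l$covariates[match(ids, ds_l$covariates$id), , drop = FALSE]
  loglloq <- log(c(ds_l$lloq_ars, ds_l$lloq_dha))
  hess_method <- if (spec$estimation == "foce") 1L else 0L
  n_gauss <- sum(vapply(subjects, function(s) sum(s$obs_bql == 0), numeric(1)))

  pk <- pack_parameters(start)
  fixed <- setdiff(fixed, "f_pop")
  fixed_names <- unique(c(
    vapply(fixed, function(f) {
      cands <- c(f, paste0("th_", f),
                 sub("^omega_", "om_", sub("^sigma_", "sg_", f)))
      hit <- cands[cands %in% names(pk$par)]
      if (!length(hit)) stop("unknown parameter in 'fixed': ", f)
      hit[1]
    }, character(1))))
  free <- setdiff(names(pk$par), fixed_names)
  if (!length(free)) stop("no free parameters")

  st <- new.env(parent = emptyenv())
  st$eta <- matrix(0, length(ids), 4)
  st$nev <- 0L
  sptr <- prepare_subjects_ptr(subjects, unname(start$sigma), loglloq,
                               spec$blq_floor)
  objective <- function(pfree) {
    p <- pk$par
    p[free] <- pfree
    m <- unpack_parameters(p, start)
    tv <- tryCatch(typical_values(m, cov), error = function(e) NULL)
    if (is.null(tv)) return(1e10)
    res <- ofv_ptr_cpp(sptr, tv, unname(m$sigma), unname(m$omega), st$eta,
                       hess_method = hess_method)
    st$nev <- st$nev + 1L
    if (!is.finite(res$ofv)) return(1e10)
    st$eta <- res$eta
    res$ofv
  }

  ctl <- modifyList(list(factr = 1e10, maxit = 300L, lmm = 25L,
                         ndeps = rep(1e-4, length(free))),
                    control)
  opt <- stats::optim(pk$par[free], objective, method = "L-BFGS-B",
                      lower = pk$lower[free], upper = pk$upper[free],
                      control = ctl)
  p <- pk$par
  p[free] <- opt$par
  est <- unpack_parameters(p, start)
  start_ofv <- laplacian_ofv(ds, start, spec)$ofv
  final <- laplacian_ofv(ds, est, spec, eta_start = st$eta)
  at_bound <- names(opt$par)[opt$par <= pk$lower[free] + 1e-10 |
                               opt$par >= pk$upper[free] - 1e-10]
  tiny_var <- c(names(est$omega)[est$omega < 1e-8],
                names(est$sigma)[est$sigma < 1e-8])
  converged <- opt$convergence == 0 && final$valid
  structure(list(estimates = est, ofv = final$ofv,
                 ofv_nonmem = final$ofv_nonmem, ebes = final$eta,
                 converged = converged,
                 boundary = c(at_bound, tiny_var),
                 successful = converged && !length(at_bound) &&
                   !length(tiny_var),
                 n_function_evals = st$nev, start_ofv = start_ofv,
                 message = opt$message, spec = spec, dataset = ds,
                 par = p, free = free),
            class = "pk_fit")
}

#' Extract the estimated parameters of a fit as a named vector
#'
#' @param fit A `pk_fit`.
#' @return Named vector of estimates on their natural scales: structural
#'   thetas, covariate-effect thetas, IIV variances (`omega_*`) and residual
#'   variances (`sigma_*`).
#' @export
fit_coef <- function(fit) {
  m <- fit$estimates
  c(setNames(unlist(m[THETA_POS]), THETA_POS),
    setNames(vapply(m$effects, `[[`, numeric(1), "theta"), names(m$effects)),
    setNames(as.numeric(m$omega), paste0("omega_", names(m$omega))),
    setNames(as.numeric(m$sigma), paste0("sigma_", names(m$sigma))))
}

#' @export
print.pk_fit <- function(x, ...) {
  cat("Population PK fit (", x$spec$estimation, ", BLQ ", x$spec$blq_method,
      ")\n", sep = "")
  cat(sprintf("  OFV %.4f (without data constants: %.4f)\n",
              x$ofv, x$ofv_nonmem))
  cat("  converged:", x$converged,
      if (length(x$boundary)) paste(" [boundary:",
                                    paste(x$boundary, collapse = ", "), "]"),
      "\n")
  cat("  objective evaluations:", x$n_function_evals, "\n")
  print(round(fit_coef(x), 5))
  invisible(x)
}
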