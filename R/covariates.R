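# Data-driven box bounds for a linear covariate effect: keep the
# multiplicative factor 1 + theta * (x - ref) above 0.05 over the observed
# covariate range.
effect_bounds <- function(x, ref) {
  dpos <- max(x - ref)
  dneg <- min(x - ref)
  lower <- if (dpos > 0) -0.95 / dpos else -Inf
  upper <- if (dneg < 0) 0.95 / (-dneg) else Inf
  c(lower, upper)
}

make_candidate_effect <- function(ds, covariate, parameter) {
  x <- ds$covariates[[covariate]]
  if (covariate == "preg")
    return(covariate_effect("preg", parameter, theta = 0, ref = 0,
                            lower = -0.95, upper = 5))
  ref <- median(x)
  b <- effect_bounds(x, ref)
  covariate_effect(covariate, parameter, theta = 0, ref = ref,
                   lower = b[1], upper = b[2])
}

#' Default candidate covariate-parameter pairs for the stepwise search
#'
#' Parasite biomass (log count), ALT, AST, bilirubin and haemoglobin as
#' linear continuous effects, and pregnancy (categorical) plus gestational
#' age (continuous) — each tested on relative bioavailability and on both
#' elimination clearances.
#'
#' @return Data frame with columns `covariate` and `parameter`.
#' @export
candidate_covariates <- function() {
  expand.grid(covariate = c("lnpc", "alt", "ast", "bil", "hb", "preg", "ega"),
              parameter = c("f", "cl_ars", "cl_dha"),
              stringsAsFactors = FALSE)
}

#' Stepwise covariate search (forward inclusion, backward elimination)
#'
#' Forward steps add, one at a time, the candidate with the largest
#' significant OFV drop (p < `forward_alpha`, chi-square with 1 df) until
#' no candidate qualifies; backward steps then remove search-added effects
#' that do not survive at p < `backward_alpha`. Ties on the OFV drop are
#' broken by covariate then parameter name. Candidate fits that fail to
#' converge are skipped and logged.
#'
#' @param ds A `study_dataset`.
#' @param base_model Base [population_model()] (its own effects are never
#'   removed by the backward step).
#' @param candidates Data frame of `covariate`/`parameter` pairs; defaults
#'   to [candidate_covariates()].
#' @param spec A [likelihood_spec()].
#' @param forward_alpha,backward_alpha Inclusion and elimination levels.
#' @param fixed,control Passed to [fit()].
#' @return List with `model` (final estimates), `fit` (final `pk_fit`),
#'   `selected` (names of retained search-added effects) and `trace`
#'   (one row per candidate evaluation).
#' @export
stepwise_covariate_search <- function(ds, base_model,
                                      candidates = candidate_covariates(),
                                      spec = likelihood_spec(),
                                      forward_alpha = 0.05,
                                      backward_alpha = 0.01,
                                      fixed = character(),
                                      control = list()) {
  candidates <- as.data.frame(candidates)
  candidates <- candidates[order(candidates$covariate, candidates$parameter), ]
  cur_fit <- fit(ds, base_model, spec = spec, fixed = fixed, control = control)
  cur <- cur_fit$estimates
  added <- character()
  trace <- list()
  note <- function(step, cand, ofv, delta, p, action)
    trace[[length(trace) + 1L]] <<- data.frame(
      step = step, candidate = cand, ofv = ofv, delta_ofv = delta,
      p_value = p, action = action)
  repeat {
    best <- NULL
    for (k in seq_len(nrow(candidates))) {
      cv <- candidates$covariate[k]
      pp <- candidates$parameter[k]
      nm <- paste0("beta_", pp, "_", cv)
      if (nm %in% c(names(cur$effects))) next
      cand_model <- cur
      cand_model$effects[[nm]] <- make_candidate_effect(ds, cv, pp)
      cand_fit <- tryCatch(fit(ds, cand_model, spec = spec, fixed = fixed,
                               control = control),
                           error = function(e) NULL)
      if (is.null(cand_fit) || !cand_fit$converged) {
        note("forward", nm, NA, NA, NA, "skipped (non-convergent)")
        next
      }
      test <- lrt(cand_fit$ofv, cur_fit$ofv, df = 1, alpha = forward_alpha)
      note("forward", nm, cand_fit$ofv, test$delta_ofv, test$p_value,
           if (test$significant) "significant" else "not significant")
      if (test$significant &&
          (is.null(best) || test$delta_ofv > best$delta))
        best <- list(nm = nm, fit = cand_fit, delta = test$delta_ofv)
    }
    if (is.null(best)) break
    cur_fit <- best$fit
    cur <- cur_fit$estimates
    added <- c(added, best$nm)
    note("forward", best$nm, cur_fit$ofv, best$delta, NA, "added")
  }
  repeat {
    worst <- NULL
    for (nm in added) {
      red_model <- cur
      red_model$effects[[nm]] <- NULL
      red_fit <- tryCatch(fit(ds, red_model, spec = spec, fixed = fixed,
                              control = control),
                          error = function(e) NULL)
      if (is.null(red_fit) || !red_fit$converged) {
        note("backward", nm, NA, NA, NA, "skipped (non-convergent)")
        next
      }
      test <- lrt(cur_fit$ofv, red_fit$ofv, df = 1, alpha = backward_alpha)
      note("backward", nm, red_fit$ofv, test$delta_ofv, test$p_value,
           if (test$significant) "retained" else "removable")
      if (!test$significant &&
          (is.null(worst) || test$delta_ofv < worst$delta))
        worst <- list(nm = nm, fit = red_fit, delta = test$delta_ofv)
    }
    if (is.null(worst)) break
    cur_fit <- worst$fit
    cur <- cur_fit$estimates
    added <- setdiff(added, worst$nm)
    note("backward", worst$nm, cur_fit$ofv, worst$delta, NA, "removed")
  }
  list(model = cur, fit = cur_fit, selected = added,
       trace = do.call(rbind, trace))
}

#' Full covariate model: bootstrapped pregnancy effects on all parameters
#'
#' Adds the categorical pregnancy effect simultaneously on relative
#' bioavailability, both elimination clearances and mean transit time,
#' fits the model, and bootstraps it (stratified on pregnancy) to obtain
#' the distribution of each pregnancy effect. Percentiles are reported for
#' box-plot display against the +/-20% reference band conventionally taken
#' as the limit of clinical relevance.
#'
#' @param ds A `study_dataset`.
#' @param model Base [population_model()] (existing pregnancy effects are
#'   replaced by the four simultaneous ones).
#' @param n_boot Bootstrap replicates (>= 1).
#' @param seed Integer seed.
#' @param spec,fixed,control Passed to [fit()]/[bootstrap()].
#' @return List with `fit` (full-covariate `pk_fit`), `percentiles` (data
#'   frame: parameter, 10/25/50/75/90th percentiles of the pregnancy
#'   effect), `estimates` (replicate x parameter matrix), `ref_band`,
#'   `n_requested`, `n_successful`.
#' @export
full_covariate_model <- function(ds, model, n_boot = 500, seed = 1,
                                 spec = likelihood_spec(),
                                 fixed = character(), control = list()) {
  if (n_boot < 1) stop("n_boot must be >= 1")
  m <- model
  m$effects <- Filter(function(e) e$covariate != "preg", m$effects)
  for (p in c("f", "cl_ars", "cl_dha", "mtt")) {
    old <- model$effects[[paste0("beta_", p, "_preg")]]
    m$effects[[paste0("beta_", p, "_preg")]] <-
      covariate_effect("preg", p, theta = if (is.null(old)) 0 else old$theta,
                       ref = 0, lower = -0.95, upper = 5)
  }
  names(m$effects) <- vapply(m$effects, effect_name, character(1))
  full_fit <- fit(ds, m, spec = spec, fixed = fixed, control = control)
  bs <- bootstrap(ds, full_fit$estimates, n = n_boot, seed = seed,
                  spec = spec, fixed = fixed, control = control)
  pn <- paste0("beta_", c("f", "cl_ars", "cl_dha", "mtt"), "_preg")
  em <- bs$estimates[, pn, drop = FALSE]
  qs <- c(0.1, 0.25, 0.5, 0.75, 0.9)
  pct <- data.frame(parameter = rep(pn, each = length(qs)),
                    percentile = rep(100 * qs, length(pn)),
                    effect = as.vector(apply(em, 2, quantile, qs)))
  list(fit = full_fit, percentiles = pct, estimates = em,
       ref_band = c(-0.2, 0.2), n_requested = bs$n_requested,
       n_successful = bs$n_successful)
}
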