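#' Define a linear covariate effect on a structural parameter
#'
#' Covariate effects enter the typical value multiplicatively as
#' `1 + theta * (x - ref)`, the parameterization used for pregnancy
#' (`ref = 0`, `x` in 0/1), ALT and log parasite biomass in the final model.
#'
#' @param covariate Covariate name; one of `"preg"`, `"ega"`, `"lnpc"`,
#'   `"hb"`, `"ast"`, `"alt"`, `"bil"`, `"wt"`.
#' @param parameter Structural parameter the effect acts on; one of
#'   `"cl_ars"`, `"v_ars"`, `"cl_dha"`, `"v_dha"`, `"mtt"`, `"f"`.
#' @param theta Effect size (fraction per covariate unit).
#' @param ref Centering value subtracted from the covariate.
#' @param lower,upper Box bounds used when the effect is estimated; chosen to
#'   keep the multiplicative factor positive over the covariate range.
#' @return A `covariate_effect` object.
#' @export
covariate_effect <- function(covariate, parameter, theta = 0, ref = 0,
                             lower = -Inf, upper = Inf) {
  covariate <- match.arg(covariate,
                         c("preg", "ega", "lnpc", "hb", "ast", "alt", "bil", "wt"))
  parameter <- match.arg(parameter,
                         c("cl_ars", "v_ars", "cl_dha", "v_dha", "mtt", "f"))
  stopifnot(is.numeric(theta), length(theta) == 1L, lower <= upper)
  structure(list(covariate = covariate, parameter = parameter,
                 theta = theta, ref = ref, lower = lower, upper = upper),
            class = "covariate_effect")
}

effect_name <- function(e) paste0("beta_", e$parameter, "_", e$covariate)

#' Construct a population pharmacokinetic model
#'
#' Holds the fixed effects, inter-individual variability (IIV) variances,
#' residual variances and structural constants of the transit-absorption
#' artesunate (ARS) to dihydroartemisinin (DHA) drug-metabolite model:
#' a dose depot feeding `nn` transit compartments at a common rate
#' `ktr = (nn + 1) / MTT`, a one-compartment ARS disposition with complete
#' conversion into a one-compartment DHA disposition. Clearances carry
#' allometric weight scaling with exponent 0.75 and volumes with exponent 1,
#' centered at `wt_ref` kg.
#'
#' @param cl_ars,v_ars Apparent ARS elimination clearance (L/h) and central
#'   volume (L).
#' @param cl_dha,v_dha Apparent DHA elimination clearance (L/h) and volume (L).
#' @param mtt Mean transit time of absorption (h).
#' @param f_pop Typical relative bioavailability, fixed to 1.
#' @param effects List of [covariate_effect()] objects.
#' @param omega Named vector of IIV variances (log-normal, variance scale) for
#'   `cl_ars`, `cl_dha`, `mtt`, `f`.
#' @param sigma Named vector of additive log-scale residual variances for
#'   `ars` and `dha`.
#' @param nn Number of transit compartments (integer, fixed).
#' @param wt_ref Allometric centering weight (kg).
#' @return A `population_model` object.
#' @seealso [final_model()] for the published final estimates.
#' @export
population_model <- function(cl_ars, v_ars, cl_dha, v_dha, mtt, f_pop = 1,
                             effects = list(),
                             omega = c(cl_ars = 0, cl_dha = 0, mtt = 0, f = 0),
                             sigma = c(ars = 0, dha = 0),
                             nn = 3L, wt_ref = 52) {
  stopifnot(cl_ars > 0, v_ars > 0, cl_dha > 0, v_dha > 0, mtt > 0,
            f_pop > 0, nn >= 1)
  omega <- omega[c("cl_ars", "cl_dha", "mtt", "f")]
  sigma <- sigma[c("ars", "dha")]
  if (anyNA(omega) || any(omega < 0)) stop("omega must be named non-negative variances")
  if (anyNA(sigma) || any(sigma < 0)) stop("sigma must be named non-negative variances")
  stopifnot(all(vapply(effects, inherits, logical(1), "covariate_effect")))
  names(effects) <- vapply(effects, effect_name, character(1))
  if (anyDuplicated(names(effects)))
    stop("duplicate covariate effects")
  structure(list(cl_ars = cl_ars, v_ars = v_ars, cl_dha = cl_dha,
                 v_dha = v_dha, mtt = mtt, f_pop = f_pop, effects = effects,
                 omega = omega, sigma = sigma, nn = as.integer(nn),
                 wt_ref = wt_ref),
            class = "population_model")
}

#' Final published model of artesunate/dihydroartemisinin in pregnancy
#'
#' The final parameter estimates: CL_ARS/F 3570 L/h, V_ARS/F 1700 L,
#' CL_DHA/F 190 L/h, V_DHA/F 267 L, MTT 0.832 h, F fixed to 1, with a +21.4%
#' pregnancy effect on DHA clearance, +2.15%/IU ALT and +13.8%/log-unit
#' parasite-biomass effects on relative bioavailability (centered at
#' 20.75 IU and 5.88 log parasites), IIV variances 0.0672 (CL_ARS),
#' 0.00810 (CL_DHA), 0.320 (MTT), 0.0887 (F), and log-scale residual
#' variances 0.892 (ARS) and 0.660 (DHA).
#'
#' @return A [population_model()].
#' @export
final_model <- function() {
  population_model(
    cl_ars = 3570, v_ars = 1700, cl_dha = 190, v_dha = 267, mtt = 0.832,
    f_pop = 1,
    effects = list(
      covariate_effect("preg", "cl_dha", theta = 0.214, ref = 0,
                       lower = -1, upper = 5),
      covariate_effect("alt", "f", theta = 0.0215, ref = 20.75,
                       lower = -0.024, upper = 0.057),
      covariate_effect("lnpc", "f", theta = 0.138, ref = 5.88,
                       lower = -0.199, upper = 0.334)),
    omega = c(cl_ars = 0.0672, cl_dha = 0.00810, mtt = 0.320, f = 0.0887),
    sigma = c(ars = 0.892, dha = 0.660))
}

# Typical (eta = 0) individual parameter values for each row of a covariate
# data frame; returns an n x 6 matrix (tvclp, v2, tvclm, v3, tvmt, tvf1).
typical_values <- function(model, cov) {
  cov <- as.data.frame(cov)
  wtf <- cov$wt / model$wt_ref
  tv <- cbind(tvclp = model$cl_ars * wtf^0.75,
              v2    = model$v_ars * wtf,
              tvclm = model$cl_dha * wtf^0.75,
              v3    = model$v_dha * wtf,
              tvmt  = rep(model$mtt, nrow(cov)),
              tvf1  = rep(model$f_pop, nrow(cov)))
  slot <- c(cl_ars = 1L, v_ars = 2L, cl_dha = 3L, v_dha = 4L, mtt = 5L, f = 6L)
  for (e in model$effects) {
    x <- cov[[e$covariate]]
    if (is.null(x)) stop("covariate '", e$covariate, "' missing from data")
    tv[, slot[[e$parameter]]] <- tv[, slot[[e$parameter]]] *
      (1 + e$theta * (x - e$ref))
  }
  if (any(tv <= 0))
    stop("non-positive typical parameter value under the linear covariate model")
  tv
}

#' Realized individual parameters from covariates and random effects
#'
#' Applies allometric weight scaling, linear covariate effects and
#' log-normally distributed inter-individual random effects:
#' `CLP = CL_ARS (WT/52)^0.75 exp(eta1)`,
#' `CLM = CL_DHA (WT/52)^0.75 (1 + preg_effect * PREG) exp(eta2)`,
#' `MT = MTT exp(eta3)`,
#' `F1 = (1 + alt_effect (ALT - ref)) (1 + biomass_effect (LNPC - ref)) exp(eta4)`,
#' volumes scaled linearly with weight, and the transit rate constant
#' `ktr = (nn + 1) / MT`.
#'
#' @param model A [population_model()].
#' @param cov Single-subject covariates (named list or one-row data frame
#'   with at least the covariates the model uses, plus `wt`).
#' @param eta Numeric vector of 4 random effects in the order
#'   CL_ARS, CL_DHA, MTT, F.
#' @return An `individual_parameters` object with elements `clp`, `v2`,
#'   `clm`, `v3`, `mt`, `f1`, `ktr` and `nn`.
#' @examples
#' ind <- individual_parameters(final_model(),
#'   list(wt = 52, preg = 0, alt = 20.75, lnpc = 5.88), eta = rep(0, 4))
#' ind$clm   # 190 L/h for the typical non-pregnant subject
#' @export
individual_parameters <- function(model, cov, eta = rep(0, 4)) {
  stopifnot(inherits(model, "population_model"), length(eta) == 4L,
            all(is.finite(eta)))
  tv <- typical_values(model, as.data.frame(as.list(cov))[1, , drop = FALSE])
  out <- list(clp = tv[1, "tvclp"] * exp(eta[1]),
              v2  = unname(tv[1, "v2"]),
              clm = tv[1, "tvclm"] * exp(eta[2]),
              v3  = unname(tv[1, "v3"]),
              mt  = tv[1, "tvmt"] * exp(eta[3]),
              f1  = tv[1, "tvf1"] * exp(eta[4]))
  out <- lapply(out, unname)
  if (any(unlist(out) <= 0)) stop("non-positive individual parameter")
  out$ktr <- (model$nn + 1) / out$mt
  out$nn <- model$nn
  structure(out, class = "individual_parameters")
}

#' @export
print.population_model <- function(x, ...) {
  cat("Population PK model (transit absorption, ARS -> DHA)\n")
  cat(sprintf("  CL_ARS/F %.4g L/h   V_ARS/F %.4g L\n", x$cl_ars, x$v_ars))
  cat(sprintf("  CL_DHA/F %.4g L/h   V_DHA/F %.4g L\n", x$cl_dha, x$v_dha))
  cat(sprintf("  MTT %.4g h   F %.4g   transit compartments %d\n",
              x$mtt, x$f_pop, x$nn))
  for (e in x$effects)
    cat(sprintf("  effect %s on %s: %.4g (ref %.4g)\n",
                e$covariate, e$parameter, e$theta, e$ref))
  cat("  omega2:", paste(sprintf("%s=%.4g", names(x$omega), x$omega),
                         collapse = " "), "\n")
  cat("  sigma2:", paste(sprintf("%s=%.4g", names(x$sigma), x$sigma),
                         collapse = " "), "\n")
  invisible(x)
}
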