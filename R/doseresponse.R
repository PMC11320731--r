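#' Four-parameter logistic (4PL) concentration-response model
#'
#' `y = basal + (emax - basal) / (1 + 10^((log_ec50 - x) * hill))` with
#' `x` the log10 molar concentration. This is the standard
#' concentration-response form for BRET-style recruitment data; with
#' `hill = 1` it reduces to the three-parameter law of mass action.
#'
#' @param x log10 concentration (M)
#' @param emax maximal response
#' @param log_ec50 log10 EC50 (M)
#' @param hill Hill slope
#' @param basal response at zero agonist (fixed to 0 in the standard
#'   analysis)
#' @return predicted response
#' @export
fourpl <- function(x, emax, log_ec50, hill, basal = 0) {
  basal + (emax - basal) / (1 + 10^((log_ec50 - x) * hill))
}

check_dose_data <- function(data) {
  data <- tibble::as_tibble(data)
  if (!all(c("log10_conc", "response") %in% names(data))) {
    abort("dose-response data needs columns `log10_conc` and `response`")
  }
  if (!all(is.finite(data$log10_conc))) abort("non-finite concentrations")
  if (!all(is.finite(data$response))) abort("non-finite responses")
  if (length(unique(data$log10_conc)) < 4) {
    abort("need at least 4 distinct concentrations")
  }
  data
}

# residual function and multistart grid shared by single and shared fits
fourpl_resid <- function(par, x, y, fix_basal) {
  basal <- if (fix_basal) 0 else par[["basal"]]
  y - fourpl(x, par[["emax"]], par[["log_ec50"]], par[["hill"]], basal)
}

fourpl_starts <- function(x, y, n_ec50 = 5, hills = c(0.5, 1, 2)) {
  rng <- range(x)
  ec <- seq(rng[1], rng[2], length.out = n_ec50)
  emax0 <- unique(c(max(y), min(y)))
  tidyr::crossing(emax = emax0, log_ec50 = ec, hill = hills)
}

#' Fit a 4PL concentration-response curve
#'
#' Unweighted least squares via Levenberg-Marquardt
#' ([minpack.lm::nls.lm()]) with a deterministic multistart grid
#' (log EC50 spread over the observed concentration range, Hill slopes
#' 0.5/1/2, Emax at the extreme observed responses; best final SS wins,
#' ties to the first start). The basal response is fixed to zero unless
#' `fix_basal = FALSE`. Standard errors come from the Jacobian at the
#' optimum; a singular Jacobian (e.g. flat data) flags the fit
#' ill-conditioned instead of failing silently.
#'
#' @param data data frame with `log10_conc` and `response` (replicates
#'   as repeated rows)
#' @param fix_basal fix the basal response to zero (default)
#' @param n_ec50 log EC50 grid points in the multistart (default 5)
#' @param hills Hill-slope starts (default 0.5, 1, 2)
#' @return a `drc_fit`
#' @export
fit_4pl <- function(data, fix_basal = TRUE, n_ec50 = 5,
                    hills = c(0.5, 1, 2)) {
  data <- check_dose_data(data)
  x <- data$log10_conc
  y <- data$response
  starts <- fourpl_starts(x, y, n_ec50 = n_ec50, hills = hills)
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    par <- c(emax = starts$emax[i], log_ec50 = starts$log_ec50[i],
             hill = starts$hill[i])
    if (!fix_basal) par <- c(par, basal = 0)
    fit <- tryCatch(
      minpack.lm::nls.lm(par, fn = fourpl_resid, x = x, y = y,
                         fix_basal = fix_basal,
                         control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL
    )
    if (is.null(fit)) next
    ss <- fit$deviance
    if (is.null(best) || ss < best$deviance - 1e-12) best <- fit
  }
  if (is.null(best)) abort("4PL fit failed from every start")
  p <- length(best$par)
  n <- length(y)
  df <- n - p
  rss <- best$deviance
  se <- rep(NA_real_, p)
  ill <- FALSE
  h <- best$hessian
  ev <- eigen(h, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) > max(ev) * 1e-10 && df > 0) {
    se <- sqrt(diag(solve(h)) * rss / df)
  } else {
    ill <- TRUE
  }
  coefs <- unlist(best$par)
  if (fix_basal) {
    coefs <- c(coefs, basal = 0)
    se <- c(se, NA_real_)
  }
  structure(list(
    coefficients = coefs,
    se = setNames(se, names(coefs)),
    rss = rss, df = df, n = n,
    converged = best$info %in% 1:3,
    ill_conditioned = ill,
    fix_basal = fix_basal,
    data = data
  ), class = "drc_fit")
}

#' @export
print.drc_fit <- function(x, ...) {
  cat("<drc_fit> 4PL fit", if (x$fix_basal) "(basal fixed to 0)" else "", "\n")
  print(round(x$coefficients, 4))
  cat(sprintf("RSS %.4g on %d df%s%s\n", x$rss, x$df,
              if (!x$converged) " [not converged]" else "",
              if (x$ill_conditioned) " [ill-conditioned]" else ""))
  invisible(x)
}

#' @export
coef.drc_fit <- function(object, ...) object$coefficients

#' @export
tidy.drc_fit <- function(x, ...) {
  tibble::tibble(term = names(x$coefficients),
                 estimate = unname(x$coefficients),
                 std.error = unname(x$se[names(x$coefficients)]))
}

#' @export
glance.drc_fit <- function(x, ...) {
  tibble::tibble(rss = x$rss, df = x$df, nobs = x$n,
                 converged = x$converged,
                 ill_conditioned = x$ill_conditioned)
}

#' @export
predict.drc_fit <- function(object, newdata = NULL, ...) {
  x <- if (is.null(newdata)) object$data$log10_conc else newdata$log10_conc
  cf <- object$coefficients
  fourpl(x, cf[["emax"]], cf[["log_ec50"]], cf[["hill"]], cf[["basal"]])
}

#' Joint 4PL fit with one parameter shared across conditions
#'
#' Fits all conditions simultaneously with `share` (`"emax"`,
#' `"log_ec50"` or `"hill"`) constrained equal across conditions and
#' the remaining parameters free per condition. This is the global
#' model of the extra sum-of-squares comparison.
#'
#' @param data data frame with `condition`, `log10_conc`, `response`
#' @param share parameter to share
#' @param fix_basal fix basal to zero (default)
#' @param independent_fits optional list of per-condition `drc_fit`
#'   objects (in `unique(data$condition)` order) used as starting
#'   values; fitted here when omitted
#' @return a `drc_shared_fit` with `rss`, `df` and per-condition
#'   coefficients
#' @export
fit_4pl_shared <- function(data, share = c("emax", "log_ec50", "hill"),
                           fix_basal = TRUE, independent_fits = NULL) {
  share <- match.arg(share)
  data <- tibble::as_tibble(data)
  if (!"condition" %in% names(data)) abort("data needs a `condition` column")
  conds <- unique(data$condition)
  if (length(conds) < 2) abort("shared fit needs at least two conditions")
  split_data <- lapply(conds, function(cc) {
    check_dose_data(data[data$condition == cc, ])
  })
  per_free <- setdiff(c("emax", "log_ec50", "hill"), share)
  # start from the independent fits
  indep <- independent_fits %||%
    lapply(split_data, fit_4pl, fix_basal = fix_basal)
  start_shared <- mean(vapply(indep, function(f) {
    f$coefficients[[share]]
  }, numeric(1)))
  par0 <- c(setNames(start_shared, share),
            unlist(lapply(seq_along(conds), function(i) {
              setNames(indep[[i]]$coefficients[per_free],
                       paste0(per_free, "_", i))
            })))
  resid_all <- function(par) {
    unlist(lapply(seq_along(conds), function(i) {
      d <- split_data[[i]]
      cf <- c(setNames(par[[share]], share),
              setNames(par[paste0(per_free, "_", i)], per_free))
      d$response - fourpl(d$log10_conc, cf[["emax"]], cf[["log_ec50"]],
                          cf[["hill"]],
                          basal = if (fix_basal) 0 else cf[["basal"]])
    }))
  }
  fit <- minpack.lm::nls.lm(par0, fn = resid_all,
                            control = minpack.lm::nls.lm.control(maxiter = 500))
  n <- sum(vapply(split_data, nrow, integer(1)))
  p <- length(par0)
  structure(list(
    share = share, conditions = conds,
    coefficients = unlist(fit$par),
    rss = fit$deviance, df = n - p, n = n,
    converged = fit$info %in% 1:3,
    independent_fits = indep
  ), class = "drc_shared_fit")
}

#' @export
print.drc_shared_fit <- function(x, ...) {
  cat(sprintf("<drc_shared_fit> %s shared across %d conditions\n",
              x$share, length(x$conditions)))
  cat(sprintf("RSS %.4g on %d df\n", x$rss, x$df))
  invisible(x)
}

#' Extra sum-of-squares F test
#'
#' Compares independent per-condition fits (the full model) with a
#' global fit sharing one parameter (the nested model):
#' `F = ((SS_shared - SS_indep) / (df_shared - df_indep)) /
#' (SS_indep / df_indep)`, with the p-value from the F distribution.
#' A shared SS materially below the independent SS signals an optimiser
#' failure and raises an error.
#'
#' @param fits_independent list of `drc_fit` objects (or a single
#'   `drc_shared_fit`'s `independent_fits`)
#' @param fit_shared a `drc_shared_fit`
#' @return tibble with `F`, `p`, `df1`, `df2`, `ss_indep`, `ss_shared`
#' @export
ess_f_test <- function(fits_independent, fit_shared) {
  ss_i <- sum(vapply(fits_independent, function(f) f$rss, numeric(1)))
  df_i <- sum(vapply(fits_independent, function(f) f$df, numeric(1)))
  f_test_ess(ss_i, df_i, fit_shared$rss, fit_shared$df)
}

#' @rdname ess_f_test
#' @param ss_indep,df_indep,ss_shared,df_shared sums of squares and
#'   degrees of freedom of the two nested models
#' @export
f_test_ess <- function(ss_indep, df_indep, ss_shared, df_shared) {
  if (df_shared <= df_indep) {
    abort("models are not nested: shared fit must have more df")
  }
  if (ss_shared < ss_indep - 1e-8 * max(1, ss_indep)) {
    abort("shared fit has lower SS than independent fits (optimizer failure)")
  }
  df1 <- df_shared - df_indep
  f <- max(0, (ss_shared - ss_indep) / df1) / (ss_indep / df_indep)
  tibble::tibble(F = f, p = pf(f, df1, df_indep, lower.tail = FALSE),
                 df1 = df1, df2 = df_indep,
                 ss_indep = ss_indep, ss_shared = ss_shared)
}

#' Normalise responses to the vehicle maximum
#'
#' Expresses every response as a percentage of the maximal response of
#' a reference (no-modulator) condition, so the reference condition's
#' maximum maps to 100%.
#'
#' @param data data frame with `condition`, `log10_conc`, `response`
#' @param reference label of the reference condition
#' @param method `"observed"` (max of per-concentration mean responses,
#'   default) or `"fitted"` (Emax of a 4PL fit to the reference)
#' @return data with `response` rescaled to percent; the reference
#'   maximum is attached as attribute `reference_max`
#' @export
normalize_percent_vehicle_max <- function(data, reference,
                                          method = c("observed", "fitted")) {
  method <- match.arg(method)
  data <- tibble::as_tibble(data)
  if (!"condition" %in% names(data)) abort("data needs a `condition` column")
  ref <- data[data$condition == reference, ]
  if (nrow(ref) == 0) {
    abort(paste0("reference condition not found: ", reference))
  }
  ref_max <- if (method == "observed") {
    means <- tapply(ref$response, ref$log10_conc, mean)
    max(means)
  } else {
    fit_4pl(ref)$coefficients[["emax"]]
  }
  if (!is.finite(ref_max) || ref_max == 0) {
    abort("reference maximum is zero; cannot normalise")
  }
  data$response <- 100 * data$response / ref_max
  attr(data, "reference_max") <- ref_max
  data
}
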