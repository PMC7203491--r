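## Random-coefficient regression (RCR): linear mixed models with per-subject
## random intercepts and slopes, REML estimation, Wald inference. Only the
## first scan of each session enters these models; same-session replicates
## are reserved for the reliability analyses.

first_scans <- function(cohort) cohort[cohort$replicate == 1L, , drop = FALSE]

## tight optimizer tolerances so that algebraically equivalent
## reparametrisations (time shifts, covariate recentring) agree numerically
rcr_control <- function() {
  lme4::lmerControl(optimizer = "bobyqa", check.conv.singular = "ignore",
                    optCtrl = list(rhoend = 1e-10, maxfun = 100000))
}

coef_table <- function(est, V, level = 0.95) {
  se <- sqrt(pmax(diag(as.matrix(V)), 0))
  z <- qnorm(1 - (1 - level) / 2)
  stat <- ifelse(se == 0, ifelse(est == 0, 0, Inf), est / se)
  data.frame(
    term = names(est),
    estimate = as.numeric(est),
    se = se,
    z = stat,
    p = ifelse(is.infinite(stat), 0, 2 * pnorm(-abs(stat))),
    lower = est - z * se,
    upper = est + z * se,
    stringsAsFactors = FALSE,
    row.names = NULL
  )
}

## Wald F-test (1 numerator df, normal reference) of c'beta = 0.
wald_contrast <- function(contrast, est, V) {
  val <- sum(contrast * est)
  v <- as.numeric(t(contrast) %*% as.matrix(V) %*% contrast)
  if (v <= 0) {
    return(list(estimate = val, se = 0, f = if (val == 0) 0 else Inf,
                p = as.numeric(val == 0)))
  }
  f <- val^2 / v
  list(estimate = val, se = sqrt(v), f = f, p = pchisq(f, 1, lower.tail = FALSE))
}

## Fit `fixed` with per-subject random intercept + slope on `time_var`.
## Deterministic data (zero OLS residual) short-circuits to the exact OLS
## solution with zero covariance; singular random-effect fits are refit with
## a diagonal (uncorrelated) covariance and flagged.
fit_rcr_engine <- function(fixed, data, time_var, level = 0.95) {
  ols <- lm(fixed, data = data)
  if (nrow(data) > length(coef(ols)) &&
      sqrt(mean(residuals(ols)^2)) < 1e-10) {
    est <- coef(ols)
    V <- matrix(0, length(est), length(est), dimnames = list(names(est), names(est)))
    return(list(coefficients = coef_table(est, V, level), vcov = V,
                ranef = c(sd_intercept = 0, sd_slope = 0, corr = NA_real_),
                sigma = 0, converged = TRUE, singular = FALSE,
                refit_diagonal = FALSE, exact = TRUE))
  }
  form <- as.formula(paste(paste(deparse(fixed), collapse = " "), "+ (", time_var, "| subject)"))
  converged <- TRUE
  fit <- withCallingHandlers(
    lme4::lmer(form, data = data, REML = TRUE,
               control = rcr_control()),
    warning = function(w) {
      if (grepl("converge", conditionMessage(w), ignore.case = TRUE)) {
        converged <<- FALSE
      }
      invokeRestart("muffleWarning")
    },
    message = function(m) invokeRestart("muffleMessage")
  )
  refit_diagonal <- FALSE
  if (lme4::isSingular(fit, tol = 1e-5)) {
    refit_diagonal <- TRUE
    form2 <- as.formula(paste(paste(deparse(fixed), collapse = " "), "+ (", time_var, "|| subject)"))
    converged <- TRUE
    fit <- withCallingHandlers(
      lme4::lmer(form2, data = data, REML = TRUE,
                 control = rcr_control()),
      warning = function(w) {
        if (grepl("converge", conditionMessage(w), ignore.case = TRUE)) {
          converged <<- FALSE
        }
        invokeRestart("muffleWarning")
      },
      message = function(m) invokeRestart("muffleMessage")
    )
  }
  est <- lme4::fixef(fit)
  V <- as.matrix(vcov(fit))
  vc <- lme4::VarCorr(fit)$subject
  sds <- attr(vc, "stddev")
  corr <- attr(vc, "correlation")
  ranef <- c(
    sd_intercept = unname(sds["(Intercept)"]),
    sd_slope = if (time_var %in% names(sds)) unname(sds[time_var]) else {
      # diagonal refit stores the slope in a second variance term
      other <- setdiff(names(sds), "(Intercept)")
      if (length(other)) unname(sds[other[1]]) else 0
    },
    corr = if (!refit_diagonal && !is.null(corr) && nrow(corr) > 1)
      corr[2, 1] else NA_real_
  )
  if (refit_diagonal) {
    vc_all <- lme4::VarCorr(fit)
    sds_all <- unlist(lapply(vc_all, function(v) attr(v, "stddev")))
    ints <- sds_all[grepl("Intercept", names(sds_all))]
    slps <- sds_all[!grepl("Intercept", names(sds_all))]
    ranef <- c(sd_intercept = if (length(ints)) unname(ints[1]) else 0,
               sd_slope = if (length(slps)) unname(slps[1]) else 0,
               corr = NA_real_)
  }
  list(coefficients = coef_table(est, V, level), vcov = V, ranef = ranef,
       sigma = stats::sigma(fit), converged = converged,
       singular = lme4::isSingular(fit, tol = 1e-5),
       refit_diagonal = refit_diagonal, exact = FALSE)
}

#' Fit the random-coefficient regression model for one region
#'
#' Models regional gray-matter density as a linear function of time since the
#' 1st MRI, with per-subject random intercepts and slopes (unstructured 2x2
#' covariance, REML). With `groups = "both"` the fixed effects are intercept
#' (the age- and gender-adjusted HC mean at the 1st MRI), group (AD-HC
#' baseline difference), time (HC slope in GMD/month), group x time (AD-HC
#' slope difference), age at 1st MRI (years) and gender (female reference).
#' With `groups = "ad_only"` the model reduces to intercept + time on the AD
#' rows; this is the fit that feeds the detection-interval statistic.
#' Only the first scan of each session is used.
#'
#' @param cohort Long-format cohort table (see [simulate_cohort()]).
#' @param region Region label.
#' @param groups `"both"` (default) or `"ad_only"`.
#' @param level Confidence level for Wald intervals.
#' @return Object of class `rcr_fit`: `coefficients` (term, estimate, se, z,
#'   p, lower, upper), `vcov` (fixed-effect covariance), `ranef`
#'   (random-effect SDs and correlation), `sigma`, `converged`, `singular`,
#'   `refit_diagonal`, `exact` (deterministic-data path), plus metadata.
#' @export
fit_rcr_region <- function(cohort, region, groups = c("both", "ad_only"),
                           level = 0.95) {
  groups <- match.arg(groups)
  d <- first_scans(cohort)
  d <- d[d$region == region, , drop = FALSE]
  if (!nrow(d)) stop("no rows for region '", region, "'")
  if (groups == "both") {
    if (!all(c("AD", "HC") %in% d$group)) stop("both groups must be present")
    d$group <- factor(d$group, levels = c("HC", "AD"))
    d$gender <- factor(d$gender, levels = c("F", "M"))
    fixed <- gmd ~ month * group + age + gender
  } else {
    d <- d[d$group == "AD", , drop = FALSE]
    if (!nrow(d)) stop("no AD rows for region '", region, "'")
    fixed <- gmd ~ month
  }
  eng <- fit_rcr_engine(fixed, d, "month", level)
  eng$groups <- groups
  eng$region <- region
  eng$n_subjects <- length(unique(d$subject))
  eng$n_obs <- nrow(d)
  eng$level <- level
  class(eng) <- "rcr_fit"
  eng
}

rcr_coef <- function(fit, term) {
  i <- match(term, fit$coefficients$term)
  if (is.na(i)) stop("term '", term, "' not in fit")
  fit$coefficients$estimate[i]
}

#' Build a minimal AD-only fit object from explicit parameter values
#'
#' Convenience constructor for working directly with the detection-interval
#' machinery when the intercept/slope estimates and their uncertainties are
#' known (e.g. reported values or hand-constructed fixtures).
#'
#' @param beta0,beta1 Intercept (GMD at 1st MRI) and slope (GMD/month).
#' @param se0,se1 Their standard errors.
#' @param cov01 Covariance between the two estimates, default 0.
#' @return An `rcr_fit` (AD-only form).
#' @export
rcr_params <- function(beta0, beta1, se0, se1, cov01 = 0) {
  est <- c("(Intercept)" = beta0, month = beta1)
  V <- matrix(c(se0^2, cov01, cov01, se1^2), 2, 2,
              dimnames = list(names(est), names(est)))
  structure(
    list(coefficients = coef_table(est, V), vcov = V,
         ranef = c(sd_intercept = NA, sd_slope = NA, corr = NA),
         sigma = NA_real_, converged = TRUE, singular = FALSE,
         refit_diagonal = FALSE, exact = FALSE, groups = "ad_only",
         region = NA_character_, n_subjects = NA_integer_,
         n_obs = NA_integer_, level = 0.95),
    class = "rcr_fit"
  )
}

#' Percent baseline deficit and percent faster decline in AD
#'
#' Converts a two-group `rcr_fit` into the two headline percentages: how much
#' lower the adjusted AD baseline is than the HC baseline,
#' `100 * (-group) / intercept`, and how much faster AD declines,
#' `100 * (slope_AD - slope_HC) / slope_HC` with
#' `slope_AD = time + group x time`. With both slopes negative, a positive
#' percentage means AD declines faster. The slope percentage is `NA` when
#' the HC slope is within `slope_floor` of zero.
#'
#' @param fit An `rcr_fit` with `groups = "both"`.
#' @param slope_floor Smallest |HC slope| for which the ratio is reported.
#' @return List `baseline_pct_lower`, `slope_pct_faster`.
#' @export
group_percent_difference <- function(fit, slope_floor = 1e-8) {
  stopifnot(inherits(fit, "rcr_fit"), fit$groups == "both")
  if (!fit$converged) stop("fit did not converge")
  b0 <- rcr_coef(fit, "(Intercept)")
  if (b0 <= 0) stop("nonpositive HC intercept")
  grp <- rcr_coef(fit, "groupAD")
  slope_hc <- rcr_coef(fit, "month")
  inter <- rcr_coef(fit, "month:groupAD")
  list(
    baseline_pct_lower = 100 * (-grp) / b0,
    slope_pct_faster = if (abs(slope_hc) < slope_floor) NA_real_
                       else 100 * inter / slope_hc
  )
}

#' Group-specific MMSE trends over time
#'
#' Random-coefficient regression of MMSE on months since the 1st MRI with
#' group-specific intercepts and slopes (cell-means coding) and per-subject
#' random intercept + slope. Group differences in intercept and slope, and
#' each group's slope against zero, are tested with Wald F-tests (1
#' numerator df, normal reference).
#'
#' @param cohort Long-format cohort table.
#' @param level Confidence level.
#' @return List with `coefficients` (per-group intercepts `groupAD`,
#'   `groupHC` and slopes `groupAD:month`, `groupHC:month`), `tests` (data
#'   frame of F-tests: AD slope = 0, HC slope = 0, intercept difference,
#'   slope difference) and the underlying engine fit fields.
#' @export
mmse_trend <- function(cohort, level = 0.95) {
  d <- first_scans(cohort)
  d <- unique(d[c("subject", "group", "month", "mmse")])
  d <- d[complete.cases(d), , drop = FALSE]
  if (!nrow(d)) stop("no MMSE values present")
  d$group <- factor(d$group, levels = c("AD", "HC"))
  eng <- fit_rcr_engine(mmse ~ 0 + group + group:month, d, "month", level)
  est <- setNames(eng$coefficients$estimate, eng$coefficients$term)
  terms <- names(est)
  cvec <- function(on) as.numeric(terms %in% on[1]) - if (length(on) > 1)
    as.numeric(terms %in% on[2]) else 0
  tests <- rbind(
    data.frame(test = "AD slope = 0",
               as.data.frame(wald_contrast(cvec("groupAD:month"), est, eng$vcov))),
    data.frame(test = "HC slope = 0",
               as.data.frame(wald_contrast(cvec("groupHC:month"), est, eng$vcov))),
    data.frame(test = "intercept AD - HC",
               as.data.frame(wald_contrast(cvec(c("groupAD", "groupHC")), est,
                                           eng$vcov))),
    data.frame(test = "slope AD - HC",
               as.data.frame(wald_contrast(cvec(c("groupAD:month",
                                                  "groupHC:month")), est,
                                           eng$vcov)))
  )
  c(eng, list(tests = tests))
}

#' Change-change regression: MMSE change on GMD change
#'
#' Computes per-subject changes from the 1st-MRI visit at every follow-up
#' visit (first scans only) and fits a random-coefficient regression of
#' MMSE change on GMD change with group-specific intercepts and slopes and a
#' per-subject random intercept. Per-group slope F-tests and the
#' between-group slope contrast are returned; across a region family the
#' p-values feed [apply_correction()].
#'
#' @param cohort Long-format cohort table.
#' @param region Region label.
#' @param level Confidence level.
#' @return List with `coefficients`, `tests` (AD slope = 0, HC slope = 0,
#'   slope AD - HC), `n_changes`, plus engine fit fields.
#' @export
change_change_rcr <- function(cohort, region, level = 0.95) {
  d <- first_scans(cohort)
  d <- d[d$region == region, , drop = FALSE]
  base <- d[d$month == 0, c("subject", "gmd", "mmse")]
  names(base) <- c("subject", "gmd0", "mmse0")
  fu <- merge(d[d$month > 0, ], base, by = "subject")
  fu$dgmd <- fu$gmd - fu$gmd0
  fu$dmmse <- fu$mmse - fu$mmse0
  fu <- fu[complete.cases(fu[c("dgmd", "dmmse")]), , drop = FALSE]
  if (!nrow(fu)) stop("no follow-up changes available")
  if (var(fu$dgmd) == 0) stop("degenerate (constant) GMD change")
  fu$group <- factor(fu$group, levels = c("AD", "HC"))

  ols <- lm(dmmse ~ 0 + group + group:dgmd, data = fu)
  if (sqrt(mean(residuals(ols)^2)) < 1e-10) {
    est <- coef(ols)
    V <- matrix(0, length(est), length(est),
                dimnames = list(names(est), names(est)))
    eng <- list(coefficients = coef_table(est, V, level), vcov = V,
                sigma = 0, converged = TRUE, singular = FALSE, exact = TRUE)
  } else {
    fit <- suppressWarnings(suppressMessages(
      lme4::lmer(dmmse ~ 0 + group + group:dgmd + (1 | subject), data = fu,
                 REML = TRUE,
                 control = rcr_control())
    ))
    est <- lme4::fixef(fit)
    V <- as.matrix(vcov(fit))
    eng <- list(coefficients = coef_table(est, V, level), vcov = V,
                sigma = stats::sigma(fit), converged = TRUE,
                singular = lme4::isSingular(fit, tol = 1e-5), exact = FALSE)
  }
  terms <- names(est)
  cvec <- function(on) as.numeric(terms %in% on[1]) - if (length(on) > 1)
    as.numeric(terms %in% on[2]) else 0
  tests <- rbind(
    data.frame(test = "AD slope = 0",
               as.data.frame(wald_contrast(cvec("groupAD:dgmd"), est, V))),
    data.frame(test = "HC slope = 0",
               as.data.frame(wald_contrast(cvec("groupHC:dgmd"), est, V))),
    data.frame(test = "slope AD - HC",
               as.data.frame(wald_contrast(cvec(c("groupAD:dgmd",
                                                  "groupHC:dgmd")), est, V)))
  )
  c(eng, list(tests = tests, n_changes = nrow(fu), region = region))
}
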