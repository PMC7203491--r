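## Test-retest agreement between the two same-session scans: percent change,
## one-way ICC with Searle's exact F interval, the multivariate image
## intraclass correlation (trace-ratio I2C2) with a subject bootstrap, and
## Bland-Altman ratio analysis on the log scale.

#' Percent change between replicate measurements
#'
#' `100 * (second - first) / first`, the within-session percent change of the
#' 2nd scan relative to the 1st.
#'
#' @param first,second Numeric vectors; `first` must be strictly positive.
#' @return Percent change (vectorised).
#' @export
percent_change <- function(first, second) {
  if (any(first <= 0)) stop("first measurement must be > 0")
  100 * (second - first) / first
}

#' Extract same-session replicate pairs from a cohort table
#'
#' @param cohort Long-format cohort table (see [simulate_cohort()]).
#' @param region Region label to extract.
#' @return Data frame `subject`, `group`, `month`, `first`, `second`, one row
#'   per subject-session that has both replicates.
#' @export
replicate_pairs <- function(cohort, region) {
  x <- cohort[cohort$region == region, , drop = FALSE]
  r1 <- x[x$replicate == 1L, c("subject", "group", "month", "gmd")]
  r2 <- x[x$replicate == 2L, c("subject", "month", "gmd")]
  names(r1)[4] <- "first"
  names(r2)[3] <- "second"
  out <- merge(r1, r2, by = c("subject", "month"))
  out <- out[order(out$subject, out$month), c("subject", "group", "month",
                                              "first", "second")]
  rownames(out) <- NULL
  out
}

## Wald summary line; SE == 0 handled so that noise-free fits give exact
## estimates with p = 1 when the estimate itself is 0.
wald_line <- function(est, se, level = 0.95) {
  z <- qnorm(1 - (1 - level) / 2)
  p <- if (se == 0) as.numeric(est == 0) else 2 * pnorm(-abs(est / se))
  c(estimate = est, se = se, lower = est - z * se, upper = est + z * se, p = p)
}

#' Within-session percent-change model
#'
#' Models the per-session percent change between the 1st and 2nd same-session
#' scans with a fixed intercept (the HC mean % change), a fixed AD-vs-HC
#' difference, and a per-subject random intercept (subjects contribute up to
#' three replicate sessions). Inference is Wald (normal reference). When the
#' data are exactly deterministic (zero residual), the fixed effects are
#' taken from ordinary least squares with zero standard errors.
#'
#' @param pairs Data frame from [replicate_pairs()] (columns `subject`,
#'   `group`, `first`, `second`).
#' @param level Confidence level, default 0.95.
#' @return List with `intercept` and `difference` (each a named vector
#'   `estimate`, `se`, `lower`, `upper`, `p`), `n_sessions`, `n_subjects`.
#' @export
within_session_change_model <- function(pairs, level = 0.95) {
  if (!all(c("AD", "HC") %in% pairs$group)) stop("both groups must be present")
  pairs$pct <- percent_change(pairs$first, pairs$second)
  pairs$group <- factor(pairs$group, levels = c("HC", "AD"))
  if (nrow(pairs) < 3L) stop("fewer sessions than model parameters")

  ols <- lm(pct ~ group, data = pairs)
  if (sd(residuals(ols)) < 1e-12 || length(unique(pairs$subject)) < 3L) {
    est <- coef(ols)
    out <- list(intercept = wald_line(unname(est[1]), 0, level),
                difference = wald_line(unname(est[2]), 0, level))
  } else {
    fit <- suppressWarnings(suppressMessages(
      lme4::lmer(pct ~ group + (1 | subject), data = pairs, REML = TRUE,
                 control = rcr_control())
    ))
    est <- lme4::fixef(fit)
    se <- sqrt(diag(as.matrix(vcov(fit))))
    out <- list(intercept = wald_line(unname(est[1]), unname(se[1]), level),
                difference = wald_line(unname(est[2]), unname(se[2]), level))
  }
  out$n_sessions <- nrow(pairs)
  out$n_subjects <- length(unique(pairs$subject))
  out
}

#' One-way random-effects intraclass correlation with exact confidence interval
#'
#' ICC(1) from a one-way ANOVA on replicate measurements of n entities
#' (k = 2 replicates each): `ICC = (MSB - MSW) / (MSB + (k-1) MSW)`. The
#' exact confidence interval follows Searle's F-based construction: with
#' `F0 = MSB/MSW` on (n-1, n(k-1)) degrees of freedom,
#' `FL = F0 / qf(1-a/2, n-1, n(k-1))`, `FU = F0 * qf(1-a/2, n(k-1), n-1)`,
#' and each limit maps through `(F - 1) / (F + k - 1)`.
#'
#' @param first,second Numeric vectors of paired replicate measurements, or a
#'   two-column matrix/data frame passed as `first`.
#' @param level Confidence level, default 0.95.
#' @return List `icc`, `lower`, `upper`, `msb`, `msw`, `n`.
#' @export
icc_oneway <- function(first, second = NULL, level = 0.95) {
  if (is.null(second)) {
    m <- as.matrix(first)
    stopifnot(ncol(m) == 2L)
    first <- m[, 1]; second <- m[, 2]
  }
  n <- length(first)
  if (n < 3L) stop("need at least 3 replicate pairs")
  k <- 2
  mean_i <- (first + second) / 2
  grand <- mean(c(first, second))
  ssb <- k * sum((mean_i - grand)^2)
  ssw <- sum((first - mean_i)^2 + (second - mean_i)^2)
  msb <- ssb / (n - 1)
  msw <- ssw / (n * (k - 1))
  if (msb + msw == 0) stop("zero total variance: ICC undefined")
  icc <- (msb - msw) / (msb + (k - 1) * msw)
  if (msw == 0) {
    lower <- upper <- 1
  } else {
    a <- 1 - level
    f0 <- msb / msw
    fl <- f0 / qf(1 - a / 2, n - 1, n * (k - 1))
    fu <- f0 * qf(1 - a / 2, n * (k - 1), n - 1)
    lower <- (fl - 1) / (fl + k - 1)
    upper <- (fu - 1) / (fu + k - 1)
  }
  list(icc = icc, lower = lower, upper = upper, msb = msb, msw = msw, n = n)
}

#' Image intraclass correlation coefficient (I2C2)
#'
#' Multivariate extension of the ICC to a vector of regions measured per
#' scan: the moment (trace-ratio) estimator
#' \deqn{I2C2 = 1 - tr(\hat\Sigma_U) / tr(\hat\Sigma_W),}
#' where the within-subject (measurement-error) trace is estimated from
#' deviations of replicate scans around subject means,
#' `sum_ij ||W_ij - Wbar_i||^2 / sum_i (J_i - 1)`, and the total trace from
#' deviations of all scans around the grand mean,
#' `sum_ij ||W_ij - Wbar||^2 / (N - 1)`. Equals the univariate variance
#' ratio `1 - sigma2_U / sigma2_W` when there is a single region, and 1 when
#' replicates agree exactly.
#'
#' @param values Numeric matrix, one row per scan, one column per region.
#' @param subject Vector of subject (entity) identifiers, one per row.
#' @return The I2C2 estimate (scalar).
#' @export
i2c2 <- function(values, subject) {
  values <- as.matrix(values)
  subject <- as.character(subject)
  stopifnot(nrow(values) == length(subject))
  tab <- table(subject)
  if (length(tab) < 3L) stop("need at least 3 subjects")
  if (any(tab < 2L)) stop("every subject needs at least 2 replicate scans")
  grand <- colMeans(values)
  tot <- sum(sweep(values, 2, grand)^2) / (nrow(values) - 1)
  if (tot == 0) stop("zero total trace: I2C2 undefined")
  sums <- rowsum(values, subject, reorder = FALSE)
  means <- sums / as.integer(tab[rownames(sums)])
  ssw <- sum((values - means[subject, , drop = FALSE])^2)
  within <- ssw / sum(tab - 1L)
  1 - within / tot
}

#' Bootstrap confidence interval for the I2C2
#'
#' Resamples subjects with replacement `B` times, recomputes [i2c2()] on each
#' resample, and returns the percentile interval. Degenerate resamples (for
#' which the estimator is undefined) are skipped and counted.
#'
#' @inheritParams i2c2
#' @param B Number of bootstrap replicates (>= 50), default 1000.
#' @param seed Integer seed; the interval is reproducible given the seed.
#' @param level Confidence level, default 0.95.
#' @return List `lower`, `upper`, `B`, `n_degenerate`, `estimates`.
#' @export
i2c2_bootstrap_ci <- function(values, subject, B = 1000, seed = 1,
                              level = 0.95) {
  if (B < 50) stop("B must be >= 50")
  values <- as.matrix(values)
  subject <- as.character(subject)
  ids <- unique(subject)
  rows_by_id <- split(seq_along(subject), subject)[ids]
  set.seed(seed)
  est <- rep(NA_real_, B)
  for (b in seq_len(B)) {
    pick <- sample(ids, length(ids), replace = TRUE)
    rows <- unlist(rows_by_id[pick], use.names = FALSE)
    # resampled copies of the same subject count as distinct entities
    newid <- rep(seq_along(pick), lengths(rows_by_id[pick]))
    est[b] <- tryCatch(i2c2(values[rows, , drop = FALSE], newid),
                       error = function(e) NA_real_)
  }
  ok <- est[!is.na(est)]
  if (!length(ok)) stop("all bootstrap resamples degenerate")
  a <- 1 - level
  qs <- quantile(ok, c(a / 2, 1 - a / 2), names = FALSE, type = 7)
  list(lower = qs[1], upper = qs[2], B = B,
       n_degenerate = sum(is.na(est)), estimates = est)
}

#' Bland-Altman ratio analysis of replicate agreement
#'
#' Works on the log scale: with `l_i = log(second_i / first_i)`, the
#' geometric mean ratio is `exp(mean(l))`, the 95% limits of agreement are
#' `exp(mean(l) +/- 1.96 sd(l))`, and the p-value for the null hypothesis
#' GMR = 1 comes from a two-sided one-sample t-test on `l`.
#'
#' @param first,second Strictly positive paired measurements.
#' @param limit_multiplier Multiplier for the limits of agreement; 1.96 by
#'   convention.
#' @return List `gmr`, `limit_lower`, `limit_upper`, `p`, `n`.
#' @export
bland_altman_ratio <- function(first, second, limit_multiplier = 1.96) {
  if (any(first <= 0) || any(second <= 0)) stop("all measurements must be > 0")
  l <- log(second / first)
  n <- length(l)
  gmr <- exp(mean(l))
  s <- if (n > 1) sd(l) else NA_real_
  lims <- if (n > 1) exp(mean(l) + c(-1, 1) * limit_multiplier * s)
          else c(NA_real_, NA_real_)
  p <- if (n > 1 && s > 0) t.test(l)$p.value
       else if (!is.na(s) && s == 0) as.numeric(mean(l) == 0)
       else NA_real_
  list(gmr = gmr, limit_lower = lims[1], limit_upper = lims[2], p = p, n = n)
}

#' Per-region test-retest reliability table
#'
#' Runs the within-session percent-change model, the per-group one-way ICC
#' and the Bland-Altman ratio analysis for each region of a cohort, giving a
#' table mirroring the layout of published regional reliability tables.
#'
#' @param cohort Long-format cohort table (see [simulate_cohort()]).
#' @param regions Regions to analyse; default all present.
#' @param level Confidence level.
#' @return Data frame, one row per region: HC mean % change with CI and p,
#'   AD-HC difference with CI and p, per-group ICC with exact CI, per-group
#'   geometric mean ratio.
#' @export
region_reliability <- function(cohort, regions = unique(cohort$region),
                               level = 0.95) {
  rows <- lapply(regions, function(r) {
    pr <- replicate_pairs(cohort, r)
    mod <- within_session_change_model(pr, level)
    ad <- pr[pr$group == "AD", ]
    hc <- pr[pr$group == "HC", ]
    icc_ad <- icc_oneway(ad$first, ad$second, level)
    icc_hc <- icc_oneway(hc$first, hc$second, level)
    ba_ad <- bland_altman_ratio(ad$first, ad$second)
    ba_hc <- bland_altman_ratio(hc$first, hc$second)
    data.frame(
      region = r,
      hc_mean_pct = mod$intercept[["estimate"]],
      hc_pct_lower = mod$intercept[["lower"]],
      hc_pct_upper = mod$intercept[["upper"]],
      hc_pct_p = mod$intercept[["p"]],
      diff_pct = mod$difference[["estimate"]],
      diff_pct_lower = mod$difference[["lower"]],
      diff_pct_upper = mod$difference[["upper"]],
      diff_pct_p = mod$difference[["p"]],
      icc_ad = icc_ad$icc, icc_ad_lower = icc_ad$lower,
      icc_ad_upper = icc_ad$upper,
      icc_hc = icc_hc$icc, icc_hc_lower = icc_hc$lower,
      icc_hc_upper = icc_hc$upper,
      gmr_ad = ba_ad$gmr, gmr_hc = ba_hc$gmr,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
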