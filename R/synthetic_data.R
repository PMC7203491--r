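## Synthetic MIRIAD-like cohorts with known ground truth.
##
## Per subject i, region r, the latent trajectory is
##   mu_ir(t) = (b_r * deficit factor + u0_i) + (s_{r,group} + u1_i) * t,
## with (u0, u1) bivariate normal across subjects, and every scan observed as
## mu + eps with eps ~ N(0, within_session_noise_sd * b_r). MMSE follows a
## group-specific linear trend clamped to [0, 30].

#' Default simulation parameters for a MIRIAD-like cohort
#'
#' Returns the parameter set emulating the MIRIAD study design: 41 AD and 21
#' HC subjects scanned at 0, 0.5, 1.5, 3.5, 6.5, 9.5, 12, 18 and 24 months,
#' with duplicate same-session scans at 0, 1.5 and 9.5 months; an AD baseline
#' gray-matter deficit of 19.1% and AD decline 81.6% faster than HC; MMSE
#' declining 0.23 points/month in AD and flat in HC; age 69.1 +/- 6.7 years.
#' Quantities the study design does not fix (HC per-region decline, the
#' random-effect and noise scales, MMSE baselines) are package defaults
#' chosen to be realistic for modulated VBM; see the package vignette.
#'
#' @param ... Named overrides for any parameter field.
#' @return A list of class `sim_params`. Fields: `n_ad`, `n_hc`,
#'   `visit_months`, `replicate_months`, `regions` (named vector of HC
#'   baseline means), `ad_baseline_deficit`, `hc_slope` (fraction of the
#'   region baseline per month), `ad_slope_multiplier`,
#'   `random_intercept_sd`, `random_slope_sd`, `intercept_slope_corr`,
#'   `within_session_noise_sd` (fraction of the region baseline),
#'   `dropout_prob`, `age_mean`, `age_sd`, `female_prob`,
#'   `mmse_baseline_mean` (named, AD/HC), `mmse_subject_sd`,
#'   `mmse_ad_slope`, `mmse_hc_slope`, `mmse_noise_sd`, `seed`.
#' @examples
#' p <- default_params(n_ad = 10, n_hc = 10, seed = 1)
#' @export
default_params <- function(...) {
  reg <- cyto_regions()
  params <- list(
    n_ad = 41L,
    n_hc = 21L,
    visit_months = c(0, 0.5, 1.5, 3.5, 6.5, 9.5, 12, 18, 24),
    replicate_months = c(0, 1.5, 9.5),
    regions = setNames(reg$hc_mean, reg$region),
    ad_baseline_deficit = 0.191,
    hc_slope = -5e-4,
    ad_slope_multiplier = 0.816,
    random_intercept_sd = 0.03,
    random_slope_sd = 3e-4,
    intercept_slope_corr = 0.3,
    within_session_noise_sd = 0.01,
    dropout_prob = 0,
    age_mean = 69.1,
    age_sd = 6.7,
    female_prob = 0.55,
    mmse_baseline_mean = c(AD = 22, HC = 29),
    mmse_subject_sd = 1.5,
    mmse_ad_slope = -0.23,
    mmse_hc_slope = 0,
    mmse_noise_sd = 1,
    seed = 1L
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(params))
  if (length(unknown)) stop("unknown parameter(s): ", paste(unknown, collapse = ", "))
  params[names(dots)] <- dots
  class(params) <- "sim_params"
  validate_params(params)
  params
}

validate_params <- function(p) {
  stopifnot(p$n_ad >= 0, p$n_hc >= 0, p$n_ad + p$n_hc > 0)
  if (is.unsorted(p$visit_months, strictly = TRUE)) {
    stop("visit_months must be strictly increasing")
  }
  if (!all(p$replicate_months %in% p$visit_months)) {
    stop("replicate_months must be a subset of visit_months")
  }
  sds <- c(p$random_intercept_sd, p$random_slope_sd, p$within_session_noise_sd,
           p$age_sd, p$mmse_subject_sd, p$mmse_noise_sd)
  if (any(sds < 0)) stop("all SDs must be >= 0")
  if (p$female_prob < 0 || p$female_prob > 1) stop("female_prob must be in [0, 1]")
  if (p$dropout_prob < 0 || p$dropout_prob > 1) stop("dropout_prob must be in [0, 1]")
  if (abs(p$intercept_slope_corr) > 1) stop("intercept_slope_corr must be in [-1, 1]")
  if (is.null(names(p$regions)) || any(p$regions <= 0)) {
    stop("regions must be a named vector of positive baseline means")
  }
  invisible(p)
}

#' Simulate a MIRIAD-like longitudinal cohort
#'
#' Draws a cohort under the linear random-coefficient model described in
#' [default_params()] and returns the long-format measurement table together
#' with the full ground truth (every subject-level coefficient), so that
#' downstream estimators can be validated by parameter recovery. Fully
#' reproducible from `params$seed`.
#'
#' @param params A `sim_params` list from [default_params()].
#' @return A list of class `sim_cohort` with elements
#'   \describe{
#'     \item{`cohort`}{data frame: `subject`, `group` (`"AD"`/`"HC"`),
#'       `age`, `gender` (`"F"`/`"M"`), `month`, `replicate` (1 or 2; 2 only
#'       at replicate sessions), `mmse`, `region`, `gmd`.}
#'     \item{`truth`}{list with `subjects` (per-subject random effects, MMSE
#'       baseline), `regions` (per-region group baselines and slopes), and
#'       the `params` used.}
#'   }
#' @export
simulate_cohort <- function(params = default_params()) {
  validate_params(params)
  p <- params
  set.seed(p$seed)

  n <- p$n_ad + p$n_hc
  subjects <- data.frame(
    subject = sprintf("S%03d", seq_len(n)),
    group = rep(c("AD", "HC"), c(p$n_ad, p$n_hc)),
    stringsAsFactors = FALSE
  )
  subjects$age <- rnorm(n, p$age_mean, p$age_sd)
  subjects$gender <- ifelse(runif(n) < p$female_prob, "F", "M")
  # bivariate normal (u0, u1) via Cholesky
  z1 <- rnorm(n); z2 <- rnorm(n)
  rho <- p$intercept_slope_corr
  subjects$u0 <- p$random_intercept_sd * z1
  subjects$u1 <- p$random_slope_sd * (rho * z1 + sqrt(1 - rho^2) * z2)
  subjects$mmse_base <- p$mmse_baseline_mean[subjects$group] +
    rnorm(n, 0, p$mmse_subject_sd)

  regions <- data.frame(
    region = names(p$regions),
    b_hc = as.numeric(p$regions),
    stringsAsFactors = FALSE
  )
  regions$b_ad <- regions$b_hc * (1 - p$ad_baseline_deficit)
  regions$slope_hc <- p$hc_slope * regions$b_hc
  regions$slope_ad <- regions$slope_hc * (1 + p$ad_slope_multiplier)

  # scan schedule: replicate 1 at every visit, replicate 2 at replicate sessions
  sched <- rbind(
    data.frame(month = p$visit_months, replicate = 1L),
    data.frame(month = p$replicate_months,
               replicate = rep(2L, length(p$replicate_months)))
  )
  sched <- sched[order(sched$month, sched$replicate), , drop = FALSE]

  scans <- merge(subjects["subject"], sched, by = NULL)
  if (p$dropout_prob > 0) {
    keep <- scans$month == 0 | runif(nrow(scans)) >= p$dropout_prob
    scans <- scans[keep, , drop = FALSE]
  }
  scans <- scans[order(scans$subject, scans$month, scans$replicate), , drop = FALSE]

  # MMSE: one value per subject-visit, shared by same-session replicates
  visits <- unique(scans[c("subject", "month")])
  visits <- merge(visits, subjects, by = "subject")
  mmse_slope <- ifelse(visits$group == "AD", p$mmse_ad_slope, p$mmse_hc_slope)
  visits$mmse <- pmin(30, pmax(0, visits$mmse_base + mmse_slope * visits$month +
                                 rnorm(nrow(visits), 0, p$mmse_noise_sd)))

  long <- merge(scans, regions, by = NULL)
  long <- merge(long, subjects, by = "subject")
  long <- merge(long, visits[c("subject", "month", "mmse")],
                by = c("subject", "month"))
  long <- long[order(long$subject, long$month, long$replicate, long$region), ,
               drop = FALSE]
  base <- ifelse(long$group == "AD", long$b_ad, long$b_hc)
  slope <- ifelse(long$group == "AD", long$slope_ad, long$slope_hc)
  mu <- (base + long$u0) + (slope + long$u1) * long$month
  eps <- rnorm(nrow(long), 0, p$within_session_noise_sd * long$b_hc)
  long$gmd <- pmax(mu + eps, 1e-8)

  cohort <- long[c("subject", "group", "age", "gender", "month", "replicate",
                   "mmse", "region", "gmd")]
  rownames(cohort) <- NULL
  structure(
    list(cohort = cohort,
         truth = list(subjects = subjects, regions = regions, params = p)),
    class = "sim_cohort"
  )
}

#' Simulate a toy voxel scene with exact regional ground truth
#'
#' Builds a smooth nonnegative gray-matter field and `n_regions` pairs of
#' Gaussian-blob probability maps (mirrored left/right), and returns the
#' exact probability-weighted regional means as oracle truth for the
#' extraction code.
#'
#' @param grid_size Voxel count per axis (scalar or length-3), >= 4.
#' @param n_regions Number of bilateral regions, >= 1.
#' @param seed Integer seed.
#' @param constant_g If not `NULL`, use a constant gray-matter field of this
#'   value instead of the random smooth field.
#' @return List with `gm` ([gm_map()]), `atlas` (named list of
#'   `list(left, right)` pairs) and `truth` (named vector of exact weighted
#'   means).
#' @export
simulate_voxel_scene <- function(grid_size = 12, n_regions = 2, seed = 1,
                                 constant_g = NULL) {
  if (length(grid_size) == 1L) grid_size <- rep(grid_size, 3L)
  if (any(grid_size < 4)) stop("grid must be at least 4 voxels per axis")
  if (n_regions < 1) stop("need at least one region")
  set.seed(seed)
  d <- as.integer(grid_size)
  ax <- lapply(d, seq_len)
  coords <- expand.grid(x = ax[[1]], y = ax[[2]], z = ax[[3]])

  if (is.null(constant_g)) {
    g <- array(0.3, dim = d)
    for (b in seq_len(3)) {
      ctr <- runif(3, 1, d)
      sig <- runif(1, d[1] / 6, d[1] / 3)
      amp <- runif(1, 0.2, 0.6)
      dist2 <- (coords$x - ctr[1])^2 + (coords$y - ctr[2])^2 + (coords$z - ctr[3])^2
      g <- g + array(amp * exp(-dist2 / (2 * sig^2)), dim = d)
    }
  } else {
    g <- array(constant_g, dim = d)
  }
  gm <- gm_map(g, subject = "sim", session_month = 0)

  atlas <- list()
  truth <- numeric(n_regions)
  half <- d[1] / 2
  for (r in seq_len(n_regions)) {
    cx <- runif(1, 1.5, max(half - 0.5, 2))
    cy <- runif(1, 1.5, d[2] - 0.5)
    cz <- runif(1, 1.5, d[3] - 0.5)
    sig <- runif(1, 1, max(d[1] / 5, 1.2))
    blob <- function(ctr_x) {
      dist2 <- (coords$x - ctr_x)^2 + (coords$y - cy)^2 + (coords$z - cz)^2
      w <- exp(-dist2 / (2 * sig^2))
      w[w < 1e-4] <- 0
      array(w, dim = d)
    }
    nm <- sprintf("region%02d", r)
    wl <- blob(cx)
    wr <- blob(d[1] + 1 - cx)   # mirrored across the midline
    atlas[[nm]] <- list(
      left = prob_region_map(wl, region = nm, hemisphere = "left"),
      right = prob_region_map(wr, region = nm, hemisphere = "right")
    )
    truth[r] <- (sum(g * wl) + sum(g * wr)) / (sum(wl) + sum(wr))
  }
  names(truth) <- names(atlas)
  list(gm = gm, atlas = atlas, truth = truth)
}
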