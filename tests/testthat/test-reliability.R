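test_that("percent change is the relative difference times 100", {
  expect_equal(percent_change(0.5, 0.5), 0)
  expect_equal(percent_change(0.50, 0.495), -1.0)
  expect_equal(percent_change(0.4, 0.5), 25)
  expect_error(percent_change(0, 1), "> 0")
})

test_that("within-session change model recovers deterministic group means", {
  mk <- function(grp, pct) {
    n <- length(pct)
    data.frame(subject = paste0(grp, seq_len(n)), group = grp,
               month = 0, first = 1, second = 1 + pct / 100)
  }
  # all changes zero
  pairs0 <- rbind(mk("HC", rep(0, 4)), mk("AD", rep(0, 4)))
  m0 <- within_session_change_model(pairs0)
  expect_equal(m0$intercept[["estimate"]], 0)
  expect_equal(m0$difference[["estimate"]], 0)
  expect_equal(m0$intercept[["p"]], 1)

  # exact HC mean -0.5, AD mean +0.2 -> difference +0.7
  pairs <- rbind(mk("HC", rep(-0.5, 5)), mk("AD", rep(0.2, 6)))
  m <- within_session_change_model(pairs)
  expect_equal(m$intercept[["estimate"]], -0.5, tolerance = 1e-10)
  expect_equal(m$difference[["estimate"]], 0.7, tolerance = 1e-10)

  expect_error(within_session_change_model(mk("AD", rep(0, 4))), "both groups")
})

test_that("within-session model CIs attain close to nominal coverage", {
  set.seed(914)
  true_hc <- -0.5
  true_diff <- 0.7
  n_rep <- 200
  cover <- logical(n_rep)
  for (r in seq_len(n_rep)) {
    subj <- data.frame(
      subject = sprintf("s%02d", 1:30),
      group = rep(c("HC", "AD"), c(12, 18)),
      u = rnorm(30, 0, 0.3)
    )
    d <- merge(subj, data.frame(month = c(0, 1.5, 9.5)), by = NULL)
    mu <- true_hc + (d$group == "AD") * true_diff + d$u
    pct <- mu + rnorm(nrow(d), 0, 0.4)
    d$first <- 1
    d$second <- 1 + pct / 100
    m <- within_session_change_model(d)
    cover[r] <- m$difference[["lower"]] <= true_diff &&
      true_diff <= m$difference[["upper"]]
  }
  expect_gte(mean(cover), 0.91)
  expect_lte(mean(cover), 0.99)
})

test_that("one-way ICC matches its definition and the ANOVA oracle", {
  # identical replicate pairs with varying subject means: no within variance
  first <- c(1, 2, 3, 4.5)
  expect_equal(icc_oneway(first, first)$icc, 1)

  # no between variance at k = 2 pins the estimator at -1
  expect_equal(icc_oneway(c(0, 1, 0, 1), c(1, 0, 1, 0))$icc, -1)

  # explicit-sum oracle on a small fixture
  f <- c(1, 2, 3, 4); s <- c(1.1, 1.9, 3.2, 3.8)
  expect_equal(icc_oneway(f, s)$icc, brute_force_icc(f, s), tolerance = 1e-10)

  # random fixtures, n <= 10
  set.seed(5)
  for (i in 1:10) {
    n <- sample(3:10, 1)
    a <- rnorm(n, 10, 2)
    b <- a + rnorm(n, 0, 0.5)
    expect_equal(icc_oneway(a, b)$icc, brute_force_icc(a, b), tolerance = 1e-10)
  }

  expect_error(icc_oneway(c(1, 2), c(1, 2)), "at least 3")
  expect_error(icc_oneway(rep(1, 5), rep(1, 5)), "zero total variance")
})

test_that("ICC is invariant to affine rescaling and its exact CI brackets it", {
  set.seed(8)
  a <- rnorm(12, 5, 1)
  b <- a + rnorm(12, 0, 0.3)
  r0 <- icc_oneway(a, b)
  r1 <- icc_oneway(3.2 * a + 7, 3.2 * b + 7)
  expect_equal(r1$icc, r0$icc, tolerance = 1e-10)
  expect_equal(r1$lower, r0$lower, tolerance = 1e-10)
  expect_lte(r0$lower, r0$icc)
  expect_gte(r0$upper, r0$icc)
})

test_that("Searle exact CI achieves near-nominal coverage", {
  # true one-way model: sigma_b = 1, sigma_w = 0.3 -> ICC = 1/(1+0.09)
  true_icc <- 1 / 1.09
  set.seed(61)
  cover <- vapply(1:300, function(i) {
    u <- rnorm(25)
    a <- u + rnorm(25, 0, 0.3)
    b <- u + rnorm(25, 0, 0.3)
    ci <- icc_oneway(a, b)
    ci$lower <= true_icc && true_icc <= ci$upper
  }, logical(1))
  expect_gte(mean(cover), 0.91)
  expect_lte(mean(cover), 0.99)
})

test_that("I2C2 is 1 for perfect replicates and reduces to the variance ratio", {
  set.seed(3)
  x <- matrix(rnorm(20 * 5), 20, 5)
  vals <- rbind(x, x)
  subj <- rep(sprintf("s%02d", 1:20), 2)
  expect_equal(i2c2(vals, subj), 1)

  # single region: 1 - (within ms) / (total variance)
  a <- rnorm(10, 0, 1); b <- a + rnorm(10, 0, 0.4)
  v <- matrix(c(a, b), ncol = 1)
  s <- rep(1:10, 2)
  all_vals <- c(a, b)
  mean_i <- (a + b) / 2
  within <- sum((a - mean_i)^2 + (b - mean_i)^2) / 10
  total <- var(all_vals)
  expect_equal(i2c2(v, s), 1 - within / total, tolerance = 1e-12)

  expect_error(i2c2(matrix(1:4, 2, 2), c("a", "b")), "3 subjects")
  expect_error(i2c2(matrix(1, 6, 1), rep(1:3, 2)), "zero total trace")
})

test_that("I2C2 bootstrap CI is reproducible and degenerates correctly", {
  set.seed(10)
  x <- matrix(rnorm(15 * 4), 15, 4)
  vals <- rbind(x, x + matrix(rnorm(15 * 4, 0, 0.2), 15, 4))
  subj <- rep(1:15, 2)
  ci1 <- i2c2_bootstrap_ci(vals, subj, B = 100, seed = 4)
  ci2 <- i2c2_bootstrap_ci(vals, subj, B = 100, seed = 4)
  expect_identical(ci1[c("lower", "upper")], ci2[c("lower", "upper")])
  expect_lte(ci1$lower, ci1$upper)

  # noise-free data: every resample returns exactly 1
  perfect <- rbind(x, x)
  ci <- i2c2_bootstrap_ci(perfect, subj, B = 60, seed = 2)
  expect_equal(ci$lower, 1)
  expect_equal(ci$upper, 1)

  expect_error(i2c2_bootstrap_ci(vals, subj, B = 10), "B must be >= 50")
})

test_that("I2C2 bootstrap CI covers the truth at roughly nominal rate", {
  # independent regions, between-var 0.9, within-var 0.1 -> true ratio 0.9
  set.seed(77)
  n <- 100; q <- 5
  cover <- vapply(1:50, function(i) {
    u <- matrix(rnorm(n * q, 0, sqrt(0.9)), n, q)
    w1 <- u + matrix(rnorm(n * q, 0, sqrt(0.1)), n, q)
    w2 <- u + matrix(rnorm(n * q, 0, sqrt(0.1)), n, q)
    ci <- i2c2_bootstrap_ci(rbind(w1, w2), rep(1:n, 2), B = 100, seed = i)
    ci$lower <= 0.9 && 0.9 <= ci$upper
  }, logical(1))
  expect_gte(mean(cover), 0.82)   # 50 replications: wide binomial band
})

test_that("Bland-Altman ratio analysis follows the log-scale construction", {
  ba <- bland_altman_ratio(c(1, 2, 3), c(1, 2, 3))
  expect_equal(ba$gmr, 1)
  expect_equal(ba$limit_lower, 1)
  expect_equal(ba$limit_upper, 1)
  expect_equal(ba$p, 1)

  expect_equal(bland_altman_ratio(1, 2)$gmr, 2)

  # ratios {1.02, 0.98} -> geometric mean sqrt(1.02 * 0.98)
  ba2 <- bland_altman_ratio(c(1, 1), c(1.02, 0.98))
  expect_equal(ba2$gmr, sqrt(1.02 * 0.98), tolerance = 1e-12)

  # swapping the pair order inverts the ratio
  set.seed(6)
  f <- runif(10, 0.4, 0.6); s <- f * exp(rnorm(10, 0, 0.01))
  expect_equal(bland_altman_ratio(f, s)$gmr * bland_altman_ratio(s, f)$gmr, 1,
               tolerance = 1e-12)
  expect_error(bland_altman_ratio(c(1, -1), c(1, 1)), "> 0")
})

test_that("the per-region reliability table has coherent columns", {
  co <- simulate_cohort(default_params(n_ad = 12, n_hc = 8, seed = 3,
                                       regions = c(CA1 = 0.55, Ch4 = 0.48)))
  tab <- region_reliability(co$cohort)
  expect_equal(tab$region, c("CA1", "Ch4"))
  expect_true(all(tab$icc_ad >= -1 & tab$icc_ad <= 1))
  expect_true(all(tab$icc_ad_lower <= tab$icc_ad))
  expect_true(all(tab$icc_ad_upper >= tab$icc_ad))
  expect_true(all(tab$hc_pct_lower <= tab$hc_mean_pct))
  expect_true(all(tab$hc_pct_upper >= tab$hc_mean_pct))
  expect_true(all(tab$gmr_ad > 0.9 & tab$gmr_ad < 1.1))
})
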