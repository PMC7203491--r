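# Independent brute-force oracles, deliberately written as explicit loops /
# explicit sums so they share no code path with the package implementation.

# triple-loop weighted bilateral mean
brute_force_density <- function(g, wl, wr) {
  num <- 0
  den <- 0
  d <- dim(g)
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
    num <- num + g[i, j, k] * wl[i, j, k] + g[i, j, k] * wr[i, j, k]
    den <- den + wl[i, j, k] + wr[i, j, k]
  }
  num / den
}

# one-way ANOVA ICC by explicit sums, k = 2
brute_force_icc <- function(first, second) {
  n <- length(first)
  grand <- 0
  for (i in seq_len(n)) grand <- grand + first[i] + second[i]
  grand <- grand / (2 * n)
  ssb <- 0
  ssw <- 0
  for (i in seq_len(n)) {
    mi <- (first[i] + second[i]) / 2
    ssb <- ssb + 2 * (mi - grand)^2
    ssw <- ssw + (first[i] - mi)^2 + (second[i] - mi)^2
  }
  msb <- ssb / (n - 1)
  msw <- ssw / n
  (msb - msw) / (msb + msw)
}

# enumerate the step rule directly on sorted p-values
brute_force_stepdown <- function(p, alpha) {
  m <- length(p)
  ord <- order(p)
  reject <- logical(m)
  for (k in seq_len(m)) {
    if (p[ord[k]] <= alpha / (m - k + 1)) reject[ord[k]] <- TRUE else break
  }
  reject
}

brute_force_stepup_bh <- function(p, alpha) {
  m <- length(p)
  ord <- order(p)
  kmax <- 0
  for (k in seq_len(m)) {
    if (p[ord[k]] <= alpha * k / m) kmax <- k
  }
  reject <- logical(m)
  if (kmax > 0) reject[ord[seq_len(kmax)]] <- TRUE
  reject
}

# analytic root of Q(t) + z * SE(t) = 0 by bisection on a fine bracket
detection_root <- function(beta0, beta1, v0, v1, c01, z = qnorm(0.975),
                           threshold = 0.005, upper_t = 24) {
  f <- function(t) {
    threshold * beta0 + beta1 * t +
      z * sqrt(threshold^2 * v0 + t^2 * v1 + 2 * threshold * t * c01)
  }
  ts <- seq(0, upper_t, by = 1e-3)
  vals <- vapply(ts, f, numeric(1))
  neg <- which(vals < 0)
  if (!length(neg)) return(NA_real_)
  i <- min(neg)
  if (i == 1) return(0)
  uniroot(f, c(ts[i - 1], ts[i]), tol = 1e-10)$root
}

# write a 3D array to a temporary NIfTI file
write_temp_nifti <- function(arr) {
  path <- tempfile(fileext = ".nii.gz")
  RNifti::writeNifti(RNifti::asNifti(arr), path)
  path
}
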