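test_that("probability maps are normalised to [0,1] on load", {
  arr <- array(0, dim = c(6, 6, 6))
  arr[2:4, 2:4, 2:4] <- 50
  arr[3, 3, 3] <- 100
  path <- write_temp_nifti(arr)
  m <- load_probability_map(path, scale_hint = "auto")
  expect_equal(max(m$probabilities), 1)
  expect_equal(as.numeric(m$probabilities), as.numeric(arr / 100),
               tolerance = 1e-6)
  expect_identical(dim(m$probabilities), dim(arr))

  frac <- array(0, dim = c(5, 5, 5))
  frac[2, 2, 2] <- 0.98
  path2 <- write_temp_nifti(frac)
  m2 <- load_probability_map(path2, scale_hint = "auto")
  expect_equal(max(m2$probabilities), 0.98, tolerance = 1e-6)

  m3 <- load_probability_map(path2, scale_hint = "percent")
  expect_equal(max(m3$probabilities), 0.0098, tolerance = 1e-8)
})

test_that("degenerate volumes are rejected on load", {
  zero <- write_temp_nifti(array(0, dim = c(4, 4, 4)))
  expect_error(load_probability_map(zero), "empty probability map")
  neg <- array(0.5, dim = c(4, 4, 4)); neg[1, 1, 1] <- -1
  expect_error(load_probability_map(write_temp_nifti(neg)), "negative")
  expect_error(prob_region_map(array(1, dim = c(4, 4))), "3D")
  expect_error(prob_region_map(array(1.5, dim = c(4, 4, 4))), "exceed")
})

test_that("atlas translation shifts the affine only and is invertible", {
  m <- prob_region_map(array(runif(64), dim = c(4, 4, 4)) / 2)
  same <- apply_atlas_translation(m, 0, 0)
  expect_identical(same$affine, m$affine)
  shifted <- apply_atlas_translation(m, 4, 5)
  expect_equal(shifted$affine[1:3, 4] - m$affine[1:3, 4], c(0, 4, 5))
  expect_identical(shifted$probabilities, m$probabilities)
  back <- apply_atlas_translation(shifted, -4, -5)
  expect_equal(back$affine, m$affine)
})

test_that("regional density is the pooled bilateral weighted mean", {
  # hand-computed: g = (1,2,3), combined weights (0.5, 1.0, 0.5) -> 2.0
  g <- gm_map(array(c(1, 2, 3), dim = c(3, 1, 1)))
  wl <- prob_region_map(array(c(0.5, 0.5, 0.0), dim = c(3, 1, 1)),
                        hemisphere = "left")
  wr <- prob_region_map(array(c(0.0, 0.5, 0.5), dim = c(3, 1, 1)),
                        hemisphere = "right")
  expect_equal(extract_regional_density(g, wl, wr)$gmd, 2.0)

  # constant field: weighted mean is the constant
  gc <- gm_map(array(0.37, dim = c(3, 1, 1)))
  expect_equal(extract_regional_density(gc, wl, wr)$gmd, 0.37)

  # per-hemisphere variant
  ph <- extract_regional_density(g, wl, wr, combine = "per_hemisphere")
  expect_equal(ph$gmd, c((1 * 0.5 + 2 * 0.5) / 1, (2 * 0.5 + 3 * 0.5) / 1))
})

test_that("zero weight and shape mismatches are hard errors", {
  g <- gm_map(array(1, dim = c(4, 4, 4)))
  expect_error(
    extract_regional_density(
      g,
      prob_region_map(array(c(1, rep(0, 511)), dim = c(8, 8, 8))),
      NULL
    ),
    "grid mismatch"
  )
  w <- array(0, dim = c(4, 4, 4)); w[1, 1, 1] <- 1
  m <- prob_region_map(w)
  m$probabilities[] <- 0   # forced degenerate after construction
  expect_error(extract_regional_density(g, m, NULL), "zero total weight")
})

test_that("nearest-neighbour resampling recovers an identically placed sub-grid", {
  big <- array(0, dim = c(8, 8, 8))
  big[1:4, 1:4, 1:4] <- array(runif(64), dim = c(4, 4, 4))
  m <- prob_region_map(big)
  g <- gm_map(array(runif(64), dim = c(4, 4, 4)))
  got <- extract_regional_density(g, m, NULL, resample = TRUE)$gmd
  want <- sum(g$values * big[1:4, 1:4, 1:4]) / sum(big[1:4, 1:4, 1:4])
  expect_equal(got, want, tolerance = 1e-12)
})

test_that("extraction matches the brute-force voxel loop on random scenes", {
  for (seed in 1:8) {
    d <- sample(6:16, 1)
    sc <- simulate_voxel_scene(d, n_regions = 2, seed = seed)
    for (nm in names(sc$atlas)) {
      pair <- sc$atlas[[nm]]
      got <- extract_regional_density(sc$gm, pair$left, pair$right)$gmd
      want <- brute_force_density(sc$gm$values, pair$left$probabilities,
                                  pair$right$probabilities)
      expect_equal(got, want, tolerance = 1e-12)
    }
  }
})

test_that("extraction is linear in g, weight-scale invariant and bounded", {
  sc <- simulate_voxel_scene(10, n_regions = 1, seed = 42)
  pair <- sc$atlas$region01
  v <- extract_regional_density(sc$gm, pair$left, pair$right)$gmd

  g2 <- sc$gm; g2$values <- 3.7 * g2$values
  expect_equal(extract_regional_density(g2, pair$left, pair$right)$gmd,
               3.7 * v, tolerance = 1e-12)

  p2 <- pair
  p2$left$probabilities <- 0.25 * p2$left$probabilities
  p2$right$probabilities <- 0.25 * p2$right$probabilities
  expect_equal(extract_regional_density(sc$gm, p2$left, p2$right)$gmd, v,
               tolerance = 1e-12)

  support <- pair$left$probabilities > 0 | pair$right$probabilities > 0
  expect_gte(v, min(sc$gm$values[support]))
  expect_lte(v, max(sc$gm$values[support]))
})

test_that("whole-atlas extraction is deterministic and matches per-region means", {
  # two disjoint box regions on an 8x8x8 grid: weighted mean with uniform
  # weights is the plain per-region mean of g
  g <- array(runif(512), dim = c(8, 8, 8))
  w1 <- array(0, dim = c(8, 8, 8)); w1[1:3, 1:8, 1:8] <- 1
  w2 <- array(0, dim = c(8, 8, 8)); w2[6:8, 1:8, 1:8] <- 1
  atlas <- list(
    boxA = list(left = prob_region_map(w1, "boxA")),
    boxB = list(left = prob_region_map(w2, "boxB"))
  )
  gm <- gm_map(g, subject = "s1", session_month = 0)
  out <- extract_all_regions(gm, atlas)
  expect_equal(out$region, c("boxA", "boxB"))
  expect_equal(out$gmd, c(mean(g[1:3, , ]), mean(g[6:8, , ])),
               tolerance = 1e-12)
  expect_identical(out, extract_all_regions(gm, atlas))

  # all-zero gray matter field gives zero densities
  gm0 <- gm_map(array(0, dim = c(8, 8, 8)))
  expect_equal(extract_all_regions(gm0, atlas)$gmd, c(0, 0))

  # errors are tagged with the region name
  atlas$boxB$left$probabilities[] <- 0
  expect_error(extract_all_regions(gm, atlas), "boxB")
})
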