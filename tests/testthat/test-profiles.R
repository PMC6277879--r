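test_that("SBP conserves the shoot pixel count and matches a per-pixel oracle", {
  set.seed(11)
  for (i in 1:100) {
    m <- random_blob_mask(40, 40)
    crown <- c(40, sample(10:30, 1))
    m[crown[1]:40, ] <- 0L  # shoot lies above the crown
    prof <- shoot_biomass_profile(m, crown, n = 25)
    expect_identical(sum(prof$values), as.numeric(sum(m)))
    expect_identical(prof$values, sbp_bruteforce(m, crown, 25))
  }
})

test_that("an empty shoot mask yields a zero profile, not an error", {
  prof <- shoot_biomass_profile(matrix(0L, 10, 10), c(10, 5))
  expect_equal(prof$values, numeric(1000))
  expect_equal(prof$source_area_px, 0L)
})

test_that("half-disk bins match brute force exactly and annulus areas approximately", {
  R <- 60; n <- 10
  h <- 80; w <- 140; crown <- c(75, 70)
  d2 <- outer((1:h - crown[1])^2, (1:w - crown[2])^2, `+`)
  m <- matrix(as.integer(d2 <= R^2 & row(d2) <= crown[1]), h, w)
  prof <- shoot_biomass_profile(m, crown, n = n, semi_axes = c(R, R))
  expect_identical(prof$values, sbp_bruteforce(m, crown, n, semi_axes = c(R, R)))
  # interior bins approximate half-annulus areas pi/2 * (r2^2 - r1^2)
  edges <- seq(0, R, length.out = n + 1)
  analytic <- pi / 2 * diff(edges^2)
  for (i in 2:(n - 1))
    expect_lt(abs(prof$values[i] - analytic[i]), 0.06 * analytic[i] + 25)
})

test_that("a solid rectangle gives a constant root profile", {
  m <- matrix(0L, 50, 40); m[10:39, 11:25] <- 1L
  prof <- root_biomass_profile(m, n = 100)
  expect_true(all(prof$values == 15))
  expect_equal(prof$source_area_px, 30L * 15L)
})

test_that("a linear taper matches independently computed row sums", {
  h <- 60; w0 <- 30
  m <- matrix(0L, h + 10, 80)
  for (z in 0:(h - 1)) {
    half <- (w0 / 2) * (1 - z / h)
    cl <- ceiling(40 - half); cr <- floor(40 + half)
    if (cl <= cr) m[z + 5, cl:cr] <- 1L
  }
  prof <- root_biomass_profile(m, n = 120)
  raw <- rowSums(m)[rowSums(m) > 0]
  oracle <- approx((seq_along(raw) - 0.5) / length(raw), raw,
                   xout = (seq_len(120) - 0.5) / 120, rule = 2)$y
  expect_equal(prof$values, oracle)
  expect_true(all(diff(prof$values) <= 1e-9))
  expect_identical(prof$source_area_px, as.integer(sum(m)))
})

test_that("root profile errors on an empty mask", {
  expect_error(root_biomass_profile(matrix(0L, 5, 5)), "no root")
})

test_that("normalization contracts hold", {
  m <- matrix(0L, 30, 30); m[5:25, 10:20] <- 1L
  p <- normalize_root_profile(root_biomass_profile(m, n = 50))
  expect_true(all(p$values == 1))
  expect_true(p$normalized)
  s <- shoot_biomass_profile(m, c(30, 15), n = 50)
  expect_error(normalize_root_profile(s), "not a root profile")
  z <- root_biomass_profile(m, n = 50); z$values[] <- 0
  expect_error(normalize_root_profile(z), "all-zero")
})

test_that("similar roots give identical normalized profiles", {
  mk <- function(scale) {
    h <- 50 * scale
    m <- matrix(0L, h + 10, 60 * scale)
    for (z in 0:(h - 1)) {
      half <- (10 * scale) * (1 - z / h)
      cl <- ceiling(30 * scale - half); cr <- floor(30 * scale + half)
      if (cl <= cr) m[z + 5, cl:cr] <- 1L
    }
    m
  }
  p1 <- normalize_root_profile(root_biomass_profile(mk(1), n = 200))
  p2 <- normalize_root_profile(root_biomass_profile(mk(3), n = 200))
  expect_lt(max(abs(p1$values - p2$values)), 0.08)
  expect_equal(max(p1$values), 1)
  expect_equal(max(p2$values), 1)
})

test_that("normalized profiles are invariant under 2x upsampling", {
  pop <- render_small(n = 3, seed = 77)
  for (i in 1:3) {
    segs <- segment_plant(render_plant(pop$specs[[i]])$image)
    m <- segs$root_mask
    up <- m[rep(seq_len(nrow(m)), each = 2), rep(seq_len(ncol(m)), each = 2)]
    p1 <- normalize_root_profile(root_biomass_profile(m, n = 200))
    p2 <- normalize_root_profile(root_biomass_profile(up, n = 200))
    expect_lte(max(abs(p1$values - p2$values)), 0.02 + 1e-9)
  }
})
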