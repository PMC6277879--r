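test_that("twice the skeleton EDT recovers the width of a bar", {
  m <- matrix(0L, 30, 60); m[12:18, 5:55] <- 1L  # 7 px wide bar
  wf <- width_feature(m, n_bins = 50, edt_cap = 10)
  expect_equal(sum(wf$descriptor), 1)
  mode_bin <- which.max(wf$descriptor)
  width_est <- 2 * (mode_bin - 0.5) / 50 * 10
  expect_lt(abs(width_est - 7), 1.5)
})

test_that("the descriptor mode tracks the petiole width of a rendered plant", {
  r <- small_ranges(petiole_width_px = c(9, 9),
                    blob_radius_per_width = c(0.6, 0.6))
  pop <- render_small(ranges = r, n = 1, seed = 12)
  segs <- segment_plant(render_plant(pop$specs[[1]])$image)
  wf <- width_feature(segs$shoot_mask, n_bins = 100, edt_cap = 20)
  mode_w <- 2 * (which.max(wf$descriptor) - 0.5) / 100 * 20
  expect_lt(abs(mode_w - 9), 1.5)
})

test_that("width feature handles degenerate masks", {
  expect_error(width_feature(matrix(0L, 5, 5)), "empty mask")
  single <- matrix(0L, 5, 5); single[3, 3] <- 1L
  wf <- width_feature(single, n_bins = 10)
  expect_equal(wf$n_skeleton_px, 1L)
  expect_equal(sum(wf$descriptor), 1)
})

test_that("PLS recovers a perfectly linear target with few components", {
  set.seed(2)
  X <- qr.Q(qr(matrix(rnorm(40 * 10), 40))) * 5  # orthogonal features
  y <- 3 * X[, 4] + 1
  m <- fit_pls(X, y, max_components = 5)
  expect_lte(m$n_components, 2)
  pred <- predict(m, X)
  expect_gte(cor(pred, y)^2, 0.999)
  expect_gte(length(m$cv_rmse_by_k), m$n_components)
})

test_that("PLS on permuted targets shows no skill", {
  set.seed(3)
  X <- matrix(rnorm(60 * 8), 60)
  y <- 2 * X[, 1] + rnorm(60, 0, 0.1)
  m <- fit_pls(X, sample(y), max_components = 5)
  expect_gt(min(m$cv_rmse_by_k), 0.75 * sd(y))
})

test_that("PLS refits are deterministic", {
  set.seed(4)
  X <- matrix(rnorm(30 * 6), 30); y <- drop(X %*% rnorm(6))
  m1 <- fit_pls(X, y); m2 <- fit_pls(X, y)
  expect_identical(m1$coef, m2$coef)
  expect_identical(m1$cv_rmse_by_k, m2$cv_rmse_by_k)
})

test_that("full-rank PLS equals ordinary least squares", {
  set.seed(5)
  for (i in 1:5) {
    X <- matrix(rnorm(35 * 6), 35)
    y <- drop(X %*% rnorm(6)) + rnorm(35, 0, 0.5)
    path <- carrotmorph:::pls1_path(X, y, 6)
    b <- path$coefs[, 6]
    ols <- lm.fit(cbind(1, X), y)$coefficients
    pred_pls <- drop(X %*% b) + path$y_mean - drop(path$x_mean %*% b)
    pred_ols <- drop(cbind(1, X) %*% ols)
    expect_lt(max(abs(pred_pls - pred_ols)) / max(abs(pred_ols)), 1e-6)
  }
})

test_that("the PLS kernel matches an independent implementation", {
  skip_if_not_installed("mixOmics")
  set.seed(6)
  X <- matrix(rnorm(40 * 6), 40); colnames(X) <- paste0("f", 1:6)
  y <- drop(X %*% rnorm(6)) + rnorm(40, 0, 0.3)
  path <- carrotmorph:::pls1_path(X, y, 3)
  mine <- drop(X %*% path$coefs[, 3]) + path$y_mean -
    drop(path$x_mean %*% path$coefs[, 3])
  mo <- mixOmics::pls(X, y, ncomp = 3, scale = FALSE, mode = "regression")
  ref <- predict(mo, X)$predict[, 1, 3]
  expect_equal(unname(mine), unname(ref), tolerance = 1e-10)
})

test_that("degenerate PLS inputs fall back to an intercept model", {
  X <- matrix(1, 10, 4)
  expect_warning(m <- fit_pls(X, rnorm(10)), "degenerate|constant")
  expect_true(all(m$coef == 0))
  X2 <- matrix(rnorm(40), 10)
  expect_warning(m2 <- fit_pls(X2, rep(5, 10)), "degenerate|constant")
  expect_equal(unname(predict(m2, X2)), rep(5, 10))
})

test_that("count feature is the area/width ratio with guards", {
  expect_equal(petiole_count_feature(1000, 10), 100)
  expect_equal(petiole_count_feature(matrix(0L, 5, 5), 4), 0)
  expect_error(petiole_count_feature(1000, 0), "positive")
  m <- matrix(0L, 10, 10); m[2:5, 2:6] <- 1L
  expect_equal(petiole_count_feature(m, 2), 10)
})

test_that("the area/width ratio tracks petiole count at fixed width and length", {
  r <- small_ranges(petiole_width_px = c(8, 8),
                    petiole_length_px = c(130, 130),
                    blob_radius_per_width = c(1.6, 1.6))
  pop <- render_small(ranges = r, n = 50, seed = 13)
  ratio <- numeric(50)
  for (i in 1:50) {
    segs <- segment_plant(render_plant(pop$specs[[i]])$image)
    ratio[i] <- petiole_count_feature(segs$shoot_mask, 8)
  }
  expect_gte(cor(ratio, pop$truth$petiole_count, method = "spearman"), 0.9)
})

test_that("petiole number predictions are clamped and need a trained model", {
  set.seed(9)
  X <- matrix(runif(30), ncol = 1) * 100
  y <- drop(X) / 10
  m <- fit_pls(X, y, max_components = 1)
  expect_error(predict_petiole_number(list(), 5), "untrained")
  expect_equal(predict_petiole_number(m, -1e5), 0)
})

test_that("petiole counts above 15 are underpredicted as overlap removes area", {
  # train in the 5-15 regime, then push into heavy 2D overlap
  r_lo <- small_ranges(petiole_width_px = c(8, 8),
                       petiole_length_px = c(130, 130),
                       blob_radius_per_width = c(1.6, 1.6))
  r_hi <- small_ranges(n_petioles = c(18, 25),
                       petiole_width_px = c(8, 8),
                       petiole_length_px = c(130, 130),
                       blob_radius_per_width = c(1.6, 1.6))
  lo <- render_small(ranges = r_lo, n = 30, seed = 17)
  hi <- render_small(ranges = r_hi, n = 12, seed = 18)
  feat <- function(pop) t(vapply(pop$specs, function(sp) {
    segs <- segment_plant(render_plant(sp)$image)
    a <- sum(segs$shoot_mask)
    c(petiole_count_feature(a, 8), a)
  }, numeric(2)))
  m <- fit_pls(feat(lo), lo$truth$petiole_count, max_components = 2)
  pred_hi <- predict_petiole_number(m, feat(hi))
  expect_lt(mean(pred_hi - hi$truth$petiole_count), 0)
})

test_that("the length model is seeded-deterministic and honours degenerate input", {
  set.seed(10)
  S <- matrix(runif(30 * 50), 30)
  L <- drop(S %*% runif(50)) + rnorm(30, 0, 0.2)
  m1 <- fit_length_model(S, L, seed = 7)
  m2 <- fit_length_model(S, L, seed = 7)
  expect_identical(predict_petiole_length(m1, S), predict_petiole_length(m2, S))
  # identical profiles with varying targets predict the target mean
  S0 <- matrix(1, 25, 40)
  y0 <- rnorm(25, 20, 3)
  m0 <- fit_length_model(S0, y0, seed = 1)
  expect_equal(predict_petiole_length(m0, S0), rep(mean(y0), 25))
  expect_error(fit_length_model(S[1:10, ], L[1:10]), "at least 20")
})

test_that("the SBP-network predicts lengths spanning 80-400 px", {
  # radial mass profiles whose extent scales with petiole length
  set.seed(14)
  n <- 100; p <- 200
  len <- runif(n, 80, 400)
  S <- t(vapply(len, function(L) {
    prof <- numeric(p)
    reach <- round(L / 450 * p)
    prof[1:reach] <- 8 + rnorm(reach, 0, 0.5)          # petiole zone
    blade <- min(p, reach + 15)
    prof[reach:blade] <- prof[reach:blade] + 30        # leaf blades
    prof
  }, numeric(p)))
  tr <- 1:80; te <- 81:100
  m <- fit_length_model(S[tr, ], len[tr], seed = 2)
  pred <- predict_petiole_length(m, S[te, ])
  expect_gte(cor(pred, len[te]), 0.85)
})

test_that("trait models round-trip through JSON bit-exactly", {
  set.seed(15)
  X <- matrix(runif(30 * 8), 30); y <- drop(X %*% rnorm(8))
  m <- fit_pls(X, y, max_components = 4)
  f <- tempfile(fileext = ".json")
  save_trait_model(m, f)
  expect_identical(predict(load_trait_model(f), X), predict(m, X))
  S <- matrix(runif(25 * 40), 25); L <- drop(S %*% rnorm(40)) * 0.1 + 20
  ml <- suppressWarnings(fit_length_model(S, L, seed = 3))
  f2 <- tempfile(fileext = ".json")
  save_trait_model(ml, f2)
  expect_identical(predict_petiole_length(load_trait_model(f2), S),
                   predict_petiole_length(ml, S))
})

test_that("descriptor length mismatches are rejected at prediction", {
  set.seed(16)
  X <- matrix(rnorm(30 * 10), 30)
  m <- fit_pls(X, rnorm(30), max_components = 2)
  wf <- structure(list(descriptor = rep(0.2, 5)), class = "width_feature")
  expect_error(predict_petiole_width(m, wf), "length")
})
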