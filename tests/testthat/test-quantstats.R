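test_that("correlation pairs behave at the identities", {
  x <- c(1, 3, 2, 8, 5)
  r <- correlation_pair(x, x)
  expect_equal(r$pearson_r, 1)
  expect_equal(r$spearman_rho, 1)
  r2 <- correlation_pair(x, -x)
  expect_equal(r2$pearson_r, -1)
  expect_equal(r2$spearman_rho, -1)
  expect_error(correlation_pair(1:2, 2:3), "at least 3")
  expect_error(correlation_pair(c(-1, 2, 3), c(1, 2, 3), log_log = TRUE),
               "positive")
})

test_that("log-log correlation recovers an allometric exponent", {
  set.seed(1)
  x <- exp(runif(200, 0, 3))
  b <- 0.75
  y <- 2.5 * x^b * exp(rnorm(200, 0, 0.05))
  r <- correlation_pair(x, y, log_log = TRUE)
  expect_equal(r$slope, b, tolerance = 0.05)
  expect_gt(r$pearson_r, 0.95)
})

sim_trial <- function(g = 20, e = 2, r = 2, sg = 2, sge = 1, sb = 0.5,
                      se = 1, sr = sqrt(2)) {
  G <- rnorm(g, 0, sg); E <- rnorm(e, 0, se)
  B <- matrix(rnorm(e * r, 0, sb), e, r)
  GE <- matrix(rnorm(g * e, 0, sge), g, e)
  d <- expand.grid(genotype_id = seq_len(g), environment_id = seq_len(e),
                   replication_id = seq_len(r))
  d$y <- 10 + G[d$genotype_id] + E[d$environment_id] +
    B[cbind(d$environment_id, d$replication_id)] +
    GE[cbind(d$genotype_id, d$environment_id)] + rnorm(nrow(d), 0, sr)
  d
}

test_that("noise-free data put all variance on genotype", {
  d <- expand.grid(genotype_id = 1:10, environment_id = 1:2,
                   replication_id = 1:2)
  d$y <- (1:10)[d$genotype_id] * 2
  v <- suppressWarnings(estimate_variance_components(d, "y"))
  expect_lt(v$var_R, 1e-6)
  expect_gt(v$var_G, 1)
})

test_that("shuffling genotype labels removes the genotype component", {
  set.seed(2)
  d <- sim_trial(sg = 3, sge = 0.1)
  d$genotype_id <- sample(d$genotype_id)
  v <- suppressWarnings(estimate_variance_components(d, "y"))
  expect_lt(v$var_G, 0.2 * v$var_R + 0.5)
})

test_that("REML and the balanced ANOVA estimator agree", {
  set.seed(3)
  d <- sim_trial()
  v1 <- suppressWarnings(estimate_variance_components(d, "y"))
  v2 <- suppressWarnings(estimate_variance_components(d, "y",
                                                      method = "anova"))
  expect_equal(v1$var_R, v2$var_R, tolerance = 0.15)
  expect_equal(v1$var_G, v2$var_G, tolerance = 0.3)
  expect_true(all(c("G", "E", "GxE") %in% names(v1$anova_p)))
})

test_that("design degeneracies are flagged", {
  d <- sim_trial()
  expect_error(estimate_variance_components(d[d$genotype_id == 1, ], "y"),
               "2 genotypes")
  expect_error(estimate_variance_components(d, "height"), "missing columns")
  d1 <- d[d$environment_id == 1, ]
  expect_warning(v <- estimate_variance_components(d1, "y"),
                 "single environment")
  expect_true(is.na(v$var_GxE))
  expect_true(v$single_environment)
})

test_that("repeatability plug-ins match hand arithmetic", {
  expect_equal(repeatability(4, 1, 2, t = 2, r = 2), 0.8)
  expect_equal(repeatability(5, 0, 0, t = 2, r = 2), 1)
  expect_equal(repeatability(0, 1, 2, t = 2, r = 2), 0)
  expect_equal(repeatability(4, 1, 2, r = 2, per_env = TRUE), 4 / 5)
  expect_error(repeatability(0, 0, 0, t = 1, r = 1), "undefined")
})

test_that("repeatability is monotone in var_G, t, and r", {
  grid <- expand.grid(vg = c(0.5, 1, 2, 4), t = c(1, 2, 4), r = c(1, 2, 4))
  R <- with(grid, mapply(function(vg, t, r)
    repeatability(vg, 1, 2, t = t, r = r), vg, t, r))
  for (tv in c(1, 2, 4)) for (rv in c(1, 2, 4)) {
    sub <- R[grid$t == tv & grid$r == rv]
    expect_true(all(diff(sub) > 0))
  }
  for (vg in c(0.5, 4)) for (rv in c(1, 2, 4)) {
    sub <- R[grid$vg == vg & grid$r == rv]
    expect_true(all(diff(sub) > 0))
  }
})

test_that("full repeatability analysis returns bounded values per environment", {
  set.seed(4)
  d <- sim_trial(g = 15, e = 3, r = 2, sg = 3)
  res <- suppressWarnings(estimate_repeatability(d, "y"))
  expect_true(res$R_overall >= 0 && res$R_overall <= 1)
  expect_length(res$R_per_env, 3)
  expect_true(all(res$R_per_env >= 0 & res$R_per_env <= 1, na.rm = TRUE))
  expect_equal(res$t_harmonic, 3)
  expect_equal(res$r_harmonic, 2)
})

test_that("PVE from LOD is increasing and bounded", {
  lods <- seq(0, 50, by = 0.5)
  p <- pve_from_lod(lods, 316)
  expect_true(all(diff(p) > 0))
  expect_true(all(p >= 0 & p < 100))
  expect_equal(pve_from_lod(0, 316), 0)
  expect_error(pve_from_lod(5, 0), ">= 1")
  expect_error(pve_from_lod(-1, 316), ">= 0")
})

test_that("marker names parse into interval widths with guards", {
  expect_equal(lod_interval_width_mb("S2_100", "S2_100"), 0)
  expect_equal(lod_interval_width_mb("S1_1000000", "S1_3500000"), 2.5)
  expect_error(lod_interval_width_mb("S1_100", "S2_200"), "chromosome")
  expect_error(lod_interval_width_mb("chr1_100", "S1_200"), "unparseable")
  expect_error(lod_interval_width_mb("S1_500", "S1_100"), "exceeds")
})

test_that("the bundled QTL table is summarized without errors", {
  path <- system.file("extdata", "qtl_f2_records.csv",
                      package = "carrotmorph")
  tab <- qtl_support_table(read.csv(path))
  expect_equal(nrow(tab), 39)
  expect_true(all(tab$pve > 0 & tab$pve < 100))
  expect_true(all(tab$interval_mb >= 0))
})
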