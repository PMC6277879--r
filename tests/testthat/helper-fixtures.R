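# Shared synthetic fixtures. Small-canvas geometry keeps per-module tests
# fast; the full-size 100-plant population used by the acceptance checks is
# rendered once per session and memoized.

small_geom <- list(width = 400, height = 480, divider_row = 280,
                   crown_col = 200)

small_ranges <- function(...) {
  r <- population_ranges()
  r$petiole_length_px <- c(120, 20, 90, 150)
  r$root_length_px <- c(100, 170)
  r$root_max_width_px <- c(40, 70)
  utils::modifyList(r, list(...))
}

render_small <- function(ranges = small_ranges(), n = 1, seed = 1) {
  pop <- do.call(generate_population,
                 c(list(n = n, ranges = ranges, seed = seed), small_geom))
  pop
}

# simple white-background test image with optional dark shapes
blank_rgb <- function(h, w, value = 250) {
  array(value, dim = c(h, w, 3))
}

.fixture_cache <- new.env(parent = emptyenv())

# 100-plant full-size fixture + measurement pass, built once per session
acceptance_fixture <- function() {
  if (!is.null(.fixture_cache$fx)) return(.fixture_cache$fx)
  dir <- file.path(tempdir(), "carrotmorph_fixture")
  out <- file.path(tempdir(), "carrotmorph_measure")
  truth <- make_fixtures(100, seed = 101, dir = dir)
  res <- run_measure(dir, out, px_per_cm = 10)
  .fixture_cache$fx <- list(dir = dir, out = out, truth = truth,
                            records = res$records, failures = res$failures,
                            measurements = res$measurements)
  .fixture_cache$fx
}

# independent per-pixel re-implementation of the radial binning rule
sbp_bruteforce <- function(shoot, crown, n, semi_axes = NULL) {
  counts <- numeric(n)
  idx <- which(shoot > 0, arr.ind = TRUE)
  if (nrow(idx) == 0) return(counts)
  if (is.null(semi_axes)) {
    a <- max(abs(idx[, 2] - crown[2]), 1)
    b <- max(crown[1] - idx[, 1], 1)
    rho_all <- numeric(nrow(idx))
    for (i in seq_len(nrow(idx)))
      rho_all[i] <- sqrt(((idx[i, 2] - crown[2]) / a)^2 +
                         ((crown[1] - idx[i, 1]) / b)^2)
    s <- max(rho_all)
    if (s > 1) rho_all <- rho_all / s
  } else {
    rho_all <- numeric(nrow(idx))
    for (i in seq_len(nrow(idx)))
      rho_all[i] <- sqrt(((idx[i, 2] - crown[2]) / semi_axes[1])^2 +
                         ((crown[1] - idx[i, 1]) / semi_axes[2])^2)
  }
  for (r in rho_all) {
    bin <- min(floor(r * n), n - 1) + 1
    counts[bin] <- counts[bin] + 1
  }
  counts
}

random_blob_mask <- function(h, w, n_blobs = 4) {
  m <- matrix(0L, h, w)
  for (b in seq_len(n_blobs)) {
    r0 <- runif(1, 1, h); c0 <- runif(1, 1, w); rad <- runif(1, 2, h / 4)
    d2 <- outer((seq_len(h) - r0)^2, (seq_len(w) - c0)^2, `+`)
    m[d2 <= rad^2] <- 1L
  }
  m
}
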