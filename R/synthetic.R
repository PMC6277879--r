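#' Specification of a synthetic carrot plant image
#'
#' Describes one procedurally rendered plant: canvas geometry, the black
#' divider line with a central gap at the crown, a storage root drawn from a
#' power-law taper blended with a rounded tip cap, and a fan of petioles
#' (oriented bars from the crown) each ending in a circular leaf blob.
#'
#' The root silhouette half-width at depth `z` below the crown is
#' `hw(z) = (max_width/2) * ((1-b) * (1 - z/L)^k + b * sqrt(1 - (z/L)^2))`
#' where `k` is the taper exponent (`k = 0`, `b = 0` gives a cylinder) and
#' `b` in `[0,1]` is the tip bluntness. The analytic silhouette area
#' `2 * integral(hw) = max_width * L * ((1-b)/(k+1) + b*pi/4)` is used as a
#' rendering oracle in the test-suite.
#'
#' @param width,height canvas size in px.
#' @param divider_row row of the divider line centre.
#' @param crown_col column of the crown (root axis).
#' @param root list with `length_px`, `max_width_px`, `taper_k`,
#'   `tip_bluntness`.
#' @param petioles data.frame with columns `angle_deg` (measured from the
#'   rightward horizontal, counter-clockwise, within the upper half-plane),
#'   `length_px`, `width_px`, `blob_radius_px`.
#' @param divider_thickness divider line thickness in px (odd).
#' @param gap_half_width half-width of the central gap in the divider; by
#'   default just wider than the root crown.
#' @param px_per_cm pixel calibration recorded in the ground truth.
#' @param noise_sd standard deviation of additive Gaussian lighting noise
#'   (0 disables it).
#' @return An object of class `plant_spec`.
#' @export
plant_spec <- function(width = 600, height = 720, divider_row = 430,
                       crown_col = 300,
                       root = list(length_px = 240, max_width_px = 70,
                                   taper_k = 1, tip_bluntness = 0.2),
                       petioles = data.frame(angle_deg = c(60, 90, 120),
                                             length_px = 200, width_px = 8,
                                             blob_radius_px = 14),
                       divider_thickness = 5, gap_half_width = NULL,
                       px_per_cm = 10, noise_sd = 0) {
  stopifnot(width >= 2, height >= 2, divider_row > 1, divider_row < height,
            crown_col >= 1, crown_col <= width)
  if (root$length_px + divider_row >= height)
    stop("root does not fit below the divider")
  if (root$max_width_px < 2 || any(petioles$width_px < 2))
    stop("all widths must be >= 2 px")
  if (any(petioles$angle_deg <= 0 | petioles$angle_deg >= 180))
    stop("petiole angles must lie in the upper half-plane (0, 180) degrees")
  gap_half_width <- gap_half_width %||% (root$max_width_px / 2 + 6)
  structure(list(width = width, height = height, divider_row = divider_row,
                 crown_col = crown_col, root = root, petioles = petioles,
                 divider_thickness = divider_thickness,
                 gap_half_width = gap_half_width, px_per_cm = px_per_cm,
                 noise_sd = noise_sd),
            class = "plant_spec")
}

root_half_width <- function(z, length_px, max_width_px, taper_k, tip_bluntness) {
  u <- pmin(pmax(z / length_px, 0), 1)
  taper <- (1 - u)^taper_k
  cap <- sqrt(pmax(0, 1 - u^2))
  (max_width_px / 2) * ((1 - tip_bluntness) * taper + tip_bluntness * cap)
}

#' Analytic silhouette area of a synthetic root
#'
#' Closed form of `2 * integral_0^L hw(z) dz` for the taper/cap blend used by
#' [render_plant()].
#' @param root root component of a [plant_spec()].
#' @return area in px^2.
#' @export
root_area_analytic <- function(root) {
  with(root, max_width_px * length_px *
         ((1 - tip_bluntness) / (taper_k + 1) + tip_bluntness * pi / 4))
}

# Fill a disk into a logical mask (in place semantics via return).
draw_disk <- function(mask, row0, col0, radius) {
  H <- nrow(mask); W <- ncol(mask)
  r1 <- max(1L, floor(row0 - radius)); r2 <- min(H, ceiling(row0 + radius))
  c1 <- max(1L, floor(col0 - radius)); c2 <- min(W, ceiling(col0 + radius))
  if (r1 > r2 || c1 > c2) return(mask)
  rr <- r1:r2; cc <- c1:c2
  d2 <- outer((rr - row0)^2, (cc - col0)^2, `+`)
  mask[rr, cc] <- mask[rr, cc] | (d2 <= radius^2)
  mask
}

# Fill an oriented bar (capsule without end caps) from (row0,col0) to
# (row1,col1) with the given full width.
draw_bar <- function(mask, row0, col0, row1, col1, width_px) {
  H <- nrow(mask); W <- ncol(mask)
  hw <- width_px / 2
  r1 <- max(1L, floor(min(row0, row1) - hw)); r2 <- min(H, ceiling(max(row0, row1) + hw))
  c1 <- max(1L, floor(min(col0, col1) - hw)); c2 <- min(W, ceiling(max(col0, col1) + hw))
  rr <- r1:r2; cc <- c1:c2
  py <- matrix(rr, length(rr), length(cc))
  px <- matrix(cc, length(rr), length(cc), byrow = TRUE)
  vy <- row1 - row0; vx <- col1 - col0
  len2 <- vy^2 + vx^2
  t <- ((py - row0) * vy + (px - col0) * vx) / len2
  t <- pmin(pmax(t, 0), 1)
  d2 <- (py - (row0 + t * vy))^2 + (px - (col0 + t * vx))^2
  mask[rr, cc] <- mask[rr, cc] | (d2 <= hw^2)
  mask
}

#' Render a synthetic carrot plant image
#'
#' Rasterizes a [plant_spec()] onto a white baseboard: black divider line with
#' a central gap, orange storage root below the divider, green petioles fanning
#' from the crown with a leaf blob at each tip. Returns the RGB image together
#' with a ground-truth record containing exact rasterized pixel counts per
#' section (using the same divider exclusion band as the segmentation step),
#' the plant's true petiole count/width/length, and the root shape parameters.
#'
#' @param spec a [plant_spec()].
#' @param band divider exclusion band half-height used when counting
#'   shoot/root section pixels (must match the segmentation configuration).
#' @return list with `image` (height x width x 3 array, 0-255) and `truth`
#'   (named list).
#' @export
render_plant <- function(spec, band = 3) {
  stopifnot(inherits(spec, "plant_spec"))
  H <- spec$height; W <- spec$width
  dr <- spec$divider_row; cc0 <- spec$crown_col

  th <- spec$petioles$angle_deg * pi / 180

  root_m <- matrix(FALSE, H, W)
  L <- spec$root$length_px
  z <- 0:L
  hw <- root_half_width(z, L, spec$root$max_width_px, spec$root$taper_k,
                        spec$root$tip_bluntness)
  for (i in seq_along(z)) {
    r <- dr + z[i]
    if (r > H) break
    half <- hw[i]                # pixel-centre coverage tracks the integral
    if (half < 0.25) next
    cl <- max(1L, ceiling(cc0 - half)); cr <- min(W, floor(cc0 + half))
    if (cl <= cr) root_m[r, cl:cr] <- TRUE
  }

  # petiole bases spread along the crown top (plants are staged with leaves
  # spread apart; petioles attach around the crown circumference, not at a
  # single point)
  np <- nrow(spec$petioles)
  gbase <- min(spec$gap_half_width - 2, spec$root$max_width_px / 2)
  base_off <- if (np > 1)
    seq(-gbase, gbase, length.out = np)[rank(-spec$petioles$angle_deg,
                                             ties.method = "first")]
  else 0
  # feasibility: every petiole tip plus its blob must stay on canvas
  rb <- spec$petioles$blob_radius_px
  tip_col <- cc0 + base_off + spec$petioles$length_px * cos(th)
  tip_row <- dr - spec$petioles$length_px * sin(th)
  if (any(tip_col - rb < 1 | tip_col + rb > W | tip_row - rb < 1))
    stop("petiole exceeds canvas; shorten lengths or steepen angles")
  shoot_m <- matrix(FALSE, H, W)
  for (i in seq_len(np)) {
    p <- spec$petioles[i, ]
    bcol <- cc0 + base_off[i]
    trow <- dr - p$length_px * sin(th[i])
    tcol <- bcol + p$length_px * cos(th[i])
    shoot_m <- draw_bar(shoot_m, dr, bcol, trow, tcol, p$width_px)
    shoot_m <- draw_disk(shoot_m, trow, tcol, p$blob_radius_px)
  }

  div_m <- matrix(FALSE, H, W)
  t2 <- (spec$divider_thickness - 1) %/% 2
  gap <- abs(seq_len(W) - cc0) <= spec$gap_half_width
  div_m[(dr - t2):(dr + t2), !gap] <- TRUE

  plant <- shoot_m | root_m
  bg <- 250
  R <- matrix(bg, H, W); G <- matrix(bg, H, W); B <- matrix(bg, H, W)
  R[div_m] <- 10;  G[div_m] <- 10;  B[div_m] <- 10
  R[root_m] <- 225; G[root_m] <- 120; B[root_m] <- 40
  R[shoot_m] <- 40; G[shoot_m] <- 140; B[shoot_m] <- 50
  img <- array(c(R, G, B), dim = c(H, W, 3))
  if (spec$noise_sd > 0) {
    img <- img + array(rnorm(length(img), 0, spec$noise_sd), dim = dim(img))
    img <- pmin(pmax(img, 0), 255)
  }

  rows <- row(plant)
  truth <- list(
    divider_row = dr, crown_col = cc0, px_per_cm = spec$px_per_cm,
    root_raster_px = sum(root_m),
    shoot_px = sum(plant & rows < dr - band),
    root_px = sum(plant & rows > dr + band),
    plant_px = sum(plant),
    fg_total = sum(plant | div_m),
    petiole_count = nrow(spec$petioles),
    petiole_width_px = mean(spec$petioles$width_px),
    petiole_length_px = mean(spec$petioles$length_px),
    blob_radius_px = mean(spec$petioles$blob_radius_px),
    root_length_px = L, root_max_width_px = spec$root$max_width_px,
    taper_k = spec$root$taper_k, tip_bluntness = spec$root$tip_bluntness,
    root_area_analytic = root_area_analytic(spec$root)
  )
  truth$petiole_width_cm <- truth$petiole_width_px / spec$px_per_cm
  truth$petiole_length_cm <- truth$petiole_length_px / spec$px_per_cm
  list(image = img, truth = truth)
}

#' Default population parameter ranges
#'
#' The default ranges emulate a single biparental F2 carrot population staged
#' on the standard baseboard: petiole number segregating widely (5-15 fully
#' expanded leaves), petiole width 4-14 px, per-plant mean petiole length
#' normally distributed (mean 210 px, sd 30 px, truncated to 140-290 px,
#' i.e. about 14% CV as expected within one cross), leaf blob radius scaling
#' allometrically with petiole width, and storage roots spanning cylindrical
#' to strongly conical shapes (taper exponent 0.3-2.5) with variable tip fill.
#'
#' A two-element numeric `c(lo, hi)` is drawn uniformly (degenerate ranges
#' with `lo == hi` are allowed); `petiole_length_px` is a four-element vector
#' `c(mean, sd, min, max)` drawn from a truncated normal, or a two-element
#' range drawn uniformly.
#' @return named list of ranges.
#' @export
population_ranges <- function() {
  list(n_petioles = c(5, 15),
       petiole_width_px = c(4, 14),
       petiole_length_px = c(210, 30, 140, 290),
       blob_radius_per_width = c(1.5, 1.7),
       root_length_px = c(180, 300),
       root_max_width_px = c(50, 100),
       taper_k = c(0.3, 2.5),
       tip_bluntness = c(0, 0.6))
}

runif1 <- function(range) if (range[1] == range[2]) range[1] else
  runif(1, range[1], range[2])

rtruncnorm1 <- function(mean, sd, lo, hi) {
  repeat {
    x <- rnorm(1, mean, sd)
    if (x >= lo && x <= hi) return(x)
  }
}

# Draw a single plant_spec from population ranges; petiole angles are spread
# evenly over the feasible arc with jitter, and individual lengths are clipped
# so tip plus blob stays on canvas.
draw_spec <- function(ranges, width = 600, height = 720, divider_row = 430,
                      crown_col = 300, px_per_cm = 10, noise_sd = 0) {
  root_len <- min(runif1(ranges$root_length_px), height - divider_row - 2)
  root_w <- runif1(ranges$root_max_width_px)
  taper_k <- runif1(ranges$taper_k)
  blunt <- runif1(ranges$tip_bluntness)
  n_pet <- round(runif1(ranges$n_petioles))
  w <- runif1(ranges$petiole_width_px)
  lr <- ranges$petiole_length_px
  mean_len <- if (length(lr) == 4) rtruncnorm1(lr[1], lr[2], lr[3], lr[4])
              else runif1(lr)
  blob_k <- runif1(ranges$blob_radius_per_width)
  base <- seq(35, 145, length.out = n_pet + 2)[2:(n_pet + 1)]
  ang <- base + runif(n_pet, -0.3, 0.3) * (110 / n_pet)
  len <- mean_len * (1 + runif(n_pet, -0.08, 0.08))
  blob <- pmax(4, blob_k * w * (1 + runif(n_pet, -0.1, 0.1)))
  # clip so tips + blobs remain on canvas (allowing for petiole-base spread
  # along the crown top)
  margin <- 8 + root_w / 2
  cosr <- abs(cos(ang * pi / 180)); sinr <- sin(ang * pi / 180)
  max_dx <- min(crown_col, width - crown_col) - margin
  max_dy <- divider_row - margin
  lmax <- pmin(ifelse(cosr > 1e-9, (max_dx - blob) / cosr, Inf),
               (max_dy - blob) / sinr)
  len <- pmin(len, lmax)
  plant_spec(width = width, height = height, divider_row = divider_row,
             crown_col = crown_col,
             root = list(length_px = root_len,
                         max_width_px = root_w,
                         taper_k = taper_k,
                         tip_bluntness = blunt),
             petioles = data.frame(angle_deg = ang, length_px = len,
                                   width_px = w, blob_radius_px = blob),
             px_per_cm = px_per_cm, noise_sd = noise_sd)
}

#' Generate a synthetic plant population
#'
#' Draws `n` plant specifications from `ranges` under a fixed seed. With
#' `dir = NULL` the specs and ground-truth table are returned and images can
#' be rendered on demand with [render_plant()] (full images are not kept in
#' memory). With a directory, every image is written as
#' `plant_<i>.png` alongside `truth.csv`.
#'
#' @param n number of plants (>= 1).
#' @param ranges parameter ranges, see [population_ranges()].
#' @param seed integer seed; the draw is fully reproducible.
#' @param dir optional output directory for PNG images and `truth.csv`.
#' @param ... geometry arguments forwarded to the spec draw
#'   (`width`, `height`, `divider_row`, `crown_col`, `px_per_cm`, `noise_sd`).
#' @return list with `specs` (list of [plant_spec()]) and `truth`
#'   (data.frame, one row per plant with an `image_id` column).
#' @export
generate_population <- function(n, ranges = population_ranges(), seed = 1,
                                dir = NULL, ...) {
  stopifnot(n >= 1)
  for (r in ranges) if (length(r) >= 2 && any(r[2] < r[1] & length(r) == 2))
    stop("empty range")
  set.seed(seed)
  if (!is.null(dir)) dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  specs <- vector("list", n)
  truths <- vector("list", n)
  for (i in seq_len(n)) {
    specs[[i]] <- draw_spec(ranges, ...)
    rp <- render_plant(specs[[i]])
    truths[[i]] <- rp$truth
    if (!is.null(dir))
      png::writePNG(rp$image / 255,
                    file.path(dir, sprintf("plant_%03d.png", i)))
  }
  truth <- do.call(rbind, lapply(seq_len(n), function(i)
    data.frame(image_id = sprintf("plant_%03d", i), truths[[i]])))
  if (!is.null(dir))
    write.csv(truth, file.path(dir, "truth.csv"), row.names = FALSE)
  list(specs = specs, truth = truth)
}
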