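#' Pixel-to-centimetre calibration
#'
#' @param px_per_cm positive pixels-per-centimetre factor.
#' @param source provenance label (`"config"` or `"reference-marker"`).
#' @return object of class `calibration`.
#' @export
calibration <- function(px_per_cm, source = "config") {
  if (!is.numeric(px_per_cm) || px_per_cm <= 0)
    stop("px_per_cm must be positive")
  structure(list(px_per_cm = px_per_cm, source = source),
            class = "calibration")
}

#' Convert pixel measurements to centimetres
#'
#' @param value_px value in px (power 1) or px^2 (power 2).
#' @param cal a [calibration()].
#' @param power 1 for lengths, 2 for areas.
#' @return value in cm or cm^2.
#' @export
to_cm <- function(value_px, cal, power = 1) {
  stopifnot(inherits(cal, "calibration"), power %in% c(1, 2))
  value_px / cal$px_per_cm^power
}

# area of the convex hull of the union of foreground pixel squares
convex_hull_area <- function(idx, mask) {
  H <- nrow(mask); W <- ncol(mask)
  # boundary pixels suffice for the hull
  pad <- matrix(0L, H + 2, W + 2); pad[2:(H + 1), 2:(W + 1)] <- mask
  nb <- pad[1:H, 2:(W + 1)] + pad[3:(H + 2), 2:(W + 1)] +
        pad[2:(H + 1), 1:W] + pad[2:(H + 1), 3:(W + 2)]
  bidx <- which(mask > 0 & nb < 4, arr.ind = TRUE)
  if (nrow(bidx) == 0) bidx <- idx
  y <- c(bidx[, 1] - 0.5, bidx[, 1] - 0.5, bidx[, 1] + 0.5, bidx[, 1] + 0.5)
  x <- c(bidx[, 2] - 0.5, bidx[, 2] + 0.5, bidx[, 2] - 0.5, bidx[, 2] + 0.5)
  h <- chull(x, y)
  xs <- x[h]; ys <- y[h]
  abs(sum(xs * c(ys[-1], ys[1]) - c(xs[-1], xs[1]) * ys)) / 2
}

# boundary length: count of exposed 4-edges (image border counts as exposed)
perimeter_edges <- function(mask) {
  H <- nrow(mask); W <- ncol(mask)
  pad <- matrix(0L, H + 2, W + 2); pad[2:(H + 1), 2:(W + 1)] <- mask
  nb <- pad[1:H, 2:(W + 1)] + pad[3:(H + 2), 2:(W + 1)] +
        pad[2:(H + 1), 1:W] + pad[2:(H + 1), 3:(W + 2)]
  sum((4 - nb)[mask > 0])
}

#' Classic region measurements of a binary mask
#'
#' Computes, over the full foreground: area, bounding box, convex hull area
#' (hull of the pixel squares, so solidity is always <= 1), eccentricity of
#' the ellipse with matching second central moments (with the 1/12 unit-pixel
#' variance added, keeping eccentricity < 1 even for 1-px-wide regions),
#' equivalent diameter `sqrt(4*area/pi)`, Euler number (8-connected
#' components minus 4-connected holes), perimeter (count of exposed pixel
#' edges, 4-neighbourhood), and solidity.
#'
#' @param mask binary matrix.
#' @return object of class `region_measurements` (named list, all `_px`
#'   fields in pixel units).
#' @export
region_measurements <- function(mask) {
  idx <- which(mask > 0, arr.ind = TRUE)
  if (nrow(idx) == 0) stop("empty mask")
  area <- nrow(idx)
  bbox_h <- diff(range(idx[, 1])) + 1
  bbox_w <- diff(range(idx[, 2])) + 1
  conv <- convex_hull_area(idx, mask)

  mu_y <- mean(idx[, 1]); mu_x <- mean(idx[, 2])
  cyy <- mean((idx[, 1] - mu_y)^2) + 1 / 12
  cxx <- mean((idx[, 2] - mu_x)^2) + 1 / 12
  cxy <- mean((idx[, 1] - mu_y) * (idx[, 2] - mu_x))
  tr <- cxx + cyy; det <- cxx * cyy - cxy^2
  disc <- sqrt(max(0, tr^2 / 4 - det))
  l1 <- tr / 2 + disc; l2 <- tr / 2 - disc
  ecc <- if (l1 <= 0) 0 else sqrt(max(0, 1 - l2 / l1))

  ncomp <- max(label_components(mask, 8L))
  bg <- 1L - mask
  bl <- label_components(bg, 4L)
  border_labels <- unique(c(bl[1, ], bl[nrow(bl), ], bl[, 1], bl[, ncol(bl)]))
  nholes <- length(setdiff(unique(bl[bl > 0]), border_labels))

  structure(list(area_px = area,
                 bbox_height_px = bbox_h, bbox_width_px = bbox_w,
                 convex_area_px = conv,
                 eccentricity = ecc,
                 equivalent_diameter_px = sqrt(4 * area / pi),
                 euler_number = ncomp - nholes,
                 perimeter_px = perimeter_edges(mask),
                 solidity = area / conv),
            class = "region_measurements")
}
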