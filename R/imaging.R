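#' Read a plant photograph
#'
#' Reads a TIF or PNG image into a `height x width x 3` RGB array scaled to
#' 0-255. Grayscale files are replicated across channels.
#'
#' @param path file path; format chosen by extension.
#' @return numeric array, dimensions `c(H, W, 3)`.
#' @export
read_plant_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
                "tif" = , "tiff" = tiff::readTIFF(path),
                "png" = png::readPNG(path),
                stop("unsupported image format: ", ext))
  if (length(dim(img)) == 2) img <- array(rep(img, 3), dim = c(dim(img), 3))
  if (dim(img)[3] > 3) img <- img[, , 1:3, drop = FALSE]
  img * 255
}

rgb_to_gray <- function(image) {
  # ITU-R BT.601 luminance weights
  0.299 * image[, , 1] + 0.587 * image[, , 2] + 0.114 * image[, , 3]
}

rgb_saturation <- function(image) {
  mx <- pmax(image[, , 1], image[, , 2], image[, , 3])
  mn <- pmin(image[, , 1], image[, , 2], image[, , 3])
  s <- (mx - mn) / mx
  s[mx == 0] <- 0
  s
}

#' Binarize a plant photograph
#'
#' Separates the dark plant (and divider line) from the white baseboard.
#' The image is converted to grayscale (BT.601 luminance) and to HSV
#' saturation; the saturation channel, scaled to the 0-255 gray range, is
#' subtracted from the grayscale image (clamped at 0) and Otsu's threshold is
#' applied to the difference. Pixels below the threshold (darker / more
#' saturated than the white board) form the foreground. Connected components
#' (8-connectivity) smaller than `min_area_frac` of the image area are
#' removed.
#'
#' @param image RGB array as from [read_plant_image()].
#' @param min_area_frac components smaller than this fraction of the image
#'   area are discarded (default 0.01%).
#' @return binary integer matrix (0/1) of the same height/width.
#' @export
binarize_plant <- function(image, min_area_frac = 1e-4) {
  g <- rgb_to_gray(image)
  s <- rgb_saturation(image) * 255
  d <- pmax(g - s, 0)
  if (diff(range(d)) < 1e-8) stop("no contrast")
  thr <- EBImage::otsu(EBImage::Image(d / 255), range = c(0, 1))
  mask <- (d / 255 < thr) * 1L
  lab <- label_components(mask, 8L)
  if (max(lab) > 0) {
    sizes <- tabulate(lab[lab > 0])
    keep <- which(sizes >= min_area_frac * length(mask))
    mask <- matrix(as.integer(lab %in% keep), nrow(mask), ncol(mask))
  }
  if (sum(mask) == 0) stop("no plant detected")
  mask
}

#' Locate the divider line between shoot and root
#'
#' Finds the dark horizontal baseboard line by the row with minimum median
#' intensity over a central column band (the median bridges the central gap
#' where the crown sits). Ties break to the topmost row.
#'
#' @param image RGB array.
#' @param col_margin fraction of columns trimmed from each side before taking
#'   row medians.
#' @param dark_margin minimum darkness (0-255) of the divider row relative to
#'   the background level; below it the divider is declared absent.
#' @return divider row index.
#' @export
detect_divider <- function(image, col_margin = 0.05, dark_margin = 50) {
  g <- rgb_to_gray(image)
  W <- ncol(g)
  cols <- max(1, floor(W * col_margin)):min(W, ceiling(W * (1 - col_margin)))
  rowmed <- apply(g[, cols, drop = FALSE], 1, median)
  bg <- median(g)
  if (bg - min(rowmed) < dark_margin) stop("divider not found")
  # the line spans several rows: return the centre of the contiguous run of
  # near-minimum rows containing the darkest row (ties: topmost run wins)
  cand <- which(rowmed <= min(rowmed) + 2)
  runs <- split(cand, cumsum(c(1, diff(cand) > 1)))
  hit <- which.min(rowmed)
  run <- runs[[which(vapply(runs, function(r) hit %in% r, logical(1)))[1]]]
  as.integer(floor(mean(run)))
}

#' Split a plant mask at the divider and locate the crown
#'
#' Partitions a binary plant mask into shoot (strictly above the divider
#' band) and root (strictly below), and places the crown at the divider row,
#' at the column midpoint of the foreground span in the first root row below
#' the band. Root tissue is contiguous at the divider, so the root-top span
#' anchors the crown more reliably than petioles that may straddle the gap.
#'
#' @param mask binary matrix from [binarize_plant()].
#' @param divider_row row index from [detect_divider()].
#' @param band half-height (px) of the exclusion band around the divider;
#'   rows within `divider_row +/- band` belong to neither section.
#' @param border what to do when foreground touches the image border
#'   (such plants cannot be measured reliably): `"error"`, `"warn"`, or
#'   `"ignore"`.
#' @return object of class `plant_segments`: list with `shoot_mask`,
#'   `root_mask`, `divider_row`, `crown = c(row, col)`.
#' @export
split_and_locate_crown <- function(mask, divider_row, band = 3,
                                   border = c("warn", "error", "ignore")) {
  border <- match.arg(border)
  H <- nrow(mask); W <- ncol(mask)
  shoot <- mask; shoot[row(mask) >= divider_row - band] <- 0L
  root <- mask; root[row(mask) <= divider_row + band] <- 0L
  if (sum(shoot) == 0) stop("no shoot foreground above the divider")
  if (sum(root) == 0) stop("no root foreground below the divider")
  # the divider line itself always reaches the image edges, so overlap is
  # judged on the plant sections only
  pl <- shoot + root
  touches <- sum(pl[1, ]) + sum(pl[H, ]) + sum(pl[, 1]) + sum(pl[, W])
  if (touches > 0) {
    msg <- "plant overlaps the image border"
    if (border == "error") stop(msg) else if (border == "warn") warning(msg)
  }
  first_root_row <- min(which(rowSums(root) > 0))
  cols <- which(root[first_root_row, ] > 0)
  crown_col <- (min(cols) + max(cols)) / 2
  structure(list(shoot_mask = shoot, root_mask = root,
                 divider_row = divider_row,
                 crown = c(row = divider_row, col = crown_col)),
            class = "plant_segments")
}

#' Segment a photograph into shoot and root with one call
#'
#' Convenience wrapper: [binarize_plant()], [detect_divider()],
#' [split_and_locate_crown()].
#' @inheritParams binarize_plant
#' @inheritParams split_and_locate_crown
#' @inheritParams detect_divider
#' @return a `plant_segments` object.
#' @export
segment_plant <- function(image, min_area_frac = 1e-4, band = 3,
                          border = "warn", dark_margin = 50) {
  mask <- binarize_plant(image, min_area_frac = min_area_frac)
  dr <- detect_divider(image, dark_margin = dark_margin)
  split_and_locate_crown(mask, dr, band = band, border = border)
}

#' Write a QC overlay image
#'
#' Writes a PNG of the binarized plant (white on black) with the divider row
#' drawn in red and the crown marked by a green disk, mirroring the fidelity
#' overlays produced per image by the measurement pipeline.
#'
#' @param segments a `plant_segments` object.
#' @param path output PNG path.
#' @export
write_qc_overlay <- function(segments, path) {
  m <- pmax(segments$shoot_mask, segments$root_mask)
  H <- nrow(m); W <- ncol(m)
  img <- array(as.numeric(m), dim = c(H, W, 3))
  img[segments$divider_row, , 1] <- 1
  img[segments$divider_row, , 2:3] <- 0
  cr <- segments$crown
  rr <- max(1, round(cr[1]) - 3):min(H, round(cr[1]) + 3)
  cc <- max(1, round(cr[2]) - 3):min(W, round(cr[2]) + 3)
  img[rr, cc, 2] <- 1; img[rr, cc, c(1, 3)] <- 0
  png::writePNG(img, path)
  invisible(path)
}
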