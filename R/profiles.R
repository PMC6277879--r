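new_biomass_profile <- function(values, kind, normalized, source_area_px) {
  structure(list(values = values, n_bins = length(values), kind = kind,
                 normalized = normalized, source_area_px = source_area_px),
            class = "biomass_profile")
}

#' @export
print.biomass_profile <- function(x, ...) {
  cat(sprintf("<biomass_profile> kind=%s n=%d area=%d normalized=%s\n",
              x$kind, x$n_bins, x$source_area_px, x$normalized))
  invisible(x)
}

#' Shoot biomass profile on a crown-anchored elliptical grid
#'
#' Integrates the shoot mask over the angular sweep of a half-elliptical grid
#' anchored at the crown: every foreground pixel is assigned a normalized
#' elliptical radius `rho = sqrt(((x-cx)/a)^2 + ((y-cy)/b)^2)` and counted
#' into one of `n` half-open radius bins `[i/n, (i+1)/n)` (the top edge
#' `rho == 1` falls in the last bin). The bin totals therefore conserve the
#' shoot pixel count exactly.
#'
#' By default the semi-axes are taken from the shoot's own extent about the
#' crown (`a` = maximum horizontal distance, `b` = maximum height) and then
#' inflated by a common factor if needed so that every pixel has `rho <= 1`.
#' For population analyses pass a common `semi_axes` for all plants (the
#' batch pipeline uses `a` = half image width, `b` = crown row) so profiles
#' share an absolute radius scale; with explicit axes, pixels beyond `rho = 1`
#' are counted into the last bin so conservation still holds.
#'
#' @param shoot binary shoot mask.
#' @param crown numeric `c(row, col)` crown point.
#' @param n number of radius bins (default 1000).
#' @param semi_axes optional numeric `c(a, b)` ellipse semi-axes in px.
#' @return a `biomass_profile` of kind `"shoot-radial"`.
#' @export
shoot_biomass_profile <- function(shoot, crown, n = 1000, semi_axes = NULL) {
  idx <- which(shoot > 0, arr.ind = TRUE)
  if (nrow(idx) == 0)
    return(new_biomass_profile(numeric(n), "shoot-radial", FALSE, 0L))
  dy <- crown[1] - idx[, 1]           # positive above the crown
  dx <- idx[, 2] - crown[2]
  if (any(dy < 0)) warning("crown lies inside the shoot mask interior")
  if (is.null(semi_axes)) {
    a <- max(abs(dx), 1); b <- max(dy, 1)
    rho <- sqrt((dx / a)^2 + (dy / b)^2)
    s <- max(rho)
    if (s > 1) rho <- rho / s         # inflate axes so the grid covers all
  } else {
    rho <- sqrt((dx / semi_axes[1])^2 + (dy / semi_axes[2])^2)
  }
  bin <- pmin(floor(rho * n), n - 1) + 1
  new_biomass_profile(as.numeric(tabulate(bin, nbins = n)),
                      "shoot-radial", FALSE, nrow(idx))
}

#' Root biomass profile from row sums
#'
#' Counts foreground pixels along each horizontal sweep of the root mask,
#' from the first to the last nonzero row (so stray wisps removed by cleanup
#' do not stretch the profile), and resamples the row-sum vector to `n`
#' points by linear interpolation over that extent.
#'
#' @param root binary root mask.
#' @param n profile length (default 1000).
#' @return a `biomass_profile` of kind `"root-depth"`; `source_area_px` is
#'   the raw (pre-resampling) pixel count.
#' @export
root_biomass_profile <- function(root, n = 1000) {
  rs <- rowSums(root)
  nz <- which(rs > 0)
  if (length(nz) == 0) stop("no root")
  raw <- rs[min(nz):max(nz)]
  # sample at normalized row centres so profiles are invariant under
  # integer upsampling of the mask
  vals <- if (length(raw) == 1) rep(raw, n) else
    approx((seq_along(raw) - 0.5) / length(raw), raw,
           xout = (seq_len(n) - 0.5) / n, rule = 2)$y
  new_biomass_profile(vals, "root-depth", FALSE, as.integer(sum(raw)))
}

#' Normalize a root profile for shape analysis
#'
#' Length normalization is the fixed-length resampling already applied by
#' [root_biomass_profile()]; width normalization divides by the maximum row
#' sum so values lie in `[0, 1]` with maximum exactly 1. Two geometrically
#' similar roots thus map to (numerically) identical profiles.
#'
#' @param profile a `biomass_profile` of kind `"root-depth"`.
#' @return the normalized profile.
#' @export
normalize_root_profile <- function(profile) {
  stopifnot(inherits(profile, "biomass_profile"))
  if (profile$kind != "root-depth") stop("profile is not a root profile")
  m <- max(profile$values)
  if (m <= 0) stop("all-zero profile cannot be normalized")
  out <- profile
  out$values <- profile$values / m
  out$normalized <- TRUE
  out
}
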