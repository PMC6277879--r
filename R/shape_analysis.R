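#' Population principal components analysis of biomass profiles
#'
#' Centred (unscaled) PCA of a profile matrix. Shoot profiles are analysed
#' raw, so the first component reflects biomass magnitude; root profiles
#' should be normalized first so components reflect shape only. Each
#' component's sign is fixed so its largest-magnitude entry is positive.
#'
#' @param profiles numeric matrix, one profile per row (>= 3 rows).
#' @return object of class `population_pca`: `mean_profile`, `components`
#'   (columns, orthonormal), `pve` (percent variance explained,
#'   non-increasing), `scores`, `sdev`.
#' @export
fit_population_pca <- function(profiles) {
  X <- as.matrix(profiles)
  if (nrow(X) < 3) stop("need at least 3 individuals")
  pr <- prcomp(X, center = TRUE, scale. = FALSE)
  tot <- sum(pr$sdev^2)
  if (tot < 1e-12) stop("zero variance")
  keep <- which(pr$sdev^2 > 1e-12 * tot)
  comp <- pr$rotation[, keep, drop = FALSE]
  scores <- pr$x[, keep, drop = FALSE]
  for (j in seq_len(ncol(comp))) {
    if (comp[which.max(abs(comp[, j])), j] < 0) {
      comp[, j] <- -comp[, j]; scores[, j] <- -scores[, j]
    }
  }
  structure(list(mean_profile = pr$center, components = comp,
                 pve = 100 * pr$sdev[keep]^2 / tot,
                 scores = scores, sdev = pr$sdev[keep]),
            class = "population_pca")
}

#' Eigenvector sweep of a principal component
#'
#' Reconstructs profiles at `mean + k * sd(scores) * component` for each
#' multiple `k`, visualizing what shape variation a component encodes.
#'
#' @param pca a `population_pca`.
#' @param component component index.
#' @param k_values standard-deviation multiples (default -2..2).
#' @return matrix of reconstructed profiles, one row per `k` (rownames give
#'   `k`).
#' @export
eigen_sweep <- function(pca, component, k_values = c(-2, -1, 0, 1, 2)) {
  stopifnot(inherits(pca, "population_pca"))
  if (component < 1 || component > ncol(pca$components))
    stop("component index out of range")
  s <- sd(pca$scores[, component])
  out <- t(vapply(k_values, function(k)
    pca$mean_profile + k * s * pca$components[, component],
    numeric(length(pca$mean_profile))))
  rownames(out) <- as.character(k_values)
  out
}
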