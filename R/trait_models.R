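#' Petiole-width descriptor from distance transform and skeleton
#'
#' Applies the Euclidean distance transform (EDT) to the binary shoot mask,
#' reduces the mask to its medial skeleton (Zhang-Suen thinning), and samples
#' the EDT at the skeleton pixels. Twice the EDT at a skeleton point
#' approximates the local full width of the object. The sampled values are
#' summarized as a fixed-length histogram (normalized to sum 1) which serves
#' as the regression input for width prediction.
#'
#' @param shoot binary shoot mask.
#' @param n_bins histogram length (default 100).
#' @param edt_cap upper edge of the histogram range in px. Defaults to the
#'   99.5th percentile of this mask's skeleton EDT values; pass a common cap
#'   (as the batch pipeline does) so descriptors are comparable across
#'   images. Values above the cap count into the last bin.
#' @return object of class `width_feature`: `descriptor` (sums to 1),
#'   `n_skeleton_px`, `edt_max_px`, `edt_cap`.
#' @export
width_feature <- function(shoot, n_bins = 100, edt_cap = NULL) {
  if (sum(shoot) == 0) stop("empty mask")
  edt <- as.matrix(EBImage::distmap(matrix(as.numeric(shoot > 0),
                                           nrow(shoot), ncol(shoot))))
  skel <- thin_zhangsuen(matrix(as.integer(shoot > 0),
                                nrow(shoot), ncol(shoot)))
  vals <- edt[skel > 0]
  n_sk <- length(vals)
  cap <- edt_cap %||% as.numeric(quantile(vals, 0.995))
  if (cap <= 0) cap <- 1
  clamped <- pmin(vals, cap)
  bin <- pmin(pmax(ceiling(clamped / cap * n_bins), 1), n_bins)
  counts <- tabulate(bin, nbins = n_bins)
  descriptor <- if (n_sk > 0) counts / n_sk else counts
  structure(list(descriptor = descriptor, n_skeleton_px = n_sk,
                 edt_max_px = max(edt), edt_cap = cap),
            class = "width_feature")
}

# PLS1 (NIPALS) coefficient path: regression coefficients for 1..kmax latent
# components on centred data.
pls1_path <- function(X, y, kmax) {
  x_mean <- colMeans(X); y_mean <- mean(y)
  E <- sweep(X, 2, x_mean); f <- y - y_mean
  p <- ncol(X)
  Wm <- matrix(0, p, 0); Pm <- matrix(0, p, 0); qv <- numeric(0)
  tol <- 1e-12 * max(1, sum(E^2)) + 1e-300
  for (j in seq_len(kmax)) {
    w <- drop(crossprod(E, f))
    nw <- sqrt(sum(w^2))
    if (!is.finite(nw) || nw^2 < tol) break
    w <- w / nw
    t_ <- drop(E %*% w)
    tt <- sum(t_^2)
    if (tt < tol) break
    pj <- drop(crossprod(E, t_)) / tt
    qj <- sum(f * t_) / tt
    E <- E - tcrossprod(t_, pj)
    f <- f - qj * t_
    Wm <- cbind(Wm, w); Pm <- cbind(Pm, pj); qv <- c(qv, qj)
  }
  k_eff <- ncol(Wm)
  coefs <- matrix(0, p, max(k_eff, 1))
  if (k_eff > 0) {
    for (k in seq_len(k_eff)) {
      Wk <- Wm[, 1:k, drop = FALSE]
      R <- Wk %*% solve(crossprod(Pm[, 1:k, drop = FALSE], Wk))
      coefs[, k] <- R %*% qv[1:k]
    }
  }
  list(coefs = coefs, k_eff = k_eff, x_mean = x_mean, y_mean = y_mean)
}

pls_point_predict <- function(path, x, k) {
  drop((x - path$x_mean) %*% path$coefs[, k, drop = FALSE]) + path$y_mean
}

#' Fit a PLS1 regression with cross-validated component selection
#'
#' Partial least squares regression of a single response on a (possibly
#' highly collinear) feature matrix. The retained number of latent
#' components minimizes the cross-validated RMSE; the one-fold-holdout
#' selection is interpreted as leave-one-out by default, with a single
#' random holdout split available as an alternative.
#'
#' With as many components as the feature rank, PLS1 predictions coincide
#' with ordinary least squares.
#'
#' @param features numeric matrix (rows = samples).
#' @param targets numeric response vector.
#' @param max_components upper bound on latent components.
#' @param cv `"loo"` (leave-one-out) or `"holdout"` (single random 75/25
#'   split).
#' @param seed seed for the holdout split.
#' @param target_name label stored in the model.
#' @return object of class `pls_model` with `coef`, `intercept`,
#'   `n_components`, `cv_rmse_by_k`, `x_mean`, `y_mean`, `target_name`.
#' @export
fit_pls <- function(features, targets, max_components = 10,
                    cv = c("loo", "holdout"), seed = 1,
                    target_name = "target") {
  cv <- match.arg(cv)
  X <- as.matrix(features); y <- as.numeric(targets)
  n <- nrow(X)
  if (n < 5) stop("need at least 5 training samples")
  if (n != length(y)) stop("features and targets are not row-matched")
  kmax <- max(1, min(max_components, ncol(X), n - 2))
  full <- pls1_path(X, y, kmax)
  if (full$k_eff == 0) {
    warning("degenerate features or constant target; intercept-only model")
    model <- structure(list(coef = numeric(ncol(X)), intercept = full$y_mean,
                            n_components = 1L,
                            cv_rmse_by_k = sd(y) %||% 0,
                            x_mean = full$x_mean, y_mean = full$y_mean,
                            target_name = target_name, cv = cv),
                       class = "pls_model")
    return(model)
  }
  kmax <- full$k_eff
  if (cv == "loo") {
    err <- matrix(NA_real_, n, kmax)
    for (i in seq_len(n)) {
      pi_ <- pls1_path(X[-i, , drop = FALSE], y[-i], kmax)
      kk <- max(pi_$k_eff, 1)
      pred <- vapply(seq_len(kmax), function(k)
        pls_point_predict(pi_, X[i, ], min(k, kk)), numeric(1))
      err[i, ] <- pred - y[i]
    }
    cv_rmse <- sqrt(colMeans(err^2))
  } else {
    set.seed(seed)
    hold <- sample(n, max(1, round(n / 4)))
    pi_ <- pls1_path(X[-hold, , drop = FALSE], y[-hold], kmax)
    kk <- max(pi_$k_eff, 1)
    cv_rmse <- vapply(seq_len(kmax), function(k) {
      pred <- apply(X[hold, , drop = FALSE], 1, pls_point_predict,
                    path = pi_, k = min(k, kk))
      sqrt(mean((pred - y[hold])^2))
    }, numeric(1))
  }
  k_opt <- which.min(cv_rmse)
  coef_k <- full$coefs[, k_opt]
  structure(list(coef = coef_k,
                 intercept = full$y_mean - drop(full$x_mean %*% coef_k),
                 n_components = k_opt, cv_rmse_by_k = cv_rmse,
                 x_mean = full$x_mean, y_mean = full$y_mean,
                 target_name = target_name, cv = cv),
            class = "pls_model")
}

#' Predict from a fitted PLS model
#'
#' @param object a `pls_model`.
#' @param newdata numeric matrix or vector of features.
#' @param ... unused.
#' @return numeric predictions.
#' @export
predict.pls_model <- function(object, newdata, ...) {
  X <- if (is.null(dim(newdata))) {
    if (length(object$coef) == 1) matrix(newdata, ncol = 1)
    else matrix(newdata, nrow = 1)
  } else as.matrix(newdata)
  if (ncol(X) != length(object$coef))
    stop("descriptor length does not match the trained model")
  drop(X %*% object$coef) + object$intercept
}

#' Predict petiole width for one plant
#'
#' Applies a trained width model to a [width_feature()] descriptor.
#' Predictions are clamped at zero. Targets are modelled in the units of the
#' training table (cm); if `cal` is supplied the model is assumed to have
#' been trained in px and the result is converted to cm.
#'
#' @param model a `pls_model` trained on width descriptors.
#' @param feature a `width_feature`.
#' @param cal optional [calibration()] for px-trained models.
#' @return predicted petiole width (cm, or training units).
#' @export
predict_petiole_width <- function(model, feature, cal = NULL) {
  stopifnot(inherits(feature, "width_feature"))
  p <- max(0, predict(model, feature$descriptor))
  if (!is.null(cal)) p <- to_cm(p, cal) else p
}

#' Area-to-width ratio feature for petiole counting
#'
#' Digital shoot biomass (foreground pixel count) divided by the predicted
#' average petiole width: petioles of roughly constant width contribute area
#' proportional to their number, so this ratio tracks petiole count.
#'
#' @param shoot binary shoot mask or a precomputed area (px).
#' @param predicted_width_px predicted petiole width in px (> 0).
#' @return ratio in px.
#' @export
petiole_count_feature <- function(shoot, predicted_width_px) {
  if (predicted_width_px <= 0) stop("petiole width must be positive")
  area <- if (is.matrix(shoot)) sum(shoot > 0) else as.numeric(shoot)
  area / predicted_width_px
}

#' Predict petiole number
#'
#' @param model a `pls_model` trained on count features.
#' @param features numeric vector/matrix of count features (the area/width
#'   ratio, optionally with the raw area).
#' @return continuous predicted count (unrounded, clamped at 0).
#' @export
predict_petiole_number <- function(model, features) {
  if (!inherits(model, "pls_model")) stop("untrained model")
  pmax(0, predict(model, features))
}

nnet_forward <- function(wts, size, X) {
  p <- (length(wts) - (size + 1)) / size - 1
  Wh <- matrix(wts[seq_len((p + 1) * size)], nrow = p + 1)
  wo <- wts[((p + 1) * size + 1):length(wts)]
  Z <- 1 / (1 + exp(-(cbind(1, X) %*% Wh)))
  drop(cbind(1, Z) %*% wo)
}

#' Fit the petiole-length model (SBP principal components + neural network)
#'
#' Shoot biomass profiles are reduced by principal components analysis
#' (components retained up to `var_explained` percent of variance, capped at
#' `max_pcs`); the standardized scores feed a feed-forward network with one
#' hidden layer (logistic units) and a linear output, trained with weight
#' decay from a seeded initialization, so refits are bit-identical.
#'
#' @param sbps matrix of shoot biomass profiles (rows = plants).
#' @param lengths petiole-length targets (training units, typically cm).
#' @param hidden_units hidden layer size (default 10).
#' @param seed integer seed for weight initialization.
#' @param var_explained percent variance the retained PCs must cover.
#' @param max_pcs hard cap on retained PCs.
#' @param maxit,decay optimizer iterations and weight decay.
#' @return object of class `length_model`.
#' @export
fit_length_model <- function(sbps, lengths, hidden_units = 10, seed = 1,
                             var_explained = 95, max_pcs = 10,
                             maxit = 500, decay = 1e-2) {
  X <- as.matrix(sbps); y <- as.numeric(lengths)
  if (nrow(X) < 20) stop("need at least 20 training samples")
  if (nrow(X) != length(y)) stop("profiles and targets are not row-matched")
  pr <- prcomp(X, center = TRUE, scale. = FALSE)
  tot <- sum(pr$sdev^2)
  if (tot < 1e-12) {
    # uninformative profiles: constant model at the target mean
    return(structure(list(constant = mean(y), n_pcs = 0L, seed = seed,
                          hidden_units = hidden_units),
                     class = "length_model"))
  }
  pve <- cumsum(100 * pr$sdev^2 / tot)
  n_pcs <- min(which(pve >= var_explained))
  n_cap <- min(nrow(X) - 1, ncol(X))
  if (n_pcs > n_cap) {
    warning("fewer samples than components; reducing to ", n_cap)
    n_pcs <- n_cap
  }
  n_pcs <- min(n_pcs, max_pcs)
  basis <- pr$rotation[, seq_len(n_pcs), drop = FALSE]
  scores <- pr$x[, seq_len(n_pcs), drop = FALSE]
  s_mean <- colMeans(scores); s_sd <- pmax(apply(scores, 2, sd), 1e-12)
  Z <- sweep(sweep(scores, 2, s_mean), 2, s_sd, "/")
  y_mean <- mean(y); y_sd <- max(sd(y), 1e-12)
  ys <- (y - y_mean) / y_sd
  set.seed(seed)
  net <- nnet::nnet(Z, ys, size = hidden_units, linout = TRUE,
                    maxit = maxit, decay = decay, trace = FALSE)
  structure(list(center = pr$center, basis = basis, n_pcs = n_pcs,
                 s_mean = s_mean, s_sd = s_sd,
                 y_mean = y_mean, y_sd = y_sd,
                 wts = net$wts, hidden_units = hidden_units, seed = seed),
            class = "length_model")
}

#' Predict petiole length from shoot biomass profiles
#'
#' @param model a `length_model`.
#' @param sbps matrix (or single vector) of shoot biomass profiles on the
#'   same grid as the training profiles.
#' @return predicted lengths (training units, clamped at 0).
#' @export
predict_petiole_length <- function(model, sbps) {
  stopifnot(inherits(model, "length_model"))
  X <- if (is.null(dim(sbps))) matrix(sbps, nrow = 1) else as.matrix(sbps)
  if (!is.null(model$constant)) return(rep(model$constant, nrow(X)))
  S <- sweep(X, 2, model$center) %*% model$basis
  Z <- sweep(sweep(S, 2, model$s_mean), 2, model$s_sd, "/")
  pmax(0, nnet_forward(model$wts, model$hidden_units, Z) *
         model$y_sd + model$y_mean)
}

#' Save or load a trait model as versioned JSON
#'
#' Both `pls_model` and `length_model` objects round-trip through a plain
#' JSON file (coefficients, preprocessing parameters, metadata, seed), so
#' predictions from a reloaded model are bit-identical.
#'
#' @param model a `pls_model` or `length_model`.
#' @param path JSON file path.
#' @return `save_trait_model` returns `path` invisibly; `load_trait_model`
#'   the restored model.
#' @export
save_trait_model <- function(model, path) {
  type <- class(model)[1]
  payload <- c(list(format_version = 1L, type = type), unclass(model))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = I(17))
  invisible(path)
}

#' @rdname save_trait_model
#' @export
load_trait_model <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  type <- x$type
  x$format_version <- NULL; x$type <- NULL
  for (nm in c("basis")) if (!is.null(x[[nm]])) x[[nm]] <- as.matrix(x[[nm]])
  structure(x, class = type)
}
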