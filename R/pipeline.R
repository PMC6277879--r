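measure_one <- function(path, n_bins, min_area_frac, band, border,
                        edt_cap, px_per_cm) {
  img <- read_plant_image(path)
  W <- dim(img)[2]
  mask <- binarize_plant(img, min_area_frac = min_area_frac)
  dr <- detect_divider(img)
  segs <- split_and_locate_crown(mask, dr, band = band, border = border)
  # common absolute-radius grid so profiles are comparable across the batch
  sbp <- shoot_biomass_profile(segs$shoot_mask, segs$crown, n = n_bins,
                               semi_axes = c(W / 2, dr))
  rootp <- root_biomass_profile(segs$root_mask, n = n_bins)
  rootn <- normalize_root_profile(rootp)
  wf <- width_feature(segs$shoot_mask, edt_cap = edt_cap)
  ms <- region_measurements(segs$shoot_mask)
  mr <- region_measurements(segs$root_mask)
  rec <- list(image_id = sub("\\.[^.]+$", "", basename(path)),
              divider_row = segs$divider_row,
              crown_row = unname(segs$crown[1]),
              crown_col = unname(segs$crown[2]),
              shoot = unclass(ms), root = unclass(mr),
              sbp = sbp$values, root_profile = rootn$values,
              root_area_raw = rootp$source_area_px,
              width_descriptor = wf$descriptor,
              n_skeleton_px = wf$n_skeleton_px)
  if (!is.null(px_per_cm)) {
    cal <- calibration(px_per_cm)
    rec$shoot_cm <- list(bbox_height_cm = to_cm(ms$bbox_height_px, cal),
                         bbox_width_cm = to_cm(ms$bbox_width_px, cal),
                         area_cm2 = to_cm(ms$area_px, cal, 2))
    rec$root_cm <- list(bbox_height_cm = to_cm(mr$bbox_height_px, cal),
                        bbox_width_cm = to_cm(mr$bbox_width_px, cal),
                        area_cm2 = to_cm(mr$area_px, cal, 2))
  }
  list(record = rec, segments = segs)
}

flatten_region <- function(x, prefix) {
  v <- unlist(x)
  setNames(as.numeric(v), paste0(prefix, "_", names(v)))
}

#' Batch measurement stage
#'
#' Processes every image in a batch independently through segmentation,
#' biomass profiles, morphometrics, and the petiole-width descriptor.
#' A failing image is logged with its reason and never aborts the batch.
#' Outputs are written under `out_dir`: `morphometrics.csv`,
#' `sbp.csv`, `root_profile.csv` (width-normalized), `width_descriptor.csv`,
#' `failures.csv`, one combined JSON record per image under `json/`, and
#' (optionally) one QC overlay PNG per image under `qc/`.
#'
#' @param input directory containing `.png`/`.tif` images, or a character
#'   vector of image paths.
#' @param out_dir output directory (created).
#' @param px_per_cm optional calibration; when given, cm fields are added.
#' @param n_bins profile length.
#' @param min_area_frac component cleanup threshold, see [binarize_plant()].
#' @param band divider exclusion band half-height.
#' @param border border-overlap policy (such plants are counted as failures
#'   under the default `"error"`).
#' @param edt_cap common histogram cap (px) for the width descriptor.
#' @param write_qc write QC overlay PNGs.
#' @return (invisibly) list with `records`, `failures` (data.frame of
#'   `image_id`, `reason`), and `measurements` (wide data.frame).
#' @export
run_measure <- function(input, out_dir, px_per_cm = NULL, n_bins = 1000,
                        min_area_frac = 1e-4, band = 3, border = "error",
                        edt_cap = 30, write_qc = FALSE) {
  files <- if (length(input) == 1 && dir.exists(input))
    list.files(input, pattern = "\\.(png|tif|tiff)$", ignore.case = TRUE,
               full.names = TRUE)
  else input
  if (length(files) == 0) stop("no input images")
  dir.create(file.path(out_dir, "json"), recursive = TRUE,
             showWarnings = FALSE)
  if (write_qc) dir.create(file.path(out_dir, "qc"), showWarnings = FALSE)

  records <- list(); fails <- list()
  for (f in files) {
    id <- sub("\\.[^.]+$", "", basename(f))
    res <- tryCatch(
      measure_one(f, n_bins, min_area_frac, band, border, edt_cap,
                  px_per_cm),
      error = function(e) conditionMessage(e))
    if (is.character(res)) {
      fails[[id]] <- data.frame(image_id = id, reason = res)
      next
    }
    records[[id]] <- res$record
    jsonlite::write_json(res$record,
                         file.path(out_dir, "json", paste0(id, ".json")),
                         auto_unbox = TRUE, digits = NA)
    if (write_qc)
      write_qc_overlay(res$segments,
                       file.path(out_dir, "qc", paste0(id, ".png")))
  }
  failures <- if (length(fails)) do.call(rbind, fails) else
    data.frame(image_id = character(), reason = character())
  write.csv(failures, file.path(out_dir, "failures.csv"), row.names = FALSE)

  measurements <- NULL
  if (length(records)) {
    rows <- lapply(records, function(r) {
      base <- c(divider_row = r$divider_row, crown_row = r$crown_row,
                crown_col = r$crown_col,
                flatten_region(r$shoot, "shoot"),
                flatten_region(r$root, "root"),
                root_area_raw = r$root_area_raw,
                n_skeleton_px = r$n_skeleton_px)
      data.frame(image_id = r$image_id, t(base))
    })
    measurements <- do.call(rbind, rows)
    write.csv(measurements, file.path(out_dir, "morphometrics.csv"),
              row.names = FALSE)
    write_profile_csv <- function(field, file) {
      m <- do.call(rbind, lapply(records, function(r) r[[field]]))
      df <- data.frame(image_id = vapply(records, `[[`, "", "image_id"), m)
      write.csv(df, file.path(out_dir, file), row.names = FALSE)
    }
    write_profile_csv("sbp", "sbp.csv")
    write_profile_csv("root_profile", "root_profile.csv")
    write_profile_csv("width_descriptor", "width_descriptor.csv")
  }
  invisible(list(records = records, failures = failures,
                 measurements = measurements))
}

read_profile_csv <- function(path) {
  df <- read.csv(path, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}

#' Batch prediction stage
#'
#' Trains the three petiole predictors on ground-truth rows (petiole width:
#' PLS on the EDT-skeleton histogram; petiole number: PLS on the
#' area-to-width ratio plus raw area; petiole length: SBP principal
#' components feeding a one-hidden-layer network), persists the fitted
#' models as JSON, and predicts all measured images.
#'
#' @param measure_dir output directory of [run_measure()].
#' @param truth data.frame or CSV path with columns `image_id`,
#'   `petiole_number`, `petiole_length_cm`, `petiole_width_cm` (>= 20 rows
#'   matched to measured images).
#' @param out_dir output directory (defaults to `measure_dir`).
#' @param px_per_cm calibration used to express the predicted width in px
#'   for the count ratio.
#' @param seed seed for the network initialization.
#' @param cv component-selection mode for the PLS fits (`"loo"` or
#'   `"holdout"`).
#' @param hidden_units network hidden-layer size.
#' @param max_components PLS component cap.
#' @return (invisibly) list with `predictions` (data.frame), `models`, and
#'   `cv` (CV RMSE records).
#' @export
run_predict <- function(measure_dir, truth, out_dir = measure_dir,
                        px_per_cm = 10, seed = 1, cv = "loo",
                        hidden_units = 10, max_components = 10) {
  if (is.character(truth)) truth <- read.csv(truth)
  need <- c("image_id", "petiole_number", "petiole_length_cm",
            "petiole_width_cm")
  miss <- setdiff(need, names(truth))
  if (length(miss)) stop("missing ground-truth columns: ",
                         paste(miss, collapse = ", "))
  sbps <- read_profile_csv(file.path(measure_dir, "sbp.csv"))
  desc <- read_profile_csv(file.path(measure_dir, "width_descriptor.csv"))
  morpho <- read.csv(file.path(measure_dir, "morphometrics.csv"))
  ids <- morpho$image_id
  train <- intersect(ids, truth$image_id)
  if (length(train) < 20) stop("need ground truth for at least 20 images")
  ti <- match(train, truth$image_id); mi <- match(train, ids)

  if (var(truth$petiole_number[ti]) == 0 ||
      var(truth$petiole_width_cm[ti]) == 0)
    warning("constant ground-truth targets; predictions will be constant")

  width_model <- fit_pls(desc[mi, , drop = FALSE],
                         truth$petiole_width_cm[ti],
                         max_components = max_components, cv = cv,
                         target_name = "petiole_width_cm")
  width_pred_cm <- pmax(0, predict(width_model, desc))
  width_pred_px <- pmax(width_pred_cm * px_per_cm, 1)

  area <- morpho$shoot_area_px
  ratio <- mapply(petiole_count_feature, area, width_pred_px)
  count_X <- cbind(ratio = ratio, area = area)
  count_model <- fit_pls(count_X[mi, , drop = FALSE],
                         truth$petiole_number[ti],
                         max_components = 2, cv = cv,
                         target_name = "petiole_number")
  count_pred <- predict_petiole_number(count_model, count_X)

  length_model <- fit_length_model(sbps[mi, , drop = FALSE],
                                   truth$petiole_length_cm[ti],
                                   hidden_units = hidden_units, seed = seed)
  length_pred <- predict_petiole_length(length_model, sbps)

  predictions <- data.frame(image_id = ids,
                            petiole_width_cm = width_pred_cm,
                            petiole_number = count_pred,
                            petiole_length_cm = length_pred)
  dir.create(file.path(out_dir, "models"), recursive = TRUE,
             showWarnings = FALSE)
  save_trait_model(width_model, file.path(out_dir, "models",
                                          "width_model.json"))
  save_trait_model(count_model, file.path(out_dir, "models",
                                          "count_model.json"))
  save_trait_model(length_model, file.path(out_dir, "models",
                                           "length_model.json"))
  write.csv(predictions, file.path(out_dir, "predictions.csv"),
            row.names = FALSE)
  cv_rec <- list(width = width_model$cv_rmse_by_k,
                 count = count_model$cv_rmse_by_k)
  invisible(list(predictions = predictions,
                 models = list(width = width_model, count = count_model,
                               length = length_model),
                 cv = cv_rec))
}

#' Write a synthetic fixture set to disk
#'
#' Renders a seeded synthetic population as PNG images plus `truth.csv`,
#' ready to be fed to [run_measure()].
#'
#' @param n number of plants.
#' @param seed integer seed.
#' @param dir output directory.
#' @param ... forwarded to [generate_population()].
#' @return (invisibly) the ground-truth data.frame.
#' @export
make_fixtures <- function(n, seed, dir, ...) {
  pop <- generate_population(n, seed = seed, dir = dir, ...)
  invisible(pop$truth)
}
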