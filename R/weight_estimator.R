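#' Geometric weight regression
#'
#' Per-food-class neural-network regression from image geometry to
#' portion weight. Two variants are trained for every class: a
#' spoon-corrected model on an 11-element feature vector (food area
#' fraction, food box corners, reference-spoon area fraction and box
#' corners, angle/90) and a no-spoon model on the 6-element vector with
#' the reference fields dropped. Both use dense layers 100/50/25 with
#' rectified-linear activations, a linear output, squared-error loss and
#' Adam. The spoon features are the only carrier of the unobserved pixel
#' scale, so the spoon-corrected variant can undo camera-distance
#' variation while the no-spoon variant cannot.
#'
#' @name weight_estimator
NULL

FEATURES_WITH_REF <- c("area", "xmin", "ymin", "xmax", "ymax",
                       "ref_area", "ref_xmin", "ref_ymin", "ref_xmax",
                       "ref_ymax", "angle_norm")
FEATURES_NO_REF <- c("area", "xmin", "ymin", "xmax", "ymax", "angle_norm")

#' Assemble the feature vector for one scene item
#'
#' Food area is the segmentation-mask area fraction when available,
#' otherwise the bounding-box area (flagged via the `area_from_box`
#' attribute); the reference area is always the spoon's bounding-box
#' area. The shooting angle enters as angle/90.
#'
#' @param scene An `annotated_scene`.
#' @param item One row of `scene$items`.
#' @param use_reference If TRUE return the 11-element spoon-corrected
#'   vector (requires `scene$reference`); if FALSE the 6-element vector.
#' @return Named numeric feature vector.
#' @export
extract_features <- function(scene, item, use_reference = !is.null(scene$reference)) {
  if (use_reference && is.null(scene$reference)) {
    stop("scene has no reference spoon; use the no-reference variant ",
         "(use_reference = FALSE)", call. = FALSE)
  }
  ma <- item$mask_area_fraction
  from_box <- is.null(ma) || is.na(ma)
  area <- if (from_box) bbox_area(item) else ma
  feats <- c(area = area, xmin = item$xmin, ymin = item$ymin,
             xmax = item$xmax, ymax = item$ymax)
  if (use_reference) {
    ref <- scene$reference
    feats <- c(feats,
               ref_area = bbox_area(ref),
               ref_xmin = ref$xmin, ref_ymin = ref$ymin,
               ref_xmax = ref$xmax, ref_ymax = ref$ymax)
  }
  feats <- c(feats, angle_norm = scene$angle_deg / 90)
  attr(feats, "area_from_box") <- from_box
  feats
}

#' Flatten scenes into a per-item training table
#'
#' One row per annotated food item, carrying its geometry, the scene's
#' spoon geometry (NA when absent), the angle and the ground-truth
#' weight. This table is the example unit for splitting, training and
#' evaluation.
#'
#' @param scenes List of `annotated_scene`s with ground-truth weights.
#' @return Data.frame with columns `scene`, `code`, `angle_deg`,
#'   `has_ref`, the feature fields and `true_weight_g`.
#' @export
scene_dataset <- function(scenes) {
  rows <- lapply(seq_along(scenes), function(i) {
    scene <- scenes[[i]]
    items <- scene$items
    if (is.null(items) || nrow(items) == 0) return(NULL)
    ref <- scene$reference
    data.frame(
      scene = i, code = items$code, angle_deg = scene$angle_deg,
      has_ref = !is.null(ref),
      area = ifelse(is.na(items$mask_area_fraction),
                    (items$xmax - items$xmin) * (items$ymax - items$ymin),
                    items$mask_area_fraction),
      xmin = items$xmin, ymin = items$ymin, xmax = items$xmax,
      ymax = items$ymax,
      ref_area = if (is.null(ref)) NA_real_ else bbox_area(ref),
      ref_xmin = if (is.null(ref)) NA_real_ else ref$xmin,
      ref_ymin = if (is.null(ref)) NA_real_ else ref$ymin,
      ref_xmax = if (is.null(ref)) NA_real_ else ref$xmax,
      ref_ymax = if (is.null(ref)) NA_real_ else ref$ymax,
      angle_norm = scene$angle_deg / 90,
      true_weight_g = items$true_weight_g,
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Stratified train/test split of the item table
#'
#' Within every (food class, shooting angle) cell, a `1 - train_frac`
#' share of items is drawn for the test set (at least one when the cell
#' has five or more items), so the three angles are represented equally
#' on both sides.
#'
#' @param dataset Item table from [scene_dataset()].
#' @param train_frac Training fraction (default 0.8).
#' @param seed Split seed.
#' @return List with integer row indices `train` and `test`.
#' @export
split_dataset <- function(dataset, train_frac = 0.8, seed = 1L) {
  stopifnot(train_frac > 0, train_frac < 1)
  cells <- split(seq_len(nrow(dataset)),
                 list(dataset$code, dataset$angle_deg), drop = TRUE)
  with_local_seed(seed, {
    test <- integer(0)
    for (rows in cells) {
      n <- length(rows)
      n_test <- round((1 - train_frac) * n)
      if (n >= 5) n_test <- max(1L, n_test)
      if (n_test > 0) test <- c(test, sample(rows, n_test))
    }
    list(train = setdiff(seq_len(nrow(dataset)), test), test = sort(test))
  })
}

feature_matrix <- function(rows, use_reference) {
  cols <- if (use_reference) FEATURES_WITH_REF else FEATURES_NO_REF
  as.matrix(rows[, cols, drop = FALSE])
}

#' Train per-class weight models (both variants)
#'
#' For each food class with at least `min_examples` training items, the
#' no-reference variant is trained on all of the class's training items
#' with the spoon fields dropped, and the spoon-corrected variant on the
#' spoon-containing subset. Classes (or variants) below the minimum are
#' skipped with a warning. Deterministic given `seed`.
#'
#' @param scenes List of `annotated_scene`s, or an item table from
#'   [scene_dataset()].
#' @param train_frac Training fraction for the stratified split.
#' @param seed Master seed (split and per-model initialization).
#' @param epochs,batch_size,lr,patience Training hyperparameters passed
#'   to the optimizer.
#' @param min_examples Minimum training items required per variant.
#' @return A `weight_registry`: trained models, the item table and the
#'   split (so held-out evaluation uses exactly the untouched rows).
#' @export
train_models <- function(scenes, train_frac = 0.8, seed = 1L, epochs = 500,
                         batch_size = 32, lr = 1e-3, patience = 50,
                         min_examples = 20) {
  ds <- if (is.data.frame(scenes)) scenes else scene_dataset(scenes)
  split <- split_dataset(ds, train_frac = train_frac, seed = seed)
  train <- ds[split$train, , drop = FALSE]
  codes <- sort(unique(ds$code))
  models <- list()
  for (ci in seq_along(codes)) {
    code <- codes[ci]
    rows_all <- train[train$code == code, , drop = FALSE]
    rows_ref <- rows_all[rows_all$has_ref, , drop = FALSE]
    if (nrow(rows_all) < min_examples) {
      warning("class ", code, ": only ", nrow(rows_all),
              " training examples (< ", min_examples, "); skipped",
              call. = FALSE)
      next
    }
    models[[paste0(code, "|no_ref")]] <- nn_train(
      feature_matrix(rows_all, FALSE), rows_all$true_weight_g,
      epochs = epochs, batch_size = batch_size, lr = lr,
      patience = patience, seed = seed + 1000L + ci
    )
    if (nrow(rows_ref) >= min_examples) {
      models[[paste0(code, "|with_ref")]] <- nn_train(
        feature_matrix(rows_ref, TRUE), rows_ref$true_weight_g,
        epochs = epochs, batch_size = batch_size, lr = lr,
        patience = patience, seed = seed + 2000L + ci
      )
    } else {
      warning("class ", code, ": only ", nrow(rows_ref),
              " spoon-containing training examples (< ", min_examples,
              "); spoon-corrected variant skipped", call. = FALSE)
    }
  }
  structure(list(models = models, dataset = ds, split = split,
                 seed = seed,
                 config = list(train_frac = train_frac, epochs = epochs,
                               batch_size = batch_size, lr = lr,
                               patience = patience,
                               min_examples = min_examples)),
            class = "weight_registry")
}

registry_codes <- function(registry) {
  sort(unique(sub("\\|.*$", "", names(registry$models))))
}

#' Predict an integer portion weight
#'
#' An 11-element feature vector is routed to the class's spoon-corrected
#' model, a 6-element vector to its no-spoon model; the network output
#' is clamped at zero and rounded to integer grams.
#'
#' @param registry A `weight_registry` from [train_models()] or an
#'   `analytic_registry` (see [analytic_registry()]).
#' @param features Feature vector from [extract_features()].
#' @param code Food code.
#' @return Integer grams (>= 0).
#' @export
predict_weight <- function(registry, features, code) {
  if (inherits(registry, "analytic_registry")) {
    return(predict_weight_analytic(registry, features, code))
  }
  variant <- switch(as.character(length(features)),
                    "11" = "with_ref", "6" = "no_ref",
                    stop("feature vector must have length 11 or 6",
                         call. = FALSE))
  model <- registry$models[[paste0(code, "|", variant)]]
  if (is.null(model)) {
    stop("no ", variant, " model for code '", code, "'; available codes: ",
         paste(registry_codes(registry), collapse = ", "), call. = FALSE)
  }
  round_weight(max(0, nn_predict(model, as.numeric(features))))
}

#' Exact inverse estimator from the generator's geometry
#'
#' A closed-form reference estimator for validation: with a spoon, the
#' pixel scale is recovered from the spoon's bounding-box area (a
#' 6 cm x 4 cm head has a 24 cm^2 box) and the weight from inverting
#' `area = shape_coeff * w^(2/3) * sin(angle) * scale^2`; without a
#' spoon, the nominal pixel scale is assumed. On noiseless scenes this
#' recovers the true weight exactly (up to integer rounding).
#'
#' @param classes Class-spec data.frame (see [demo_food_classes()]).
#' @param pixel_scale_base Nominal pixel scale assumed when no spoon is
#'   visible.
#' @return An `analytic_registry`.
#' @export
analytic_registry <- function(classes, pixel_scale_base = 0.03) {
  structure(list(classes = classes, pixel_scale_base = pixel_scale_base),
            class = "analytic_registry")
}

predict_weight_analytic <- function(registry, features, code) {
  spec <- registry$classes[registry$classes$code == code, , drop = FALSE]
  if (nrow(spec) == 0) {
    stop("no class spec for code '", code, "'; available codes: ",
         paste(registry$classes$code, collapse = ", "), call. = FALSE)
  }
  f <- as.numeric(features)
  if (length(f) == 11) {
    scale2 <- f[6] / (SPOON_DX_CM * SPOON_DY_CM)
    angle <- f[11] * 90
  } else if (length(f) == 6) {
    scale2 <- registry$pixel_scale_base^2
    angle <- f[6] * 90
  } else {
    stop("feature vector must have length 11 or 6", call. = FALSE)
  }
  w <- (f[1] / (spec$shape_coeff * sin(angle * pi / 180) * scale2))^(3 / 2)
  round_weight(max(0, w))
}

predict_rows <- function(registry, rows) {
  vapply(seq_len(nrow(rows)), function(i) {
    row <- rows[i, , drop = FALSE]
    use_ref <- isTRUE(row$has_ref) &&
      (inherits(registry, "analytic_registry") ||
         !is.null(registry$models[[paste0(row$code, "|with_ref")]]))
    feats <- as.numeric(feature_matrix(row, use_ref))
    predict_weight(registry, feats, row$code)
  }, numeric(1))
}

#' Evaluate weight and carbohydrate error on held-out items
#'
#' Predicts every test item's weight (spoon-corrected model when the
#' scene has a spoon, no-spoon model otherwise), converts predicted and
#' true weights to carbohydrate grams through the composition table, and
#' reports per-class weight/carbohydrate RMSE plus the pooled
#' carbohydrate RMSE over all test items.
#'
#' @param registry A `weight_registry` (or `analytic_registry`).
#' @param table A `food_table` covering the dataset's codes.
#' @param test_rows Item table rows to evaluate; defaults to the
#'   registry's own held-out split.
#' @return An `eval_report` list: `per_class` data.frame,
#'   `overall_carb_rmse`, `overall_weight_rmse`, `cell_counts`, and the
#'   per-item `details` table.
#' @export
evaluate_models <- function(registry, table, test_rows = NULL) {
  if (is.null(test_rows)) {
    if (!inherits(registry, "weight_registry")) {
      stop("`test_rows` must be given for an analytic registry",
           call. = FALSE)
    }
    test_rows <- registry$dataset[registry$split$test, , drop = FALSE]
  }
  if (nrow(test_rows) == 0) stop("empty test set", call. = FALSE)
  if (inherits(registry, "weight_registry")) {
    test_rows <- test_rows[test_rows$code %in% registry_codes(registry), ,
                           drop = FALSE]
    if (nrow(test_rows) == 0) {
      stop("no test items with a trained model", call. = FALSE)
    }
  }
  pred <- predict_rows(registry, test_rows)
  carb_per_g <- vapply(test_rows$code, function(code) {
    lookup_food(table, code)$carb_g_per_100g / 100
  }, numeric(1))
  details <- data.frame(
    code = test_rows$code, angle_deg = test_rows$angle_deg,
    has_ref = test_rows$has_ref,
    true_weight_g = test_rows$true_weight_g, pred_weight_g = pred,
    true_carb_g = test_rows$true_weight_g * carb_per_g,
    pred_carb_g = pred * carb_per_g, stringsAsFactors = FALSE
  )
  rmse_of <- function(a, b) sqrt(mean((a - b)^2))
  per_class <- do.call(rbind, lapply(split(details, details$code), function(d) {
    data.frame(code = d$code[1], n = nrow(d),
               weight_rmse_g = rmse_of(d$pred_weight_g, d$true_weight_g),
               carb_rmse_g = rmse_of(d$pred_carb_g, d$true_carb_g),
               mean_true_weight_g = mean(d$true_weight_g),
               stringsAsFactors = FALSE)
  }))
  rownames(per_class) <- NULL
  structure(list(
    per_class = per_class,
    overall_carb_rmse = rmse_of(details$pred_carb_g, details$true_carb_g),
    overall_weight_rmse = rmse_of(details$pred_weight_g,
                                  details$true_weight_g),
    cell_counts = as.data.frame(table(code = details$code,
                                      angle = details$angle_deg)),
    details = details
  ), class = "eval_report")
}

## ---- registry serialization -----------------------------------------

#' Save a trained registry to a directory
#'
#' Writes `manifest.json` (architecture, frozen feature order,
#' normalization constants, seed) plus one JSON parameter file per
#' (class, variant).
#'
#' @param registry A `weight_registry`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
save_registry <- function(registry, dir) {
  stopifnot(inherits(registry, "weight_registry"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  entries <- lapply(names(registry$models), function(id) {
    model <- registry$models[[id]]
    file <- paste0(gsub("[^A-Za-z0-9_]", "_", id), ".json")
    payload <- list(
      id = id, sizes = model$sizes,
      x_center = model$x_center, x_scale = model$x_scale,
      y_center = model$y_center, y_scale = model$y_scale,
      seed = model$seed, epochs_run = model$epochs_run,
      val_loss = model$val_loss,
      layers = lapply(model$params, function(p) {
        list(W = as.vector(p$W), b = p$b, dim = dim(p$W))
      })
    )
    jsonlite::write_json(payload, file.path(dir, file), digits = NA,
                         auto_unbox = TRUE)
    list(id = id, file = file)
  })
  manifest <- list(
    format = "carbcount_weight_registry_v1",
    feature_order_with_ref = FEATURES_WITH_REF,
    feature_order_no_ref = FEATURES_NO_REF,
    seed = registry$seed, config = registry$config, models = entries
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       digits = NA, auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}

#' Load a registry saved by [save_registry()]
#'
#' The returned registry predicts and evaluates against supplied rows
#' (it does not carry the original training table).
#'
#' @param dir Registry directory.
#' @return A `weight_registry`.
#' @export
load_registry <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = TRUE, simplifyDataFrame = FALSE)
  if (!identical(manifest$format, "carbcount_weight_registry_v1")) {
    stop("not a carbcount weight-registry directory: ", dir, call. = FALSE)
  }
  models <- list()
  for (entry in manifest$models) {
    payload <- jsonlite::read_json(file.path(dir, entry$file),
                                   simplifyVector = TRUE,
                                   simplifyDataFrame = FALSE)
    params <- lapply(payload$layers, function(layer) {
      list(W = matrix(layer$W, layer$dim[1], layer$dim[2]), b = layer$b)
    })
    models[[entry$id]] <- structure(list(
      params = params, sizes = payload$sizes,
      x_center = payload$x_center, x_scale = payload$x_scale,
      y_center = payload$y_center, y_scale = payload$y_scale,
      loss_curve = numeric(0), val_loss = payload$val_loss,
      epochs_run = payload$epochs_run, seed = payload$seed
    ), class = "nn_model")
  }
  structure(list(models = models, dataset = NULL, split = NULL,
                 seed = manifest$seed, config = manifest$config),
            class = "weight_registry")
}
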