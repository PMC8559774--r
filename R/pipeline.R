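#' End-to-end estimation pipeline
#'
#' Orchestrates detect -> segment -> extract features -> predict weight
#' -> compute nutrients for one scene or a batch. The object detector is
#' a pluggable interface; the bundled mock detector reads a scene's
#' ground-truth annotations and corrupts them per configuration
#' (class-dependent misses, bounding-box jitter), standing in for a
#' trained detector that cannot be reproduced without its image dataset.
#'
#' @name pipeline
NULL

#' Mock-detector configuration
#'
#' @param recall Named numeric vector of per-class detection
#'   probabilities; classes not named fall back to `default_recall`.
#'   Garnish and meat classes, which carry little carbohydrate, are the
#'   natural candidates for lowered recall.
#' @param default_recall Recall for unnamed classes.
#' @param bbox_jitter_cv Coefficient of variation of multiplicative
#'   jitter applied to detected box corners (around the box center).
#' @param seed Detector seed.
#' @return A `mock_detector_config`.
#' @export
mock_detector_config <- function(recall = numeric(0), default_recall = 1.0,
                                 bbox_jitter_cv = 0.02, seed = 1L) {
  stopifnot(all(recall >= 0), all(recall <= 1),
            default_recall >= 0, default_recall <= 1, bbox_jitter_cv >= 0)
  structure(list(recall = recall, default_recall = default_recall,
                 bbox_jitter_cv = bbox_jitter_cv, seed = as.integer(seed)),
            class = "mock_detector_config")
}

#' Build a detector from a mock configuration
#'
#' The returned function takes an `annotated_scene` and returns a list
#' with `items` (detected rows with a `confidence` column) and
#' `reference` (the spoon row or NULL). An oracle detector — truth
#' boxes, nothing missed — is `mock_detector(mock_detector_config())`.
#'
#' @param config A `mock_detector_config`.
#' @return Detector function.
#' @export
mock_detector <- function(config = mock_detector_config()) {
  force(config)
  counter <- new.env(parent = emptyenv())
  counter$i <- 0L
  function(scene) {
    counter$i <- counter$i + 1L
    with_local_seed(config$seed + counter$i, {
      items <- scene$items
      keep <- logical(nrow(items))
      for (k in seq_len(nrow(items))) {
        p <- config$recall[items$code[k]]
        if (is.na(p) || is.null(p)) p <- config$default_recall
        keep[k] <- stats::runif(1) < p
      }
      detected <- items[keep, , drop = FALSE]
      if (nrow(detected) > 0 && config$bbox_jitter_cv > 0) {
        for (k in seq_len(nrow(detected))) {
          cx <- (detected$xmin[k] + detected$xmax[k]) / 2
          cy <- (detected$ymin[k] + detected$ymax[k]) / 2
          fx <- lognormal_factor(1, config$bbox_jitter_cv)
          fy <- lognormal_factor(1, config$bbox_jitter_cv)
          detected$xmin[k] <- max(0, cx - (cx - detected$xmin[k]) * fx)
          detected$xmax[k] <- min(1, cx + (detected$xmax[k] - cx) * fx)
          detected$ymin[k] <- max(0, cy - (cy - detected$ymin[k]) * fy)
          detected$ymax[k] <- min(1, cy + (detected$ymax[k] - cy) * fy)
        }
      }
      detected$confidence <- if (nrow(detected) > 0) {
        stats::runif(nrow(detected), 0.75, 1)
      } else {
        numeric(0)
      }
      list(items = detected, reference = scene$reference)
    })
  }
}

#' Run the pipeline on one scene
#'
#' Fixed stage order: the detector proposes boxes; when the scene has a
#' raster and `segmentation` is not NULL each box is segmented and the
#' mask area replaces the annotated area (with the full box as a flagged
#' fallback); features are assembled (spoon-corrected iff the detector
#' reports the reference); weights are predicted and converted to
#' nutrients through the composition table. Detected codes without a
#' model or composition entry are skipped and flagged; no detections is
#' a valid empty result, not an error.
#'
#' @param scene An `annotated_scene` (optionally with `scene$image`).
#' @param detector Detector function (see [mock_detector()]).
#' @param registry A `weight_registry` or `analytic_registry`.
#' @param table A `food_table`.
#' @param segmentation NULL, or a list of [segment_box()] arguments
#'   (e.g. `list(iterations = 5, K = 5, gamma = 50)`) to run on
#'   `scene$image`.
#' @return A `pipeline_result`: `items` (per-item table with predicted
#'   weight and nutrients), `totals`, `flags`.
#' @export
run_scene <- function(scene, detector, registry, table,
                      segmentation = NULL) {
  det <- detector(scene)
  flags <- character(0)
  items <- det$items
  empty_items <- data.frame(
    code = character(0), xmin = numeric(0), ymin = numeric(0),
    xmax = numeric(0), ymax = numeric(0), mask_area_fraction = numeric(0),
    pred_weight_g = numeric(0), carb_g = numeric(0), protein_g = numeric(0),
    fat_g = numeric(0), stringsAsFactors = FALSE
  )
  if (is.null(items) || nrow(items) == 0) {
    return(structure(list(items = empty_items,
                          totals = c(carb_g = 0, protein_g = 0, fat_g = 0),
                          flags = "no_detections"),
                     class = "pipeline_result"))
  }
  if (is.null(det$reference)) flags <- c(flags, "no_reference")
  known <- vapply(items$code, function(code) code %in% table$code, logical(1))
  if (any(!known)) {
    flags <- c(flags, paste0("unknown_code:", items$code[!known]))
    items <- items[known, , drop = FALSE]
  }
  if (inherits(registry, "weight_registry")) {
    covered <- items$code %in% registry_codes(registry)
    if (any(!covered)) {
      flags <- c(flags, paste0("no_model:", items$code[!covered]))
      items <- items[covered, , drop = FALSE]
    }
  }
  if (nrow(items) == 0) {
    return(structure(list(items = empty_items,
                          totals = c(carb_g = 0, protein_g = 0, fat_g = 0),
                          flags = unique(c(flags, "no_detections"))),
                     class = "pipeline_result"))
  }
  det_scene <- structure(list(items = items, reference = det$reference,
                              angle_deg = scene$angle_deg,
                              pixel_scale = scene$pixel_scale,
                              image = scene$image),
                         class = "annotated_scene")
  out <- vector("list", nrow(items))
  for (k in seq_len(nrow(items))) {
    item <- items[k, , drop = FALSE]
    if (!is.null(segmentation) && !is.null(scene$image)) {
      seg <- do.call(segment_box,
                     c(list(image = scene$image,
                            box = c(xmin = item$xmin, ymin = item$ymin,
                                    xmax = item$xmax, ymax = item$ymax)),
                       segmentation))
      if (seg$fallback) flags <- c(flags, paste0("seg_fallback:", item$code))
      item$mask_area_fraction <- seg$area_fraction
    }
    use_ref <- !is.null(det$reference) &&
      (inherits(registry, "analytic_registry") ||
         !is.null(registry$models[[paste0(item$code, "|with_ref")]]))
    feats <- extract_features(det_scene, item, use_reference = use_ref)
    if (isTRUE(attr(feats, "area_from_box"))) {
      flags <- c(flags, paste0("area_from_box:", item$code))
    }
    w <- predict_weight(registry, feats, item$code)
    pc <- if (!is.null(item$piece_count)) item$piece_count else NA_integer_
    nut <- nutrients_for_weight(lookup_food(table, item$code),
                                item_estimate(item$code, w, pc))
    out[[k]] <- data.frame(
      code = item$code, xmin = item$xmin, ymin = item$ymin,
      xmax = item$xmax, ymax = item$ymax,
      mask_area_fraction = item$mask_area_fraction, pred_weight_g = w,
      carb_g = nut[["carb_g"]], protein_g = nut[["protein_g"]],
      fat_g = nut[["fat_g"]], stringsAsFactors = FALSE
    )
  }
  items_out <- do.call(rbind, c(out, list(make.row.names = FALSE)))
  totals <- c(carb_g = sum(items_out$carb_g),
              protein_g = sum(items_out$protein_g),
              fat_g = sum(items_out$fat_g))
  structure(list(items = items_out, totals = totals, flags = unique(flags)),
            class = "pipeline_result")
}

#' Batch evaluation: measured vs estimated carbohydrate per scene
#'
#' Runs [run_scene()] on every scene and tabulates the measured
#' (ground-truth weights through the composition table) and estimated
#' carbohydrate totals, plus the summed totals and their percent error.
#'
#' @param scenes List of `annotated_scene`s with ground truth.
#' @param detector Detector function.
#' @param registry Weight registry.
#' @param table A `food_table`.
#' @param segmentation Optional segmentation settings (see
#'   [run_scene()]).
#' @return List with `per_scene` data.frame (`scene`,
#'   `measured_carb_g`, `estimated_carb_g`, `flags`), `measured_total`,
#'   `estimated_total`, `percent_error`.
#' @export
batch_evaluate <- function(scenes, detector, registry, table,
                           segmentation = NULL) {
  rows <- lapply(seq_along(scenes), function(i) {
    scene <- scenes[[i]]
    measured <- aggregate_scene(
      data.frame(code = scene$items$code,
                 weight_g = scene$items$true_weight_g,
                 piece_count = scene$items$piece_count,
                 stringsAsFactors = FALSE),
      table)[["carb_g"]]
    res <- run_scene(scene, detector, registry, table, segmentation)
    data.frame(scene = i, measured_carb_g = measured,
               estimated_carb_g = res$totals[["carb_g"]],
               flags = paste(res$flags, collapse = ";"),
               stringsAsFactors = FALSE)
  })
  per_scene <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  measured_total <- sum(per_scene$measured_carb_g)
  estimated_total <- sum(per_scene$estimated_carb_g)
  list(per_scene = per_scene, measured_total = measured_total,
       estimated_total = estimated_total,
       percent_error = percent_error(measured_total, estimated_total))
}

## ---- flat TOML-subset configuration ---------------------------------

#' Read a flat TOML-dialect configuration file
#'
#' Supports `[section]` headers, `key = value` lines with string
#' (quoted), numeric, boolean and flat-array (`[1, 2, 3]`) values, and
#' `#` comments. Nested tables are not supported.
#'
#' @param path Config file path.
#' @return Nested named list (one list per section; top-level keys
#'   before any section sit at the top).
#' @export
read_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  out <- list()
  section <- NULL
  parse_scalar <- function(txt) {
    txt <- trimws(txt)
    if (grepl('^".*"$', txt)) return(gsub('^"|"$', "", txt))
    if (grepl("^'.*'$", txt)) return(gsub("^'|'$", "", txt))
    if (txt %in% c("true", "false")) return(txt == "true")
    num <- suppressWarnings(as.numeric(txt))
    if (!is.na(num)) return(num)
    txt
  }
  for (line in lines) {
    line <- sub("#.*$", "", line)
    line <- trimws(line)
    if (!nzchar(line)) next
    if (grepl("^\\[.*\\]$", line)) {
      section <- gsub("^\\[|\\]$", "", line)
      if (is.null(out[[section]])) out[[section]] <- list()
      next
    }
    eq <- regexpr("=", line, fixed = TRUE)
    if (eq < 0) stop("cannot parse config line: ", line, call. = FALSE)
    key <- trimws(substr(line, 1, eq - 1))
    val <- trimws(substr(line, eq + 1, nchar(line)))
    value <- if (grepl("^\\[.*\\]$", val)) {
      parts <- strsplit(gsub("^\\[|\\]$", "", val), ",")[[1]]
      unlist(lapply(parts, parse_scalar))
    } else {
      parse_scalar(val)
    }
    if (is.null(section)) out[[key]] <- value
    else out[[section]][[key]] <- value
  }
  out
}
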