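#' Plate scenes: data model and synthetic generator
#'
#' A scene is one photographed plate: 1-4 food items on a white background,
#' optionally a tablespoon head as a reference object of known real size,
#' shot from 30, 60 or 90 degrees above the tabletop. The generator
#' emulates the acquisition protocol behind the training data: portions
#' grow in half- or whole-exchange steps, the projected footprint of a
#' mound-like portion scales as weight^(2/3), foreshortening shrinks it by
#' sin(angle), and camera distance enters as an unobserved pixel scale
#' that only the spoon's apparent size can reveal.
#'
#' @name scenes
NULL

# Reserved code for the spoon-head reference object.
SPOON_CODE <- "SPOON"
# Spoon head modeled as a 6 cm x 4 cm ellipse; its bounding box is
# 24 cm^2 and its elliptical area pi*6 cm^2 at unit pixel scale.
SPOON_DX_CM <- 6
SPOON_DY_CM <- 4
SPOON_AREA_CM2 <- pi * (SPOON_DX_CM / 2) * (SPOON_DY_CM / 2)

VALID_ANGLES <- c(30, 60, 90)

#' Construct a normalized bounding box
#'
#' Coordinates are fractions of the image, origin top-left.
#'
#' @param xmin,ymin,xmax,ymax Corners in `[0, 1]` with positive extent.
#' @return Named numeric vector with the four corners.
#' @export
bounding_box <- function(xmin, ymin, xmax, ymax) {
  if (!(xmin >= 0 && xmin < xmax && xmax <= 1 &&
        ymin >= 0 && ymin < ymax && ymax <= 1)) {
    stop("invalid bounding box: need 0 <= min < max <= 1 on both axes",
         call. = FALSE)
  }
  c(xmin = xmin, ymin = ymin, xmax = xmax, ymax = ymax)
}

#' Area of a normalized bounding box
#' @param box Named vector or one-row data.frame with xmin/ymin/xmax/ymax.
#' @return Area as an image fraction.
#' @export
bbox_area <- function(box) {
  (box[["xmax"]] - box[["xmin"]]) * (box[["ymax"]] - box[["ymin"]])
}

#' Geometry specs for the bundled synthetic food classes
#'
#' Thirteen carbohydrate-bearing classes from the bundled composition
#' table, each with a shape coefficient `shape_coeff` (overhead footprint
#' in cm^2 per gram^(2/3)): flat spreading foods (noodles) get larger
#' coefficients than compact mounds (sticky rice).
#'
#' @return Data.frame with columns `code`, `name`, `shape_coeff`,
#'   `grams_per_exchange`, `carb_g_per_100g`, `render_color`.
#' @export
demo_food_classes <- function() {
  comp <- demo_composition()
  geom <- data.frame(
    code = c("11001", "11002", "11003", "12001", "12002", "13001", "13002",
             "13003", "13004", "14001", "14002", "14003", "15001"),
    shape_coeff = c(3.8, 3.6, 2.6, 5.2, 5.0, 3.0, 3.2,
                    4.2, 2.2, 3.4, 3.6, 3.0, 2.8),
    render_color = c("#F2E8C9", "#D9A441", "#EDEDE4", "#C9B458", "#E8D8C3",
                     "#BFD8B8", "#E3C567", "#B5651D", "#D4A017", "#FFB347",
                     "#F4E04D", "#EFD510", "#C8A2C8"),
    stringsAsFactors = FALSE
  )
  merged <- merge(geom, as.data.frame(comp)[, c("code", "name",
                                                "grams_per_exchange",
                                                "carb_g_per_100g")],
                  by = "code", sort = TRUE)
  merged[, c("code", "name", "shape_coeff", "grams_per_exchange",
             "carb_g_per_100g", "render_color")]
}

#' Generator configuration
#'
#' @param n_scenes Number of scenes to generate (> 0).
#' @param classes Data.frame of food-class geometry specs (see
#'   [demo_food_classes()]).
#' @param portion_steps Exchange-unit multipliers portions are drawn from.
#' @param area_noise_cv Coefficient of variation of the multiplicative
#'   lognormal noise on each item's projected area.
#' @param scale_jitter_cv Coefficient of variation of the per-scene pixel
#'   scale (camera distance) around its nominal value.
#' @param spoon_probability Probability that a scene contains the
#'   reference spoon.
#' @param pixel_scale_base Nominal pixel scale in image fraction per cm
#'   (0.03 puts a 23 cm plate at ~70% of the image width).
#' @param max_items Maximum items per scene (drawn uniformly from
#'   1..max_items).
#' @param seed Integer seed making the scene stream reproducible.
#' @return A `generator_config` list.
#' @export
generator_config <- function(n_scenes,
                             classes = demo_food_classes(),
                             portion_steps = c(0.5, 1, 1.5, 2, 2.5, 3),
                             area_noise_cv = 0.05,
                             scale_jitter_cv = 0.15,
                             spoon_probability = 0.8,
                             pixel_scale_base = 0.03,
                             max_items = 4,
                             seed = 1L) {
  stopifnot(n_scenes > 0, nrow(classes) >= 1,
            area_noise_cv >= 0, scale_jitter_cv >= 0,
            spoon_probability >= 0, spoon_probability <= 1,
            pixel_scale_base > 0, max_items >= 1,
            all(classes$shape_coeff > 0))
  structure(list(n_scenes = as.integer(n_scenes), classes = classes,
                 portion_steps = portion_steps,
                 area_noise_cv = area_noise_cv,
                 scale_jitter_cv = scale_jitter_cv,
                 spoon_probability = spoon_probability,
                 pixel_scale_base = pixel_scale_base,
                 max_items = as.integer(max_items),
                 seed = as.integer(seed)),
            class = "generator_config")
}

#' Deterministic projected area of a portion
#'
#' `area = shape_coeff * weight^(2/3) * sin(angle) * pixel_scale^2`:
#' footprint grows with the 2/3 power of weight (volume-to-footprint
#' scaling of a mound), shrinks by sin(angle) when shot obliquely, and
#' scales quadratically with pixels-per-cm. Noise is applied separately
#' by the generator.
#'
#' @param weight_g Portion weight in grams (>= 0).
#' @param spec One row of a class-spec data.frame (needs `shape_coeff`).
#' @param angle_deg Shooting angle, one of 30, 60, 90.
#' @param pixel_scale Image fraction per cm (> 0).
#' @return Projected area as an image fraction.
#' @export
project_area <- function(weight_g, spec, angle_deg, pixel_scale) {
  stopifnot(all(weight_g >= 0), pixel_scale > 0,
            all(angle_deg %in% VALID_ANGLES))
  spec$shape_coeff * weight_g^(2 / 3) * sin(angle_deg * pi / 180) *
    pixel_scale^2
}

# Inverse of project_area: exact weight from a noiseless area.
invert_area <- function(area, spec, angle_deg, pixel_scale) {
  (area / (spec$shape_coeff * sin(angle_deg * pi / 180) * pixel_scale^2))^(3 / 2)
}

lognormal_factor <- function(n, cv) {
  if (cv <= 0) return(rep(1, n))
  s2 <- log(1 + cv^2)
  stats::rlnorm(n, meanlog = -s2 / 2, sdlog = sqrt(s2))
}

boxes_overlap <- function(a, b) {
  !(a[["xmax"]] <= b[["xmin"]] || b[["xmax"]] <= a[["xmin"]] ||
    a[["ymax"]] <= b[["ymin"]] || b[["ymax"]] <= a[["ymin"]])
}

# Place a dx-by-dy box uniformly at random, avoiding `placed` (list of
# boxes); NULL on failure after `tries` attempts.
place_box <- function(dx, dy, placed, tries = 40) {
  if (dx >= 1 || dy >= 1) return(NULL)
  for (i in seq_len(tries)) {
    x0 <- stats::runif(1, 0, 1 - dx)
    y0 <- stats::runif(1, 0, 1 - dy)
    box <- c(xmin = x0, ymin = y0, xmax = x0 + dx, ymax = y0 + dy)
    if (!any(vapply(placed, boxes_overlap, logical(1), b = box))) return(box)
  }
  NULL
}

#' Draw one synthetic scene
#'
#' Items get true weights on the exchange-step grid, noisy elliptical
#' footprints consistent with [project_area()], and non-overlapping
#' uniform-random placements; the spoon (when present) has a noise-free
#' footprint so that its apparent size carries the pixel scale. Uses the
#' current RNG state; see [generate_scenes()] for a seeded stream.
#'
#' @param config A `generator_config`.
#' @return An `annotated_scene` list: `items` data.frame (code, bbox
#'   corners, `mask_area_fraction`, `true_weight_g`, `piece_count`),
#'   `reference` (one-row data.frame or NULL), `angle_deg`, `pixel_scale`.
#' @export
sample_scene <- function(config) {
  for (attempt in 1:20) {
    scene <- try_sample_scene(config)
    if (!is.null(scene)) return(scene)
  }
  stop("could not place scene items without overlap after 20 attempts; ",
       "reduce portion sizes or max_items", call. = FALSE)
}

try_sample_scene <- function(config) {
  classes <- config$classes
  n_items <- sample.int(min(config$max_items, nrow(classes)), 1)
  idx <- sample.int(nrow(classes), n_items)
  angle <- sample(VALID_ANGLES, 1)
  pixel_scale <- config$pixel_scale_base *
    lognormal_factor(1, config$scale_jitter_cv)
  placed <- list()
  rows <- vector("list", n_items)
  for (k in seq_len(n_items)) {
    spec <- classes[idx[k], , drop = FALSE]
    step <- sample(config$portion_steps, 1)
    weight <- round_weight(spec$grams_per_exchange * step)
    area <- project_area(weight, spec, angle, pixel_scale) *
      lognormal_factor(1, config$area_noise_cv)
    # ellipse inscribed in its box: area = (pi/4) dx dy, dy = dx sin(angle)
    dx <- sqrt(area / ((pi / 4) * sin(angle * pi / 180)))
    dy <- dx * sin(angle * pi / 180)
    box <- place_box(dx, dy, placed)
    if (is.null(box)) return(NULL)
    placed <- c(placed, list(box))
    rows[[k]] <- data.frame(code = spec$code, xmin = box[["xmin"]],
                            ymin = box[["ymin"]], xmax = box[["xmax"]],
                            ymax = box[["ymax"]], mask_area_fraction = area,
                            true_weight_g = weight,
                            piece_count = NA_integer_,
                            stringsAsFactors = FALSE)
  }
  reference <- NULL
  if (stats::runif(1) < config$spoon_probability) {
    dx <- SPOON_DX_CM * pixel_scale
    dy <- SPOON_DY_CM * pixel_scale
    box <- place_box(dx, dy, placed)
    if (is.null(box)) return(NULL)
    reference <- data.frame(code = SPOON_CODE, xmin = box[["xmin"]],
                            ymin = box[["ymin"]], xmax = box[["xmax"]],
                            ymax = box[["ymax"]],
                            mask_area_fraction = SPOON_AREA_CM2 * pixel_scale^2,
                            true_weight_g = NA_real_,
                            piece_count = NA_integer_,
                            stringsAsFactors = FALSE)
  }
  structure(list(items = do.call(rbind, rows), reference = reference,
                 angle_deg = angle, pixel_scale = pixel_scale, image = NULL),
            class = "annotated_scene")
}

#' Generate a reproducible stream of scenes
#'
#' @param config A `generator_config`; `config$seed` fixes the stream.
#' @return List of `annotated_scene`s of length `config$n_scenes`.
#' @export
generate_scenes <- function(config) {
  set.seed(config$seed)
  lapply(seq_len(config$n_scenes), function(i) sample_scene(config))
}

#' Render a scene to an RGB raster
#'
#' White background; each item is a filled ellipse of its class color
#' inscribed in its bounding box; the spoon is a gray ellipse. Per-pixel
#' Gaussian color noise is added (sd `noise_sd` in [0,1] units). A
#' ground-truth label raster is returned alongside: 0 background, item
#' index for each food, `n_items + 1` for the spoon.
#'
#' @param scene An `annotated_scene` without a raster.
#' @param size_px Image side length in pixels.
#' @param noise_sd Gaussian color-noise standard deviation (default 5/255).
#' @param class_colors Named character vector code -> color; defaults to
#'   the bundled class colors.
#' @return List with `image` (size x size x 3 array in [0,1]) and `labels`
#'   (integer matrix).
#' @export
render_scene <- function(scene, size_px = 128, noise_sd = 5 / 255,
                         class_colors = NULL) {
  if (is.null(class_colors)) {
    cls <- demo_food_classes()
    class_colors <- stats::setNames(cls$render_color, cls$code)
  }
  img <- array(1, dim = c(size_px, size_px, 3))
  labels <- matrix(0L, size_px, size_px)
  # pixel centers in normalized coordinates (row = y, col = x)
  centers <- (seq_len(size_px) - 0.5) / size_px
  draw <- function(box, color, label) {
    cx <- (box[["xmin"]] + box[["xmax"]]) / 2
    cy <- (box[["ymin"]] + box[["ymax"]]) / 2
    rx <- (box[["xmax"]] - box[["xmin"]]) / 2
    ry <- (box[["ymax"]] - box[["ymin"]]) / 2
    inside <- outer(((centers - cy) / ry)^2, ((centers - cx) / rx)^2, "+") <= 1
    rgb <- grDevices::col2rgb(color)[, 1] / 255
    for (ch in 1:3) {
      plane <- img[, , ch]
      plane[inside] <- rgb[ch]
      img[, , ch] <<- plane
    }
    labels[inside] <<- label
  }
  items <- scene$items
  if (!is.null(items) && nrow(items) > 0) {
    for (k in seq_len(nrow(items))) {
      color <- class_colors[[items$code[k]]]
      if (is.null(color) || is.na(color)) color <- "#888888"
      draw(items[k, ], color, k)
    }
  }
  if (!is.null(scene$reference)) {
    draw(scene$reference[1, ], "#A0A0A8",
         if (is.null(items)) 1L else nrow(items) + 1L)
  }
  if (noise_sd > 0) {
    img <- img + array(stats::rnorm(length(img), 0, noise_sd), dim = dim(img))
    img[img < 0] <- 0
    img[img > 1] <- 1
  }
  list(image = img, labels = labels)
}

#' Write scenes to a COCO-style JSON annotation file
#'
#' The file follows the images / annotations / categories layout with
#' pixel-unit `bbox = [x, y, width, height]`, plus the extension fields
#' `true_weight_g`, `piece_count` and `is_reference` on annotations and
#' `angle_deg` and `pixel_scale` on images. Normalized in-memory corners
#' are converted to pixels on write and back on read.
#'
#' @param scenes List of `annotated_scene`s.
#' @param path Output JSON path.
#' @param width,height Nominal raster size in pixels.
#' @return `path`, invisibly.
#' @export
write_scenes_json <- function(scenes, path, width = 800, height = 800) {
  codes <- sort(unique(c(unlist(lapply(scenes, function(s) s$items$code)),
                         SPOON_CODE)))
  categories <- data.frame(id = seq_along(codes), name = codes,
                           stringsAsFactors = FALSE)
  cat_id <- stats::setNames(categories$id, categories$name)
  images <- data.frame(
    id = seq_along(scenes),
    file_name = sprintf("scene_%05d.png", seq_along(scenes)),
    width = width, height = height,
    angle_deg = vapply(scenes, function(s) s$angle_deg, numeric(1)),
    pixel_scale = vapply(scenes, function(s) s$pixel_scale, numeric(1)),
    stringsAsFactors = FALSE
  )
  ann <- list()
  aid <- 0L
  for (i in seq_along(scenes)) {
    scene <- scenes[[i]]
    rows <- scene$items
    if (!is.null(scene$reference)) rows <- rbind(rows, scene$reference)
    is_ref <- rows$code == SPOON_CODE
    for (k in seq_len(nrow(rows))) {
      aid <- aid + 1L
      ann[[aid]] <- data.frame(
        id = aid, image_id = i, category_id = cat_id[[rows$code[k]]],
        bbox_x = rows$xmin[k] * width, bbox_y = rows$ymin[k] * height,
        bbox_w = (rows$xmax[k] - rows$xmin[k]) * width,
        bbox_h = (rows$ymax[k] - rows$ymin[k]) * height,
        area = rows$mask_area_fraction[k] * width * height,
        true_weight_g = rows$true_weight_g[k],
        piece_count = rows$piece_count[k],
        is_reference = is_ref[k], stringsAsFactors = FALSE
      )
    }
  }
  ann <- do.call(rbind, ann)
  out <- list(
    images = images,
    annotations = data.frame(
      id = ann$id, image_id = ann$image_id, category_id = ann$category_id,
      area = ann$area, true_weight_g = ann$true_weight_g,
      piece_count = ann$piece_count, is_reference = ann$is_reference
    ),
    categories = categories
  )
  out$annotations$bbox <- lapply(seq_len(nrow(ann)), function(k) {
    c(ann$bbox_x[k], ann$bbox_y[k], ann$bbox_w[k], ann$bbox_h[k])
  })
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", na = "null", pretty = FALSE)
  invisible(path)
}

#' Read scenes from a COCO-style JSON annotation file
#'
#' @param path Path written by [write_scenes_json()] (or any file in the
#'   same dialect).
#' @return List of `annotated_scene`s.
#' @export
read_scenes_json <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = TRUE)
  images <- doc$images
  ann <- doc$annotations
  categories <- doc$categories
  code_of <- stats::setNames(as.character(categories$name), categories$id)
  bbox <- do.call(rbind, lapply(ann$bbox, as.numeric))
  if (is.null(ann$true_weight_g)) ann$true_weight_g <- NA_real_
  if (is.null(ann$piece_count)) ann$piece_count <- NA_integer_
  if (is.null(ann$is_reference)) ann$is_reference <- FALSE
  ann$is_reference[is.na(ann$is_reference)] <- FALSE
  scenes <- vector("list", nrow(images))
  for (i in seq_len(nrow(images))) {
    w <- images$width[i]; h <- images$height[i]
    sel <- which(ann$image_id == images$id[i])
    rows <- data.frame(
      code = unname(code_of[as.character(ann$category_id[sel])]),
      xmin = bbox[sel, 1] / w, ymin = bbox[sel, 2] / h,
      xmax = (bbox[sel, 1] + bbox[sel, 3]) / w,
      ymax = (bbox[sel, 2] + bbox[sel, 4]) / h,
      mask_area_fraction = ann$area[sel] / (w * h),
      true_weight_g = as.numeric(ann$true_weight_g[sel]),
      piece_count = suppressWarnings(as.integer(ann$piece_count[sel])),
      stringsAsFactors = FALSE
    )
    is_ref <- ann$is_reference[sel]
    reference <- if (any(is_ref)) rows[which(is_ref)[1], , drop = FALSE] else NULL
    if (!is.null(reference)) rownames(reference) <- NULL
    items <- rows[!is_ref, , drop = FALSE]
    rownames(items) <- NULL
    pixel_scale <- if (!is.null(images$pixel_scale)) images$pixel_scale[i] else NA_real_
    scenes[[i]] <- structure(
      list(items = items, reference = reference,
           angle_deg = images$angle_deg[i], pixel_scale = pixel_scale,
           image = NULL),
      class = "annotated_scene")
  }
  scenes
}

#' Write a rendered raster (and optional label raster) as PNG
#'
#' @param render Output of [render_scene()].
#' @param path PNG path for the RGB image.
#' @param labels_path Optional PNG path for the single-channel label
#'   raster (labels stored as gray levels label/255).
#' @return `path`, invisibly.
#' @export
write_render_png <- function(render, path, labels_path = NULL) {
  png::writePNG(render$image, path)
  if (!is.null(labels_path)) {
    png::writePNG(render$labels / 255, labels_path)
  }
  invisible(path)
}
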