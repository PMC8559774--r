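test_that("projected area follows the 2/3-power, sine and scale laws", {
  spec <- demo_food_classes()[1, ]
  expect_equal(project_area(0, spec, 90, 0.03), 0)
  a90 <- project_area(120, spec, 90, 0.03)
  a30 <- project_area(120, spec, 30, 0.03)
  expect_equal(a30 / a90, 0.5)  # sin(30) = 1/2
  expect_equal(project_area(8 * 120, spec, 90, 0.03) / a90, 4)  # 8^(2/3)
  # strictly increasing in weight and in pixel scale
  w <- seq(10, 300, by = 10)
  expect_true(all(diff(project_area(w, spec, 60, 0.03)) > 0))
  s <- seq(0.01, 0.05, by = 0.005)
  areas <- vapply(s, function(si) project_area(100, spec, 60, si), numeric(1))
  expect_true(all(diff(areas) > 0))
})

test_that("the generator is reproducible and respects its invariants", {
  cfg <- generator_config(n_scenes = 60, seed = 123)
  s1 <- generate_scenes(cfg)
  s2 <- generate_scenes(cfg)
  expect_identical(s1, s2)
  grid <- sort(unique(as.vector(outer(cfg$portion_steps,
                                      cfg$classes$grams_per_exchange))))
  for (scene in s1) {
    expect_true(scene$angle_deg %in% c(30, 60, 90))
    items <- scene$items
    expect_true(all(items$xmin >= 0 & items$xmax <= 1 &
                      items$ymin >= 0 & items$ymax <= 1))
    box_areas <- (items$xmax - items$xmin) * (items$ymax - items$ymin)
    expect_true(all(items$mask_area_fraction <= box_areas + 1e-6))
    expect_true(all(items$true_weight_g %in% round_weight(grid)))
    # no two boxes overlap
    rows <- rbind(items, scene$reference)
    if (nrow(rows) > 1) {
      for (i in 1:(nrow(rows) - 1)) {
        for (j in (i + 1):nrow(rows)) {
          expect_false(rows$xmin[j] < rows$xmax[i] &&
                         rows$xmin[i] < rows$xmax[j] &&
                         rows$ymin[j] < rows$ymax[i] &&
                         rows$ymin[i] < rows$ymax[j])
        }
      }
    }
  }
})

test_that("noiseless areas equal the deterministic projection and invert exactly", {
  cfg <- noiseless_config(40, n_classes = 4, seed = 5, spoon_probability = 1)
  scenes <- generate_scenes(cfg)
  classes <- cfg$classes
  for (scene in scenes) {
    expect_equal(scene$pixel_scale, cfg$pixel_scale_base)
    for (k in seq_len(nrow(scene$items))) {
      item <- scene$items[k, ]
      spec <- classes[classes$code == item$code, ]
      expect_equal(item$mask_area_fraction,
                   project_area(item$true_weight_g, spec, scene$angle_deg,
                                scene$pixel_scale))
      # the generator's inverse oracle recovers the weight
      w <- (item$mask_area_fraction /
              (spec$shape_coeff * sin(scene$angle_deg * pi / 180) *
                 scene$pixel_scale^2))^(3 / 2)
      expect_equal(w, item$true_weight_g, tolerance = 1e-9)
    }
    # spoon footprint is noise-free: fixed real area times scale^2
    expect_equal(scene$reference$mask_area_fraction,
                 pi * 3 * 2 * scene$pixel_scale^2)
  }
})

test_that("spoon presence matches its configured probability", {
  cfg <- generator_config(n_scenes = 1000, seed = 77)
  scenes <- generate_scenes(cfg)
  n_spoon <- sum(vapply(scenes, function(s) !is.null(s$reference),
                        logical(1)))
  # binomial 3-sigma band around 0.8
  expect_lt(abs(n_spoon - 800), 3 * sqrt(1000 * 0.8 * 0.2))
})

test_that("rendering reproduces mask areas and labels; empty scene is white", {
  set.seed(3)
  cfg <- noiseless_config(5, n_classes = 3, seed = 9, spoon_probability = 1)
  scene <- generate_scenes(cfg)[[1]]
  r <- render_scene(scene, size_px = 160, noise_sd = 0)
  for (k in seq_len(nrow(scene$items))) {
    frac <- mean(r$labels == k)
    expect_equal(frac, scene$items$mask_area_fraction[k],
                 tolerance = 0.05)
  }
  # label raster and image agree: labeled pixels are non-white
  expect_true(all(r$image[, , 1][r$labels == 0] == 1))
  empty <- structure(list(items = scene$items[0, ], reference = NULL,
                          angle_deg = 90, pixel_scale = 0.03, image = NULL),
                     class = "annotated_scene")
  re <- render_scene(empty, size_px = 32, noise_sd = 0)
  expect_true(all(re$image == 1))
  expect_true(all(re$labels == 0))
})

test_that("scenes round-trip through the COCO-style JSON dialect", {
  cfg <- generator_config(n_scenes = 8, seed = 31)
  scenes <- generate_scenes(cfg)
  path <- withr::local_tempfile(fileext = ".json")
  write_scenes_json(scenes, path)
  back <- read_scenes_json(path)
  expect_length(back, length(scenes))
  for (i in seq_along(scenes)) {
    expect_equal(back[[i]]$items$code, scenes[[i]]$items$code)
    expect_equal(back[[i]]$items$xmin, scenes[[i]]$items$xmin,
                 tolerance = 1e-12)
    expect_equal(back[[i]]$items$mask_area_fraction,
                 scenes[[i]]$items$mask_area_fraction, tolerance = 1e-12)
    expect_equal(back[[i]]$items$true_weight_g,
                 scenes[[i]]$items$true_weight_g)
    expect_equal(back[[i]]$angle_deg, scenes[[i]]$angle_deg)
    expect_equal(is.null(back[[i]]$reference),
                 is.null(scenes[[i]]$reference))
  }
})

test_that("bounding-box constructor rejects degenerate boxes", {
  expect_error(bounding_box(0.5, 0.1, 0.5, 0.2), "invalid")
  expect_error(bounding_box(-0.1, 0.1, 0.5, 0.2), "invalid")
  box <- bounding_box(0.2, 0.2, 0.6, 0.6)
  expect_equal(bbox_area(box), 0.16)
})
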