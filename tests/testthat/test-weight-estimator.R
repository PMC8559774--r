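test_that("feature vectors assemble in the frozen order", {
  scene <- example_scene(angle_deg = 60)
  f <- extract_features(scene, scene$items[1, ], use_reference = TRUE)
  expect_length(f, 11)
  expect_equal(as.numeric(f),
               c(0.10, 0.2, 0.2, 0.6, 0.6,
                 0.15 * 0.10, 0.70, 0.40, 0.85, 0.50, 2 / 3),
               tolerance = 1e-12)
  f6 <- extract_features(scene, scene$items[1, ], use_reference = FALSE)
  expect_length(f6, 6)
  expect_equal(as.numeric(f6), c(0.10, 0.2, 0.2, 0.6, 0.6, 2 / 3),
               tolerance = 1e-12)
  scene90 <- example_scene(angle_deg = 90)
  expect_equal(unname(extract_features(scene90, scene90$items[1, ],
                                       use_reference = FALSE))[6], 1.0)
  no_spoon <- example_scene(with_spoon = FALSE)
  expect_error(extract_features(no_spoon, no_spoon$items[1, ],
                                use_reference = TRUE), "no-reference")
  # missing mask: bounding-box area is used and flagged
  item <- scene$items[1, ]
  item$mask_area_fraction <- NA_real_
  fb <- extract_features(scene, item, use_reference = FALSE)
  expect_equal(unname(fb)[1], 0.16)
  expect_true(attr(fb, "area_from_box"))
})

test_that("the stratified split partitions items with 80/20 per class-angle cell", {
  cfg <- generator_config(n_scenes = 300, seed = 17)
  ds <- scene_dataset(generate_scenes(cfg))
  split <- split_dataset(ds, seed = 3)
  expect_setequal(c(split$train, split$test), seq_len(nrow(ds)))
  expect_length(intersect(split$train, split$test), 0)
  cells <- split(seq_len(nrow(ds)), list(ds$code, ds$angle_deg), drop = TRUE)
  for (rows in cells) {
    n_test <- length(intersect(rows, split$test))
    expect_lte(abs(n_test - 0.2 * length(rows)), 1)
    if (length(rows) >= 5) expect_gte(n_test, 1)
  }
  # deterministic given the seed
  expect_identical(split, split_dataset(ds, seed = 3))
})

test_that("training is deterministic and predictions route by feature length", {
  cfg <- generator_config(n_scenes = 150,
                          classes = demo_food_classes()[1:2, ], seed = 41)
  ds <- scene_dataset(generate_scenes(cfg))
  r1 <- suppressWarnings(train_models(ds, seed = 9, epochs = 25,
                                      patience = 10, min_examples = 10))
  r2 <- suppressWarnings(train_models(ds, seed = 9, epochs = 25,
                                      patience = 10, min_examples = 10))
  row <- ds[ds$has_ref, ][1, ]
  f11 <- as.numeric(carbcount:::feature_matrix(row, TRUE))
  f6 <- as.numeric(carbcount:::feature_matrix(row, FALSE))
  expect_identical(predict_weight(r1, f11, row$code),
                   predict_weight(r2, f11, row$code))
  expect_identical(predict_weight(r1, f6, row$code),
                   predict_weight(r2, f6, row$code))
  # routing and clamping
  expect_gte(predict_weight(r1, f11 * 0, row$code), 0)
  expect_error(predict_weight(r1, f11[1:5], row$code), "11 or 6")
  expect_error(predict_weight(r1, f11, "99999"), "available codes")
  expect_equal(predict_weight(r1, f11, row$code) %% 1, 0)
})

test_that("registries round-trip through their on-disk format", {
  cfg <- generator_config(n_scenes = 120,
                          classes = demo_food_classes()[1:2, ], seed = 43)
  ds <- scene_dataset(generate_scenes(cfg))
  reg <- suppressWarnings(train_models(ds, seed = 5, epochs = 15,
                                       patience = 5, min_examples = 10))
  dir <- withr::local_tempdir()
  save_registry(reg, dir)
  expect_true(file.exists(file.path(dir, "manifest.json")))
  back <- load_registry(dir)
  expect_setequal(names(back$models), names(reg$models))
  for (i in 1:5) {
    row <- ds[sample(nrow(ds), 1), ]
    use_ref <- row$has_ref &&
      !is.null(reg$models[[paste0(row$code, "|with_ref")]])
    f <- as.numeric(carbcount:::feature_matrix(row, use_ref))
    expect_identical(predict_weight(reg, f, row$code),
                     predict_weight(back, f, row$code))
  }
})

test_that("evaluation reports zero error for a perfect estimator and pools items", {
  cfg <- noiseless_config(60, n_classes = 3, seed = 19, spoon_probability = 1)
  ds <- scene_dataset(generate_scenes(cfg))
  ar <- analytic_registry(cfg$classes)
  rep <- evaluate_models(ar, demo_composition(), test_rows = ds)
  expect_true(all(rep$per_class$weight_rmse_g == 0))
  expect_true(all(rep$per_class$carb_rmse_g == 0))
  expect_equal(rep$overall_carb_rmse, 0)
  # pooled RMSE is computed over items, not averaged over classes
  d <- rep$details
  expect_equal(rep$overall_carb_rmse,
               sqrt(mean((d$pred_carb_g - d$true_carb_g)^2)))
  expect_error(evaluate_models(ar, demo_composition(), test_rows = ds[0, ]),
               "empty")
})

test_that("a constant carbohydrate offset yields exactly that pooled RMSE", {
  # analytic registry against a table whose carbohydrate density is
  # shifted: every item inherits a fixed +10 g carbohydrate error
  cfg <- noiseless_config(30, n_classes = 1, seed = 23, spoon_probability = 1)
  cfg$portion_steps <- 2  # fixed 110 g portions for class 11001
  ds <- scene_dataset(generate_scenes(cfg))
  ar <- analytic_registry(cfg$classes)
  tab <- demo_composition()
  pred <- carbcount:::predict_rows(ar, ds)
  expect_equal(pred, ds$true_weight_g)  # exact recovery first
  # shift the ground truth so every item carries a +10 g carbohydrate error
  carb_density <- lookup_food(tab, "11001")$carb_g_per_100g / 100
  ds_shift <- ds
  ds_shift$true_weight_g <- ds$true_weight_g - 10 / carb_density
  rep <- evaluate_models(ar, tab, test_rows = ds_shift)
  expect_equal(rep$overall_carb_rmse, 10, tolerance = 1e-9)
  expect_equal(rep$per_class$carb_rmse_g, 10, tolerance = 1e-9)
})
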