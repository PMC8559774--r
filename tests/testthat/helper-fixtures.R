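# Small in-code fixtures shared across test files.

# minimal composition table: plain rice, raisin-topped fried rice, a
# zero-carbohydrate meat, and a piece-counted fruit
tiny_table <- function() {
  as_food_table(data.frame(
    code = c("11001", "11002", "16001", "17001"),
    name = c("steamed white rice", "fried rice", "raisins",
             "boiled chicken breast"),
    carb_g_per_100g = c(30, 29, 72, 0),
    protein_g_per_100g = c(2.5, 6, 3, 31),
    fat_g_per_100g = c(0.3, 8, 0.5, 3.5),
    exchange_group = c("rice", "rice", "fruit", "meat"),
    grams_per_exchange = c(55, 55, 20, 40),
    carb_g_per_piece = c(NA, NA, 1, NA),
    stringsAsFactors = FALSE
  ))
}

# the raisin-topped fried rice worked example: 1 dish + 10 raisins,
# detector finds the dish and 5 raisins
raisin_truth <- function() {
  rbind(item_estimate("11002", 100), item_estimate("16001", 0, 10))
}
raisin_detected <- function() {
  rbind(item_estimate("11002", 100), item_estimate("16001", 0, 5))
}

# a hand-built scene matching the feature-assembly example
example_scene <- function(angle_deg = 60, with_spoon = TRUE) {
  items <- data.frame(code = "11001", xmin = 0.2, ymin = 0.2, xmax = 0.6,
                      ymax = 0.6, mask_area_fraction = 0.10,
                      true_weight_g = 110, piece_count = NA_integer_,
                      stringsAsFactors = FALSE)
  reference <- if (with_spoon) {
    data.frame(code = "SPOON", xmin = 0.70, ymin = 0.40, xmax = 0.85,
               ymax = 0.50, mask_area_fraction = 0.15 * 0.10 * pi / 4,
               true_weight_g = NA_real_, piece_count = NA_integer_,
               stringsAsFactors = FALSE)
  } else {
    NULL
  }
  structure(list(items = items, reference = reference,
                 angle_deg = angle_deg, pixel_scale = 0.03, image = NULL),
            class = "annotated_scene")
}

# small noiseless generator configuration for recovery-style tests
noiseless_config <- function(n_scenes, n_classes = 2, seed = 11L,
                             spoon_probability = 0.8) {
  generator_config(n_scenes = n_scenes,
                   classes = demo_food_classes()[seq_len(n_classes), ],
                   area_noise_cv = 0, scale_jitter_cv = 0,
                   spoon_probability = spoon_probability, seed = seed)
}

# definitional (brute-force) statistics used as oracles
oracle_rmse <- function(x, y) sqrt(sum((y - x)^2) / length(x))
oracle_pearson <- function(x, y) {
  sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
}
oracle_lin <- function(x, y) {
  n <- length(x)
  sxy <- sum((x - mean(x)) * (y - mean(y))) / n
  2 * sxy / (sum((x - mean(x))^2) / n + sum((y - mean(y))^2) / n +
               (mean(x) - mean(y))^2)
}
oracle_paired_t <- function(x, y) {
  d <- y - x
  n <- length(d)
  t <- mean(d) / (sd(d) / sqrt(n))
  list(t = t, p = 2 * pt(-abs(t), n - 1))
}
oracle_bland_altman <- function(x, y) {
  d <- y - x
  list(bias = mean(d), loa_low = mean(d) - 1.96 * sd(d),
       loa_high = mean(d) + 1.96 * sd(d))
}
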