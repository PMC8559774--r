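test_that("weights round to integer grams with halves away from zero", {
  expect_equal(round_weight(63.4), 63)
  expect_equal(round_weight(55.5), 56)
  expect_equal(round_weight(0), 0)
  expect_equal(round_weight(c(0.5, 1.5, 2.49)), c(1, 2, 2))
  # never further than half a gram from the raw reading
  set.seed(42)
  x <- runif(200, 0, 500)
  expect_true(all(abs(round_weight(x) - x) <= 0.5))
  expect_error(round_weight(-1), "non-negative")
})

test_that("per-portion nutrients scale per 100 g with an additive piece term", {
  tab <- tiny_table()
  rice <- lookup_food(tab, "11001")
  expect_equal(
    nutrients_for_weight(rice, item_estimate("11001", 100))[["carb_g"]], 30)
  # fried rice plus 10 raisins: 29 g from the dish + 1 g per raisin
  fried <- lookup_food(tab, "11002")
  raisin <- lookup_food(tab, "16001")
  carb <- nutrients_for_weight(fried, item_estimate("11002", 100))[["carb_g"]] +
    nutrients_for_weight(raisin, item_estimate("16001", 0, 10))[["carb_g"]]
  expect_equal(carb, 39)
  expect_equal(unname(nutrients_for_weight(rice, item_estimate("11001", 0))),
               c(0, 0, 0))
  # linearity in weight (no piece term)
  n1 <- nutrients_for_weight(fried, item_estimate("11002", 80))
  n2 <- nutrients_for_weight(fried, item_estimate("11002", 160))
  expect_equal(n2, 2 * n1)
  expect_error(nutrients_for_weight(rice, item_estimate("11002", 10)),
               "mismatch")
  expect_error(nutrients_for_weight(rice, item_estimate("11001", 10, 3)),
               "per-piece")
})

test_that("exchange units convert to rounded grams", {
  entry <- lookup_food(tiny_table(), "11001")  # 55 g per exchange
  expect_equal(exchange_to_grams(entry, 1), 55)
  expect_equal(exchange_to_grams(entry, 1.5), 83)  # 82.5 away from zero
  expect_equal(exchange_to_grams(entry, 0), 0)
  expect_error(exchange_to_grams(entry, -0.5), ">= 0")
})

test_that("scene aggregation is additive and permutation-invariant", {
  tab <- tiny_table()
  expect_equal(unname(aggregate_scene(list(), tab)), c(0, 0, 0))
  items <- list(item_estimate("11001", 100), item_estimate("11002", 100),
                item_estimate("16001", 0, 10))
  expect_equal(aggregate_scene(items, tab)[["carb_g"]], 30 + 39)
  single <- item_estimate("11002", 73)
  expect_equal(aggregate_scene(list(single), tab),
               nutrients_for_weight(lookup_food(tab, "11002"), single))
  # permutation invariance and additivity over partitions
  set.seed(7)
  perm <- sample(length(items))
  expect_equal(aggregate_scene(items[perm], tab), aggregate_scene(items, tab))
  expect_equal(aggregate_scene(items, tab),
               aggregate_scene(items[1:2], tab) +
                 aggregate_scene(items[3], tab))
  expect_error(aggregate_scene(list(item_estimate("99999", 5)), tab), "99999")
})

test_that("detection accuracy counts pieces and carbohydrate error is absolute", {
  tab <- tiny_table()
  res <- detection_and_carb_error(raisin_truth(), raisin_detected(), tab)
  expect_equal(res$detection_accuracy_percent, 55)  # 6 of 11 items
  expect_equal(res$carb_error_g, 5)
  perfect <- detection_and_carb_error(raisin_truth(), raisin_truth(), tab)
  expect_equal(perfect$detection_accuracy_percent, 100)
  expect_equal(perfect$carb_error_g, 0)
  miss <- detection_and_carb_error(raisin_truth(), list(), tab)
  expect_equal(miss$detection_accuracy_percent, 0)
  expect_equal(miss$carb_error_g,
               aggregate_scene(raisin_truth(), tab)[["carb_g"]])
  # a detection with no truth counterpart is flagged, not matched
  spurious <- detection_and_carb_error(
    list(item_estimate("11001", 50)),
    list(item_estimate("11001", 50), item_estimate("17001", 40)), tab)
  expect_equal(spurious$unmatched_detected, "17001")
  expect_equal(spurious$detection_accuracy_percent, 100)
})

test_that("composition tables round-trip through CSV and reject bad input", {
  tab <- tiny_table()
  path <- withr::local_tempfile(fileext = ".csv")
  write_composition_table(tab, path)
  back <- read_composition_table(path)
  expect_equal(as.data.frame(back), as.data.frame(tab))
  dup <- as.data.frame(tab)
  dup$code[2] <- "11001"
  expect_error(as_food_table(dup), "duplicate")
  bad <- as.data.frame(tab)
  bad$grams_per_exchange[1] <- 0
  expect_error(as_food_table(bad), "grams_per_exchange")
})

test_that("the bundled composition table is valid and spans the groups", {
  tab <- demo_composition()
  expect_s3_class(tab, "food_table")
  expect_gte(nrow(tab), 20)
  expect_setequal(
    intersect(c("rice", "noodle", "dessert", "fruit", "meat", "vegetable"),
              tab$exchange_group),
    c("rice", "noodle", "dessert", "fruit", "meat", "vegetable"))
  expect_true(max(tab$carb_g_per_100g) >= 70)
  expect_true(min(tab$carb_g_per_100g) == 0)
})

test_that("nutrient reports end with a totals row equal to the item sum", {
  tab <- tiny_table()
  items <- list(item_estimate("11001", 100), item_estimate("16001", 20, 10))
  rep <- nutrient_report(items, tab)
  expect_equal(rep$code[nrow(rep)], "TOTAL")
  expect_equal(rep$carb_g[nrow(rep)], sum(rep$carb_g[-nrow(rep)]))
  expect_equal(rep$carb_g[nrow(rep)],
               aggregate_scene(items, tab)[["carb_g"]])
})
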