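#' Food-composition tables and nutrient arithmetic
#'
#' Portion weights are integer grams; dishes are looked up in a composition
#' table holding per-100 g macronutrients, the gram weight of one exchange
#' unit, and (for piece-counted foods such as raisins) an additive
#' carbohydrate increment per piece.
#'
#' @name foodcomp
NULL

#' Round a raw weight to integer grams
#'
#' Kitchen-scale readings are recorded to the nearest integer gram; exact
#' half grams round away from zero, so 63.4 g becomes 63 g and 55.5 g
#' becomes 56 g.
#'
#' @param raw_weight Numeric vector of non-negative weights in grams.
#' @return Integer-valued numeric vector of rounded weights.
#' @examples
#' round_weight(c(63.4, 55.5))  # 63 56
#' @export
round_weight <- function(raw_weight) {
  if (!is.numeric(raw_weight) || any(!is.finite(raw_weight))) {
    stop("`raw_weight` must be finite numeric", call. = FALSE)
  }
  if (any(raw_weight < 0)) {
    stop("`raw_weight` must be non-negative", call. = FALSE)
  }
  floor(raw_weight + 0.5)
}

#' Construct a food-composition entry
#'
#' @param code Food code (stored as character; 5-digit codes keep leading
#'   zeros).
#' @param name Human-readable food name.
#' @param carb_g_per_100g,protein_g_per_100g,fat_g_per_100g Macronutrient
#'   grams per 100 g of food.
#' @param exchange_group Exchange-list group label (e.g. "rice", "fruit").
#' @param grams_per_exchange Gram weight of one exchange unit (> 0).
#' @param carb_g_per_piece Additive carbohydrate grams per piece for
#'   piece-counted foods, or `NA` when the food is not piece-counted.
#' @return A one-row data.frame of class `food_entry`.
#' @export
food_entry <- function(code, name, carb_g_per_100g, protein_g_per_100g,
                       fat_g_per_100g, exchange_group, grams_per_exchange,
                       carb_g_per_piece = NA_real_) {
  stopifnot(length(code) == 1)
  nutrients <- c(carb_g_per_100g, protein_g_per_100g, fat_g_per_100g)
  if (any(!is.finite(nutrients)) || any(nutrients < 0)) {
    stop("per-100 g nutrient values must be finite and >= 0", call. = FALSE)
  }
  if (!is.finite(grams_per_exchange) || grams_per_exchange <= 0) {
    stop("`grams_per_exchange` must be > 0", call. = FALSE)
  }
  entry <- data.frame(
    code = as.character(code), name = name,
    carb_g_per_100g = carb_g_per_100g,
    protein_g_per_100g = protein_g_per_100g,
    fat_g_per_100g = fat_g_per_100g,
    exchange_group = exchange_group,
    grams_per_exchange = grams_per_exchange,
    carb_g_per_piece = as.numeric(carb_g_per_piece),
    stringsAsFactors = FALSE
  )
  class(entry) <- c("food_entry", class(entry))
  entry
}

#' Read a food-composition table from CSV
#'
#' Expected columns: `code,name,carb_g_per_100g,protein_g_per_100g,`
#' `fat_g_per_100g,exchange_group,grams_per_exchange,carb_g_per_piece`
#' (the last may be empty). Unknown columns are ignored; codes are kept as
#' character strings so leading zeros survive.
#'
#' @param path Path to a CSV file with a header row.
#' @return A `food_table` data.frame, one row per food code.
#' @export
read_composition_table <- function(path) {
  raw <- utils::read.csv(path, colClasses = c(code = "character"),
                         stringsAsFactors = FALSE)
  required <- c("code", "name", "carb_g_per_100g", "protein_g_per_100g",
                "fat_g_per_100g", "exchange_group", "grams_per_exchange")
  missing <- setdiff(required, names(raw))
  if (length(missing) > 0) {
    stop("composition table is missing columns: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (!"carb_g_per_piece" %in% names(raw)) raw$carb_g_per_piece <- NA_real_
  raw$carb_g_per_piece <- suppressWarnings(as.numeric(raw$carb_g_per_piece))
  tab <- raw[, c(required, "carb_g_per_piece")]
  as_food_table(tab)
}

#' Validate and class a composition data.frame
#'
#' @param tab A data.frame with the composition-table columns.
#' @return The same data.frame with class `food_table`.
#' @export
as_food_table <- function(tab) {
  stopifnot(is.data.frame(tab))
  tab$code <- as.character(tab$code)
  if (anyDuplicated(tab$code)) {
    stop("duplicate food codes in composition table: ",
         paste(unique(tab$code[duplicated(tab$code)]), collapse = ", "),
         call. = FALSE)
  }
  nut <- as.matrix(tab[, c("carb_g_per_100g", "protein_g_per_100g",
                           "fat_g_per_100g")])
  if (any(!is.finite(nut)) || any(nut < 0)) {
    stop("per-100 g nutrient values must be finite and >= 0", call. = FALSE)
  }
  if (any(!is.finite(tab$grams_per_exchange)) ||
      any(tab$grams_per_exchange <= 0)) {
    stop("`grams_per_exchange` must be > 0 for every entry", call. = FALSE)
  }
  class(tab) <- unique(c("food_table", class(tab)))
  tab
}

#' Write a composition table to CSV
#' @param tab A `food_table`.
#' @param path Output CSV path.
#' @export
write_composition_table <- function(tab, path) {
  utils::write.csv(as.data.frame(tab), path, row.names = FALSE, na = "")
  invisible(path)
}

#' Look up one entry in a composition table
#' @param tab A `food_table`.
#' @param code Food code string.
#' @return The matching `food_entry` row.
#' @export
lookup_food <- function(tab, code) {
  i <- match(as.character(code), tab$code)
  if (is.na(i)) {
    stop("food code '", code, "' not found in composition table",
         call. = FALSE)
  }
  entry <- as.data.frame(tab)[i, , drop = FALSE]
  rownames(entry) <- NULL
  class(entry) <- c("food_entry", class(entry))
  entry
}

#' Construct an item estimate (one detected or measured portion)
#'
#' @param code Food code.
#' @param weight_g Integer grams (>= 0; already rounded).
#' @param piece_count Integer number of pieces for piece-counted foods, or
#'   `NA`.
#' @return A one-row data.frame of class `item_estimate`.
#' @export
item_estimate <- function(code, weight_g, piece_count = NA_integer_) {
  if (!is.finite(weight_g) || weight_g < 0) {
    stop("`weight_g` must be >= 0", call. = FALSE)
  }
  if (abs(weight_g - round(weight_g)) > 1e-9) {
    stop("`weight_g` must be integer grams (apply round_weight() first)",
         call. = FALSE)
  }
  if (!is.na(piece_count) && (piece_count < 0 ||
                              abs(piece_count - round(piece_count)) > 1e-9)) {
    stop("`piece_count` must be a non-negative integer or NA", call. = FALSE)
  }
  out <- data.frame(code = as.character(code), weight_g = round(weight_g),
                    piece_count = as.integer(round(piece_count)),
                    stringsAsFactors = FALSE)
  class(out) <- c("item_estimate", class(out))
  out
}

#' Nutrients contributed by one portion
#'
#' Carbohydrate is `weight_g * carb_g_per_100g / 100` plus, for
#' piece-counted foods, `piece_count * carb_g_per_piece`. Protein and fat
#' scale per 100 g only.
#'
#' @param entry A `food_entry` (or one row of a `food_table`).
#' @param item An `item_estimate` with the same food code.
#' @return Named numeric vector `c(carb_g, protein_g, fat_g)`.
#' @export
nutrients_for_weight <- function(entry, item) {
  if (entry$code != item$code) {
    stop("code mismatch: entry '", entry$code, "' vs item '", item$code, "'",
         call. = FALSE)
  }
  w <- item$weight_g
  pieces <- if (is.na(item$piece_count)) 0 else item$piece_count
  per_piece <- if (is.na(entry$carb_g_per_piece)) 0 else entry$carb_g_per_piece
  if (pieces > 0 && is.na(entry$carb_g_per_piece)) {
    stop("item for '", entry$code,
         "' carries a piece count but the entry has no per-piece carbohydrate",
         call. = FALSE)
  }
  c(carb_g = w * entry$carb_g_per_100g / 100 + pieces * per_piece,
    protein_g = w * entry$protein_g_per_100g / 100,
    fat_g = w * entry$fat_g_per_100g / 100)
}

#' Convert exchange units to integer grams
#'
#' @param entry A `food_entry`.
#' @param units Non-negative number of exchange units.
#' @return Integer grams (`units * grams_per_exchange`, rounded with
#'   [round_weight()]).
#' @export
exchange_to_grams <- function(entry, units) {
  if (!is.finite(units) || units < 0) {
    stop("`units` must be >= 0", call. = FALSE)
  }
  round_weight(units * entry$grams_per_exchange)
}

#' Total nutrients for a list of portions
#'
#' @param items A list of `item_estimate` rows (or a data.frame with columns
#'   `code`, `weight_g`, `piece_count`).
#' @param tab A `food_table` covering every item code.
#' @return Named numeric vector `c(carb_g, protein_g, fat_g)`; zeros for an
#'   empty list.
#' @export
aggregate_scene <- function(items, tab) {
  items <- items_as_list(items)
  total <- c(carb_g = 0, protein_g = 0, fat_g = 0)
  for (item in items) {
    total <- total + nutrients_for_weight(lookup_food(tab, item$code), item)
  }
  total
}

items_as_list <- function(items) {
  if (is.data.frame(items)) {
    if (nrow(items) == 0) return(list())
    if (!"piece_count" %in% names(items)) items$piece_count <- NA_integer_
    return(lapply(seq_len(nrow(items)), function(i) items[i, , drop = FALSE]))
  }
  items
}

# One matching unit per piece of a piece-counted food, else one per item.
item_units <- function(item) {
  if (!is.na(item$piece_count) && item$piece_count > 0) item$piece_count else 1L
}

#' Detection accuracy and carbohydrate error for a detected-item set
#'
#' Each piece of a piece-counted food counts as one item, so missing 5 of
#' 10 raisins alongside a detected dish scores 6 matches out of 11.
#' Accuracy is reported as an integer percent; the carbohydrate error is
#' the absolute difference between the truth total and the detected total.
#'
#' @param truth,detected Lists of `item_estimate`s; `detected` should be a
#'   sub-multiset of `truth` by code (weights need not match). Detected
#'   items with no truth counterpart are not matched and are flagged.
#' @param tab A `food_table`.
#' @return List with `detection_accuracy_percent`, `carb_error_g`,
#'   `matched_units`, `truth_units`, and `unmatched_detected` (codes).
#' @export
detection_and_carb_error <- function(truth, detected, tab) {
  truth <- items_as_list(truth)
  detected <- items_as_list(detected)
  if (length(truth) == 0) stop("`truth` must be non-empty", call. = FALSE)

  truth_units_by_code <- list()
  total_units <- 0L
  for (item in truth) {
    u <- item_units(item)
    total_units <- total_units + u
    prev <- truth_units_by_code[[item$code]]
    truth_units_by_code[[item$code]] <- if (is.null(prev)) u else prev + u
  }
  matched <- 0L
  unmatched_detected <- character(0)
  for (item in detected) {
    u <- item_units(item)
    avail <- truth_units_by_code[[item$code]]
    if (is.null(avail) || avail <= 0) {
      unmatched_detected <- c(unmatched_detected, item$code)
      next
    }
    take <- min(u, avail)
    if (take < u) unmatched_detected <- c(unmatched_detected, item$code)
    matched <- matched + take
    truth_units_by_code[[item$code]] <- avail - take
  }
  carb_truth <- aggregate_scene(truth, tab)[["carb_g"]]
  carb_det <- if (length(detected) == 0) 0 else
    aggregate_scene(detected, tab)[["carb_g"]]
  list(
    detection_accuracy_percent = round(100 * matched / total_units),
    carb_error_g = abs(carb_truth - carb_det),
    matched_units = matched,
    truth_units = total_units,
    unmatched_detected = unmatched_detected
  )
}

#' Per-item nutrient report
#'
#' One row per item with its weight and macronutrients, plus a `TOTAL` row.
#'
#' @param items List or data.frame of item estimates.
#' @param tab A `food_table`.
#' @param path Optional CSV path; when given the report is also written.
#' @return Data.frame report (invisibly returns `path` unchanged semantics:
#'   the data.frame is always returned).
#' @export
nutrient_report <- function(items, tab, path = NULL) {
  items <- items_as_list(items)
  rows <- lapply(items, function(item) {
    entry <- lookup_food(tab, item$code)
    nut <- nutrients_for_weight(entry, item)
    data.frame(code = item$code, name = entry$name, weight_g = item$weight_g,
               piece_count = item$piece_count,
               carb_g = nut[["carb_g"]], protein_g = nut[["protein_g"]],
               fat_g = nut[["fat_g"]], stringsAsFactors = FALSE)
  })
  report <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  if (is.null(report)) {
    report <- data.frame(code = character(0), name = character(0),
                         weight_g = numeric(0), piece_count = integer(0),
                         carb_g = numeric(0), protein_g = numeric(0),
                         fat_g = numeric(0))
  }
  total <- data.frame(code = "TOTAL", name = "", weight_g = sum(report$weight_g),
                      piece_count = NA_integer_, carb_g = sum(report$carb_g),
                      protein_g = sum(report$protein_g),
                      fat_g = sum(report$fat_g), stringsAsFactors = FALSE)
  report <- rbind(report, total)
  if (!is.null(path)) utils::write.csv(report, path, row.names = FALSE, na = "")
  report
}

#' Bundled synthetic composition table
#'
#' A ~20-entry stand-in for a national food-composition database, spanning
#' rice, noodle, dessert, fruit, meat and vegetable exchange groups with
#' carbohydrate densities from 0 to 80 g/100 g. Values are synthetic.
#'
#' @return A `food_table`.
#' @export
demo_composition <- function() {
  read_composition_table(system.file("extdata", "composition_synthetic.csv",
                                     package = "carbcount", mustWork = TRUE))
}
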