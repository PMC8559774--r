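#' Method-agreement statistics
#'
#' The statistics used to validate a new measurement method against a
#' reference: RMSE, Pearson correlation, Lin's concordance correlation
#' coefficient, the paired t-test, Bland-Altman bias and limits of
#' agreement, the Dupont-Plummer paired-design sample size, and percent
#' error of summed totals. Inputs are paired series: `x` the reference
#' (measured) values, `y` the comparison (estimated) values.
#'
#' @name agreement_stats
NULL

check_paired <- function(x, y, min_n = 2) {
  if (length(x) != length(y)) {
    stop("paired series must have equal length (", length(x), " vs ",
         length(y), ")", call. = FALSE)
  }
  if (length(x) < min_n) {
    stop("need at least ", min_n, " pairs", call. = FALSE)
  }
  if (any(!is.finite(x)) || any(!is.finite(y))) {
    stop("paired series must be finite", call. = FALSE)
  }
  invisible(TRUE)
}

#' Root mean square error of paired values
#' @param x Reference values.
#' @param y Comparison values.
#' @return `sqrt(mean((y - x)^2))`.
#' @export
rmse <- function(x, y) {
  check_paired(x, y, min_n = 1)
  sqrt(mean((y - x)^2))
}

#' Lin's concordance correlation coefficient
#'
#' `Rc = 2 s_xy / (s_x^2 + s_y^2 + (mean(x) - mean(y))^2)` with
#' n-denominator moments: agreement is penalized for both poor
#' correlation and location/scale shifts, so `|Rc| <= |r|`.
#'
#' @param x Reference values.
#' @param y Comparison values.
#' @return Concordance coefficient in [-1, 1].
#' @export
lin_rc <- function(x, y) {
  check_paired(x, y)
  n <- length(x)
  sxy <- mean((x - mean(x)) * (y - mean(y)))
  sx2 <- mean((x - mean(x))^2)
  sy2 <- mean((y - mean(y))^2)
  if (sx2 <= 0 || sy2 <= 0) {
    stop("Lin's Rc is undefined when either series has zero variance",
         call. = FALSE)
  }
  2 * sxy / (sx2 + sy2 + (mean(x) - mean(y))^2)
}

#' Pearson correlation of paired values
#' @param x Reference values.
#' @param y Comparison values.
#' @return Correlation coefficient.
#' @export
pearson_r <- function(x, y) {
  check_paired(x, y)
  stats::cor(x, y)
}

#' Paired t-test on differences y - x
#'
#' Two-sided, n - 1 degrees of freedom. When every difference equals the
#' same nonzero constant the statistic is infinite; `p = 0` is returned
#' with `degenerate = TRUE`.
#'
#' @param x Reference values.
#' @param y Comparison values.
#' @return List with `t`, `df`, `p`, `mean_diff`, `degenerate`.
#' @export
paired_t <- function(x, y) {
  check_paired(x, y)
  d <- y - x
  if (stats::sd(d) < 1e-12) {
    if (abs(mean(d)) < 1e-12) {
      return(list(t = 0, df = length(d) - 1, p = 1, mean_diff = mean(d),
                  degenerate = TRUE))
    }
    return(list(t = sign(mean(d)) * Inf, df = length(d) - 1, p = 0,
                mean_diff = mean(d), degenerate = TRUE))
  }
  ht <- stats::t.test(y, x, paired = TRUE)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = ht$p.value, mean_diff = mean(d), degenerate = FALSE)
}

#' Bland-Altman bias and limits of agreement
#'
#' Differences are oriented comparison minus reference; limits are
#' `bias +/- 1.96 * sd(differences)` (n - 1 denominator).
#'
#' @param x Reference values.
#' @param y Comparison values.
#' @return List with `bias`, `loa_low`, `loa_high`, `sd_diff`, and the
#'   per-point `means` and `differences`.
#' @export
bland_altman <- function(x, y) {
  check_paired(x, y)
  d <- y - x
  bias <- mean(d)
  s <- stats::sd(d)
  list(bias = bias, loa_low = bias - 1.96 * s, loa_high = bias + 1.96 * s,
       sd_diff = s, means = (x + y) / 2, differences = d)
}

#' Minimal Bland-Altman scatter export
#'
#' Writes a PNG scatter of per-pair means against differences with the
#' bias and limit-of-agreement lines.
#'
#' @param x,y Paired series (reference, comparison).
#' @param path Output PNG path.
#' @param main Plot title.
#' @return `path`, invisibly.
#' @export
plot_bland_altman <- function(x, y, path, main = "Bland-Altman") {
  ba <- bland_altman(x, y)
  grDevices::png(path, width = 640, height = 480)
  on.exit(grDevices::dev.off())
  graphics::plot(ba$means, ba$differences, pch = 19,
                 xlab = "Mean of methods (g)", ylab = "Difference (g)",
                 main = main)
  graphics::abline(h = ba$bias, lty = 1)
  graphics::abline(h = c(ba$loa_low, ba$loa_high), lty = 2, col = "orange")
  invisible(path)
}

#' Dupont-Plummer paired-design sample size
#'
#' Smallest `n >= 2` with
#' `n >= (t_{1-alpha/2, n-1} + t_{power, n-1})^2 * (sigma / delta)^2`,
#' iterated from the normal-approximation start. With a detectable mean
#' difference of 10 g and an SD of paired differences of 10.12 g at
#' alpha 0.05 and power 0.9 this gives 13 pairs.
#'
#' @param delta Mean paired difference to detect (> 0).
#' @param sigma Standard deviation of the paired differences (> 0).
#' @param alpha Two-sided type-I error rate.
#' @param power Desired power (1 - beta).
#' @return Integer sample size.
#' @export
paired_sample_size <- function(delta, sigma, alpha = 0.05, power = 0.9) {
  stopifnot(delta > 0, sigma > 0, alpha > 0, alpha < 1, power > 0, power < 1)
  ratio2 <- (sigma / delta)^2
  need <- function(n) {
    (stats::qt(1 - alpha / 2, n - 1) + stats::qt(power, n - 1))^2 * ratio2
  }
  n <- max(2, ceiling((stats::qnorm(1 - alpha / 2) + stats::qnorm(power))^2 *
                        ratio2))
  for (i in 1:1000) {
    if (n >= need(n)) {
      # confirm minimality: walk back while the inequality still holds
      while (n > 2 && (n - 1) >= need(n - 1)) n <- n - 1
      return(as.integer(n))
    }
    n <- n + 1
  }
  stop("sample-size iteration did not converge (pathological inputs)",
       call. = FALSE)
}

#' Percent error of a total against the measured total
#'
#' `100 * |other - measured| / measured`, reported to one decimal, the
#' convention used for summed carbohydrate totals (682 g measured vs
#' 655 g estimated is a 4.0% error).
#'
#' @param measured_total Reference total (> 0).
#' @param other_total Comparison total.
#' @return Percent error rounded to one decimal.
#' @export
percent_error <- function(measured_total, other_total) {
  if (!is.finite(measured_total) || measured_total <= 0) {
    stop("`measured_total` must be > 0", call. = FALSE)
  }
  round(100 * abs(other_total - measured_total) / measured_total, 1)
}

#' Agreement report for one estimator against a reference
#'
#' @param x Reference values.
#' @param y Comparison values.
#' @return An `agreement_report` list: `n`, `rmse`, `pearson_r`,
#'   `lin_rc`, `mean_y`, `sd_y`, `t`, `p`, `bias`, `loa_low`, `loa_high`.
#' @export
agreement_report <- function(x, y) {
  pt <- paired_t(x, y)
  ba <- bland_altman(x, y)
  identical_series <- isTRUE(all.equal(x, y, tolerance = 0))
  r <- if (identical_series) 1 else pearson_r(x, y)
  rc <- if (identical_series) 1 else lin_rc(x, y)
  structure(list(
    n = length(x), rmse = rmse(x, y), pearson_r = r, lin_rc = rc,
    mean_y = mean(y), sd_y = stats::sd(y), t = pt$t, p = pt$p,
    bias = ba$bias, loa_low = ba$loa_low, loa_high = ba$loa_high,
    degenerate = pt$degenerate || identical_series
  ), class = "agreement_report")
}

#' Multi-estimator comparison table
#'
#' One row per estimator with RMSE, Lin's Rc, Pearson's r, mean +/- SD,
#' the paired-t p-value and a significance star at p < 0.05; the
#' `carb_source` label records whether the estimators' carbohydrate
#' values were recomputed from converted gram weights or taken as
#' stated.
#'
#' @param reference Reference series (measured values).
#' @param estimators Named list of comparison series.
#' @param carb_source Either "recomputed" or "as_stated".
#' @param path Optional CSV output path.
#' @return Data.frame of class `comparison_report`.
#' @export
comparison_report <- function(reference, estimators,
                              carb_source = c("recomputed", "as_stated"),
                              path = NULL) {
  carb_source <- match.arg(carb_source)
  stopifnot(is.list(estimators), length(estimators) >= 1,
            !is.null(names(estimators)), all(nzchar(names(estimators))))
  rows <- lapply(names(estimators), function(name) {
    rep <- agreement_report(reference, estimators[[name]])
    data.frame(
      estimator = name, n = rep$n, rmse = rep$rmse, lin_rc = rep$lin_rc,
      pearson_r = rep$pearson_r, mean = rep$mean_y, sd = rep$sd_y,
      t = rep$t, p = rep$p,
      significant = !is.na(rep$p) & rep$p < 0.05,
      degenerate = rep$degenerate,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  attr(out, "carb_source") <- carb_source
  class(out) <- c("comparison_report", class(out))
  if (!is.null(path)) {
    utils::write.csv(cbind(out, carb_source = carb_source), path,
                     row.names = FALSE)
  }
  out
}

#' @export
format.comparison_report <- function(x, ...) {
  star <- ifelse(x$significant, "*", " ")
  header <- sprintf("%-12s %4s %8s %7s %7s %16s %8s",
                    "Estimator", "n", "RMSE", "Rc", "r", "Mean +/- SD", "p")
  lines <- sprintf("%-12s %4d %8.2f %7.3f %7.3f %8.2f +/- %5.2f %7.4f%s",
                   x$estimator, x$n, x$rmse, x$lin_rc, x$pearson_r,
                   x$mean, x$sd, x$p, star)
  paste(c(header, lines,
          paste0("carbohydrate values: ", attr(x, "carb_source"),
                 "; * p < 0.05")),
        collapse = "\n")
}

#' @export
print.comparison_report <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

#' Read paired series from a CSV file
#'
#' First column is the reference; every remaining column is an
#' estimator.
#'
#' @param path CSV path with a header row.
#' @return List with `reference` (numeric) and `estimators` (named list).
#' @export
read_paired_csv <- function(path) {
  tab <- utils::read.csv(path)
  if (ncol(tab) < 2) {
    stop("paired CSV needs a reference column and at least one estimator",
         call. = FALSE)
  }
  list(reference = as.numeric(tab[[1]]),
       estimators = lapply(tab[-1], as.numeric))
}
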