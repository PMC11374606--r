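# Germination-vigor statistics: germination rate (percentage germinated by a
# time point), germination index (early germination weighted more), and the
# aggregation of time-stamped detections into per-dish germination series.

#' Germination rate
#'
#' Percentage of seeds germinated by a time point: `100 * N_t / N`.
#'
#' @param n_t Cumulative number of germinated seeds at the time point.
#' @param n Total number of seeds sown (49 for a full 7 x 7 dish).
#' @return Percentage in \[0, 100\]. Vectorized over `n_t`.
#' @examples
#' germination_rate(24, 49)
#' @export
germination_rate <- function(n_t, n) {
  if (length(n) != 1L || !is.finite(n) || n <= 0) stop("N must be a positive count")
  if (any(n_t < 0) || any(n_t > n)) stop("N_t must lie in [0, N]")
  100 * n_t / n
}

#' Germination index
#'
#' `sum(G_t / D_t)` where `G_t` is the number of seeds newly germinated on day
#' `D_t`. Seeds that germinate earlier contribute more, so the index measures
#' vigor, not just the final rate.
#'
#' @param series A `germination_series` (see [germination_series()]), or a
#'   data frame with columns `day` and `newly_germinated`.
#' @return Non-negative scalar; 0 for an empty series.
#' @examples
#' germination_index(data.frame(day = c(1, 2), newly_germinated = c(2, 3))) # 3.5
#' @export
germination_index <- function(series) {
  obs <- if (inherits(series, "germination_series")) series$observations else series
  if (is.null(obs) || nrow(obs) == 0) return(0)
  if (any(obs$day <= 0)) stop("days D_t must be positive")
  if (any(obs$newly_germinated < 0)) stop("G_t must be non-negative")
  sum(obs$newly_germinated / obs$day)
}

#' Per-dish germination time series
#'
#' @param dish_id Identifier of the culture dish.
#' @param observations Tibble with columns `day` (strictly increasing, >= 1),
#'   `cumulative_germinated` (non-decreasing, <= `n_seeds`); the column
#'   `newly_germinated` is derived if absent.
#' @param n_seeds Total seeds sown in the dish (default 49).
#' @param treatment Optional treatment label (e.g. NaCl concentration in
#'   mmol/L).
#' @return An object of class `germination_series`.
#' @export
germination_series <- function(dish_id, observations, n_seeds = 49,
                               treatment = NA) {
  obs <- tibble::as_tibble(observations)
  if (nrow(obs) > 0) {
    if (any(diff(obs$day) <= 0)) stop("days must be strictly increasing")
    if (any(obs$day < 1)) stop("days must be >= 1")
    if (any(diff(obs$cumulative_germinated) < 0)) {
      stop("cumulative germination counts must be non-decreasing")
    }
    if (any(obs$cumulative_germinated > n_seeds)) {
      stop("cumulative count exceeds the number of seeds sown")
    }
    if (!"newly_germinated" %in% names(obs)) {
      obs$newly_germinated <- diff(c(0, obs$cumulative_germinated))
    }
  } else if (!"newly_germinated" %in% names(obs)) {
    obs$newly_germinated <- double(0)
  }
  structure(list(dish_id = dish_id, treatment = treatment, n_seeds = n_seeds,
                 observations = obs),
            class = "germination_series")
}

#' @export
print.germination_series <- function(x, ...) {
  cat(sprintf("Germination series for dish %s (%s seeds%s): %d observations\n",
              x$dish_id, x$n_seeds,
              if (is.na(x$treatment)) "" else paste0(", treatment ", x$treatment),
              nrow(x$observations)))
  final <- if (nrow(x$observations)) utils::tail(x$observations$cumulative_germinated, 1) else 0L
  cat(sprintf("  final rate %.2f%%, index %.3f\n",
              germination_rate(final, x$n_seeds), germination_index(x)))
  invisible(x)
}

#' @export
tidy.germination_series <- function(x, ...) {
  obs <- x$observations
  obs$dish_id <- x$dish_id
  obs$treatment <- x$treatment
  obs$rate <- germination_rate(obs$cumulative_germinated, x$n_seeds)
  obs[, c("dish_id", "treatment", "day", "cumulative_germinated",
          "newly_germinated", "rate")]
}

#' @export
glance.germination_series <- function(x, ...) {
  final <- if (nrow(x$observations)) utils::tail(x$observations$cumulative_germinated, 1) else 0L
  tibble::tibble(dish_id = x$dish_id, treatment = x$treatment,
                 n_seeds = x$n_seeds,
                 final_rate = germination_rate(final, x$n_seeds),
                 index = germination_index(x))
}

#' @export
autoplot.germination_series <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$day, y = .data$rate)) +
    ggplot2::geom_step() + ggplot2::geom_point() +
    ggplot2::labs(x = "day", y = "germination rate (%)",
                  title = paste("Dish", object$dish_id)) +
    ggplot2::ylim(0, 100)
}

# centers of a rows x cols dish grid in normalized [0,1] coordinates
grid_cell_centers <- function(rows, cols) {
  cx <- (rep(seq_len(cols), each = rows) - 0.5) / cols
  cy <- (rep(seq_len(rows), times = cols) - 0.5) / rows
  cbind(cx = cx, cy = cy)
}

#' Aggregate time-stamped detections into a germination series
#'
#' Each detection is snapped to the nearest cell center of the known dish
#' grid. A seed counts as germinated from the first day any root detection
#' (either class) with confidence at or above the threshold lands in its
#' cell; multiple detections in one cell on one day collapse to a single
#' seed, and germination is latched (a seed never reverts). Detections whose
#' centers fall outside the unit dish are dropped.
#'
#' @param detections Tibble with columns `day`, `class_id`, `cx`, `cy`,
#'   `w`, `h`, `conf` (box centers normalized to the dish, i.e. \[0, 1\]).
#' @param rows,cols Dish grid layout (default 7 x 7).
#' @param n_seeds Seeds sown (defaults to `rows * cols`).
#' @param confidence_threshold Minimum detection confidence (default 0.5).
#' @param days Days the dish was observed; defaults to the days present in
#'   `detections`. Days with no detections still appear in the series.
#' @param dish_id,treatment Metadata forwarded to [germination_series()].
#' @return A `germination_series`.
#' @export
detections_to_series <- function(detections, rows = 7, cols = 7,
                                 n_seeds = rows * cols,
                                 confidence_threshold = 0.5,
                                 days = NULL, dish_id = "dish",
                                 treatment = NA) {
  det <- tibble::as_tibble(detections)
  if (is.null(days)) days <- sort(unique(det$day))
  if (nrow(det) > 0) {
    inside <- det$cx >= 0 & det$cx <= 1 & det$cy >= 0 & det$cy <= 1
    if (any(!inside)) {
      message(sum(!inside), " detection(s) outside dish bounds dropped")
      det <- det[inside, , drop = FALSE]
    }
    det <- det[det$conf >= confidence_threshold, , drop = FALSE]
  }
  centers <- grid_cell_centers(rows, cols)
  germinated_on <- rep(Inf, rows * cols)
  if (nrow(det) > 0) {
    # nearest cell center; equidistant detections go to the lower cell index
    d2 <- outer(det$cx, centers[, "cx"], `-`)^2 +
      outer(det$cy, centers[, "cy"], `-`)^2
    cell <- apply(d2, 1, which.min)
    first <- tapply(det$day, cell, min)
    idx <- as.integer(names(first))
    germinated_on[idx] <- pmin(germinated_on[idx], as.numeric(first))
  }
  obs <- tibble::tibble(
    day = days,
    cumulative_germinated = vapply(days, function(d) sum(germinated_on <= d),
                                   numeric(1))
  )
  germination_series(dish_id, obs, n_seeds = n_seeds, treatment = treatment)
}

#' Summarize germination series across treatments
#'
#' @param series_list List of `germination_series` objects (e.g. one per dish
#'   or per salt-stress treatment).
#' @return A list of class `stress_report`: `summary` (per-series final rate
#'   and index) and `curves` (long tibble of rate over days).
#' @export
stress_report <- function(series_list) {
  if (length(series_list) == 0) stop("need at least one series")
  if (inherits(series_list, "germination_series")) series_list <- list(series_list)
  ns <- vapply(series_list, function(s) s$n_seeds, numeric(1))
  if (length(unique(ns)) > 1) {
    warning("series have different seed totals; rates are per-dish normalized")
  }
  structure(list(
    summary = dplyr::bind_rows(lapply(series_list, glance)),
    curves = dplyr::bind_rows(lapply(series_list, tidy))
  ), class = "stress_report")
}

#' @export
print.stress_report <- function(x, ...) {
  cat("Germination vigor report\n")
  print(x$summary)
  invisible(x)
}

#' @export
tidy.stress_report <- function(x, ...) x$curves

#' @export
glance.stress_report <- function(x, ...) x$summary

#' @export
autoplot.stress_report <- function(object, ...) {
  df <- object$curves
  df$label <- ifelse(is.na(df$treatment), as.character(df$dish_id),
                     as.character(df$treatment))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$day, y = .data$rate,
                                   colour = .data$label)) +
    ggplot2::geom_step() + ggplot2::geom_point() +
    ggplot2::labs(x = "day", y = "germination rate (%)", colour = "series",
                  title = "Germination under treatments") +
    ggplot2::ylim(0, 100)
}

#' Write a stress report to CSV and PNG files
#'
#' @param report A [stress_report()] object.
#' @param dir Output directory (created if missing).
#' @return Invisibly, the paths written.
#' @export
write_stress_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  summary_path <- file.path(dir, "germination_summary.csv")
  curves_path <- file.path(dir, "germination_curves.csv")
  plot_path <- file.path(dir, "germination_curves.png")
  utils::write.csv(report$summary, summary_path, row.names = FALSE)
  utils::write.csv(report$curves, curves_path, row.names = FALSE)
  p <- autoplot(report)
  grDevices::png(plot_path, width = 800, height = 500)
  print(p)
  grDevices::dev.off()
  invisible(c(summary_path, curves_path, plot_path))
}
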