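#' Tidy and glance methods
#'
#' Broom-style summaries of the package's fitted and derived objects.
#'
#' @param x the object.
#' @param ... unused.
#' @return A tibble.
#' @name osteomap-tidiers
NULL

#' @rdname osteomap-tidiers
#' @method tidy correspondence_map
#' @export
tidy.correspondence_map <- function(x, ...) {
  tibble::as_tibble(x)[, c("source_index", "target_index", "score")]
}

#' @rdname osteomap-tidiers
#' @method glance correspondence_map
#' @export
glance.correspondence_map <- function(x, ...) {
  tibble::tibble(
    n_vertices = nrow(x),
    median_score = stats::median(x$score),
    min_score = min(x$score),
    frac_identity = mean(x$source_index == x$target_index),
    r = attr(x, "r") %||% NA_real_,
    rho = attr(x, "rho") %||% NA_real_
  )
}

#' @rdname osteomap-tidiers
#' @method tidy growth_curve
#' @export
tidy.growth_curve <- function(x, ...) {
  tibble::tibble(time = x$times, cumulative = x$cumulative,
                 fitted = x$fun(x$times), rate = x$fun(x$times, deriv = 1L))
}

#' @rdname osteomap-tidiers
#' @method glance growth_curve
#' @export
glance.growth_curve <- function(x, ...) {
  resid <- x$cumulative - x$fun(x$times)
  tibble::tibble(n_instances = length(x$times), smoothing = x$smoothing,
                 rss = sum(resid^2),
                 mean_rate = mean(x$fun(x$times, deriv = 1L)))
}

#' @rdname osteomap-tidiers
#' @method glance growth_field
#' @export
glance.growth_field <- function(x, ...) {
  tibble::tibble(n_vertices = attr(x, "n_vertices"),
                 n_instances = length(attr(x, "times")),
                 mean_rate = mean(x$rate),
                 max_rate = max(x$rate), min_rate = min(x$rate))
}

#' Plot regional growth-rate trajectories
#'
#' One line per region, faceted by direction, over the monitoring intervals —
#' the standard way the regional rates are compared.
#'
#' @param object a `region_summary`.
#' @param ... unused.
#' @return A ggplot.
#' @method autoplot region_summary
#' @export
autoplot.region_summary <- function(object, ...) {
  d <- tibble::as_tibble(object)
  d <- d[d$instance > 1L, ]
  ggplot2::ggplot(d, ggplot2::aes(x = .data$time, y = .data$mean,
                                  colour = .data$region)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::facet_wrap(~direction) +
    ggplot2::labs(x = "time (months)", y = "growth rate (%/month)",
                  colour = "region") +
    ggplot2::theme_minimal()
}

#' Plot the per-vertex rate distribution over time
#'
#' Median and interquartile ribbon of the per-vertex total rates per
#' instance.
#'
#' @param object a `growth_field`.
#' @param ... unused.
#' @return A ggplot.
#' @method autoplot growth_field
#' @export
autoplot.growth_field <- function(object, ...) {
  d <- dplyr::summarise(
    dplyr::group_by(tibble::as_tibble(object), .data$time),
    q25 = stats::quantile(.data$rate, 0.25),
    median = stats::median(.data$rate),
    q75 = stats::quantile(.data$rate, 0.75), .groups = "drop")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$time, y = .data$median)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$q25, ymax = .data$q75),
                         alpha = 0.25) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (months)", y = "vertex growth rate (%/month)") +
    ggplot2::theme_minimal()
}

#' Histogram of correspondence scores
#'
#' @param map a `correspondence_map`.
#' @param bins histogram bins.
#' @return A ggplot.
#' @export
plot_score_distribution <- function(map, bins = 40) {
  ggplot2::ggplot(tibble::as_tibble(map), ggplot2::aes(x = .data$score)) +
    ggplot2::geom_histogram(bins = bins) +
    ggplot2::labs(x = "neighborhood correlation score", y = "vertices") +
    ggplot2::theme_minimal()
}
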