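#' Tracked edge lengths and normalized monthly changes
#'
#' For every edge (pair of adjacent vertices) of the first model, both
#' endpoints are followed through the chain of correspondence maps; the edge
#' length is recorded at every instance and the normalized monthly change
#' `g_i = 100 * (L(T_{i+1}) - L(T_i)) / L(T_i)` (%/month) is computed for
#' every interval. The change over an interval is assigned to the interval's
#' end instance. Negative changes (resorption) are allowed and propagate as
#' negative rates.
#'
#' @param series a [mesh_series()].
#' @param maps list of consecutive `correspondence_map`s (one per interval,
#'   `length(series) - 1` of them, mapping mesh i onto mesh i+1).
#' @param edges optional edge matrix; defaults to `mesh_edges()` of the first
#'   mesh.
#' @param drop_zero drop (with a warning) edges whose tracked length collapses
#'   to zero instead of failing. Useful when the series has no exact
#'   vertex-to-vertex correspondence, e.g. across independently decimated
#'   meshes in the vertex-count sensitivity scan; the default keeps the
#'   strict error.
#' @return An `edge_growth_series`: list with `edges` (E x 2), `tracked`
#'   (n x K vertex index paths), `lengths` (E x K, mm), `changes`
#'   (E x (K-1), %/month), `times`.
#' @export
edge_length_changes <- function(series, maps, edges = NULL,
                                drop_zero = FALSE) {
  K <- length(series)
  if (length(maps) != K - 1L) {
    stop("need one correspondence map per interval: ", K - 1L, " maps for ",
         K, " instances", call. = FALSE)
  }
  edges <- edges %||% mesh_edges(series$meshes[[1]])
  n <- n_vertices(series$meshes[[1]])
  ids <- matrix(NA_integer_, n, K)
  ids[, 1] <- seq_len(n)
  for (k in seq_len(K - 1L)) {
    mk <- maps[[k]]
    if (nrow(mk) < n) stop("map ", k, " covers fewer vertices than the series",
                           call. = FALSE)
    ids[, k + 1L] <- mk$target_index[ids[, k]]
  }
  E <- nrow(edges)
  lengths <- matrix(NA_real_, E, K)
  for (k in seq_len(K)) {
    vk <- series$meshes[[k]]$vertices
    pa <- vk[ids[edges[, 1], k], , drop = FALSE]
    pb <- vk[ids[edges[, 2], k], , drop = FALSE]
    lengths[, k] <- sqrt(rowSums((pa - pb)^2))
  }
  zero <- which(lengths == 0, arr.ind = TRUE)
  if (nrow(zero)) {
    if (!drop_zero) {
      e <- zero[1, 1]
      stop(sprintf("zero edge length for edge (%d, %d) at instance %d",
                   edges[e, 1], edges[e, 2], zero[1, 2]), call. = FALSE)
    }
    bad <- unique(zero[, 1])
    warning("dropping ", length(bad),
            " tracked edges with collapsed (zero) length", call. = FALSE)
    edges <- edges[-bad, , drop = FALSE]
    lengths <- lengths[-bad, , drop = FALSE]
  }
  changes <- 100 * (lengths[, -1L, drop = FALSE] - lengths[, -K, drop = FALSE]) /
    lengths[, -K, drop = FALSE]
  structure(list(edges = edges, tracked = ids, lengths = lengths,
                 changes = changes, times = series$times),
            class = "edge_growth_series")
}

#' @export
print.edge_growth_series <- function(x, ...) {
  cat("<edge_growth_series>", nrow(x$edges), "edges x", ncol(x$lengths),
      "instances; mean change",
      sprintf("%.3f %%/month\n", mean(x$changes)))
  invisible(x)
}

#' @method tidy edge_growth_series
#' @export
tidy.edge_growth_series <- function(x, ...) {
  K <- ncol(x$lengths)
  tibble::tibble(
    a = rep(x$edges[, 1], K), b = rep(x$edges[, 2], K),
    instance = rep(seq_len(K), each = nrow(x$edges)),
    time = rep(x$times, each = nrow(x$edges)),
    length = as.vector(x$lengths),
    change = as.vector(cbind(NA_real_, x$changes))
  )
}

#' Least-squares cubic spline of cumulative normalized change
#'
#' The per-interval normalized changes are accumulated into a cumulative
#' change curve `C(T_1) = 0, C(T_{i+1}) = C(T_i) + g_i` and a cubic spline is
#' fitted to `C` versus time (months). Rates are read off as the spline
#' gradient, so a constant monthly change `c` yields a linear `C` and a rate
#' of exactly `c` at every instance (any cubic basis reproduces a line
#' exactly in the least-squares sense).
#'
#' By default (`df = NULL` with enough instances) the fit is a least-squares
#' cubic B-spline regression with fewer coefficients than data points —
#' roughly one basis function per three instances — which averages
#' measurement noise across time instead of chasing it. With `df` set to the
#' number of instances, or with fewer than eight instances, or with
#' `df = NA`, the spline interpolates (Forsythe-Malcolm-Moler end conditions,
#' so cubic polynomial data are reproduced exactly at zero smoothing);
#' `smoothing > 0` instead fits a penalized smoothing spline with that
#' `lambda`.
#'
#' @param changes numeric vector of normalized monthly changes (%/month), one
#'   per interval (length = instances - 1, at least 3 so that at least 4
#'   cumulative points support a cubic).
#' @param times instance times in months (length = `length(changes) + 1`).
#' @param smoothing penalty parameter for the smoothing-spline variant;
#'   0 selects the `df`-based behavior.
#' @param df degrees of freedom of the least-squares regression spline
#'   (>= 4); `NULL` picks `max(4, ceiling(K/3) + 2)` capped below the
#'   instance count K (interpolation for short series); `NA` forces
#'   interpolation.
#' @return A `growth_curve` object; use [rate_at_instance()] for gradients.
#' @export
fit_growth_curve <- function(changes, times = seq_len(length(changes) + 1L),
                             smoothing = 0, df = NULL) {
  changes <- as.numeric(changes)
  times <- as.numeric(times)
  if (length(times) != length(changes) + 1L) {
    stop("times must have one more element than changes", call. = FALSE)
  }
  K <- length(times)
  if (K < 4L) {
    stop("cubic spline fitting needs at least 4 instances", call. = FALSE)
  }
  if (is.null(df)) {
    df <- if (K < 8L) NA_integer_ else max(4L, as.integer(ceiling(K / 3)) + 2L)
  }
  if (!is.na(df) && df < 4L) stop("df must be at least 4 (cubic)", call. = FALSE)
  cum <- c(0, cumsum(changes))
  if (smoothing > 0) {
    fit <- stats::smooth.spline(times, cum, lambda = smoothing,
                                all.knots = TRUE)
    fun <- function(t, deriv = 0) stats::predict(fit, t, deriv = deriv)$y
  } else if (is.na(df) || df >= K || K < 8L) {
    fun <- stats::splinefun(times, cum, method = "fmm")
  } else {
    fun <- ls_cubic_spline(times, cum, df)
  }
  structure(list(fun = fun, range = range(times), cumulative = cum,
                 times = times, smoothing = smoothing, df = df),
            class = "growth_curve")
}

# least-squares cubic B-spline regression: df basis functions, interior
# knots at quantiles of the observation times
ls_cubic_spline <- function(x, y, df) {
  n_interior <- df - 4L
  interior <- if (n_interior > 0L) {
    stats::quantile(x, probs = seq_len(n_interior) / (n_interior + 1L),
                    names = FALSE)
  } else {
    numeric(0)
  }
  knots <- c(rep(min(x), 4L), interior, rep(max(x), 4L))
  B <- splines::splineDesign(knots, x, ord = 4L)
  coefs <- qr.coef(qr(B), y)
  function(t, deriv = 0) {
    as.numeric(splines::splineDesign(knots, t, ord = 4L,
                                     derivs = rep(deriv, length(t))) %*% coefs)
  }
}

#' @export
print.growth_curve <- function(x, ...) {
  cat("<growth_curve> cubic spline over", length(x$times), "instances,",
      "smoothing", x$smoothing, "\n")
  invisible(x)
}

#' Instantaneous rate from a fitted growth curve
#'
#' First derivative of the fitted cumulative-change spline, in %/month.
#' Evaluation outside the fitted time range is refused (no extrapolation).
#'
#' @param curve a `growth_curve` from [fit_growth_curve()].
#' @param t time(s) in months, within the fitted range.
#' @return Rate(s) in %/month.
#' @export
rate_at_instance <- function(curve, t) {
  stopifnot(inherits(curve, "growth_curve"))
  if (any(t < curve$range[1] - 1e-9 | t > curve$range[2] + 1e-9)) {
    stop("rate requested outside the fitted range [", curve$range[1], ", ",
         curve$range[2], "]: no extrapolation", call. = FALSE)
  }
  curve$fun(t, deriv = 1L)
}

#' Spline-smoothed rates for every tracked edge
#'
#' Fits [fit_growth_curve()] per edge and evaluates the gradient at every
#' instance time.
#'
#' @param egs an `edge_growth_series` from [edge_length_changes()].
#' @param smoothing,df passed to [fit_growth_curve()].
#' @return E x K matrix of rates (%/month).
#' @export
edge_rates <- function(egs, smoothing = 0, df = NULL) {
  K <- ncol(egs$lengths)
  out <- matrix(NA_real_, nrow(egs$edges), K)
  for (e in seq_len(nrow(egs$edges))) {
    curve <- fit_growth_curve(egs$changes[e, ], egs$times, smoothing, df)
    out[e, ] <- rate_at_instance(curve, egs$times)
  }
  out
}

# mean over incident edges, per vertex: returns n x K
average_over_incident_edges <- function(edge_values, edges, n) {
  deg <- tabulate(c(edges[, 1], edges[, 2]), nbins = n)
  if (any(deg == 0L)) {
    stop("isolated vertices (no incident edge): ",
         paste(utils::head(which(deg == 0L), 5), collapse = ", "), call. = FALSE)
  }
  sums <- rowsum(rbind(edge_values, edge_values), c(edges[, 1], edges[, 2]))
  out <- matrix(0, n, ncol(sums))
  out[as.integer(rownames(sums)), ] <- sums
  out / deg
}

#' Per-vertex rates from incident edge rates
#'
#' The rate of a vertex at an instance is the unweighted mean of the rates of
#' all edges incident to it.
#'
#' @param rates E x K matrix of edge rates from [edge_rates()].
#' @param edges E x 2 edge matrix.
#' @param n number of vertices.
#' @return n x K matrix of vertex rates (%/month).
#' @export
vertex_rates <- function(rates, edges, n) {
  average_over_incident_edges(rates, edges, n)
}

#' Decompose edge rates into anatomical direction components
#'
#' Each edge's rate `g` is split over the anatomical axes by squared
#' direction cosines: the component along axis `a` is `g * (u . a)^2`, where
#' `u` is the unit edge direction expressed at the given instance. Because
#' the axes are orthonormal the three components sum to `g` exactly, so the
#' decomposition conserves the total rate both per edge and per vertex.
#'
#' @param rates E x K edge rate matrix.
#' @param egs the `edge_growth_series` (for tracked endpoint positions).
#' @param series the [mesh_series()].
#' @param frame an [anatomical_frame()]; identity axes by default.
#' @return List of three E x K matrices `ap`, `si`, `ml`.
#' @export
directional_decompose <- function(rates, egs, series, frame = NULL) {
  frame <- frame %||% anatomical_frame()
  K <- ncol(rates)
  E <- nrow(egs$edges)
  ap <- si <- ml <- matrix(NA_real_, E, K)
  for (k in seq_len(K)) {
    vk <- series$meshes[[k]]$vertices
    pa <- vk[egs$tracked[egs$edges[, 1], k], , drop = FALSE]
    pb <- vk[egs$tracked[egs$edges[, 2], k], , drop = FALSE]
    u <- pb - pa
    len <- sqrt(rowSums(u^2))
    if (any(len == 0)) {
      stop("degenerate zero-length edge direction at instance ", k, call. = FALSE)
    }
    u <- u / len
    ap[, k] <- rates[, k] * (u %*% frame$ap)^2
    si[, k] <- rates[, k] * (u %*% frame$si)^2
    ml[, k] <- rates[, k] * (u %*% frame$ml)^2
  }
  list(ap = ap, si = si, ml = ml)
}

#' Per-vertex growth field of a mesh series
#'
#' End-to-end growth computation: tracked edge lengths
#' ([edge_length_changes()]), per-edge cumulative-change splines
#' ([fit_growth_curve()]), gradient rates at every instance, per-vertex
#' averaging over incident edges and directional decomposition in an
#' anatomical frame.
#'
#' @param series a [mesh_series()].
#' @param maps list of consecutive `correspondence_map`s.
#' @param frame optional [anatomical_frame()] for the A/P, S/I, M/L
#'   components; identity axes by default.
#' @param smoothing,df spline parameters, see [fit_growth_curve()].
#' @param edges optional edge set; defaults to the first mesh's edges.
#' @param drop_zero see [edge_length_changes()].
#' @return A `growth_field` tibble with columns `vertex_index`, `instance`,
#'   `time`, `rate`, `ap`, `si`, `ml` (all rates in %/month).
#' @export
growth_field <- function(series, maps, frame = NULL, smoothing = 0,
                         df = NULL, edges = NULL, drop_zero = FALSE) {
  egs <- edge_length_changes(series, maps, edges, drop_zero = drop_zero)
  er <- edge_rates(egs, smoothing, df)
  n <- n_vertices(series$meshes[[1]])
  vr <- vertex_rates(er, egs$edges, n)
  comp <- directional_decompose(er, egs, series, frame)
  vap <- average_over_incident_edges(comp$ap, egs$edges, n)
  vsi <- average_over_incident_edges(comp$si, egs$edges, n)
  vml <- average_over_incident_edges(comp$ml, egs$edges, n)
  K <- ncol(vr)
  out <- tibble::tibble(
    vertex_index = rep(seq_len(n), K),
    instance = rep(seq_len(K), each = n),
    time = rep(egs$times, each = n),
    rate = as.vector(vr),
    ap = as.vector(vap),
    si = as.vector(vsi),
    ml = as.vector(vml)
  )
  structure(out, class = c("growth_field", class(out)),
            n_vertices = n, times = egs$times)
}

#' @export
print.growth_field <- function(x, ...) {
  cat("<growth_field>", attr(x, "n_vertices"), "vertices x",
      length(attr(x, "times")), "instances\n")
  NextMethod()
}

#' Write a growth field to CSV
#'
#' @param field a `growth_field`.
#' @param path CSV path.
#' @return `path`, invisibly.
#' @export
write_growth_field <- function(field, path) {
  readr::write_csv(tibble::as_tibble(field), path)
  invisible(path)
}
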