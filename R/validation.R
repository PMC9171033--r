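#' Propagate landmarks through a correspondence chain
#'
#' Each landmark is snapped to its nearest vertex on the first mesh (the snap
#' distance is recorded; a warning is raised when it exceeds 3 x mean edge
#' length) and then follows that vertex through the consecutive
#' correspondence maps: the landmark position at instance k is the position
#' of the propagated vertex on mesh k.
#'
#' @param landmarks a [landmark_set()] located on/near the first mesh.
#' @param series a [mesh_series()].
#' @param maps list of consecutive `correspondence_map`s (one per interval).
#' @return A tibble with columns `name`, `instance`, `time`, `x`, `y`, `z`,
#'   `vertex_index`, and attribute `snap_distances`.
#' @export
propagate_landmarks <- function(landmarks, series, maps) {
  K <- length(series)
  if (length(maps) != K - 1L) {
    stop("need one correspondence map per interval", call. = FALSE)
  }
  m1 <- series$meshes[[1]]
  lm_xyz <- as.matrix(landmarks[, c("x", "y", "z")])
  nn <- nearest_indices(lm_xyz, m1$vertices)
  snap <- sqrt(rowSums((lm_xyz - m1$vertices[nn, , drop = FALSE])^2))
  lim <- 3 * mean_edge_length(m1)
  if (any(snap > lim)) {
    warning("landmarks snapped from more than 3 x mean edge length away: ",
            paste(landmarks$name[snap > lim], collapse = ", "), call. = FALSE)
  }
  ids <- matrix(NA_integer_, length(nn), K)
  ids[, 1] <- nn
  for (k in seq_len(K - 1L)) ids[, k + 1L] <- maps[[k]]$target_index[ids[, k]]
  out <- purrr::map_dfr(seq_len(K), function(k) {
    vk <- series$meshes[[k]]$vertices[ids[, k], , drop = FALSE]
    tibble::tibble(name = landmarks$name, instance = k, time = series$times[k],
                   x = vk[, 1], y = vk[, 2], z = vk[, 3],
                   vertex_index = ids[, k])
  })
  attr(out, "snap_distances") <- stats::setNames(snap, landmarks$name)
  out
}

#' RMSE of landmark positions against a gold standard
#'
#' For every landmark and instance, the root mean square of the Euclidean
#' position errors over the replicate axis (the study's subjects). Estimated
#' and gold tables must carry matching `name`, `instance` and `replicate`
#' keys.
#'
#' @param estimated,gold tibbles with columns `name`, `instance`,
#'   `replicate`, `x`, `y`, `z`. A `replicate` column is added (single
#'   replicate) if absent.
#' @return A tibble `name`, `instance`, `rmse` (mm), `n_replicates`.
#' @export
position_rmse <- function(estimated, gold) {
  estimated <- ensure_replicate(estimated)
  gold <- ensure_replicate(gold)
  joined <- dplyr::inner_join(estimated, gold,
                              by = c("name", "instance", "replicate"),
                              suffix = c("", "_gold"))
  if (nrow(joined) != nrow(estimated) || nrow(joined) != nrow(gold)) {
    stop("estimated and gold landmark tables do not match on name/instance/replicate",
         call. = FALSE)
  }
  joined$err2 <- (joined$x - joined$x_gold)^2 + (joined$y - joined$y_gold)^2 +
    (joined$z - joined$z_gold)^2
  dplyr::summarise(dplyr::group_by(joined, .data$name, .data$instance),
                   rmse = sqrt(mean(.data$err2)),
                   n_replicates = dplyr::n(), .groups = "drop")
}

ensure_replicate <- function(tbl) {
  if (!"replicate" %in% names(tbl)) tbl$replicate <- 1L
  tbl
}

#' Inter-landmark distances per instance and replicate
#'
#' @param landmarks tibble with `name`, `instance`, `x`, `y`, `z` and
#'   optionally `replicate`.
#' @param pairs 2-column character matrix (or data frame) of landmark name
#'   pairs.
#' @return Tibble `pair`, `instance`, `replicate`, `distance` (mm).
#' @export
inter_landmark_distances <- function(landmarks, pairs) {
  landmarks <- ensure_replicate(landmarks)
  pairs <- as.matrix(pairs)
  purrr::map_dfr(seq_len(nrow(pairs)), function(k) {
    a <- landmarks[landmarks$name == pairs[k, 1], ]
    b <- landmarks[landmarks$name == pairs[k, 2], ]
    j <- dplyr::inner_join(a, b, by = c("instance", "replicate"),
                           suffix = c("_a", "_b"))
    if (nrow(j) == 0L) {
      stop("no matching instances for pair ", pairs[k, 1], "-", pairs[k, 2],
           call. = FALSE)
    }
    tibble::tibble(pair = paste0(pairs[k, 1], "-", pairs[k, 2]),
                   instance = j$instance, replicate = j$replicate,
                   distance = sqrt((j$x_a - j$x_b)^2 + (j$y_a - j$y_b)^2 +
                                     (j$z_a - j$z_b)^2))
  })
}

#' Normalized monthly change rates of inter-landmark distances
#'
#' `rate_i = 100 * (D(T_{i+1}) - D(T_i)) / D(T_i)` %/month; the interval is
#' labeled by its end instance.
#'
#' @param distances tibble from [inter_landmark_distances()].
#' @return Tibble `pair`, `interval_end`, `replicate`, `rate`.
#' @export
distance_change_rates <- function(distances) {
  distances <- dplyr::arrange(distances, .data$pair, .data$replicate,
                              .data$instance)
  if (any(distances$distance == 0)) {
    stop("zero inter-landmark distance: rate undefined", call. = FALSE)
  }
  dplyr::ungroup(dplyr::mutate(
    dplyr::group_by(distances, .data$pair, .data$replicate),
    rate = 100 * (.data$distance - dplyr::lag(.data$distance)) /
      dplyr::lag(.data$distance),
    interval_end = .data$instance
  ))[, c("pair", "interval_end", "replicate", "rate")] |>
    dplyr::filter(!is.na(.data$rate))
}

#' RMSE of inter-landmark rate changes against a gold standard
#'
#' Rates are computed for both distance tables with
#' [distance_change_rates()]; the RMSE of (estimated - gold) is taken per
#' pair per interval over replicates.
#'
#' @param estimated,gold distance tibbles from [inter_landmark_distances()].
#' @return Tibble `pair`, `interval_end`, `rmse` (%/month), `n_replicates`.
#' @export
rate_rmse <- function(estimated, gold) {
  if (any(gold$distance == 0)) stop("zero gold distance: rate undefined",
                                    call. = FALSE)
  re <- distance_change_rates(estimated)
  rg <- distance_change_rates(gold)
  j <- dplyr::inner_join(re, rg, by = c("pair", "interval_end", "replicate"),
                         suffix = c("", "_gold"))
  if (nrow(j) != nrow(re)) {
    stop("estimated and gold rate tables do not match on pair/interval/replicate",
         call. = FALSE)
  }
  dplyr::summarise(dplyr::group_by(j, .data$pair, .data$interval_end),
                   rmse = sqrt(mean((.data$rate - .data$rate_gold)^2)),
                   n_replicates = dplyr::n(), .groups = "drop")
}

#' Paper-style wide RMSE tables
#'
#' Reshapes an RMSE slice into a wide table: one row per landmark (or pair),
#' one column per instance (or interval), plus `Mean` and `SD` columns over
#' the row and `Mean`/`SD` rows over the columns.
#'
#' @param slice output of [position_rmse()] or [rate_rmse()].
#' @return A wide tibble.
#' @export
rmse_table <- function(slice) {
  key <- if ("name" %in% names(slice)) "name" else "pair"
  col <- if ("instance" %in% names(slice)) "instance" else "interval_end"
  wide <- tidyr::pivot_wider(slice[, c(key, col, "rmse")],
                             names_from = dplyr::all_of(col),
                             values_from = "rmse", names_prefix = "T")
  vals <- as.matrix(wide[, -1])
  wide$Mean <- rowMeans(vals)
  wide$SD <- apply(vals, 1L, stats::sd)
  bottom <- tibble::tibble(!!key := c("Mean", "SD"))
  for (cn in colnames(vals)) {
    bottom[[cn]] <- c(mean(vals[, cn]), stats::sd(vals[, cn]))
  }
  bottom$Mean <- NA_real_
  bottom$SD <- NA_real_
  dplyr::bind_rows(wide, bottom)
}

#' Vertex-count sensitivity scan
#'
#' Runs the full correspondence + growth pipeline at `start_n` vertices, then
#' repeatedly decimates the whole series by a fixed fraction of `start_n` and
#' compares the per-region mean percent changes (region x instance) against
#' the `start_n` reference with a paired two-sided test. The scan stops at
#' the first significant difference and returns the previous (second-to-last)
#' vertex count, together with the full trace.
#'
#' Region labels are transferred to each decimated mesh by nearest-vertex
#' lookup on the first full-resolution mesh.
#'
#' @param series a [mesh_series()].
#' @param labels [region_labels()] for the first mesh of `series`.
#' @param start_n initial vertex count (meshes are decimated to it if
#'   larger).
#' @param decrement_fraction fraction of `start_n` removed per step
#'   (default 0.05).
#' @param alpha significance level of the paired test.
#' @param test `"t"` (paired t-test, default) or `"wilcoxon"` (paired
#'   Wilcoxon signed-rank).
#' @param min_n floor vertex count for the scan.
#' @param params correspondence parameters, see [correspondence_params()].
#' @param smoothing spline smoothing for [growth_field()].
#' @return A list: `chosen_n`, and `trace` (tibble with `n_vertices`,
#'   `p_value`, `max_abs_diff`, `significant`).
#' @export
vertex_count_sensitivity <- function(series, labels, start_n,
                                     decrement_fraction = 0.05,
                                     alpha = 0.05, test = c("t", "wilcoxon"),
                                     min_n = NULL,
                                     params = correspondence_params(),
                                     smoothing = 0) {
  test <- match.arg(test)
  stopifnot(decrement_fraction > 0, decrement_fraction < 1)
  n0 <- n_vertices(series$meshes[[1]])
  if (start_n > n0) stop("start_n exceeds the series vertex count", call. = FALSE)
  step <- max(1L, as.integer(round(decrement_fraction * start_n)))
  min_n <- min_n %||% max(4L, as.integer(round(0.5 * start_n)))
  counts <- seq(start_n, min_n, by = -step)
  if (length(counts) < 2L) stop("no decrement steps between start_n and min_n",
                                call. = FALSE)

  ref_mesh <- series$meshes[[1]]
  run_at <- function(count) {
    ms <- lapply(series$meshes, function(m) {
      if (n_vertices(m) > count) decimate(m, count) else m
    })
    s <- mesh_series(ms, series$times)
    maps <- lapply(seq_len(length(s) - 1L), function(k) {
      build_correspondence(s$meshes[[k]], s$meshes[[k + 1]], params)
    })
    fld <- suppressWarnings(growth_field(s, maps, smoothing = smoothing,
                                         drop_zero = TRUE))
    lab_k <- region_labels(labels$label[nearest_indices(ms[[1]]$vertices,
                                                        ref_mesh$vertices)])
    rs <- region_summary(fld, lab_k)
    rs <- rs[rs$direction == "total" & rs$instance > 1L, ]
    stats::setNames(rs$mean, paste(rs$region, rs$instance))
  }

  ref <- run_at(counts[1])
  trace <- tibble::tibble(n_vertices = counts[1], p_value = NA_real_,
                          max_abs_diff = 0, significant = FALSE)
  chosen <- counts[1]
  for (k in seq_along(counts)[-1]) {
    cur <- run_at(counts[k])
    cur <- cur[names(ref)]
    p <- if (test == "t") {
      stats::t.test(cur, ref, paired = TRUE)$p.value
    } else {
      stats::wilcox.test(cur, ref, paired = TRUE, exact = FALSE)$p.value
    }
    sig <- is.finite(p) && p < alpha
    trace <- dplyr::bind_rows(trace, tibble::tibble(
      n_vertices = counts[k], p_value = p,
      max_abs_diff = max(abs(cur - ref)), significant = sig))
    if (sig) {
      if (k == 2L) {
        warning("significant difference at the first decrement step; ",
                "returning start_n", call. = FALSE)
        chosen <- counts[1]
      } else {
        chosen <- counts[k - 1L]
      }
      return(list(chosen_n = chosen, trace = trace))
    }
    chosen <- counts[k]
  }
  list(chosen_n = chosen, trace = trace)
}
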