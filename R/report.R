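#' Reference validation and growth-rate tables
#'
#' Tables transcribed from a published 12-month CBCT monitoring study of
#' growing minipig mandibles (n = 8 subjects, 17 landmarks, 653-vertex
#' models), distributed with the package as long-format fixtures:
#'
#' * `ref_position_rmse()`: per-landmark, per-instance RMSE (mm) of
#'   propagated landmark positions against the gold standard.
#' * `ref_rate_rmse()`: per landmark pair, per interval RMSE (%/month) of
#'   inter-landmark distance change rates against the gold standard.
#' * `ref_region_rates()`: per region, direction and interval mean growth
#'   rates (%/month) over the six mandibular regions.
#'
#' These let the reporting and summary machinery be exercised against real
#' published magnitudes without any data download.
#'
#' @return A tibble in long format (`landmark`/`pair`/`region` keys plus
#'   `instance` or `interval` and `value`).
#' @export
ref_position_rmse <- function() {
  tbl <- readr::read_csv(ref_path("reference_landmark_position_rmse.csv"),
                         show_col_types = FALSE)
  long <- tidyr::pivot_longer(tbl, -"landmark", names_to = "instance",
                              values_to = "rmse")
  long$instance <- as.integer(sub("^T", "", long$instance))
  long
}

#' @rdname ref_position_rmse
#' @export
ref_rate_rmse <- function() {
  tbl <- readr::read_csv(ref_path("reference_interlandmark_rate_rmse.csv"),
                         show_col_types = FALSE)
  long <- tidyr::pivot_longer(tbl, -"pair", names_to = "interval",
                              values_to = "rmse")
  long$interval_end <- as.integer(sub("^T\\d+-T", "", long$interval))
  long
}

#' @rdname ref_position_rmse
#' @export
ref_region_rates <- function() {
  tbl <- readr::read_csv(ref_path("reference_region_growth_rates.csv"),
                         show_col_types = FALSE)
  long <- tidyr::pivot_longer(tbl, -c("region", "direction"),
                              names_to = "interval", values_to = "rate")
  long$interval_end <- as.integer(sub("^T\\d+-T", "", long$interval))
  long
}

ref_path <- function(file) {
  p <- system.file("extdata", file, package = "osteomap")
  if (p == "") stop("reference table not found: ", file, call. = FALSE)
  p
}

#' Ensemble mean and SD of per-interval values
#'
#' The ensemble statistics used in the regional growth-rate reports: the
#' unweighted mean of the per-interval values and their standard deviation.
#'
#' @param values numeric vector of per-interval values.
#' @return Named numeric vector `c(mean =, sd =)`.
#' @export
ensemble_stats <- function(values) {
  c(mean = mean(values), sd = stats::sd(values))
}

#' Write a region summary as a wide report table
#'
#' Rows are region x direction; columns are the intervals (labeled
#' `T1-T2` ... by end instance) plus the ensemble mean (unweighted mean of
#' the interval means) and ensemble SD (SD of the interval means).
#'
#' @param summary a `region_summary` from [region_summary()].
#' @param path optional CSV path; when given the table is also written there.
#' @return The wide tibble, invisibly when `path` is given.
#' @export
write_region_table <- function(summary, path = NULL) {
  tbl <- tibble::as_tibble(summary)
  tbl <- tbl[tbl$instance > 1L, ]                 # changes start at interval 1
  tbl$interval <- paste0("T", tbl$instance - 1L, "-T", tbl$instance)
  wide <- tidyr::pivot_wider(tbl[, c("region", "direction", "interval", "mean")],
                             names_from = "interval", values_from = "mean")
  vals <- as.matrix(wide[, -(1:2)])
  wide$ensemble_mean <- rowMeans(vals)
  wide$ensemble_sd <- apply(vals, 1L, stats::sd)
  if (!is.null(path)) {
    readr::write_csv(wide, path)
    return(invisible(wide))
  }
  wide
}

#' Export a mesh with a growth-rate color map
#'
#' Rates are clamped to `range`, mapped linearly onto the palette and written
#' to PLY as per-vertex colors, alongside the raw rate as the scalar
#' `quality` channel. Keeping `range` fixed across instances makes the
#' monthly color maps comparable.
#'
#' @param mesh a [tri_mesh()].
#' @param rates numeric per-vertex rates (%/month), length `n_vertices(mesh)`.
#' @param path output PLY path.
#' @param range length-2 numeric, color range in %/month (`min < max`).
#' @param palette character vector of colors interpolated linearly; default a
#'   blue-to-red ramp.
#' @return `path`, invisibly.
#' @export
export_colormap_mesh <- function(mesh, rates, path, range = c(0, 2),
                                 palette = c("#2166AC", "#F7F7F7", "#B2182B")) {
  if (length(rates) != n_vertices(mesh)) {
    stop("rates must have one value per vertex", call. = FALSE)
  }
  if (any(is.na(rates))) {
    stop("NaN/NA rates at vertices: ",
         paste(utils::head(which(is.na(rates)), 10), collapse = ", "),
         call. = FALSE)
  }
  if (!all(is.finite(range)) || range[1] >= range[2]) {
    stop("range must be finite with min < max", call. = FALSE)
  }
  clamped <- pmin(range[2], pmax(range[1], rates))
  s <- (clamped - range[1]) / (range[2] - range[1])
  cols <- grDevices::colorRamp(palette)(s)
  write_mesh(mesh, path, format = "ply", per_vertex_scalars = rates,
             per_vertex_colors = round(cols))
  invisible(path)
}

#' Pipeline configuration
#'
#' Bundles the inputs and parameters of [run_pipeline()]. Paths must exist;
#' numeric parameters must be positive where applicable.
#'
#' @param mesh_paths character vector of mesh files, time-ordered (>= 2).
#' @param times instance times in months; defaults to 1..K.
#' @param landmarks_path optional landmark CSV (columns name,x,y,z).
#' @param labels_path optional region-label CSV (vertex_index,label).
#' @param gold_landmarks_path optional gold-standard landmark tracks CSV
#'   (name,instance,x,y,z) for validation.
#' @param r,rho correspondence radii (mm); `NULL` = scale-aware defaults.
#' @param smoothing spline smoothing parameter (>= 0).
#' @param thickness_cutoff ray-casting cutoff (mm).
#' @param colormap_range fixed color range in %/month.
#' @param out_dir output directory (created if missing).
#' @param seed integer seed recorded in the run metadata (the pipeline itself
#'   is deterministic).
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(mesh_paths, times = NULL, landmarks_path = NULL,
                            labels_path = NULL, gold_landmarks_path = NULL,
                            r = NULL, rho = NULL, smoothing = 0,
                            thickness_cutoff = 30, colormap_range = c(0, 2),
                            out_dir = "osteomap_out", seed = 1L) {
  if (length(mesh_paths) < 2L) stop("need at least 2 mesh paths", call. = FALSE)
  for (p in c(mesh_paths, landmarks_path, labels_path, gold_landmarks_path)) {
    if (!is.null(p) && !file.exists(p)) stop("missing input: ", p, call. = FALSE)
  }
  stopifnot(smoothing >= 0, thickness_cutoff > 0)
  if (!is.null(r)) stopifnot(r > 0)
  if (!is.null(rho)) stopifnot(rho > 0)
  structure(list(mesh_paths = mesh_paths, times = times,
                 landmarks_path = landmarks_path, labels_path = labels_path,
                 gold_landmarks_path = gold_landmarks_path, r = r, rho = rho,
                 smoothing = smoothing, thickness_cutoff = thickness_cutoff,
                 colormap_range = colormap_range, out_dir = out_dir,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Run the full growth-mapping pipeline
#'
#' Reads the mesh series, builds consecutive correspondences, computes the
#' growth field (with anatomical directions when landmarks are supplied),
#' summarises regions when labels are supplied, validates propagated
#' landmarks against a gold standard when one is supplied, and writes CSV
#' maps, color-mapped PLY models, a run-metadata JSON and a plain-text log to
#' the output directory. Deterministic: identical inputs and configuration
#' produce identical outputs.
#'
#' @param config a [pipeline_config()].
#' @param verbose print stage progress.
#' @return Invisibly, a list with the computed objects (`series`, `maps`,
#'   `field`, `summary`, `validation`) and the written file paths
#'   (`artifacts`).
#' @export
run_pipeline <- function(config, verbose = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  say <- function(...) if (verbose) message(...)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_lines <- c(sprintf("osteomap run, seed %d", config$seed))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  say("reading ", length(config$mesh_paths), " meshes")
  meshes <- stage("read", lapply(seq_along(config$mesh_paths), function(i) {
    m <- read_mesh(config$mesh_paths[i])
    m$instance_label <- paste0("T", i)
    m
  }))
  series <- mesh_series(meshes, config$times %||% seq_along(meshes))

  landmarks <- if (!is.null(config$landmarks_path)) {
    stage("landmarks", read_landmarks(config$landmarks_path))
  }
  labels <- if (!is.null(config$labels_path)) {
    stage("labels", read_region_labels(config$labels_path))
  }
  frame <- if (!is.null(landmarks)) stage("frame", build_frame(landmarks))

  say("building correspondences")
  params <- correspondence_params(r = config$r, rho = config$rho)
  maps <- stage("correspond", lapply(seq_len(length(series) - 1L), function(k) {
    build_correspondence(series$meshes[[k]], series$meshes[[k + 1L]], params)
  }))
  scores <- unlist(lapply(maps, function(m) m$score))
  log_lines <- c(log_lines,
                 sprintf("correspondence: %d pairs, score median %.4f min %.4f",
                         length(maps), stats::median(scores), min(scores)))

  say("computing growth field")
  field <- stage("growth", growth_field(series, maps, frame = frame,
                                        smoothing = config$smoothing))
  artifacts <- character()
  for (k in seq_along(maps)) {
    p <- file.path(config$out_dir, sprintf("correspondence_T%d_T%d.csv", k, k + 1L))
    write_correspondence(maps[[k]], p)
    artifacts <- c(artifacts, p)
  }
  p <- file.path(config$out_dir, "growth_field.csv")
  write_growth_field(field, p)
  artifacts <- c(artifacts, p)

  summary <- NULL
  if (!is.null(labels)) {
    say("summarising regions")
    summary <- stage("regions", region_summary(field, labels))
    p <- file.path(config$out_dir, "region_rates.csv")
    write_region_table(summary, p)
    artifacts <- c(artifacts, p)
  }

  validation <- NULL
  if (!is.null(landmarks) && !is.null(config$gold_landmarks_path)) {
    say("validating against gold standard")
    gold <- readr::read_csv(config$gold_landmarks_path, show_col_types = FALSE)
    est <- stage("validate", propagate_landmarks(landmarks, series, maps))
    validation <- position_rmse(est, gold)
    p <- file.path(config$out_dir, "position_rmse.csv")
    readr::write_csv(rmse_table(validation), p)
    artifacts <- c(artifacts, p)
  }

  say("exporting color maps")
  for (k in seq_len(length(series))) {
    rates_k <- field$rate[field$instance == k]
    p <- file.path(config$out_dir, sprintf("rates_T%d.ply", k))
    export_colormap_mesh(series$meshes[[k]], rates_k, p,
                         range = config$colormap_range)
    artifacts <- c(artifacts, p)
  }

  meta <- list(seed = config$seed, n_instances = length(series),
               n_vertices = n_vertices(series$meshes[[1]]),
               smoothing = config$smoothing,
               r = attr(maps[[1]], "r"), rho = attr(maps[[1]], "rho"),
               score_median = stats::median(scores), score_min = min(scores))
  p <- file.path(config$out_dir, "run_metadata.json")
  jsonlite::write_json(meta, p, auto_unbox = TRUE, digits = NA)
  artifacts <- c(artifacts, p)
  writeLines(c(log_lines, paste("artifacts:", length(artifacts))),
             file.path(config$out_dir, "run.log"))

  invisible(list(series = series, maps = maps, field = field,
                 summary = summary, validation = validation,
                 artifacts = artifacts))
}
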