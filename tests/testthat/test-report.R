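test_that("reference region-rate table reproduces the published summary rates", {
  rr <- ref_region_rates()

  ens <- function(region, direction) {
    ensemble_stats(rr$rate[rr$region == region & rr$direction == direction])[["mean"]]
  }
  # ensemble means over the 11 intervals, printed to two decimals
  expect_lt(abs(ens("posterior_ramus", "ap") - 0.75), 0.0051)
  expect_lt(abs(ens("posterior_ramus", "si") - 0.62), 0.0051)
  expect_lt(abs(ens("posterior_ramus", "ml") - 0.53), 0.0051)
  expect_lt(abs(ens("middle_corpus", "ap") - 0.39), 0.0051)
  expect_lt(abs(ens("anterior_corpus", "ap") - 0.53), 0.0051)

  # early growth period (first four intervals) of the condyle
  early <- function(direction) {
    v <- rr[rr$region == "condyle" & rr$direction == direction &
              rr$interval_end <= 5L, ]
    mean(v$rate)
  }
  expect_lt(abs(early("ap") - 1.19), 0.0051)
  expect_lt(abs(early("si") - 1.03), 0.0076)
  expect_lt(abs(early("ml") - 0.85), 0.0051)

  # the condyle leads every region in the A/P ensemble
  ap_ens <- vapply(unique(rr$region), ens, numeric(1), direction = "ap")
  expect_equal(names(which.max(ap_ens)), "condyle")
})

test_that("reference RMSE tables reproduce the published bounds", {
  pos <- ref_position_rmse()
  col_means <- tapply(pos$rmse, pos$instance, mean)
  expect_lt(abs(min(col_means) - 0.17), 0.0051)
  expect_lt(abs(max(col_means) - 0.66), 0.0051)
  expect_equal(max(pos$rmse), 0.86, tolerance = 1e-9)
  expect_lte(max(col_means[as.character(1:8)]), 0.29 + 0.005)

  rate <- ref_rate_rmse()
  rate_means <- tapply(rate$rmse, rate$interval_end, mean)
  expect_lte(max(rate_means[as.character(2:8)]), 0.06 + 0.005)
  expect_lte(max(rate_means[as.character(9:12)]), 0.08 + 0.005)
})

test_that("region tables carry interval columns and ensemble statistics", {
  tpl <- small_template()
  sc <- growth_scenario(n_instances = 5L, noise_sd = 0)
  tf <- ground_truth_rates(sc, tpl)
  rs <- region_summary(tf, tpl$labels)
  tbl <- write_region_table(rs)
  expect_true(all(c("T1-T2", "T4-T5", "ensemble_mean", "ensemble_sd") %in%
                    names(tbl)))
  # constant-rate region: ensemble mean is that constant, SD 0
  row <- tbl[tbl$region == "middle_corpus" & tbl$direction == "total", ]
  expect_equal(row$ensemble_mean, 0.4, tolerance = 1e-6)
  expect_equal(row$ensemble_sd, 0, tolerance = 1e-6)

  f <- tempfile(fileext = ".csv")
  write_region_table(rs, f)
  expect_true(file.exists(f))
})

test_that("color-map export clamps, colors and rejects bad input", {
  m <- tetrahedron_mesh()
  f <- tempfile(fileext = ".ply")
  export_colormap_mesh(m, c(-1, 0, 1, 5), f, range = c(0, 2))
  txt <- readLines(f)
  expect_true(any(grepl("property uchar red", txt)))
  # vertex records: x y z quality r g b; clamped ends share the extreme colors
  vrec <- read.table(text = txt[(which(txt == "end_header") + 1):
                                  (which(txt == "end_header") + 4)])
  expect_equal(as.numeric(vrec[1, 5:7]), as.numeric(vrec[2, 5:7]))  # -1 clamps to 0
  expect_equal(vrec[4, 5], 178)  # above max: clamped to the last palette color

  expect_error(export_colormap_mesh(m, c(NA, 0, 1, 2), f), "NaN|NA")
  expect_error(export_colormap_mesh(m, 1:3, f), "per vertex")
  expect_error(export_colormap_mesh(m, 1:4, f, range = c(2, 2)), "min < max")
})

test_that("run_pipeline produces deterministic artifacts end to end", {
  tpl <- small_template()
  sc <- growth_scenario(n_instances = 4L, noise_sd = 0.05, seed = 3L)
  gs <- grow_series(tpl, sc)
  dir <- tempfile()
  dir.create(dir)
  paths <- vapply(seq_len(4L), function(k) {
    p <- file.path(dir, sprintf("T%d.ply", k))
    write_mesh(gs$series$meshes[[k]], p)
    p
  }, character(1))
  lm_path <- file.path(dir, "landmarks.csv")
  write_landmarks(gs$landmarks, lm_path)
  lab_path <- file.path(dir, "labels.csv")
  write_region_labels(gs$labels, lab_path)
  gold_path <- file.path(dir, "gold.csv")
  readr::write_csv(gs$gold_landmarks, gold_path)

  config <- pipeline_config(mesh_paths = paths, landmarks_path = lm_path,
                            labels_path = lab_path,
                            gold_landmarks_path = gold_path,
                            out_dir = file.path(dir, "out"))
  res <- run_pipeline(config)
  expect_true(all(file.exists(res$artifacts)))
  expect_s3_class(res$field, "growth_field")
  expect_s3_class(res$summary, "region_summary")
  expect_true(all(res$validation$rmse >= 0))

  # rerun into a second directory: byte-identical CSV outputs
  config2 <- pipeline_config(mesh_paths = paths, landmarks_path = lm_path,
                             labels_path = lab_path,
                             gold_landmarks_path = gold_path,
                             out_dir = file.path(dir, "out2"))
  res2 <- run_pipeline(config2)
  for (a in res$artifacts[grepl("\\.csv$", res$artifacts)]) {
    b <- file.path(dirname(res2$artifacts[1]), basename(a))
    expect_identical(readLines(a), readLines(b))
  }

  expect_error(pipeline_config(mesh_paths = paths,
                               labels_path = "no/such/file.csv"),
               "missing input")
})
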