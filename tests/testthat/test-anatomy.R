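test_that("landmark sets validate and round-trip through CSV", {
  nm <- mandible_landmark_names()
  expect_length(nm, 17L)
  set.seed(111)
  lm <- landmark_set(nm, matrix(rnorm(51, sd = 20), ncol = 3))
  f <- tempfile(fileext = ".csv")
  write_landmarks(lm, f)
  back <- read_landmarks(f)
  expect_equal(back$name, lm$name)
  expect_lt(max(abs(as.matrix(back[, 2:4]) - as.matrix(lm[, 2:4]))), 1e-9)

  expect_error(landmark_set(c("GT", "GT"), matrix(0, 2, 3)), "duplicate")
  f2 <- tempfile(fileext = ".csv")
  writeLines(c("name,x,y", "GT,1,2"), f2)
  expect_error(read_landmarks(f2), "columns")
})

test_that("the anatomical frame is orthonormal, right-handed and equivariant", {
  # canonical configuration: ML along z, AP along x
  lm <- landmark_set(
    c("L_Cd-lat", "R_Cd-lat", "L_Go", "R_Go", "GT"),
    rbind(c(-40, 40, 40), c(-40, 40, -40), c(-35, 0, 38), c(-35, 0, -38),
          c(38, 5, 0)))
  fr <- build_frame(lm)
  expect_equal(fr$ml, c(0, 0, 1), tolerance = 1e-12)
  expect_equal(fr$ap, c(1, 0.0685, 0) / sqrt(1 + 0.0685^2), tolerance = 1e-3)
  A <- cbind(fr$ap, fr$si, fr$ml)
  expect_lt(max(abs(crossprod(A) - diag(3))), 1e-9)
  expect_gt(det(A), 0)

  # rigid equivariance
  set.seed(121)
  R <- random_rotation()
  t0 <- c(7, -3, 11)
  lm2 <- landmark_set(lm$name,
                      sweep(as.matrix(lm[, 2:4]) %*% t(R), 2L, t0, "+"))
  fr2 <- build_frame(lm2)
  expect_lt(max(abs(fr2$ap - as.numeric(R %*% fr$ap))), 1e-9)
  expect_lt(max(abs(fr2$ml - as.numeric(R %*% fr$ml))), 1e-9)
  expect_lt(max(abs(fr2$origin - (as.numeric(R %*% fr$origin) + t0))), 1e-9)

  # collinear configuration is degenerate
  lmc <- landmark_set(lm$name,
                      rbind(c(0, 0, 2), c(0, 0, -2), c(0, 0, 1), c(0, 0, -1),
                            c(0, 0, 3)))
  expect_error(build_frame(lmc), "degenerate")
  expect_error(build_frame(lm[-5, ]), "GT")
})

test_that("region summaries obey the partition identity", {
  tpl <- small_template()
  sc <- growth_scenario(n_instances = 4L, noise_sd = 0)
  tf <- ground_truth_rates(sc, tpl)
  rs <- region_summary(tf, tpl$labels)

  counts <- rs[rs$direction == "total" & rs$instance == 1L, ]
  expect_equal(sum(counts$n_vertices), n_vertices(tpl$mesh))

  # whole-mesh mean equals the vertex-count-weighted mean of region means
  for (k in unique(rs$instance)) {
    slice <- rs[rs$direction == "total" & rs$instance == k, ]
    whole <- mean(tf$rate[tf$instance == k])
    expect_equal(sum(slice$mean * slice$n_vertices) / sum(slice$n_vertices),
                 whole, tolerance = 1e-12)
  }

  # forcing a region to a constant rate gives that mean with zero SD
  tf2 <- tf
  cond <- tpl$labels$vertex_index[tpl$labels$label == "condyle"]
  tf2$rate[tf2$vertex_index %in% cond & tf2$instance == 2L] <- 1.92
  rs2 <- region_summary(tf2, tpl$labels)
  row <- rs2[rs2$region == "condyle" & rs2$instance == 2L &
               rs2$direction == "total", ]
  expect_equal(row$mean, 1.92)
  expect_equal(row$sd, 0)

  expect_error(region_summary(tf, region_labels(rep("condyle", 10))),
               "labels cover")
})

test_that("thickness by normal ray casting matches slab and sphere geometry", {
  # two parallel square plates 2 mm apart, facing each other
  plate <- function(z, flip = FALSE) {
    v <- cbind(expand.grid(x = seq(0, 10, by = 2.5), y = seq(0, 10, by = 2.5)),
               z = z)
    idx <- function(i, j) (j - 1L) * 5L + i
    f <- list()
    for (i in 1:4) for (j in 1:4) {
      f[[length(f) + 1L]] <- c(idx(i, j), idx(i + 1L, j), idx(i + 1L, j + 1L))
      f[[length(f) + 1L]] <- c(idx(i, j), idx(i + 1L, j + 1L), idx(i, j + 1L))
    }
    f <- do.call(rbind, f)
    if (flip) f <- f[, c(1, 3, 2)]
    list(v = as.matrix(v), f = f)
  }
  top <- plate(2)
  bot <- plate(0, flip = TRUE)
  slab <- tri_mesh(rbind(top$v, bot$v), rbind(top$f, bot$f + nrow(top$v)))
  th <- suppressWarnings(region_thickness(slab, cutoff = 30))
  expect_equal(th$mean_thickness, 2, tolerance = 1e-6)

  # sphere: thickness along the inward normal is the diameter
  s <- make_sphere(10, 14, radius = 5)
  ths <- region_thickness(s, cutoff = 30)
  expect_equal(ths$mean_thickness, 10, tolerance = 0.05)
  expect_equal(ths$hit_fraction, 1)

  # labels restrict the vertex set; empty region errors
  tpl <- small_template()
  expect_error(region_thickness(tpl$mesh, tpl$labels, "nonexistent"),
               "empty region|unknown")
})

test_that("condylar width is the Cd-lat to Cd-med distance, rigid invariant", {
  lm <- landmark_set(c("L_Cd-lat", "L_Cd-med"), rbind(c(0, 0, 0), c(0, 15, 0)))
  expect_equal(condylar_width(lm, "L"), 15)
  lm0 <- landmark_set(c("R_Cd-lat", "R_Cd-med"), rbind(c(1, 2, 3), c(1, 2, 3)))
  expect_equal(condylar_width(lm0, "R"), 0)

  set.seed(131)
  R <- random_rotation()
  lm2 <- landmark_set(lm$name, sweep(as.matrix(lm[, 2:4]) %*% t(R), 2L,
                                     c(4, 5, 6), "+"))
  expect_equal(condylar_width(lm2, "L"), 15, tolerance = 1e-9)
  expect_error(condylar_width(lm, "R"), "missing")
})
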