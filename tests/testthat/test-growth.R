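identity_maps <- function(n, K) {
  lapply(seq_len(K - 1L), function(k)
    identity_correspondence(n, paste0("T", k), paste0("T", k + 1L)))
}

test_that("normalized monthly changes follow the defining arithmetic", {
  # two-vertex edge going 10 -> 10.5 mm: 5 %/month
  v1 <- rbind(c(0, 0, 0), c(10, 0, 0), c(0, 10, 0), c(0, 0, 10))
  m1 <- tri_mesh(v1, rbind(c(1, 2, 3), c(1, 2, 4), c(1, 3, 4), c(2, 3, 4)))
  v2 <- v1
  v2[2, 1] <- 10.5
  m2 <- tri_mesh(v2, m1$faces)
  s <- mesh_series(list(m1, m2))
  egs <- edge_length_changes(s, identity_maps(4L, 2L))
  e12 <- which(egs$edges[, 1] == 1L & egs$edges[, 2] == 2L)
  expect_equal(egs$changes[e12, 1], 5)

  # identical meshes: all changes zero
  s0 <- mesh_series(list(m1, m1, m1))
  egs0 <- edge_length_changes(s0, identity_maps(4L, 3L))
  expect_true(all(egs0$changes == 0))

  # zero-length edges are rejected with the edge named
  vz <- v1
  vz[2, ] <- vz[1, ]
  sz <- mesh_series(list(m1, tri_mesh(vz, m1$faces)))
  expect_error(edge_length_changes(sz, identity_maps(4L, 2L)), "zero edge length")
})

test_that("uniform scaling yields the exact uniform rate", {
  set.seed(71)
  m <- random_blob(5, 9)
  s_fac <- 1.02
  meshes <- list(m)
  for (k in 2:5) {
    meshes[[k]] <- tri_mesh(meshes[[k - 1]]$vertices * s_fac, m$faces)
  }
  s <- mesh_series(meshes)
  egs <- edge_length_changes(s, identity_maps(n_vertices(m), 5L))
  expect_equal(max(abs(egs$changes - 2)), 0, tolerance = 1e-9)

  er <- edge_rates(egs)
  vr <- vertex_rates(er, egs$edges, n_vertices(m))
  expect_lt(max(abs(vr - 2)), 0.1)
})

test_that("the cumulative-change spline reproduces polynomials and slopes", {
  # constant change c: cumulative is linear, the rate is c at every instance
  g <- rep(1.5, 11)
  curve <- fit_growth_curve(g)
  expect_equal(rate_at_instance(curve, 1:12), rep(1.5, 12), tolerance = 1e-9)
  expect_lt(max(abs(curve$fun(1:12) - curve$cumulative)), 1e-9)

  # cubic polynomial data are interpolated exactly at zero smoothing
  tt <- 1:8
  cubic <- function(t) 0.3 * t^3 - 2 * t^2 + t
  g3 <- diff(cubic(tt))
  curve3 <- fit_growth_curve(g3, tt)
  fine <- seq(1, 8, by = 0.25)
  expect_lt(max(abs(curve3$fun(fine) - (cubic(fine) - cubic(1)))), 1e-8)
  # gradient matches the analytic derivative: rate 2t for C = t^2
  gq <- diff((1:12)^2)
  curveq <- fit_growth_curve(gq)
  expect_equal(rate_at_instance(curveq, c(2, 5, 11)), c(4, 10, 22),
               tolerance = 1e-8)

  # noisy linear cumulative: least-squares slope recovered within 3 sd/sqrt(n)
  set.seed(81)
  slope <- 0.8
  noise_sd <- 0.05
  g_noisy <- diff(slope * (1:12) + rnorm(12, sd = noise_sd))
  curve_n <- fit_growth_curve(g_noisy, smoothing = 1)
  mid_rates <- rate_at_instance(curve_n, 3:10)
  expect_lt(abs(mean(mid_rates) - slope), 3 * noise_sd / sqrt(12) + 0.05)

  expect_error(fit_growth_curve(c(1, 2), 1:3), "at least 4")
  expect_error(rate_at_instance(curve, 13), "extrapolation|outside")

  # decelerating growth: monotone decreasing fitted rates at the knots
  g_dec <- 2 * 0.5^(0:9)
  curve_d <- fit_growth_curve(g_dec)
  rates_d <- rate_at_instance(curve_d, 2:10)
  expect_true(all(diff(rates_d) < 0))
})

test_that("vertex rates average incident edge rates", {
  # star: vertex 1 incident to exactly the three outer edges of a tetrahedron
  edges <- rbind(c(1L, 2L), c(1L, 3L), c(1L, 4L))
  rates <- matrix(c(1, 2, 3), ncol = 1)
  vr <- vertex_rates(rates, edges, 4L)
  expect_equal(vr[1, 1], 2)         # mean of {1, 2, 3}
  expect_equal(vr[2, 1], 1)         # single incident edge

  expect_error(vertex_rates(rates, edges, 5L), "isolated")
})

test_that("directional components conserve the total rate", {
  frame <- anatomical_frame()
  # edge along AP with rate 1: components (1, 0, 0)
  v <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  m <- tri_mesh(v, rbind(c(1, 2, 3), c(1, 2, 4), c(1, 3, 4), c(2, 3, 4)))
  s <- mesh_series(list(m, m))
  egs <- edge_length_changes(s, identity_maps(4L, 2L))
  E <- nrow(egs$edges)
  rates <- matrix(1, E, 2)
  comp <- directional_decompose(rates, egs, s, frame)
  e12 <- which(egs$edges[, 1] == 1L & egs$edges[, 2] == 2L)
  expect_equal(c(comp$ap[e12, 1], comp$si[e12, 1], comp$ml[e12, 1]), c(1, 0, 0),
               tolerance = 1e-12)

  # edge at equal angles to all axes with rate 3: (1, 1, 1)
  v2 <- v
  v2[2, ] <- c(1, 1, 1) / sqrt(3)
  m2 <- tri_mesh(v2, m$faces)
  s2 <- mesh_series(list(m2, m2))
  egs2 <- edge_length_changes(s2, identity_maps(4L, 2L))
  comp2 <- directional_decompose(matrix(3, E, 2), egs2, s2, frame)
  e12b <- which(egs2$edges[, 1] == 1L & egs2$edges[, 2] == 2L)
  expect_equal(c(comp2$ap[e12b, 1], comp2$si[e12b, 1], comp2$ml[e12b, 1]),
               c(1, 1, 1), tolerance = 1e-12)

  # random rates: components always sum to the total, per edge
  set.seed(91)
  rr <- matrix(rnorm(E * 2), E, 2)
  comp3 <- directional_decompose(rr, egs, s, frame)
  expect_lt(max(abs(comp3$ap + comp3$si + comp3$ml - rr)), 1e-12)
})

test_that("growth_field conserves components per vertex and is rigid-motion invariant", {
  set.seed(101)
  tpl <- small_template()
  sc <- growth_scenario(n_instances = 5L, noise_sd = 0)
  gs <- grow_series(tpl, sc)
  fld <- growth_field(gs$series, gs$truth_maps)
  expect_lt(max(abs(fld$ap + fld$si + fld$ml - fld$rate)), 1e-9)

  tr <- rigid_transform(random_rotation(), c(10, -4, 2))
  moved <- mesh_series(lapply(gs$series$meshes, apply_transform, transform = tr),
                       gs$series$times)
  fld2 <- growth_field(moved, gs$truth_maps)
  expect_lt(max(abs(fld2$rate - fld$rate)), 1e-9)

  # zero-growth series: all rates zero
  s0 <- mesh_series(list(tpl$mesh, tpl$mesh, tpl$mesh, tpl$mesh))
  f0 <- growth_field(s0, identity_maps(n_vertices(tpl$mesh), 4L))
  expect_lt(max(abs(f0$rate)), 1e-9)
})
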