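test_that("mesh construction enforces the invariants", {
  v <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0))
  expect_error(tri_mesh(v, rbind(c(1, 2, 4))), "outside")
  expect_error(tri_mesh(v, rbind(c(1, 1, 2))), "degenerate")
  expect_error(tri_mesh(rbind(c(0, 0, NA)), rbind(c(1, 1, 1))), "non-finite|degenerate")

  m <- tetrahedron_mesh()
  expect_equal(n_vertices(m), 4L)
  expect_equal(n_faces(m), 4L)
})

test_that("mesh_edges matches the closed-surface Euler count", {
  expect_equal(nrow(mesh_edges(tetrahedron_mesh())), 6L)  # K4

  # a 2-face triangle strip has 5 edges
  strip <- tri_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(1, 1, 0)),
                    rbind(c(1, 2, 3), c(2, 4, 3)))
  expect_equal(nrow(mesh_edges(strip)), 5L)

  s <- make_sphere(7, 11)
  expect_true(is_watertight(s))
  expect_equal(euler_characteristic(s), 2L)
  expect_equal(nrow(mesh_edges(s)), 3L * n_vertices(s) - 6L)
})

test_that("vertex_neighborhood equals the brute-force distance scan", {
  # unit tetrahedron with r larger than the diameter: everything
  expect_equal(vertex_neighborhood(tetrahedron_mesh(), 1L, 2), 1:4)
  # r below the minimum edge length: singleton
  expect_equal(vertex_neighborhood(tetrahedron_mesh(), 2L, 0.5), 2L)

  set.seed(5)
  for (rep in 1:3) {
    m <- random_blob(6, 11, bump = 0.3)   # ~68 vertices
    r <- runif(1, 1, 8)
    for (j in sample(n_vertices(m), 10)) {
      expect_equal(vertex_neighborhood(m, j, r), neighborhood_scan(m, j, r))
    }
  }

  # geodesic variant never returns more than the Euclidean ball on a convex
  # sphere, and always contains the center
  s <- make_sphere(5, 8, radius = 3)
  g <- vertex_neighborhood(s, 10L, 4, metric = "geodesic")
  expect_true(10L %in% g)
  expect_true(all(g %in% vertex_neighborhood(s, 10L, 4)))
})

test_that("welding collapses duplicate vertices (STL soup)", {
  m <- tetrahedron_mesh()
  f <- tempfile(fileext = ".stl")
  write_mesh(m, f)                       # ascii STL duplicates corners 3x
  m2 <- read_mesh(f)
  expect_equal(n_vertices(m2), 4L)       # brute-force duplicate scan: 12 -> 4
  expect_equal(n_faces(m2), 4L)
  # same geometry as a point set
  o <- m$vertices[order(m$vertices[, 1], m$vertices[, 2], m$vertices[, 3]), ]
  o2 <- m2$vertices[order(m2$vertices[, 1], m2$vertices[, 2], m2$vertices[, 3]), ]
  expect_lt(max(abs(o - o2)), 1e-6)
})

test_that("round-trip I/O preserves geometry within 1e-6 mm in every format", {
  set.seed(9)
  m <- random_blob(5, 9)
  for (spec in list(c("ply", FALSE), c("ply", TRUE), c("stl", FALSE),
                    c("stl", TRUE), c("obj", FALSE))) {
    fmt <- spec[1]
    f <- tempfile(fileext = paste0(".", fmt))
    write_mesh(m, f, binary = as.logical(spec[2]))
    m2 <- read_mesh(f)
    if (fmt == "stl") {
      expect_equal(n_vertices(m2), n_vertices(m))
      a <- m$vertices[do.call(order, as.data.frame(m$vertices)), ]
      b <- m2$vertices[do.call(order, as.data.frame(m2$vertices)), ]
      expect_lt(max(abs(a - b)), 1e-5)
    } else {
      expect_lt(max(abs(m2$vertices - m$vertices)), 1e-6)
      expect_equal(m2$faces, m$faces)
    }
  }
})

test_that("PLY carries per-vertex scalars and colors; contracts enforced", {
  m <- tetrahedron_mesh()
  f <- tempfile(fileext = ".ply")
  write_mesh(m, f, per_vertex_scalars = c(0.5, 1, 1.5, 2),
             per_vertex_colors = matrix(c(0, 255, 128, 64), 4, 3))
  txt <- readLines(f)
  expect_true(any(grepl("property float quality", txt)))
  expect_true(any(grepl("property uchar red", txt)))

  expect_error(write_mesh(m, f, per_vertex_scalars = 1:3), "length")
  expect_error(write_mesh(m, f, per_vertex_colors = matrix(300, 4, 3)),
               "\\[0, 255\\]")
})

test_that("parse errors name the offending location", {
  f <- tempfile(fileext = ".obj")
  writeLines(c("v 0 0 0", "v 1 0 0", "v 0 1 0", "f 0 1 2"), f)
  expect_error(read_mesh(f), "1-based")

  f2 <- tempfile(fileext = ".ply")
  writeLines(c("ply", "format ascii 1.0", "element vertex 4",
               "property double x", "property double y", "property double z",
               "element face 4", "property list uchar int vertex_indices",
               "end_header", "0 0 0", "1 0 0"), f2)
  expect_error(read_mesh(f2), "truncated|line")

  expect_error(read_mesh(tempfile(fileext = ".ply")), "not found")
})

test_that("decimation reaches the target count exactly and stays accurate", {
  s <- make_sphere(14, 20, radius = 10)    # 282 vertices
  expect_identical(decimate(s, n_vertices(s)), s)
  expect_error(decimate(s, n_vertices(s) + 1L), "exceeds")

  d <- decimate(s, 150L)
  expect_equal(n_vertices(d), 150L)
  expect_true(is_watertight(d))
  expect_equal(euler_characteristic(d), 2L)
  # surface deviation: mean radial error well below 1% of the radius
  radii <- sqrt(rowSums(d$vertices^2))
  expect_lt(mean(abs(radii - 10)), 0.1)
})
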