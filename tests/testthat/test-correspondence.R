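test_that("neighborhood correlation matches its closed-form cases and an independent Pearson", {
  set.seed(31)
  m <- random_blob(5, 9)
  q <- neighborhood(m, 3L, 6)
  expect_gte(length(q$indices), 2L)

  # exact copy under a known transform scores exactly 1
  R <- random_rotation()
  tr <- rigid_transform(R, c(2, 0, -1))
  q2 <- q
  q2$points <- transform_points(tr, q$points)
  expect_equal(neighborhood_correlation(q, q2, tr), 1, tolerance = 1e-12)

  # reflection through the centroid anti-correlates exactly under index pairing
  q3 <- q2
  ctr <- colMeans(q2$points)
  q3$points <- sweep(-sweep(q2$points, 2L, ctr), 2L, ctr, "+")
  expect_equal(neighborhood_correlation(q, q3, tr, pairing = "index"), -1,
               tolerance = 1e-12)

  # random 10-point neighborhoods: equals a hand-rolled Pearson on the
  # nearest-neighbor matched lists
  a <- q
  a$points <- matrix(rnorm(30, sd = 3), ncol = 3)
  b <- q
  b$points <- matrix(rnorm(30, sd = 3), ncol = 3)
  idn <- rigid_transform()
  x <- a$points
  d2 <- outer(rowSums(x^2), rowSums(b$points^2), "+") - 2 * tcrossprod(x, b$points)
  y <- b$points[max.col(-d2, ties.method = "first"), ]
  xc <- as.vector(sweep(x, 2L, colMeans(x)))
  yc <- as.vector(sweep(y, 2L, colMeans(y)))
  expect_equal(neighborhood_correlation(a, b, idn),
               sum(xc * yc) / sqrt(sum(xc^2) * sum(yc^2)), tolerance = 1e-12)

  # coincident points have no defined score
  z <- a
  z$points <- matrix(1, 5, 3)
  expect_error(neighborhood_correlation(z, b, idn), "zero variance")
  expect_error(neighborhood_correlation(a, b, idn, pairing = "index"), NA)
})

test_that("global_align recovers a known rigid motion via ICP", {
  set.seed(41)
  m <- random_blob(6, 10)
  ang <- 0.25
  R <- rbind(c(cos(ang), -sin(ang), 0), c(sin(ang), cos(ang), 0), c(0, 0, 1))
  tr <- rigid_transform(R, c(4, -2, 1))
  tgt <- apply_transform(m, tr)
  fit <- global_align(m, tgt)
  expect_lt(max(abs(fit$rotation - R)), 1e-6)
  expect_lt(max(abs(fit$translation - tr$translation)), 1e-6)
  expect_lt(attr(fit, "rms"), 1e-9)

  # identical meshes: identity
  fit0 <- global_align(m, m)
  expect_true(is_identity_transform(fit0, tol = 1e-9))

  # isotropic 2% scaling admits no exact rigid fit: RMS comparable to the
  # direct Kabsch residual on the known correspondence
  sc <- tri_mesh(m$vertices * 1.02, m$faces)
  fit2 <- global_align(m, sc)
  direct <- kabsch(m$vertices, sc$vertices)
  rms_direct <- sqrt(mean(rowSums(
    (transform_points(direct, m$vertices) - sc$vertices)^2)))
  expect_gt(attr(fit2, "rms"), 0)
  expect_lte(attr(fit2, "rms"), rms_direct * 1.5 + 1e-12)
})

test_that("match_vertex finds identity matches on identical meshes", {
  tpl <- small_template()
  m <- tpl$mesh
  r <- 5 * mean_edge_length(m)
  for (j in c(1L, 25L, 77L, n_vertices(m))) {
    vm <- match_vertex(m, m, j, r = r, rho = 3 * mean_edge_length(m))
    expect_identical(vm$target_index, j)
    expect_equal(vm$score, 1, tolerance = 1e-9)
    expect_true(is_identity_transform(vm$transform, tol = 1e-7))
  }
  far <- apply_transform(m, rigid_transform(diag(3), c(500, 0, 0)))
  expect_error(match_vertex(m, far, 1L, r = r, rho = 1), "no candidate")
})

test_that("match_vertex with unbounded search equals the exhaustive oracle", {
  set.seed(51)
  agree <- 0L
  total <- 0L
  for (rep in 1:6) {
    src <- random_blob(4, 7, bump = 0.3)              # 30 vertices
    tgt <- smooth_deform(src, amplitude = 0.15 * mean_edge_length(src))
    r <- 3 * mean_edge_length(src)
    pre <- global_align(src, tgt)
    for (j in sample(n_vertices(src), 8)) {
      got <- match_vertex(src, tgt, j, r = r, rho = Inf, pre_align = pre)
      want <- oracle_exhaustive_match(src, tgt, j, r, pre)
      total <- total + 1L
      agree <- agree + as.integer(got$target_index == want)
    }
  }
  expect_identical(agree, total)
})

test_that("scaled sphere matches the same spherical direction", {
  s <- make_sphere(7, 11, radius = 10)
  s2 <- tri_mesh(s$vertices * 1.05, s$faces)
  r <- 5 * mean_edge_length(s)
  pre <- global_align(s, s2)
  mel <- mean_edge_length(s2)
  for (j in c(5L, 30L, 60L)) {
    vm <- match_vertex(s, s2, j, r = r, rho = 3 * mean_edge_length(s), pre)
    # angular error below one edge length on the scaled sphere
    p <- s$vertices[j, ] * 1.05
    q <- s2$vertices[vm$target_index, ]
    expect_lt(sqrt(sum((p - q)^2)), mel)
  }
})

test_that("build_correspondence is an identity map on identical meshes and equivariant", {
  tpl <- small_template()
  m <- tpl$mesh
  map <- build_correspondence(m, m)
  expect_identical(map$target_index, map$source_index)
  expect_equal(map$score, rep(1, n_vertices(m)), tolerance = 1e-9)

  # rigidly moving the target changes transforms, not matches or scores
  # (moderate motion: the ICP pre-alignment has a basin of attraction)
  ang <- 0.25
  tr <- rigid_transform(rbind(c(cos(ang), -sin(ang), 0),
                              c(sin(ang), cos(ang), 0),
                              c(0, 0, 1)), c(5, 2, -3))
  map2 <- build_correspondence(m, apply_transform(m, tr))
  expect_identical(map2$target_index, map$target_index)
  expect_equal(map2$score, map$score, tolerance = 1e-9)

  # all local transforms are proper rotations
  for (k in sample(nrow(map2), 10)) {
    R <- matrix(as.numeric(map2[k, c("r00", "r01", "r02", "r10", "r11", "r12",
                                     "r20", "r21", "r22")]), 3, 3, byrow = TRUE)
    expect_lt(max(abs(crossprod(R) - diag(3))), 1e-9)
    expect_equal(det(R), 1, tolerance = 1e-9)
  }
})

test_that("correspondence maps compose and serialize", {
  n <- 5L
  id <- identity_correspondence(n, "T1", "T2")
  id2 <- identity_correspondence(n, "T2", "T3")
  comp <- compose_correspondence(list(id, id2))
  expect_identical(comp$target_index, 1:5)
  expect_equal(comp$score, rep(1, 5))

  # two mutually inverse permutation maps compose to the identity
  perm <- c(3L, 1L, 2L, 5L, 4L)
  mk <- function(pi_, from, to) {
    m <- identity_correspondence(n, from, to)
    m$target_index <- pi_
    m
  }
  m1 <- mk(perm, "T1", "T2")
  m2 <- mk(order(perm), "T2", "T3")
  expect_identical(compose_correspondence(list(m1, m2))$target_index, 1:5)

  bad <- identity_correspondence(n, "T9", "T10")
  expect_error(compose_correspondence(list(id, bad)), "chain mismatch")

  f <- tempfile(fileext = ".csv")
  write_correspondence(id, f)
  back <- read_correspondence(f)
  expect_equal(back$target_index, id$target_index)
  expect_equal(back$score, id$score)
})
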