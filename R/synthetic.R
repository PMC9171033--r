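#' Synthetic mandible-like template mesh
#'
#' Builds a closed, watertight horseshoe-arch surface schematizing a
#' mandible: a swept tube following a corpus arch with two posterior rami
#' rising to condylar knobs, capped at the condyle tops. The sweep parameter
#' `t` runs from -1 (left condyle) through 0 (anterior midline) to +1 (right
#' condyle); regions are bands of `|t|` pooled bilaterally, proportioned like
#' the six mandibular regions; the 17 landmark analogs (bilateral Cd-lat,
#' Cd-med, Cr, Go, MF1-MF3, GF plus midline GT) are placed at deterministic
#' template vertices. The tube radius varies smoothly along the sweep (bulged
#' condylar knobs, waisted ramus) with a small seeded modulation so local
#' surface shape is distinctive — the property the correspondence search
#' exploits on real bone.
#'
#' The template keeps its generative description (centerline tangent field,
#' sweep speed, ring frames and radii), so growth scenarios can rebuild every
#' instance in closed form: growing a region stretches the centerline arc
#' length and the ring radii by the local factor, which makes local edge
#' growth track the local rate field instead of a global scaling lever.
#'
#' This is a synthetic stand-in geometry for testing, not an anatomically
#' accurate mandible.
#'
#' @param n_vertices target vertex count (>= 100); met exactly when
#'   `n_vertices - 2` is divisible by the ring segment count, otherwise the
#'   closest achievable count is used.
#' @param n_segments vertices per tube ring.
#' @param scale overall size multiplier (default path spans ~110 mm).
#' @param seed RNG seed for the surface modulation; same seed, same mesh.
#' @return A `mandible_template`: list with `mesh` ([tri_mesh()]),
#'   `landmarks` ([landmark_set()]), `labels` ([region_labels()]), `vertex_t`
#'   (sweep parameter per vertex) and the generative fields under `gen`.
#' @export
make_template_mandible <- function(n_vertices = 653L, n_segments = 21L,
                                   scale = 1, seed = 1L) {
  if (n_vertices < 100L) stop("template needs at least 100 vertices", call. = FALSE)
  if (n_segments < 5L) stop("need at least 5 segments per ring", call. = FALSE)
  n_rings <- max(10L, as.integer(round((n_vertices - 2L) / n_segments)))
  set.seed(seed)

  # Centerline built from straight and circular-arc segments with explicit
  # bend radii (anterior arch 40 mm, posterior blend 55 mm, gonion corner
  # 20 mm), so no bend approaches the tube radius and inside-of-bend edges
  # never collapse. The left half runs from the anterior midline apex to the
  # left condyle top; the right half is its z-mirror.
  half <- mandible_half_path(scale)
  pathpos <- rbind(half[rev(seq_len(nrow(half))), ] %*% diag(c(1, 1, 1)),
                   (half %*% diag(c(1, 1, -1)))[-1, , drop = FALSE])
  # uniform arc-length parameter: t = signed arc fraction in [-1, 1]
  npath <- nrow(pathpos)
  tg <- seq(-1, 1, length.out = npath)
  seglen <- sqrt(rowSums(diff(pathpos)^2))
  speed <- rep(sum(seglen) / 2, npath)       # constant by construction
  tangent_g <- rbind(pathpos[2, ] - pathpos[1, ],
                     (pathpos[-(1:2), ] - pathpos[seq_len(npath - 2L), ]) / 2,
                     pathpos[npath, ] - pathpos[npath - 1L, ])
  tangent_g <- tangent_g / sqrt(rowSums(tangent_g^2))

  # radius profile vs arc fraction: corpus body, waisted ramus, condylar knob
  rq <- c(0, 0.12, 0.3, 0.45, 0.62, 0.75, 0.88, 0.96, 1)
  rr <- c(7.5, 8.8, 9.6, 9.2, 7.6, 7, 7.8, 10.2, 7.8) * scale
  frad <- stats::splinefun(rq, rr, method = "fmm")
  mod_phase <- stats::runif(2, 0, 2 * pi)

  tv <- seq(-1, 1, length.out = n_rings)     # rings uniform in arc length
  saf_g <- tg
  saf_ring <- tv
  ring_idx_g <- round(stats::approx(tg, seq_len(npath), tv)$y)
  tangents <- tangent_g[ring_idx_g, , drop = FALSE]

  # parallel-transported ring frames avoid twist jumps along the sweep
  u <- matrix(NA_real_, n_rings, 3L)
  w <- matrix(NA_real_, n_rings, 3L)
  ref <- c(0, 1, 0)
  if (abs(sum(ref * tangents[1, ])) > 0.9) ref <- c(1, 0, 0)
  u[1, ] <- normalize3(cross3(tangents[1, ], ref))
  w[1, ] <- cross3(tangents[1, ], u[1, ])
  for (i in 2:n_rings) {
    ui <- u[i - 1, ] - sum(u[i - 1, ] * tangents[i, ]) * tangents[i, ]
    if (sqrt(sum(ui^2)) < 1e-8) ui <- cross3(tangents[i, ], w[i - 1, ])
    u[i, ] <- normalize3(ui)
    w[i, ] <- cross3(tangents[i, ], u[i, ])
  }

  theta <- 2 * pi * (seq_len(n_segments) - 1L) / n_segments
  # oval, slowly twisting cross-section (mandibular sections are not round)
  # plus a fine helical surface relief: real bone surfaces are not
  # featureless tubes, and local shape detail is what the correlation
  # matching keys on — without it, neighboring candidates score identically
  # up to measurement noise
  base_rad <- frad(abs(tv)) * (1 + 0.05 * sin(5 * pi * tv + mod_phase[1]))
  twist <- 0.8 * sin(3 * pi * tv)
  rad_vertex <- outer(seq_len(n_rings), seq_len(n_segments),
                      function(i, j) {
                        base_rad[i] *
                          (1 + 0.10 * cos(2 * (theta[j] + twist[i]))) *
                          (1 + 0.05 * sin(14 * pi * tv[i] + theta[j] +
                                            mod_phase[2]))
                      })

  gen <- list(tg = tg, speed = speed, tangent_g = tangent_g,
              origin = pathpos[which.min(abs(tg)), ],
              tv = tv, u = u, w = w, theta = theta, rad_vertex = rad_vertex,
              n_rings = n_rings, n_segments = n_segments,
              saf_g = saf_g, saf_ring = saf_ring,
              pole_len = frad(1) * 0.8,
              pole_tangent = rbind(tangents[1, ], tangents[n_rings, ]))

  verts <- synth_vertices(gen, m_ring = rep(1, n_rings),
                          m_grid = rep(1, length(tg)), m_pole = c(1, 1))

  faces <- list()
  ring_idx <- function(i) (i - 1L) * n_segments + seq_len(n_segments)
  for (i in seq_len(n_rings - 1L)) {
    a <- ring_idx(i)
    b <- ring_idx(i + 1L)
    for (j in seq_len(n_segments)) {
      jn <- if (j == n_segments) 1L else j + 1L
      faces[[length(faces) + 1L]] <- c(a[j], b[j], b[jn])
      faces[[length(faces) + 1L]] <- c(a[j], b[jn], a[jn])
    }
  }
  a <- ring_idx(1L)
  b <- ring_idx(n_rings)
  pole1 <- n_rings * n_segments + 1L
  pole2 <- n_rings * n_segments + 2L
  for (j in seq_len(n_segments)) {
    jn <- if (j == n_segments) 1L else j + 1L
    faces[[length(faces) + 1L]] <- c(pole1, a[jn], a[j])
    faces[[length(faces) + 1L]] <- c(pole2, b[j], b[jn])
  }
  mesh <- tri_mesh(verts, do.call(rbind, faces), "template")
  if (signed_volume(mesh) < 0) {
    mesh <- tri_mesh(mesh$vertices, mesh$faces[, c(1, 3, 2)], "template")
  }

  vertex_t <- c(rep(tv, each = n_segments), -1, 1)
  vertex_saf <- c(rep(saf_ring, each = n_segments), -1, 1)

  # region bands of the arc fraction, proportioned like the mandibular
  # regions; thresholds snap to midpoints between ring positions so no ring
  # sits on a band boundary (or inside a growth-rate transition)
  afs <- sort(unique(round(abs(saf_ring), 9)))
  mids <- (afs[-1] + afs[-length(afs)]) / 2
  bands <- vapply(c(0.199, 0.399, 0.599, 0.663, 0.738), function(thr) {
    mids[which.min(abs(mids - thr))]
  }, numeric(1))
  if (anyDuplicated(bands)) {
    stop("too few rings to separate the six anatomical regions", call. = FALSE)
  }
  at <- abs(vertex_saf)
  lab <- rep("anterior_corpus", length(at))
  lab[at >= bands[1]] <- "middle_corpus"
  lab[at >= bands[2]] <- "posterior_corpus"
  lab[at >= bands[3]] <- "anterior_ramus"
  lab[at >= bands[4]] <- "posterior_ramus"
  lab[at >= bands[5]] <- "condyle"
  labels <- region_labels(lab)

  ring_at <- function(tval) which.min(abs(saf_ring - tval))
  pick <- function(tval, fn) {
    idx <- ring_idx(ring_at(tval))
    idx[fn(mesh$vertices[idx, , drop = FALSE])]
  }
  lm_idx <- c(
    "L_Cd-lat" = pick(-0.97, function(p) which.max(p[, 3])),
    "L_Cd-med" = pick(-0.97, function(p) which.min(p[, 3])),
    "L_Cr" = pick(-0.80, function(p) which.max(p[, 1])),
    "L_Go" = pick(-0.65, function(p) which.min(p[, 1] + p[, 2])),
    "L_MF1" = pick(-0.22, function(p) which.max(p[, 3])),
    "L_MF2" = pick(-0.30, function(p) which.max(p[, 3])),
    "L_MF3" = pick(-0.38, function(p) which.max(p[, 3])),
    "L_GF" = pick(-0.08, function(p) which.min(p[, 3])),
    "R_Cd-lat" = pick(0.97, function(p) which.min(p[, 3])),
    "R_Cd-med" = pick(0.97, function(p) which.max(p[, 3])),
    "R_Cr" = pick(0.80, function(p) which.max(p[, 1])),
    "R_Go" = pick(0.65, function(p) which.min(p[, 1] + p[, 2])),
    "R_MF1" = pick(0.22, function(p) which.min(p[, 3])),
    "R_MF2" = pick(0.30, function(p) which.min(p[, 3])),
    "R_MF3" = pick(0.38, function(p) which.min(p[, 3])),
    "R_GF" = pick(0.08, function(p) which.max(p[, 3])),
    "GT" = pick(0, function(p) which.max(p[, 1]))
  )
  landmarks <- landmark_set(names(lm_idx), mesh$vertices[lm_idx, , drop = FALSE])

  gen$bands <- bands
  structure(list(mesh = mesh, landmarks = landmarks, labels = labels,
                 vertex_t = vertex_t, vertex_saf = vertex_saf,
                 region_bands = bands, gen = gen, seed = seed,
                 landmark_vertices = lm_idx),
            class = "mandible_template")
}

# vertices of one instance from the generative description and cumulative
# local growth multipliers (per fine-grid point, per ring, per pole):
# centerline re-integrated with stretched speed, ring radii scaled locally
synth_vertices <- function(gen, m_ring, m_grid, m_pole) {
  integrand <- gen$tangent_g * (m_grid * gen$speed)
  cum <- apply(integrand, 2L, cumtrapz_reg, x = gen$tg)
  i0 <- which.min(abs(gen$tg))                      # tg contains 0 (odd grid)
  cum <- sweep(cum, 2L, cum[i0, ])
  centers <- cbind(stats::approx(gen$tg, cum[, 1], gen$tv)$y,
                   stats::approx(gen$tg, cum[, 2], gen$tv)$y,
                   stats::approx(gen$tg, cum[, 3], gen$tv)$y)
  centers <- sweep(centers, 2L, gen$origin, "+")
  n_rings <- gen$n_rings
  n_seg <- gen$n_segments
  verts <- matrix(NA_real_, n_rings * n_seg + 2L, 3L)
  ct <- cos(gen$theta)
  st <- sin(gen$theta)
  for (i in seq_len(n_rings)) {
    ring <- (outer(ct, gen$u[i, ]) + outer(st, gen$w[i, ])) *
      (gen$rad_vertex[i, ] * m_ring[i])
    verts[(i - 1L) * n_seg + seq_len(n_seg), ] <- sweep(ring, 2L, centers[i, ], "+")
  }
  verts[n_rings * n_seg + 1L, ] <- centers[1, ] -
    gen$pole_tangent[1, ] * gen$pole_len * m_pole[1]
  verts[n_rings * n_seg + 2L, ] <- centers[n_rings, ] +
    gen$pole_tangent[2, ] * gen$pole_len * m_pole[2]
  verts
}

cumtrapz_reg <- function(y, x) {
  c(0, cumsum((y[-1] + y[-length(y)]) / 2 * diff(x)))
}

# Left half of the mandibular centerline, anterior midline apex -> left
# condyle top, sampled uniformly in arc length. Piecewise straight/circular
# segments with gentle drifts; x anterior, y superior, z left (mm).
mandible_half_path <- function(scale = 1, ds = 0.25, n_out = 2000L) {
  p <- c(38, 5, 0)            # apex
  h <- c(0, 0, 1)             # initial heading: leftward along the arch
  pts <- list(p)
  add_segment <- function(len, kappa, axis, drift) {
    n <- max(2L, ceiling(len / ds))
    step <- len / n
    out <- matrix(NA_real_, n, 3L)
    for (i in seq_len(n)) {
      if (kappa != 0) {
        phi <- -kappa * step
        h <<- if (axis == "y") {
          c(h[1] * cos(phi) + h[3] * sin(phi), h[2],
            -h[1] * sin(phi) + h[3] * cos(phi))
        } else {
          c(h[1] * cos(phi) - h[2] * sin(phi),
            h[1] * sin(phi) + h[2] * cos(phi), h[3])
        }
        h <<- h / sqrt(sum(h^2))
      }
      p <<- p + h * step + drift / n
      out[i, ] <- p
    }
    pts[[length(pts) + 1L]] <<- out
  }
  add_segment(38, 1 / 40, "y", c(0, -3, 0))       # anterior arch
  add_segment(35, 1 / 55, "y", c(0, -2, 0))       # posterior corpus blend
  add_segment(14, 0, "y", c(0, -1, 0.5))          # corpus run to the angle
  add_segment(20 * pi / 2, 1 / 20, "z", c(0, 0, 1))  # gonion corner, up
  add_segment(26, 0, "z", c(-2, 0, 1.5))          # ramus to the condyle
  raw <- do.call(rbind, pts)
  arc <- c(0, cumsum(sqrt(rowSums(diff(raw)^2))))
  s_out <- seq(0, arc[length(arc)], length.out = n_out)
  cbind(stats::approx(arc, raw[, 1], s_out)$y,
        stats::approx(arc, raw[, 2], s_out)$y,
        stats::approx(arc, raw[, 3], s_out)$y) * scale
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}
normalize3 <- function(a) a / sqrt(sum(a^2))

#' @export
print.mandible_template <- function(x, ...) {
  cat("<mandible_template>", n_vertices(x$mesh), "vertices,",
      n_faces(x$mesh), "faces, 17 landmarks, 6 regions\n")
  invisible(x)
}

#' Growth scenario for the synthetic generator
#'
#' Defines the study conditions a synthetic series emulates: per-region total
#' growth rates in %/month (defaults follow the observed regional ordering:
#' fastest condyle ~1.9, posterior ramus ~1.5, slow corpora ~0.4), a temporal
#' profile multiplying the rates per interval (constant by default), the
#' surface measurement noise (0.2 mm along vertex normals, the scale of CBCT
#' surface reconstruction error), the number of monthly instances (12) and
#' the RNG seed.
#'
#' @param region_rates named numeric vector of total rates (%/month) for the
#'   six regions.
#' @param profile per-interval multiplier of the rates; length
#'   `n_instances - 1`, default all 1.
#' @param n_instances number of measurement instances (>= 2).
#' @param noise_sd Gaussian noise standard deviation along vertex normals
#'   (mm), >= 0.
#' @param transition_width half-width (in sweep parameter units) of the
#'   smooth blend between adjacent region rate plateaus.
#' @param seed RNG seed; identical scenario + seed gives a bit-identical
#'   series.
#' @return A `growth_scenario` list.
#' @export
growth_scenario <- function(region_rates = c(condyle = 1.9,
                                             posterior_ramus = 1.5,
                                             anterior_ramus = 1.0,
                                             posterior_corpus = 0.4,
                                             middle_corpus = 0.4,
                                             anterior_corpus = 0.4),
                            profile = NULL, n_instances = 12L,
                            noise_sd = 0.2, transition_width = 0.005,
                            seed = 1L) {
  stopifnot(n_instances >= 2L, noise_sd >= 0, all(is.finite(region_rates)))
  missing_regions <- setdiff(mandible_region_names(), names(region_rates))
  if (length(missing_regions)) {
    stop("region_rates must name all six regions; missing: ",
         paste(missing_regions, collapse = ", "), call. = FALSE)
  }
  profile <- profile %||% rep(1, n_instances - 1L)
  if (length(profile) != n_instances - 1L) {
    stop("profile must have one multiplier per interval", call. = FALSE)
  }
  structure(list(region_rates = region_rates, profile = as.numeric(profile),
                 n_instances = as.integer(n_instances),
                 noise_sd = noise_sd, transition_width = transition_width,
                 seed = as.integer(seed)),
            class = "growth_scenario")
}

# rate (%/month) as a function of the signed arc fraction: region plateaus
# with narrow smoothstep blends across the band boundaries
scenario_rate_at <- function(scenario, tvals,
                             bands = c(0.199, 0.399, 0.599, 0.663, 0.738)) {
  rates <- scenario$region_rates[c("anterior_corpus", "middle_corpus",
                                   "posterior_corpus", "anterior_ramus",
                                   "posterior_ramus", "condyle")]
  at <- abs(tvals)
  w <- scenario$transition_width
  out <- rep(rates[1], length(at))
  for (k in seq_along(bands)) {
    s <- pmin(1, pmax(0, (at - (bands[k] - w)) / (2 * w)))
    s <- s * s * (3 - 2 * s)                     # smoothstep
    out <- out * (1 - s) + rates[k + 1] * s
  }
  as.numeric(out)
}

# per-vertex rate field of the template under a scenario
vertex_rate_field <- function(template, scenario) {
  scenario_rate_at(scenario, template$vertex_saf, template$region_bands)
}

# noiseless vertex positions of all instances; single source of truth for
# both the generated meshes and the analytic ground-truth rates
synth_instances <- function(template, scenario) {
  gen <- template$gen
  K <- scenario$n_instances
  r_grid <- scenario_rate_at(scenario, gen$saf_g, gen$bands)
  r_ring <- scenario_rate_at(scenario, gen$saf_ring, gen$bands)
  r_pole <- scenario_rate_at(scenario, c(-1, 1), gen$bands)
  if (any(1 + scenario$profile %o% (c(r_grid, r_ring) / 100) <= 0)) {
    stop("growth field collapses the surface (local scale factor <= 0): ",
         "self-intersecting series", call. = FALSE)
  }
  m_grid <- rep(1, length(r_grid))
  m_ring <- rep(1, length(r_ring))
  m_pole <- c(1, 1)
  out <- vector("list", K)
  out[[1]] <- synth_vertices(gen, m_ring, m_grid, m_pole)
  for (k in 2:K) {
    f <- scenario$profile[k - 1]
    m_grid <- m_grid * (1 + f * r_grid / 100)
    m_ring <- m_ring * (1 + f * r_ring / 100)
    m_pole <- m_pole * (1 + f * r_pole / 100)
    out[[k]] <- synth_vertices(gen, m_ring, m_grid, m_pole)
  }
  out
}

#' Generate a growing synthetic mesh series with ground truth
#'
#' Every instance is synthesized in closed form from the template's
#' generative description: the centerline is re-integrated with its speed
#' stretched by the cumulative local growth factor
#' `m_{k+1}(t) = m_k(t) * (1 + profile_k * rate(t) / 100)` and the ring radii
#' are scaled by the same local factor, so local edge growth follows the
#' local rate field. Instance meshes then receive iid Gaussian noise of
#' `noise_sd` mm along their vertex normals — surface-measurement-like error
#' without the tangential drift that would corrupt the ground-truth
#' correspondence. Vertex identity is preserved across instances, so the
#' ground-truth correspondence between consecutive meshes is the identity map
#' and exact noiseless edge rates are available analytically.
#'
#' @param template a [make_template_mandible()] object.
#' @param scenario a [growth_scenario()].
#' @return A list: `series` (noisy [mesh_series()]), `noiseless_series`,
#'   `truth_maps` (identity `correspondence_map`s per interval),
#'   `truth_field` (ground-truth `growth_field`), `gold_landmarks` (tibble of
#'   noiseless landmark tracks), `labels`, `landmarks` (template landmark
#'   set), `rate_field` (per-vertex %/month).
#' @export
grow_series <- function(template, scenario) {
  stopifnot(inherits(template, "mandible_template"),
            inherits(scenario, "growth_scenario"))
  K <- scenario$n_instances
  noiseless <- synth_instances(template, scenario)
  mel <- mean_edge_length(template$mesh)
  if (scenario$noise_sd > 0.3 * mel) {
    max_disp <- max(vapply(2:K, function(k)
      max(sqrt(rowSums((noiseless[[k]] - noiseless[[k - 1]])^2))), numeric(1)))
    stop(sprintf(paste0("noise_sd %.3g mm risks self-intersection ",
                        "(max growth displacement %.3g mm, mean edge %.3g mm)"),
                 scenario$noise_sd, max_disp, mel), call. = FALSE)
  }

  set.seed(scenario$seed)
  faces <- template$mesh$faces
  noisy <- vector("list", K)
  noiseless_meshes <- vector("list", K)
  for (k in seq_len(K)) {
    mesh_k <- tri_mesh(noiseless[[k]], faces, paste0("T", k))
    noiseless_meshes[[k]] <- mesh_k
    if (scenario$noise_sd > 0) {
      nrm <- vertex_normals(mesh_k)
      eps <- stats::rnorm(nrow(nrm), sd = scenario$noise_sd)
      noisy[[k]] <- tri_mesh(noiseless[[k]] + nrm * eps, faces, paste0("T", k))
    } else {
      noisy[[k]] <- mesh_k
    }
  }
  series <- mesh_series(noisy)
  noiseless_series <- mesh_series(noiseless_meshes)
  truth_maps <- lapply(seq_len(K - 1L), function(k) {
    identity_correspondence(n_vertices(template$mesh),
                            source_label = paste0("T", k),
                            target_label = paste0("T", k + 1L))
  })
  truth_field <- ground_truth_rates(scenario, template)
  lm_idx <- template$landmark_vertices
  gold_landmarks <- purrr::map_dfr(seq_len(K), function(k) {
    p <- noiseless[[k]][lm_idx, , drop = FALSE]
    tibble::tibble(name = names(lm_idx), instance = k, time = k,
                   x = p[, 1], y = p[, 2], z = p[, 3])
  })
  list(series = series, noiseless_series = noiseless_series,
       truth_maps = truth_maps, truth_field = truth_field,
       gold_landmarks = gold_landmarks, labels = template$labels,
       landmarks = template$landmarks,
       rate_field = vertex_rate_field(template, scenario))
}

#' Identity correspondence map
#'
#' @param n number of vertices.
#' @param source_label,target_label optional instance labels.
#' @return A `correspondence_map` matching every vertex to itself with score
#'   1 and identity transforms.
#' @export
identity_correspondence <- function(n, source_label = NULL, target_label = NULL) {
  tbl <- tibble::tibble(source_index = seq_len(n), target_index = seq_len(n),
                        score = 1,
                        r00 = 1, r01 = 0, r02 = 0,
                        r10 = 0, r11 = 1, r12 = 0,
                        r20 = 0, r21 = 0, r22 = 1,
                        t0 = 0, t1 = 0, t2 = 0)
  new_correspondence_map(tbl, source_label = source_label,
                         target_label = target_label,
                         pre_align = rigid_transform())
}

#' Analytic ground-truth growth field of a scenario
#'
#' Computes the exact noiseless vertex positions of every instance from the
#' generative construction, turns the exact edge lengths into normalized
#' monthly changes assigned to the interval's end instance, and averages over
#' incident edges — the same shape and units as the pipeline's
#' [growth_field()], so recovery can be compared directly. The rate at the
#' first instance copies the first interval (no preceding interval exists).
#'
#' @param scenario a [growth_scenario()].
#' @param template a [make_template_mandible()] object.
#' @return A `growth_field` tibble.
#' @export
ground_truth_rates <- function(scenario, template) {
  K <- scenario$n_instances
  pos <- synth_instances(template, scenario)
  edges <- mesh_edges(template$mesh)
  E <- nrow(edges)
  n <- n_vertices(template$mesh)
  lengths <- matrix(NA_real_, E, K)
  for (k in seq_len(K)) {
    lengths[, k] <- sqrt(rowSums((pos[[k]][edges[, 1], , drop = FALSE] -
                                    pos[[k]][edges[, 2], , drop = FALSE])^2))
  }
  g <- 100 * (lengths[, -1L, drop = FALSE] - lengths[, -K, drop = FALSE]) /
    lengths[, -K, drop = FALSE]
  er <- cbind(g[, 1], g)                         # instance 1 copies interval 1
  vr <- average_over_incident_edges(er, edges, n)

  frame <- anatomical_frame()
  ap <- si <- ml <- matrix(NA_real_, E, K)
  for (k in seq_len(K)) {
    u <- pos[[k]][edges[, 2], , drop = FALSE] - pos[[k]][edges[, 1], , drop = FALSE]
    u <- u / sqrt(rowSums(u^2))
    ap[, k] <- er[, k] * (u %*% frame$ap)^2
    si[, k] <- er[, k] * (u %*% frame$si)^2
    ml[, k] <- er[, k] * (u %*% frame$ml)^2
  }
  vap <- average_over_incident_edges(ap, edges, n)
  vsi <- average_over_incident_edges(si, edges, n)
  vml <- average_over_incident_edges(ml, edges, n)
  out <- tibble::tibble(
    vertex_index = rep(seq_len(n), K),
    instance = rep(seq_len(K), each = n),
    time = rep(seq_len(K), each = n),
    rate = as.vector(vr), ap = as.vector(vap), si = as.vector(vsi),
    ml = as.vector(vml)
  )
  structure(out, class = c("growth_field", class(out)),
            n_vertices = n, times = seq_len(K))
}
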