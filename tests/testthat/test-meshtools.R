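simple_tet <- function() {
  tet_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1)),
           matrix(1:4, 1))
}

# triangulated sphere (lat-long) used as an analytic surface fixture
sphere_surface_mesh <- function(radius = 1, n = 24) {
  th <- seq(0, pi, length.out = n)
  ph <- seq(0, 2 * pi, length.out = 2 * n + 1)[- (2 * n + 1)]
  g <- expand.grid(th = th, ph = ph)
  nodes <- radius * cbind(sin(g$th) * cos(g$ph), sin(g$th) * sin(g$ph),
                          cos(g$th))
  idx <- function(i, j) (j - 1) * n + i
  tris <- list()
  for (j in seq_len(2 * n)) {
    jn <- j %% (2 * n) + 1
    for (i in seq_len(n - 1)) {
      tris[[length(tris) + 1L]] <- c(idx(i, j), idx(i + 1, j), idx(i, jn))
      tris[[length(tris) + 1L]] <- c(idx(i + 1, j), idx(i + 1, jn), idx(i, jn))
    }
  }
  list(nodes = nodes, triangles = do.call(rbind, tris))
}

test_that("tet_mesh validates and orients its elements", {
  m <- simple_tet()
  expect_gt(tet_signed_volumes(m$nodes, m$tets), 0)
  # a negatively oriented input is flipped on construction
  m2 <- tet_mesh(m$nodes, matrix(c(1, 2, 4, 3), 1))
  expect_gt(tet_signed_volumes(m2$nodes, m2$tets), 0)
  expect_error(tet_mesh(m$nodes, matrix(c(1, 2, 3, 9), 1)), "range")
})

test_that("warp_mesh moves nodes pointwise and preserves connectivity", {
  set.seed(40)
  m <- tet_mesh_ellipsoid(c(0, 0, 0), c(8, 6, 5), h = 2)
  Tt <- ffd_transform(c(-40, -40, -40), c(20, 20, 20), c(5, 5, 5),
                      matrix(rep(c(2, -1, 3), each = 125), ncol = 3))
  w <- warp_mesh(m, Tt)
  expect_identical(w$tets, m$tets)
  expect_equal(w$nodes, sweep(m$nodes, 2, c(2, -1, 3), "+"),
               tolerance = 1e-10)
  Tr <- random_ffd(shape = c(6, 6, 6), spacing = c(10, 10, 10),
                   origin = c(-25, -25, -25), sd = 0.5)
  w2 <- warp_mesh(m, Tr)
  oracle <- t(vapply(seq_len(nrow(m$nodes)), function(i)
    ffd_apply(Tr, m$nodes[i, ]), numeric(3)))
  expect_equal(w2$nodes, oracle, tolerance = 1e-12)
  # element count conserved for any mesh size
  expect_identical(nrow(w2$tets), nrow(m$tets))
  Tsmall <- ffd_transform(c(0, 0, 0), c(2, 2, 2), c(4, 4, 4))
  expect_error(warp_mesh(m, Tsmall), "support")
})

test_that("point-to-surface accuracy is exact against brute-force scans", {
  set.seed(41)
  # unit-scale mesh so on-surface distances are tested at full precision
  m <- tet_mesh_ellipsoid(c(0, 0, 0), c(0.8, 0.6, 0.5), h = 0.25)
  tri <- boundary_faces(m)
  bc <- matrix(runif(30), ncol = 3); bc <- bc / rowSums(bc)
  f <- sample(nrow(tri), 10, replace = TRUE)
  on_surf <- bc[, 1] * m$nodes[tri[f, 1], ] + bc[, 2] * m$nodes[tri[f, 2], ] +
    bc[, 3] * m$nodes[tri[f, 3], ]
  expect_lt(point_to_surface_accuracy(on_surf, m), 1e-9)
  # random points against the constrained-optimizer oracle
  pts <- matrix(runif(24, -1, 1), ncol = 3)
  got <- attr(point_to_surface_accuracy(pts, m), "distances")
  oracle <- vapply(seq_len(nrow(pts)), function(i) {
    min(vapply(seq_len(nrow(tri)), function(k)
      point_tri_dist_oracle(pts[i, ], m$nodes[tri[k, 1], ],
                            m$nodes[tri[k, 2], ], m$nodes[tri[k, 3], ]),
      numeric(1)))
  }, numeric(1))
  expect_lt(max(abs(got - oracle)), 1e-7)
})

test_that("points at radius 2 from a unit sphere surface lie 1 mm away", {
  s <- sphere_surface_mesh(radius = 1, n = 28)
  m <- list(nodes = s$nodes, tets = matrix(integer(0), 0, 4),
            surface = s$triangles)
  class(m) <- "tet_mesh"
  set.seed(42)
  dirs <- matrix(rnorm(60), ncol = 3)
  dirs <- dirs / sqrt(rowSums(dirs^2))
  acc <- point_to_surface_accuracy(2 * dirs, m)
  # faceting of the lat-long sphere keeps the chordal error well under 2%
  expect_equal(as.numeric(acc), 1.0, tolerance = 0.02)
})

test_that("node-to-node accuracy and its per-node field behave as distances", {
  set.seed(43)
  m <- tet_mesh_ellipsoid(c(0, 0, 0), c(8, 6, 5), h = 2)
  expect_equal(as.numeric(node_to_node_accuracy(m, m)), 0)
  t0 <- c(1, 2, -2)
  m2 <- m; m2$nodes <- sweep(m$nodes, 2, t0, "+")
  expect_equal(as.numeric(node_to_node_accuracy(m, m2)), sqrt(sum(t0^2)),
               tolerance = 1e-12)
  m3 <- m; m3$nodes <- m$nodes + matrix(rnorm(length(m$nodes), 0, 0.3),
                                        ncol = 3)
  ids <- surface_node_ids(m)
  direct <- mean(sqrt(rowSums((m$nodes[ids, ] - m3$nodes[ids, ])^2)))
  expect_equal(as.numeric(node_to_node_accuracy(m, m3)), direct,
               tolerance = 1e-12)
  m4 <- tet_mesh(m$nodes, m$tets[-1, , drop = FALSE])
  expect_error(node_to_node_accuracy(m, m4), "topology")
})

test_that("j10 averages the lowest decile of Jacobian determinants", {
  d <- c(10, 10, 10)
  mk <- array(FALSE, d); mk[3:7, 3:7, 3:7] <- TRUE
  mask <- mask_volume(mk, c(2, 2, 2), -(d - 1))
  T0 <- ffd_transform(c(-40, -40, -40), c(10, 10, 10), c(9, 9, 9))
  expect_equal(j10(T0, mask), 1)
  set.seed(44)
  Tr <- random_ffd(shape = c(9, 9, 9), spacing = c(10, 10, 10),
                   origin = c(-40, -40, -40), sd = 1)
  pts <- domain_points(mask)
  jd <- sort(jacobian_det(Tr, pts))
  oracle <- mean(jd[seq_len(ceiling(0.1 * length(jd)))])
  expect_equal(j10(Tr, mask), oracle, tolerance = 1e-12)
  # 10 values: the lowest decile is exactly the single smallest value
  mk10 <- array(FALSE, d); mk10[1:10, 1, 1] <- TRUE
  m10 <- mask_volume(mk10, c(2, 2, 2), -(d - 1))
  expect_equal(j10(Tr, m10),
               min(jacobian_det(Tr, domain_points(m10))), tolerance = 1e-12)
  expect_error(j10(T0, mask_volume(array(FALSE, d), c(2, 2, 2), -(d - 1))),
               "empty")
})

test_that("prediction score and best-candidate selection follow the rule", {
  expect_equal(prediction_score(1.61, 0.47), 0.452249)
  expect_equal(prediction_score(5, 1), 0)
  expect_equal(prediction_score(0, 0.2), 0)
  expect_error(prediction_score(-1, 0.5), ">= 0")
  cand <- data.frame(accuracy = c(2.0, 1.61, 1.0, 1.0, 3.0),
                     j10 = c(0.9, 0.47, 0.5, 0.5, 0.99),
                     lambda1 = c(10, 26.21, 20, 15, 12))
  best <- select_best_prediction(cand)
  sc <- attr(best, "score")
  expect_equal(sc[2], 0.452249)
  # rows 3 and 4 tie on score and j10; the smaller lambda1 wins
  expect_equal(sc[3], sc[4])
  expect_identical(as.integer(best), which.min(sc + 1e-30 * seq_along(sc)))
  cand2 <- data.frame(accuracy = c(1, 2), j10 = c(0.5, 1 - sqrt(0.125)))
  b2 <- select_best_prediction(cand2) # equal scores; larger j10 wins
  expect_identical(as.integer(b2), 2L)
  cand3 <- data.frame(accuracy = c(1, 1), j10 = c(0.5, 0.5),
                      lambda1 = c(20, 10))
  expect_identical(as.integer(select_best_prediction(cand3)), 2L)
})

test_that("mesh I/O round-trips through MSH, VTK and STL", {
  set.seed(45)
  m <- tet_mesh_ellipsoid(c(1, -2, 0.5), c(7, 6, 5), h = 2.5)
  m$surface <- boundary_faces(m)
  f1 <- withr::local_tempfile(fileext = ".msh")
  write_mesh(m, f1)
  r1 <- read_mesh(f1)
  expect_equal(r1$nodes, m$nodes, tolerance = 1e-15)
  expect_identical(r1$tets, m$tets)
  expect_identical(r1$surface, m$surface)
  f2 <- withr::local_tempfile(fileext = ".vtk")
  write_mesh(m, f2, point_data = list(dist = rowSums(m$nodes^2)))
  r2 <- read_mesh(f2)
  expect_equal(r2$nodes, m$nodes, tolerance = 1e-15)
  expect_identical(r2$tets, m$tets)
  expect_true(any(grepl("SCALARS dist", readLines(f2))))
  s <- sphere_surface_mesh(radius = 2, n = 6)
  f3 <- withr::local_tempfile(fileext = ".stl")
  write_stl(s$nodes, s$triangles, f3)
  r3 <- read_stl(f3)
  # the triangle soup (per-face vertex coordinates) is preserved exactly up
  # to the STL text precision; vertex indexing may differ
  soup <- function(nodes, tris) {
    m <- cbind(nodes[tris[, 1], ], nodes[tris[, 2], ], nodes[tris[, 3], ])
    round(m[do.call(order, as.data.frame(m)), ], 9)
  }
  expect_equal(soup(r3$nodes, r3$triangles), soup(s$nodes, s$triangles),
               tolerance = 1e-9)
  expect_identical(nrow(r3$triangles), nrow(s$triangles))
})
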