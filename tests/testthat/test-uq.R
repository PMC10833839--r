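test_that("parameter densities integrate to one and behave as documented", {
  u <- pdf_spec("uniform", bounds = c(0, 1000))
  expect_equal(pdf_eval(u, c(0, 500, 1000)), rep(0.001, 3))
  expect_identical(pdf_eval(u, c(-1, 1001)), c(0, 0))
  g <- pdf_spec("truncated_gaussian", mean = 20, sd = 4, bounds = c(8, 32))
  expect_gt(pdf_eval(g, 20), pdf_eval(g, 8))
  for (spec in list(u, g)) {
    q <- stats::integrate(function(x) pdf_eval(spec, x), spec$bounds[1],
                          spec$bounds[2], rel.tol = 1e-10)
    expect_equal(q$value, 1, tolerance = 1e-8)
  }
  # inverse-CDF sampling stays in bounds and matches the density shape
  set.seed(50)
  s <- pdf_sample(g, 5000)
  expect_true(all(s >= 8 & s <= 32))
  expect_equal(mean(s), 20, tolerance = 0.15)
})

test_that("Delaunay triangulation satisfies the empty-circumcircle property", {
  for (s in 1:4) {
    set.seed(s)
    n <- 25 + 10 * s
    pts <- cbind(runif(n), runif(n) * c(1, 1000)[s %% 2 + 1])
    tr <- delaunay_triangulate(pts)
    # verify in the same range-normalized coordinates the builder uses
    ctr <- colMeans(pts)
    scl <- apply(pts, 2, function(x) diff(range(x)))
    pn <- sweep(sweep(pts, 2, ctr), 2, scl, "/")
    worst <- 0
    for (t in seq_len(nrow(tr))) {
      others <- setdiff(seq_len(n), tr[t, ])
      for (i in others)
        worst <- max(worst, incircle_oracle(pn[tr[t, 1], ], pn[tr[t, 2], ],
                                            pn[tr[t, 3], ], pn[i, ]))
      expect_lt(worst, 1e-9)
    }
    # triangles tile the convex hull exactly
    hull <- pts[grDevices::chull(pts), ]
    expect_equal(sum(tri_areas(pts, tr)), polygon_area(hull),
                 tolerance = 1e-9)
  }
  expect_error(delaunay_triangulate(rbind(c(0, 0), c(1, 1))), "at least 3")
  expect_error(delaunay_triangulate(rbind(c(0, 0), c(1, 1), c(0, 0))),
               "duplicate")
  expect_error(delaunay_triangulate(cbind(0:4, 0:4)), "collinear")
})

test_that("initial tessellations have the documented shape and determinism", {
  sp <- unit_square_space()
  q <- analytic_qoi("quadratic")
  t3 <- initial_tessellation(sp, 3, q, seed = 1, include_corners = FALSE)
  expect_identical(nrow(t3$triangles), 1L)
  t4 <- new_tessellation(space_corners(sp), q(space_corners(sp)), sp)
  expect_identical(nrow(t4$triangles), 2L)
  expect_equal(sum(tri_areas(t4$vertices, t4$triangles)), 1)
  a <- initial_tessellation(sp, 15, q, seed = 42)
  b <- initial_tessellation(sp, 15, q, seed = 42)
  expect_identical(a$vertices, b$vertices)
  expect_identical(a$triangles, b$triangles)
  # corners guarantee full coverage of the domain
  expect_equal(sum(tri_areas(a$vertices, a$triangles)), 1, tolerance = 1e-12)
})

test_that("the metamodel interpolates exactly where it should", {
  sp <- unit_square_space()
  qa <- analytic_qoi("affine")
  tess <- initial_tessellation(sp, 12, qa, seed = 2)
  # vertex values are reproduced exactly
  expect_equal(metamodel_eval(tess, tess$vertices), tess$values)
  # affine functions are reproduced exactly anywhere
  set.seed(51)
  pts <- cbind(runif(100), runif(100))
  expect_lt(max(abs(metamodel_eval(tess, pts) - qa(pts))), 1e-12)
  expect_error(metamodel_eval(tess, c(2, 2)), "outside")
  # quadratic at a centroid equals the hand-computed barycentric average
  qq <- analytic_qoi("quadratic")
  tq <- new_tessellation(rbind(c(0, 0), c(1, 0), c(0, 1)),
                         qq(rbind(c(0, 0), c(1, 0), c(0, 1))), sp)
  cen <- c(1, 1) / 3
  expect_equal(metamodel_eval(tq, cen), mean(tq$values), tolerance = 1e-12)
})

test_that("the L1 interpolation error matches closed-form integration", {
  sp <- unit_square_space()
  qa <- analytic_qoi("affine")
  ta <- initial_tessellation(sp, 10, qa, seed = 3)
  expect_lt(interpolation_error_l1(ta, qa), 1e-12)
  # Q = l1^2 on the square split into two unit right triangles:
  # dense-grid quadrature as the independent integration oracle
  q1 <- function(l) {
    l <- if (is.null(dim(l))) matrix(l, ncol = 2) else l
    l[, 1]^2
  }
  tq <- new_tessellation(space_corners(sp), q1(space_corners(sp)), sp)
  got <- interpolation_error_l1(tq, q1, n_mc = 40000L)
  g <- as.matrix(expand.grid(x = seq(0.0005, 0.9995, by = 0.001),
                             y = seq(0.0025, 0.9975, by = 0.005)))
  oracle <- mean(abs(q1(g) - metamodel_eval(tq, g)))
  expect_equal(got, oracle, tolerance = 0.02)
  # refining a convex QoI never increases the error
  qq <- analytic_qoi("quadratic")
  tess <- initial_tessellation(sp, 8, qq, seed = 4)
  errs <- interpolation_error_l1(tess, qq)
  for (r in 1:4) {
    met <- optimal_metric(tess, sp, budget = 200)
    tess <- refine(tess, met, 8, qq, seed = r)
    errs <- c(errs, interpolation_error_l1(tess, qq))
  }
  expect_true(all(diff(errs) <= 1e-12))
})

test_that("the Hessian estimator recovers quadratic curvature exactly", {
  sp <- unit_square_space()
  qA <- function(l) {
    l <- if (is.null(dim(l))) matrix(l, ncol = 2) else l
    drop(2 * l[, 1]^2 + 2 * l[, 1] * l[, 2] + 3 * l[, 2]^2)
  }
  tess <- initial_tessellation(sp, 20, qA, seed = 5)
  for (v in c(1, 7, 15)) {
    H <- estimate_qoi_hessian(tess, v)
    expect_lt(max(abs(H - rbind(c(4, 2), c(2, 6)))), 1e-6)
  }
  ta <- initial_tessellation(sp, 20, analytic_qoi("affine"), seed = 6)
  expect_lt(max(abs(estimate_qoi_hessian(ta, 3))), 1e-8)
  tc <- initial_tessellation(sp, 20, function(l) 7, seed = 7)
  expect_lt(max(abs(estimate_qoi_hessian(tc, 3))), 1e-10)
  # anisotropic parameter units do not break the fit
  sp2 <- parameter_space()
  qB <- function(l) {
    l <- if (is.null(dim(l))) matrix(l, ncol = 2) else l
    drop(l[, 1]^2 + (l[, 2] / 100)^2)
  }
  tb <- initial_tessellation(sp2, 25, qB, seed = 8)
  Hb <- estimate_qoi_hessian(tb, 10)
  expect_equal(Hb[1, 1], 2, tolerance = 1e-4)
  expect_equal(Hb[2, 2], 2e-4, tolerance = 1e-4)
})

test_that("the optimal metric scales and specializes as the closed form says", {
  sp <- unit_square_space()
  qq <- analytic_qoi("quadratic")
  tess <- initial_tessellation(sp, 20, qq, seed = 9)
  m100 <- optimal_metric(tess, sp, budget = 100)
  m200 <- optimal_metric(tess, sp, budget = 200)
  for (i in seq_along(m100)) {
    # constant Hessian + uniform pdf: spatially constant, isotropic metric
    expect_lt(max(abs(m100[[i]] - m100[[1]])), 1e-6 * max(abs(m100[[1]])))
    expect_equal(m100[[i]][1, 1], m100[[i]][2, 2], tolerance = 1e-8)
    # doubling the budget doubles the metric (factor C^(2/n), n = 2)
    expect_equal(m200[[i]], 2 * m100[[i]], tolerance = 1e-12)
    ev <- eigen(m100[[i]], symmetric = TRUE, only.values = TRUE)$values
    expect_true(all(ev > 0))
  }
  # flat QoI falls back to a uniform metric with a warning
  tf <- initial_tessellation(sp, 15, function(l) 1, seed = 10)
  expect_warning(mf <- optimal_metric(tf, sp, budget = 50), "zero")
  expect_equal(mf[[1]], 50 * diag(2), tolerance = 1e-9)
})

test_that("the optimal-metric error estimate matches independent quadrature", {
  sp <- unit_square_space()
  qq <- analytic_qoi("quadratic")
  tess <- initial_tessellation(sp, 40, qq, seed = 11)
  # closed form for Q = l1^2 + l2^2, uniform pdf: |H| = diag(2,2),
  # I = integral det(2 I)^(1/4) = sqrt(2), E = 2 * C^-1 * I^2 = 4 / C
  e100 <- error_on_metric(sp, tess, 100)
  expect_equal(e100, 0.04, tolerance = 0.02)
  expect_equal(error_on_metric(sp, tess, 200) / e100, 0.5, tolerance = 1e-9)
  # exactly zero Hessian field gives a zero estimate
  zf <- rep(list(matrix(0, 2, 2)), nrow(tess$vertices))
  expect_equal(error_on_metric(sp, zf, 100, tess = tess), 0)
})

test_that("refinement follows the metric anisotropically", {
  sp <- unit_square_space()
  qq <- analytic_qoi("quadratic")
  # uniform 4x4 grid
  g <- as.matrix(expand.grid(x = seq(0, 1, by = 1 / 3),
                             y = seq(0, 1, by = 1 / 3)))
  tess <- new_tessellation(g, qq(g), sp)
  iso <- rep(list(diag(2)), nrow(g))
  r1 <- refine(tess, iso, 4, qq, seed = 1)
  expect_identical(nrow(r1$vertices), nrow(g) + 4L)
  expect_equal(sum(tri_areas(r1$vertices, r1$triangles)), 1,
               tolerance = 1e-12)
  # with an isotropic metric the longest edges (cell diagonals) are split
  # first: inserted midpoints are cell centers at odd multiples of 1/6
  newpts <- r1$vertices[-(seq_len(nrow(g))), , drop = FALSE]
  expect_true(all(abs(newpts %% (1 / 3) - 1 / 6) < 1e-9))
  # anisotropic metric: edges with an axis-1 extent measure ~10x longer, so
  # every split edge carries axis-1 extent and no pure axis-2 edge is split
  aniso <- rep(list(diag(c(100, 1))), nrow(g))
  r2 <- refine(tess, aniso, 6, qq, seed = 2)
  newpts2 <- r2$vertices[-(seq_len(nrow(g))), , drop = FALSE]
  # bisected midpoints of axis-1-extended edges have x at odd multiples of 1/6
  expect_true(all(abs(newpts2[, 1] %% (1 / 3) - 1 / 6) < 1e-9))
  # brute-force metric lengths confirm the ordering the refiner used
  elen <- function(e) sqrt(100 * e[1]^2 + e[2]^2)
  expect_gt(elen(c(1 / 3, 0)), elen(c(0, 1 / 3)))
  expect_gt(elen(c(1 / 3, 1 / 3)), elen(c(0, 1 / 3)))
})

test_that("adaptation is exact for affine QoIs and respects its budget", {
  sp <- unit_square_space()
  qa <- analytic_qoi("affine")
  r <- adapt(sp, qa, adapt_config(budget = 40, n_adap = 3, n0 = 10,
                                  seed = 3))
  expect_lt(interpolation_error_l1(r$tessellation, qa), 1e-10)
  expect_lte(r$n_evaluations, 40L)
  expect_equal(r$mean, qa(matrix(c(0.5, 0.5), 1)), tolerance = 0.02)
  # determinism of the whole loop
  r2 <- adapt(sp, qa, adapt_config(budget = 40, n_adap = 3, n0 = 10,
                                   seed = 3))
  expect_identical(r$tessellation$vertices, r2$tessellation$vertices)
})

test_that("adaptation concentrates samples where the QoI curves", {
  sp <- unit_square_space()
  qb <- analytic_qoi("gaussian_bump") # bump centred in the (0.75, 0.75) quadrant
  r <- adapt(sp, qb, adapt_config(budget = 100, n_adap = 4, n0 = 12,
                                  seed = 1))
  v <- r$tessellation$vertices
  in_bump <- sum(v[, 1] > 0.5 & v[, 2] > 0.5)
  in_opp <- sum(v[, 1] < 0.5 & v[, 2] < 0.5)
  expect_gte(in_bump, 2 * in_opp)
})

test_that("failed QoI evaluations are excluded with a warning", {
  sp <- unit_square_space()
  flaky <- function(l) {
    if (l[1] > 0.45 && l[1] < 0.55) stop("registration failed")
    sum(l^2)
  }
  w <- testthat::capture_warnings(
    r <- adapt(sp, flaky, adapt_config(budget = 30, n_adap = 2, n0 = 10,
                                       seed = 6)))
  expect_true(any(grepl("failed", w)))
  expect_true(all(is.finite(r$tessellation$values)))
})
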