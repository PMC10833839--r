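test_that("ffd_apply matches the naive full-lattice summation oracle", {
  set.seed(10)
  T1 <- random_ffd()
  pts <- matrix(runif(60, 2, 12), ncol = 3)
  expect_lt(max(abs(ffd_apply(T1, pts) - ffd_brute(T1, pts))), 1e-12)
  # with a pre-affine component
  T2 <- random_ffd(pre_affine = affine_transform(diag(c(1.1, 0.9, 1)),
                                                 c(1, -2, 0.5)))
  expect_lt(max(abs(ffd_apply(T2, pts) - ffd_brute(T2, pts))), 1e-12)
})

test_that("zero coefficients give the identity, constants a pure translation", {
  T0 <- ffd_transform(c(-10, -10, -10), c(5, 5, 5), c(8, 8, 8))
  set.seed(11)
  pts <- matrix(runif(3000, 0, 14), ncol = 3)
  expect_identical(ffd_apply(T0, pts), pts)
  d <- c(1.5, -2.25, 0.75)
  Tt <- ffd_transform(c(-10, -10, -10), c(5, 5, 5), c(8, 8, 8),
                      matrix(rep(d, each = 8^3), ncol = 3))
  expect_lt(max(abs(ffd_apply(Tt, pts) - sweep(pts, 2, d, "+"))), 1e-10)
})

test_that("points outside the lattice support are rejected", {
  T0 <- ffd_transform(c(0, 0, 0), c(5, 5, 5), c(4, 4, 4))
  expect_error(ffd_apply(T0, c(100, 0, 0)), "support")
  expect_error(ffd_apply(T0, c(1, 1, 1)), "support") # margin row needed
})

test_that("jacobian_det matches closed forms and finite differences", {
  T0 <- ffd_transform(c(-10, -10, -10), c(5, 5, 5), c(8, 8, 8))
  set.seed(12)
  pts <- matrix(runif(60, 2, 12), ncol = 3)
  expect_equal(jacobian_det(T0, pts), rep(1, 20))
  s <- c(1.4, 0.7, 1.1)
  Ts <- ffd_transform(c(-30, -30, -30), c(10, 10, 10), c(8, 8, 8),
                      pre_affine = affine_transform(diag(s)))
  expect_equal(jacobian_det(Ts, pts), rep(prod(s), 20), tolerance = 1e-12)
  T1 <- random_ffd()
  jd <- jacobian_det(T1, pts)
  fd <- vapply(seq_len(nrow(pts)), function(i) jacdet_fd(T1, pts[i, ]),
               numeric(1))
  expect_lt(max(abs(jd - fd) / abs(fd)), 1e-4)
})

test_that("bending energy is zero for affine maps and matches finite differences", {
  set.seed(13)
  pts <- matrix(runif(30, 2, 12), ncol = 3)
  Taff <- ffd_transform(c(-10, -10, -10), c(5, 5, 5), c(8, 8, 8),
                        pre_affine = affine_transform(
                          diag(c(2, 0.5, 1.3)) + 0.1, c(3, -1, 2)))
  expect_identical(bending_energy(Taff, pts), 0)
  d <- c(4, -3, 2)
  Tt <- ffd_transform(c(-10, -10, -10), c(5, 5, 5), c(8, 8, 8),
                      matrix(rep(d, each = 8^3), ncol = 3))
  expect_equal(bending_energy(Tt, pts), 0, tolerance = 1e-20)
  # single perturbed control point and a fully random lattice
  Tp <- ffd_transform(c(-10, -10, -10), c(5, 5, 5), c(8, 8, 8))
  Tp$coefficients[100, ] <- c(2, -1, 1.5)
  for (Tc in list(Tp, random_ffd())) {
    be <- bending_energy(Tc, pts)
    fd <- mean(vapply(seq_len(nrow(pts)), function(i)
      hess_frob2_fd(Tc, pts[i, ]), numeric(1)))
    expect_lt(abs(be - fd) / fd, 1e-3)
  }
  expect_error(bending_energy(Tp, matrix(numeric(0), 0, 3)), "empty")
})

test_that("symmetric lattices are exactly mirror-symmetric about the plane", {
  dom <- volume_image(array(0, c(51, 41, 41)), c(2, 2.5, 2.5),
                      c(-50, -50, -50))
  for (sp in c(26.21, 8, 15.5)) {
    g <- build_symmetric_grid(dom, sp, plane_axis = 1L)
    cp <- control_points(g)
    plane <- mid_plane_coord(dom, 1L)
    refl <- 2 * plane - cp[, 1]
    # every mirrored control coordinate is again a control coordinate
    expect_lt(max(abs(sort(unique(refl)) - sort(unique(cp[, 1])))), 1e-12)
    # lattice covers the domain with the cubic support margin
    b <- volume_bounds(dom)
    expect_true(all(cp[1, ] <= b[1, ] - g$control_spacing))
    pts <- voxel_centers(dom)[c(1, 10000, nrow(cp)), , drop = FALSE]
    expect_identical(ffd_apply(g, pts), pts) # zero coefficients: identity
  }
})

test_that("a single-span domain still yields a valid lattice", {
  dom <- volume_image(array(0, c(5, 5, 5)), c(1, 1, 1))
  g <- build_symmetric_grid(dom, 100, 1L)
  pts <- voxel_centers(dom)
  expect_identical(ffd_apply(g, pts), pts)
})

test_that("lattice subdivision reproduces the coarse field (continuation)", {
  set.seed(14)
  T1 <- random_ffd(pre_affine = affine_transform(diag(c(1.05, 1, 0.95)),
                                                 c(0.5, 0, -0.5)))
  fine <- subdivide_ffd(T1)
  expect_equal(fine$control_spacing, T1$control_spacing / 2)
  pts <- matrix(runif(900, 2, 12), ncol = 3)
  expect_lt(max(abs(ffd_apply(T1, pts) - ffd_apply(fine, pts))), 1e-10)
  # twice-subdivided as used across the three resolution levels
  fine2 <- subdivide_ffd(fine)
  expect_lt(max(abs(ffd_apply(T1, pts) - ffd_apply(fine2, pts))), 1e-10)
})

test_that("landmark affine fit recovers known similarity maps", {
  set.seed(15)
  fp <- matrix(runif(63, -20, 20), ncol = 3)
  lf <- landmark_set(1:21, paste0("L", 1:21), fp)
  # moving = fixed: identity, zero residual
  A0 <- fit_affine_landmarks(lf, lf)
  expect_equal(A0$matrix, diag(3), tolerance = 1e-9)
  expect_lt(attr(A0, "residual"), 1e-9)
  # known rotation / anisotropic scale / translation
  th <- 0.35
  R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  M <- R %*% diag(c(1.3, 0.8, 1.1)); tt <- c(5, -3, 2)
  lm2 <- landmark_set(1:21, paste0("L", 1:21), sweep(fp %*% t(M), 2, tt, "+"))
  A <- fit_affine_landmarks(lf, lm2, subset = c(2, 4, 7, 20, 21))
  expect_lt(attr(A, "residual"), 1e-9)
  expect_lt(max(abs(A$matrix - M)), 1e-7)
  expect_lt(max(abs(A$translation - tt)), 1e-7)
  expect_error(fit_affine_landmarks(lf, lm2, subset = 1:2), "at least 3")
})

test_that("noisy affine fit matches an independent optimizer on the same objective", {
  set.seed(16)
  fp <- matrix(runif(30, -20, 20), ncol = 3)
  th <- 0.2
  R <- rbind(c(1, 0, 0), c(0, cos(th), -sin(th)), c(0, sin(th), cos(th)))
  M <- R %*% diag(c(1.1, 0.95, 1.2))
  mp <- sweep(fp %*% t(M), 2, c(2, 1, -4), "+") +
    matrix(rnorm(30, sd = 0.5), ncol = 3)
  lf <- landmark_set(1:10, paste0("L", 1:10), fp)
  lm2 <- landmark_set(1:10, paste0("L", 1:10), mp)
  A <- fit_affine_landmarks(lf, lm2)
  mapped <- transform_points(A, fp)
  res <- mean(sqrt(rowSums((mapped - mp)^2)))
  expect_equal(res, attr(A, "residual"), tolerance = 1e-12)
  # independent oracle: 12-parameter direct search over (R(angles), s, t)
  rot <- function(a) {
    Rx <- rbind(c(1, 0, 0), c(0, cos(a[1]), -sin(a[1])),
                c(0, sin(a[1]), cos(a[1])))
    Ry <- rbind(c(cos(a[2]), 0, sin(a[2])), c(0, 1, 0),
                c(-sin(a[2]), 0, cos(a[2])))
    Rz <- rbind(c(cos(a[3]), -sin(a[3]), 0), c(sin(a[3]), cos(a[3]), 0),
                c(0, 0, 1))
    Rz %*% Ry %*% Rx
  }
  obj <- function(par) {
    Mm <- rot(par[1:3]) %*% diag(exp(par[4:6]))
    mean(sqrt(rowSums((sweep(fp %*% t(Mm), 2, par[7:9], "+") - mp)^2)))
  }
  o <- stats::optim(c(0, 0, th, 0, 0, 0, 2, 1, -4), obj,
                    method = "Nelder-Mead",
                    control = list(maxit = 20000, reltol = 1e-15))
  o <- stats::optim(o$par, obj, method = "Nelder-Mead",
                    control = list(maxit = 20000, reltol = 1e-15))
  expect_lt(abs(res - o$value), 1e-6)
})

test_that("coplanar landmarks warn and still produce a usable fit", {
  set.seed(17)
  fp <- cbind(0, matrix(runif(12, -10, 10), ncol = 2))
  lf <- landmark_set(1:6, paste0("L", 1:6), fp)
  lm2 <- landmark_set(1:6, paste0("L", 1:6),
                      sweep(fp, 2, c(0, 1, -2), "+"))
  expect_warning(A <- fit_affine_landmarks(lf, lm2), "coplanar")
  expect_lt(attr(A, "residual"), 1e-6)
})

test_that("transform serialization round-trips bit-exactly", {
  set.seed(18)
  T1 <- random_ffd(pre_affine = affine_transform(diag(3) + rnorm(9, sd = 0.01),
                                                 rnorm(3)))
  f <- withr::local_tempfile(fileext = ".json")
  write_transform(T1, f)
  T2 <- read_transform(f)
  expect_identical(T2$coefficients, T1$coefficients)
  expect_identical(T2$pre_affine$matrix, T1$pre_affine$matrix)
  expect_identical(T2$control_origin, T1$control_origin)
  A <- affine_transform(diag(3) + rnorm(9, sd = 0.01), rnorm(3))
  write_transform(A, f)
  expect_identical(read_transform(f)$matrix, A$matrix)
})
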