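#' Affine transform (matrix + translation)
#'
#' Represents the global translation/rotation/scaling component of the
#' mapping, applied as `y = M x + t` (world mm).
#'
#' @param matrix invertible 3 x 3 matrix.
#' @param translation numeric 3-vector (mm).
#' @return An object of class `affine_transform`.
#' @export
affine_transform <- function(matrix = diag(3), translation = c(0, 0, 0)) {
  matrix <- unname(as.matrix(matrix))
  if (!all(dim(matrix) == c(3, 3))) stop("affine matrix must be 3x3")
  if (abs(det(matrix)) < 1e-12) stop("affine matrix must be invertible")
  structure(list(matrix = matrix, translation = as.numeric(translation)),
            class = "affine_transform")
}

#' Free-form deformation transform
#'
#' Cubic B-spline FFD: `T(x) = A x + t + sum_k B3((x - c_k) / h) mu_k`, where
#' the `c_k` are control points of a regular axis-aligned lattice and `mu_k`
#' their 3D displacement coefficients (mm). The displacement field is
#' evaluated at the *untransformed* point `x`, so the lattice lives in the
#' fixed-image domain.
#'
#' @param control_origin world position (mm) of the first control point.
#' @param control_spacing lattice spacing per axis (mm).
#' @param control_shape integer 3-vector of control counts per axis.
#' @param coefficients `prod(control_shape) x 3` matrix of displacements (mm),
#'   control points in column-major (axis-1 fastest) order. Defaults to zero.
#' @param pre_affine an [affine_transform()]; identity by default.
#' @return An object of class `ffd_transform`.
#' @export
ffd_transform <- function(control_origin, control_spacing, control_shape,
                          coefficients = NULL, pre_affine = affine_transform()) {
  control_shape <- as.integer(control_shape)
  if (any(control_shape < 4L))
    stop("ffd_transform: need at least 4 control points per axis")
  n <- prod(control_shape)
  if (is.null(coefficients)) coefficients <- matrix(0, n, 3)
  coefficients <- unname(as.matrix(coefficients))
  if (nrow(coefficients) != n || ncol(coefficients) != 3L)
    stop("ffd_transform: coefficients must be prod(control_shape) x 3")
  if (!all(is.finite(coefficients)))
    stop("ffd_transform: coefficients must be finite")
  structure(list(control_origin = as.numeric(control_origin),
                 control_spacing = as.numeric(control_spacing),
                 control_shape = control_shape,
                 coefficients = coefficients,
                 pre_affine = pre_affine),
            class = "ffd_transform")
}

#' @export
print.ffd_transform <- function(x, ...) {
  cat(sprintf("<ffd_transform> lattice %s, spacing %s mm, max |mu| %.3g mm\n",
              paste(x$control_shape, collapse = "x"),
              paste(signif(x$control_spacing, 4), collapse = ", "),
              max(abs(x$coefficients))))
  invisible(x)
}

as_point_matrix <- function(x) {
  if (is.null(dim(x))) matrix(x, ncol = 3) else as.matrix(x)
}

#' Apply a transform to points
#'
#' Generic point map used throughout: `NULL` is the identity, functions are
#' called directly, [affine_transform()] and [ffd_transform()] are applied
#' analytically.
#'
#' @param transform the transform (or `NULL`).
#' @param pts N x 3 matrix of world points (mm).
#' @return N x 3 matrix of mapped points.
#' @export
transform_points <- function(transform, pts) {
  pts <- as_point_matrix(pts)
  if (is.null(transform)) return(pts)
  if (is.function(transform)) return(as_point_matrix(transform(pts)))
  UseMethod("transform_points")
}

#' @export
transform_points.affine_transform <- function(transform, pts) {
  pts <- as_point_matrix(pts)
  sweep(pts %*% t(transform$matrix), 2, transform$translation, "+")
}

#' @export
transform_points.ffd_transform <- function(transform, pts) {
  pts <- as_point_matrix(pts)
  base <- transform_points(transform$pre_affine, pts)
  disp <- cpp_ffd_disp(pts, transform$control_origin,
                       transform$control_spacing, transform$control_shape,
                       transform$coefficients)
  base + disp
}

#' Evaluate an FFD transform at points
#'
#' `T(x) = pre_affine(x) + sum_k B3((x - c_k)/h) mu_k` with tensor-product
#' cubic B-spline weights. Points must lie inside the lattice support.
#'
#' @param transform an [ffd_transform()].
#' @param x a 3-vector or N x 3 matrix of world points (mm).
#' @return mapped point(s), same shape as `x`.
#' @export
ffd_apply <- function(transform, x) {
  single <- is.null(dim(x))
  out <- transform_points(transform, x)
  if (single) drop(out) else out
}

#' Jacobian determinant of an FFD transform
#'
#' `J(x) = det(grad T(x))`, computed from analytic B-spline derivative
#' weights composed with the pre-affine matrix. `J > 0` everywhere means the
#' transform is locally invertible (no folding); `J = 1` is isochoric.
#'
#' @param transform an [ffd_transform()].
#' @param x a 3-vector or N x 3 matrix of world points (mm).
#' @return numeric vector of determinants.
#' @export
jacobian_det <- function(transform, x) {
  pts <- as_point_matrix(x)
  as.numeric(cpp_ffd_jacdet(pts, transform$control_origin,
                            transform$control_spacing,
                            transform$control_shape,
                            transform$coefficients,
                            transform$pre_affine$matrix))
}

#' Bending energy of an FFD transform over a domain
#'
#' Mean over the domain voxels of the squared Frobenius norm of the second
#' spatial derivative tensor of `T` (a 3 x 3 x 3 tensor of all second partial
#' derivatives; the affine part contributes nothing). Penalizes curvature of
#' the deformation; exactly zero for any affine map.
#'
#' @param transform an [ffd_transform()].
#' @param domain a [mask_volume()] (mean over its `TRUE` voxel centers) or an
#'   N x 3 matrix of evaluation points.
#' @return scalar bending energy (1/mm^2).
#' @export
bending_energy <- function(transform, domain) {
  pts <- domain_points(domain)
  if (nrow(pts) == 0L) stop("bending_energy: empty domain")
  cpp_ffd_bend(pts, transform$control_origin, transform$control_spacing,
               transform$control_shape, transform$coefficients,
               FALSE)$energy
}

domain_points <- function(domain) {
  if (inherits(domain, "mask_volume")) {
    voxel_centers(domain)[as.vector(domain$data), , drop = FALSE]
  } else if (inherits(domain, "volume_image")) {
    voxel_centers(domain)
  } else {
    as_point_matrix(domain)
  }
}

#' Build a zero FFD on a lattice symmetric about the mid-sagittal plane
#'
#' Control points are axis-aligned and, along `plane_axis`, mirror-symmetric
#' about the domain's central voxel plane (an odd number of controls, one on
#' the plane). The lattice covers the domain with a two-span cubic-support
#' margin on every side, so the whole domain is inside the valid support and
#' a factor-2 subdivision of the lattice remains valid on it.
#'
#' @param domain a [volume_image()] whose world bounds define the region the
#'   transform must cover.
#' @param spacing lattice spacing (mm), scalar or 3-vector.
#' @param plane_axis axis index of the mid-sagittal plane normal (1..3).
#' @param pre_affine optional [affine_transform()] to embed.
#' @return an [ffd_transform()] with zero coefficients.
#' @export
build_symmetric_grid <- function(domain, spacing, plane_axis = 1L,
                                 pre_affine = affine_transform()) {
  spacing <- rep(as.numeric(spacing), length.out = 3)
  if (any(spacing <= 0)) stop("build_symmetric_grid: spacing must be > 0")
  b <- volume_bounds(domain)
  center <- colMeans(b)
  center[plane_axis] <- mid_plane_coord(domain, plane_axis)
  m <- integer(3); origin <- numeric(3); shape <- integer(3)
  for (a in 1:3) {
    half <- max(b[2, a] - center[a], center[a] - b[1, a])
    m[a] <- ceiling(half / spacing[a]) + 2L
    origin[a] <- center[a] - m[a] * spacing[a]
    shape[a] <- 2L * m[a] + 1L
  }
  ffd_transform(origin, spacing, shape, pre_affine = pre_affine)
}

#' World coordinates of all FFD control points
#' @param transform an [ffd_transform()].
#' @return `prod(control_shape) x 3` matrix (column-major, axis-1 fastest).
#' @export
control_points <- function(transform) {
  d <- transform$control_shape
  ax <- lapply(1:3, function(a)
    transform$control_origin[a] + (seq_len(d[a]) - 1) * transform$control_spacing[a])
  cbind(rep(ax[[1]], times = d[2] * d[3]),
        rep(rep(ax[[2]], each = d[1]), times = d[3]),
        rep(ax[[3]], each = d[1] * d[2]))
}

# 1D cubic B-spline subdivision matrix (two-scale relation, zero extension
# outside the coarse lattice).
subdivision_matrix <- function(K) {
  Kf <- 2L * K - 1L
  S <- matrix(0, Kf, K)
  for (j in seq_len(Kf) - 1L) {
    if (j %% 2L == 0L) {
      k <- j %/% 2L
      for (kk in c(k - 1L, k, k + 1L)) {
        if (kk >= 0L && kk < K)
          S[j + 1L, kk + 1L] <- if (kk == k) 6 / 8 else 1 / 8
      }
    } else {
      k <- (j - 1L) %/% 2L
      for (kk in c(k, k + 1L)) {
        if (kk >= 0L && kk < K) S[j + 1L, kk + 1L] <- 1 / 2
      }
    }
  }
  S
}

#' Subdivide an FFD lattice (coarse to fine, factor 2)
#'
#' Halves the control spacing and applies the cubic B-spline two-scale
#' relation per axis, so the refined transform reproduces the coarse
#' displacement field exactly on the covered domain (up to rounding). Used
#' for multi-resolution continuation.
#'
#' @param transform an [ffd_transform()].
#' @return the refined [ffd_transform()].
#' @export
subdivide_ffd <- function(transform) {
  K <- transform$control_shape
  co <- array(transform$coefficients, c(K, 3L))
  for (axis in 1:3) {
    S <- subdivision_matrix(dim(co)[axis])
    co <- apply_matrix_along(co, S, axis)
  }
  ffd_transform(transform$control_origin, transform$control_spacing / 2,
                2L * K - 1L, matrix(co, ncol = 3),
                pre_affine = transform$pre_affine)
}

# multiply 4D array by matrix M along the given axis
apply_matrix_along <- function(arr, M, axis) {
  d <- dim(arr)
  perm <- c(axis, setdiff(seq_along(d), axis))
  a <- aperm(arr, perm)
  da <- dim(a)
  a <- M %*% matrix(a, nrow = da[1])
  dim(a) <- c(nrow(M), da[-1])
  aperm(a, order(perm))
}

# ---------------------------------------------------------------------------
# Affine initialization from paired landmarks

euler_to_rotation <- function(theta) {
  cx <- cos(theta[1]); sx <- sin(theta[1])
  cy <- cos(theta[2]); sy <- sin(theta[2])
  cz <- cos(theta[3]); sz <- sin(theta[3])
  Rx <- rbind(c(1, 0, 0), c(0, cx, -sx), c(0, sx, cx))
  Ry <- rbind(c(cy, 0, sy), c(0, 1, 0), c(-sy, 0, cy))
  Rz <- rbind(c(cz, -sz, 0), c(sz, cz, 0), c(0, 0, 1))
  Rz %*% Ry %*% Rx
}

rotation_to_euler <- function(R) {
  # inverse of euler_to_rotation (Z-Y-X intrinsic), gimbal-safe enough for
  # initialization purposes
  sy <- -R[3, 1]
  sy <- max(-1, min(1, sy))
  theta2 <- asin(sy)
  if (abs(cos(theta2)) > 1e-8) {
    theta1 <- atan2(R[3, 2], R[3, 3])
    theta3 <- atan2(R[2, 1], R[1, 1])
  } else {
    theta1 <- atan2(-R[2, 3], R[2, 2])
    theta3 <- 0
  }
  c(theta1, theta2, theta3)
}

#' Fit translation + rotation + anisotropic scaling to paired landmarks
#'
#' Finds the map `y = R diag(s) x + t` minimizing the mean Euclidean distance
#' from the mapped fixed-subset landmarks to the moving-subset landmarks.
#' Used to initialize the global (affine) component of the registration from
#' a small, manually chosen landmark subset.
#'
#' @param fixed,moving paired [landmark_set()]s (same ids, same order).
#' @param subset integer ids to use; default all shared ids.
#' @return an [affine_transform()] with attribute `residual` (mean distance,
#'   mm).
#' @export
fit_affine_landmarks <- function(fixed, moving, subset = fixed$id) {
  if (!all(subset %in% fixed$id) || !all(subset %in% moving$id))
    stop("fit_affine_landmarks: subset ids missing from a landmark set")
  fp <- landmark_points(fixed)[match(subset, fixed$id), , drop = FALSE]
  mp <- landmark_points(moving)[match(subset, moving$id), , drop = FALSE]
  n <- nrow(fp)
  if (n < 3L) stop("fit_affine_landmarks: need at least 3 landmarks")
  fc <- colMeans(fp); mc <- colMeans(mp)
  X <- sweep(fp, 2, fc); Y <- sweep(mp, 2, mc)
  sv <- svd(X)
  coplanar <- sv$d[3] < 1e-8 * sv$d[1]
  if (coplanar)
    warning("fit_affine_landmarks: landmarks are coplanar; ",
            "scaling along the plane normal is unidentifiable ",
            "(regularized fit)")
  # least-squares full affine on centered points, then project onto R diag(s)
  A <- if (coplanar) {
    t(solve(crossprod(X) + 1e-8 * sv$d[1]^2 * diag(3), crossprod(X, Y)))
  } else {
    t(solve(crossprod(X), crossprod(X, Y)))
  }
  s0 <- sqrt(colSums(A^2)); s0[s0 < 1e-12] <- 1
  R0 <- A %*% diag(1 / s0)
  # orthonormalize the rotation guess
  svr <- svd(R0)
  R0 <- svr$u %*% t(svr$v)
  if (det(R0) < 0) {
    svr$u[, 3] <- -svr$u[, 3]
    R0 <- svr$u %*% t(svr$v)
  }
  M0 <- R0 %*% diag(s0)
  par0 <- c(rotation_to_euler(R0), log(s0), mc - as.vector(M0 %*% fc))
  objective <- function(par) {
    M <- euler_to_rotation(par[1:3]) %*% diag(exp(par[4:6]))
    mapped <- sweep(fp %*% t(M), 2, par[7:9], "+")
    mean(sqrt(rowSums((mapped - mp)^2)))
  }
  fit <- stats::optim(par0, objective, method = "Nelder-Mead",
                      control = list(maxit = 10000, reltol = 1e-15))
  fit <- stats::optim(fit$par, objective, method = "Nelder-Mead",
                      control = list(maxit = 10000, reltol = 1e-15))
  M <- euler_to_rotation(fit$par[1:3]) %*% diag(exp(fit$par[4:6]))
  out <- affine_transform(M, fit$par[7:9])
  attr(out, "residual") <- objective(fit$par)
  out
}

# ---------------------------------------------------------------------------
# Serialization (documented JSON, bit-exact round trip)

#' Write a transform to JSON
#'
#' Full-precision JSON serialization of affine or FFD transforms; reading the
#' file back with [read_transform()] reproduces the object bit-exactly.
#'
#' @param transform an [affine_transform()] or [ffd_transform()].
#' @param path output path.
#' @export
write_transform <- function(transform, path) {
  obj <- if (inherits(transform, "affine_transform")) {
    list(type = "affine", matrix = as.vector(transform$matrix),
         translation = transform$translation)
  } else if (inherits(transform, "ffd_transform")) {
    list(type = "ffd",
         control_origin = transform$control_origin,
         control_spacing = transform$control_spacing,
         control_shape = transform$control_shape,
         coefficients = as.vector(transform$coefficients),
         pre_affine = list(matrix = as.vector(transform$pre_affine$matrix),
                           translation = transform$pre_affine$translation))
  } else stop("write_transform: unsupported transform class")
  # 17 significant digits round-trip IEEE doubles bit-exactly
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = I(17))
  invisible(path)
}

#' Read a transform written by [write_transform()]
#' @param path JSON file path.
#' @return an [affine_transform()] or [ffd_transform()].
#' @export
read_transform <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (identical(obj$type, "affine")) {
    affine_transform(matrix(obj$matrix, 3, 3), obj$translation)
  } else if (identical(obj$type, "ffd")) {
    ffd_transform(obj$control_origin, obj$control_spacing, obj$control_shape,
                  matrix(obj$coefficients, ncol = 3),
                  pre_affine = affine_transform(
                    matrix(obj$pre_affine$matrix, 3, 3),
                    obj$pre_affine$translation))
  } else stop("read_transform: unknown transform type")
}
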