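#' Specification of the synthetic head/neck phantom
#'
#' Describes a CT-like scene standing in for a head/neck exam: a bright bone
#' shell (ellipsoid) enclosing a mid-intensity soft-tissue body containing an
#' air cavity bounded below by a tongue-like organ. The scene is
#' mirror-symmetric about the central plane of the first axis. A smooth,
#' mirror-symmetric ground-truth FFD with bounded maximum displacement
#' relates the pair; the moving volume shows the same scene geometry carried
#' through that deformation.
#'
#' @param shape grid size, default `c(64, 64, 64)`.
#' @param spacing voxel spacing (mm), default 2 mm isotropic.
#' @param bone_radii outer semi-axes of the bone shell (mm).
#' @param bone_thickness shell thickness (mm).
#' @param bone_hu,soft_hu,organ_hu,air_hu intensities (HU) of the strata;
#'   defaults 700 / 40 / 55 / -1000 (representative clinical values).
#' @param cavity_center,cavity_radii air cavity geometry (mm).
#' @param organ_center,organ_radii tongue-analogue ellipsoid (mm), strictly
#'   inside the soft tissue, bounding the cavity from below.
#' @param n_landmarks number of paired landmarks on the bone shell (>= 5;
#'   two are placed off the midline so the affine-initialization subset is
#'   non-coplanar).
#' @param deform_spacing control spacing (mm) of the ground-truth FFD;
#'   coarse (>= 20 mm) so the registration lattice can represent it.
#' @param max_displacement maximum ground-truth displacement magnitude (mm).
#' @param noise_sd additive Gaussian noise (HU) applied to the moving volume
#'   after deformation (mirrored so the volume stays exactly symmetric).
#' @param n_surface_points evaluation points sampled on the deformed organ's
#'   upper surface.
#' @param translation optional 3-vector (mm): instead of a random smooth
#'   deformation, use this exact rigid translation as the ground truth
#'   (constant B-spline coefficients; a nonzero first component breaks the
#'   pair's mirror symmetry and is allowed only for such controlled tests).
#' @param seed RNG seed; generation is fully deterministic given the seed.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(shape = c(64L, 64L, 64L), spacing = c(2, 2, 2),
                         bone_radii = c(48, 56, 52), bone_thickness = 6,
                         bone_hu = 700, soft_hu = 40, organ_hu = 55,
                         air_hu = -1000,
                         cavity_center = c(0, 14, -4),
                         cavity_radii = c(22, 20, 16),
                         organ_center = c(0, 12, -22),
                         organ_radii = c(18, 16, 14),
                         n_landmarks = 21L, deform_spacing = 24,
                         max_displacement = 8, noise_sd = 10,
                         n_surface_points = 608L, translation = NULL,
                         seed = 1L) {
  stopifnot(n_landmarks >= 5L, deform_spacing > 0, max_displacement >= 0)
  structure(list(shape = as.integer(shape), spacing = as.numeric(spacing),
                 bone_radii = bone_radii, bone_thickness = bone_thickness,
                 bone_hu = bone_hu, soft_hu = soft_hu, organ_hu = organ_hu,
                 air_hu = air_hu, cavity_center = cavity_center,
                 cavity_radii = cavity_radii, organ_center = organ_center,
                 organ_radii = organ_radii,
                 n_landmarks = as.integer(n_landmarks),
                 deform_spacing = deform_spacing,
                 max_displacement = max_displacement, noise_sd = noise_sd,
                 n_surface_points = as.integer(n_surface_points),
                 translation = translation,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

ellipsoid_q <- function(pts, center, radii) {
  ((pts[, 1] - center[1]) / radii[1])^2 +
    ((pts[, 2] - center[2]) / radii[2])^2 +
    ((pts[, 3] - center[3]) / radii[3])^2
}

phantom_scene <- function(spec) {
  inner <- spec$bone_radii - spec$bone_thickness
  function(pts) {
    hu <- rep(spec$air_hu, nrow(pts))
    q_outer <- ellipsoid_q(pts, c(0, 0, 0), spec$bone_radii)
    q_inner <- ellipsoid_q(pts, c(0, 0, 0), inner)
    hu[q_outer <= 1] <- spec$bone_hu
    hu[q_inner <= 1] <- spec$soft_hu
    q_cav <- ellipsoid_q(pts, spec$cavity_center, spec$cavity_radii)
    hu[q_cav <= 1 & q_inner <= 1] <- spec$air_hu
    q_org <- ellipsoid_q(pts, spec$organ_center, spec$organ_radii)
    hu[q_org <= 1] <- spec$organ_hu
    hu
  }
}

# mirror-symmetrize FFD coefficients about the central control plane of
# axis 1: the axis-1 displacement component is odd, the others even
symmetrize_coefficients <- function(coef, shape) {
  co <- array(coef, c(shape, 3L))
  K1 <- shape[1]
  rev1 <- K1:1
  co[, , , 1] <- (co[, , , 1] - co[rev1, , , 1]) / 2
  co[, , , 2] <- (co[, , , 2] + co[rev1, , , 2]) / 2
  co[, , , 3] <- (co[, , , 3] + co[rev1, , , 3]) / 2
  matrix(co, ncol = 3)
}

# invert y = x + disp(x) by fixed-point iteration (the displacement is a
# contraction at the phantom's smoothness/magnitude scales)
invert_ffd_points <- function(transform, y, iters = 30L, tol = 1e-8) {
  x <- y
  for (i in seq_len(iters)) {
    d <- cpp_ffd_disp(x, transform$control_origin, transform$control_spacing,
                      transform$control_shape, transform$coefficients)
    xn <- y - d
    if (max(abs(xn - x)) < tol) { x <- xn; break }
    x <- xn
  }
  x
}

#' Generate a phantom volume pair with known ground-truth deformation
#'
#' Builds the fixed scene analytically, draws a smooth mirror-symmetric
#' ground-truth FFD `T` scaled to the requested maximum displacement
#' (rejecting any draw whose Jacobian is not safely positive), and renders
#' the moving volume by evaluating the scene at `T^{-1}(y)` for every moving
#' voxel center — so `I_moving(T(x)) = I_fixed(x)` holds by construction,
#' with no resampling blur. Landmarks are mapped exactly; symmetric Gaussian
#' noise is added to the moving volume.
#'
#' @param spec a [phantom_spec()].
#' @return list with components `fixed`, `moving` ([volume_image()]s),
#'   `fixed_side`, `moving_side` ([side_label_image()]s), `fixed_landmarks`,
#'   `moving_landmarks` ([landmark_set()]s), `truth` (the ground-truth
#'   [ffd_transform()]), `organ_mesh` (a [tet_mesh()] of the organ, fixed
#'   frame), `surface_points` (moving frame, on the deformed organ's upper
#'   surface), `organ_mask` ([mask_volume()], fixed frame), `eval_points`
#'   (fixed-frame points for withheld-error evaluation), `min_jacobian`,
#'   and `spec`.
#' @export
generate_phantom_pair <- function(spec = phantom_spec()) {
  old_seed <- get0(".Random.seed", globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(spec$seed)

  origin <- -(spec$shape - 1) / 2 * spec$spacing
  template <- volume_image(array(0, spec$shape), spec$spacing, origin)
  centers <- voxel_centers(template)
  scene <- phantom_scene(spec)

  fixed <- template
  fixed$data <- array(scene(centers), spec$shape)

  # ground-truth deformation on a coarse symmetric lattice
  truth <- build_symmetric_grid(template, spec$deform_spacing, 1L)
  nco <- prod(truth$control_shape)
  if (!is.null(spec$translation)) {
    # exact rigid translation via the B-spline partition of unity
    truth$coefficients <- matrix(rep(spec$translation, each = nco), ncol = 3)
  } else {
  coef <- matrix(stats::rnorm(nco * 3), ncol = 3)
  coef <- symmetrize_coefficients(coef, truth$control_shape)
  truth$coefficients <- coef
  if (spec$max_displacement > 0) {
    disp <- cpp_ffd_disp(centers, truth$control_origin, truth$control_spacing,
                         truth$control_shape, truth$coefficients)
    mx <- max(sqrt(rowSums(disp^2)))
    truth$coefficients <- truth$coefficients * (spec$max_displacement / mx)
  } else {
    truth$coefficients[] <- 0
  }
  }
  head_sel <- ellipsoid_q(centers, c(0, 0, 0), spec$bone_radii) <= 1
  jd <- jacobian_det(truth, centers[head_sel, , drop = FALSE])
  min_j <- min(jd)
  if (min_j <= 0)
    stop("generate_phantom_pair: requested deformation folds (min J = ",
         signif(min_j, 3), "); reduce max_displacement or increase ",
         "deform_spacing")

  # moving volume: scene at the inverse-mapped voxel centers
  xinv <- invert_ffd_points(truth, centers)
  moving <- template
  moving$data <- array(scene(xinv), spec$shape)
  if (spec$noise_sd > 0) {
    noise <- array(stats::rnorm(prod(spec$shape), sd = spec$noise_sd),
                   spec$shape)
    nv <- symmetrize(volume_image(noise, spec$spacing, origin), 1L)$volume
    moving$data <- moving$data + nv$data
  }

  # side labels: voxel side of the central plane (identical grids)
  side <- symmetrize(fixed, 1L)$side

  # landmarks on the bone shell mid-surface; all but the last two on the
  # mid-sagittal plane, the last two mirrored off-plane
  rm_ <- spec$bone_radii - spec$bone_thickness / 2
  nl <- spec$n_landmarks
  nmid <- nl - 2L
  th <- seq(0, 2 * pi, length.out = nmid + 1L)[seq_len(nmid)] + 0.13
  lm_pts <- cbind(0, rm_[2] * cos(th), rm_[3] * sin(th))
  u <- c(0.6, 0.55, 0.58)
  for (sgn in c(1, -1)) {
    uu <- u * c(sgn, 1, 1)
    s <- 1 / sqrt(sum((uu / rm_)^2))
    lm_pts <- rbind(lm_pts, s * uu)
  }
  lm_names <- c(sprintf("midline_%02d", seq_len(nmid)),
                "orbital_right", "orbital_left")
  fixed_lm <- landmark_set(seq_len(nl), lm_names, lm_pts)
  moving_lm <- landmark_set(seq_len(nl), lm_names,
                            transform_points(truth, lm_pts))

  # organ mesh (fixed frame) and upper-surface evaluation points (moving)
  mesh <- tet_mesh_ellipsoid(spec$organ_center, spec$organ_radii * 0.92,
                             h = min(spec$spacing) * 2.5)
  nphi <- ceiling(sqrt(spec$n_surface_points))
  gs <- expand.grid(a = seq(0.05, 0.95, length.out = nphi),
                    b = seq(0.05, 0.95, length.out = nphi))
  gs <- gs[seq_len(min(nrow(gs), spec$n_surface_points)), ]
  phi <- gs$a * pi              # azimuth around the vertical axis
  psi <- gs$b * (pi / 2)        # elevation, upper hemisphere only
  sp_fixed <- cbind(
    spec$organ_center[1] + spec$organ_radii[1] * cos(phi) * cos(psi),
    spec$organ_center[2] + spec$organ_radii[2] * sin(phi) * cos(psi),
    spec$organ_center[3] + spec$organ_radii[3] * sin(psi))
  surface_points <- transform_points(truth, sp_fixed)

  organ_mask <- mask_volume(
    array(ellipsoid_q(centers, spec$organ_center, spec$organ_radii) <= 1,
          spec$shape), spec$spacing, origin)

  # withheld evaluation points: organ surface + interior, never used by the
  # registration cost
  ev <- rbind(sp_fixed,
              sweep(0.5 * sweep(sp_fixed, 2, spec$organ_center, "-"),
                    2, spec$organ_center, "+"))

  list(fixed = fixed, moving = moving, fixed_side = side, moving_side = side,
       fixed_landmarks = fixed_lm, moving_landmarks = moving_lm,
       truth = truth, organ_mesh = mesh, surface_points = surface_points,
       organ_mask = organ_mask, eval_points = ev, min_jacobian = min_j,
       spec = spec)
}

#' Closed-form test response surfaces for the UQ machinery
#'
#' Named analytic quantities of interest on the unit square, with documented
#' Hessians, used to validate the stochastic-collocation metamodel: `affine`
#' (`2 l1 + 3 l2 + 1`, zero Hessian — linear interpolation is exact),
#' `quadratic` (`l1^2 + l2^2`, constant Hessian `diag(2, 2)`),
#' `gaussian_bump` (`exp(-10 ||l - (0.75, 0.75)||^2)`, localized curvature),
#' and `step` (indicator of `l1 + l2 > 1`, zero Hessian away from the
#' discontinuity — exercises singularity capture).
#'
#' @param name one of `"affine"`, `"quadratic"`, `"gaussian_bump"`, `"step"`.
#' @return a function `lambda -> scalar` (accepts a 2-vector or N x 2
#'   matrix), with attribute `hessian`: a function returning the 2 x 2
#'   Hessian at a point.
#' @export
analytic_qoi <- function(name = c("affine", "quadratic", "gaussian_bump",
                                  "step")) {
  name <- match.arg(name)
  as_mat <- function(l) if (is.null(dim(l))) matrix(l, ncol = 2) else as.matrix(l)
  switch(name,
    affine = {
      f <- function(lambda) {
        l <- as_mat(lambda); drop(2 * l[, 1] + 3 * l[, 2] + 1)
      }
      attr(f, "hessian") <- function(lambda) matrix(0, 2, 2)
      f
    },
    quadratic = {
      f <- function(lambda) {
        l <- as_mat(lambda); drop(l[, 1]^2 + l[, 2]^2)
      }
      attr(f, "hessian") <- function(lambda) diag(c(2, 2))
      f
    },
    gaussian_bump = {
      ctr <- c(0.75, 0.75)
      f <- function(lambda) {
        l <- as_mat(lambda)
        drop(exp(-10 * ((l[, 1] - ctr[1])^2 + (l[, 2] - ctr[2])^2)))
      }
      attr(f, "hessian") <- function(lambda) {
        d <- as.numeric(lambda) - ctr
        q <- exp(-10 * sum(d^2))
        (400 * (d %o% d) - 20 * diag(2)) * q
      }
      f
    },
    step = {
      f <- function(lambda) {
        l <- as_mat(lambda); drop(as.numeric(l[, 1] + l[, 2] > 1))
      }
      attr(f, "hessian") <- function(lambda) matrix(0, 2, 2)
      f
    })
}
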