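#' Cost-function weights
#'
#' Weights of the four-term registration cost
#' `F = NC + alpha * SD + beta * D + gamma * P`: normalized cross-correlation
#' (intensity similarity), sum-of-squared-differences on the side-label
#' images (mid-sagittal symmetry), mean paired-landmark distance, and the
#' bending-energy penalty. `beta` and `gamma` are per-level schedules
#' (coarse to fine); `gamma` is derived from the finest-level weight
#' `lambda2` as `(0, lambda2/2, lambda2)`. Weights are not normalized across
#' terms.
#'
#' @param alpha symmetry weight; default 1 (mid-sagittal alignment treated as
#'   important as intensity alignment).
#' @param beta landmark weights per level; default `c(0, 0.05, 0.1)`.
#' @param lambda2 finest-level bending-energy weight; default 500.
#' @param gamma explicit per-level penalty weights, overriding the
#'   `lambda2`-derived schedule.
#' @return An object of class `cost_weights`.
#' @export
cost_weights <- function(alpha = 1, beta = c(0, 0.05, 0.1), lambda2 = 500,
                         gamma = c(0, lambda2 / 2, lambda2)) {
  stopifnot(length(beta) == 3L, length(gamma) == 3L)
  structure(list(alpha = alpha, beta = beta, gamma = gamma,
                 lambda2 = lambda2),
            class = "cost_weights")
}

#' Registration configuration
#'
#' @param lambda1 finest FFD grid spacing (mm); the coarser levels use
#'   `2 * lambda1` and `4 * lambda1`.
#' @param weights a [cost_weights()].
#' @param samples_per_iter random head/neck-mask points drawn per iteration
#'   for the stochastic cost estimate; default 20000.
#' @param iterations iterations per resolution level (coarse to fine).
#' @param seed RNG seed; a fixed seed makes the whole run deterministic.
#' @param step_delta target magnitude (mm) of the first optimizer step, used
#'   to auto-scale the gain of the adaptive stochastic gradient descent.
#' @param step_A,step_alpha ASGD decay `a / (A + t)^alpha` hyperparameters.
#' @param plane_axis mid-sagittal plane axis (1..3).
#' @param affine_subset landmark ids used for the affine initialization.
#' @return An object of class `registration_config`.
#' @export
registration_config <- function(lambda1 = 20, weights = cost_weights(),
                                samples_per_iter = 20000L,
                                iterations = c(2000L, 2000L, 2000L),
                                seed = 1L, step_delta = 1.0, step_A = 20,
                                step_alpha = 0.602, plane_axis = 1L,
                                affine_subset = c(2L, 4L, 7L, 20L, 21L)) {
  stopifnot(lambda1 > 0, samples_per_iter >= 2, length(iterations) == 3L)
  structure(list(lambda1 = lambda1, weights = weights,
                 samples_per_iter = as.integer(samples_per_iter),
                 iterations = as.integer(iterations), seed = as.integer(seed),
                 step_delta = step_delta, step_A = step_A,
                 step_alpha = step_alpha, plane_axis = as.integer(plane_axis),
                 affine_subset = as.integer(affine_subset)),
            class = "registration_config")
}

# ---------------------------------------------------------------------------
# Cost terms (exported individually so they can be validated in isolation)

#' Normalized cross-correlation term
#'
#' Returns the *negative* Pearson correlation between the fixed intensities
#' at the sample points and the moving intensities at their transformed
#' positions, so that minimizing the cost maximizes the correlation. If
#' either sample vector has zero variance the term is uninformative and
#' defined as 0.
#'
#' @param transform point map fixed -> moving domain.
#' @param fixed,moving [volume_image()]s.
#' @param sample_points N x 3 matrix of fixed-domain points (mm).
#' @param fill out-of-bounds intensity for the moving volume.
#' @return scalar in `[-1, 1]`.
#' @export
nc_term <- function(transform, fixed, moving, sample_points, fill = -1000) {
  f <- interp_volume(fixed, sample_points)
  m <- interp_volume(moving, transform_points(transform, sample_points),
                     fill = fill)
  if (stats::sd(f) == 0 || stats::sd(m) == 0) return(0)
  -stats::cor(f, m)
}

#' Mid-sagittal symmetry term (SSD on side labels)
#'
#' Mean over the sample points of the squared difference between the fixed
#' side label and the (linearly interpolated) moving side label at the
#' transformed position. Zero when the transform maps each side onto the
#' same side; 1 when it reflects the volume across the plane.
#'
#' @param transform point map fixed -> moving domain.
#' @param fixed_side,moving_side [side_label_image()]s.
#' @param sample_points N x 3 matrix of fixed-domain points (mm).
#' @return scalar in `[0, 1]`.
#' @export
sd_term <- function(transform, fixed_side, moving_side, sample_points) {
  sh <- interp_volume(fixed_side, sample_points, fill = 0)
  sb <- interp_volume(moving_side, transform_points(transform, sample_points),
                      fill = 0)
  mean((sh - sb)^2)
}

#' Paired-landmark distance term
#'
#' Mean Euclidean distance (mm) between the transformed fixed landmarks and
#' their moving pairs.
#'
#' @param transform point map fixed -> moving domain.
#' @param fixed_landmarks,moving_landmarks paired [landmark_set()]s.
#' @return scalar mean distance (mm).
#' @export
landmark_term <- function(transform, fixed_landmarks, moving_landmarks) {
  if (!identical(fixed_landmarks$id, moving_landmarks$id))
    stop("landmark_term: landmark sets are not paired (id mismatch)")
  tl <- transform_points(transform, landmark_points(fixed_landmarks))
  mean(sqrt(rowSums((tl - landmark_points(moving_landmarks))^2)))
}

#' Total four-term registration cost
#'
#' `F = NC + alpha * SD + beta * D + gamma * P`, with the bending energy `P`
#' evaluated over `bend_domain` (defaults to the sample points).
#'
#' @param transform an [ffd_transform()].
#' @param fixed,moving [volume_image()]s.
#' @param fixed_side,moving_side [side_label_image()]s.
#' @param fixed_landmarks,moving_landmarks paired [landmark_set()]s.
#' @param alpha,beta,gamma scalar weights for this evaluation.
#' @param sample_points N x 3 matrix of fixed-domain sample points.
#' @param bend_domain domain for [bending_energy()]; defaults to
#'   `sample_points`.
#' @return scalar cost, with the four term values as attribute `terms`.
#' @export
total_cost <- function(transform, fixed, moving, fixed_side, moving_side,
                       fixed_landmarks, moving_landmarks,
                       alpha = 1, beta = 0, gamma = 0,
                       sample_points, bend_domain = sample_points) {
  nc <- nc_term(transform, fixed, moving, sample_points)
  sd_ <- sd_term(transform, fixed_side, moving_side, sample_points)
  d <- landmark_term(transform, fixed_landmarks, moving_landmarks)
  p <- if (gamma != 0 || !is.null(bend_domain))
    bending_energy(transform, bend_domain) else 0
  out <- nc + alpha * sd_ + beta * d + gamma * p
  attr(out, "terms") <- c(NC = nc, SD = sd_, D = d, P = p)
  out
}

# ---------------------------------------------------------------------------
# Gaussian pyramid

gaussian_kernel_matrix <- function(n, sigma) {
  if (sigma <= 0) return(diag(n))
  r <- ceiling(3 * sigma)
  g <- exp(-((-r:r)^2) / (2 * sigma^2))
  Fm <- matrix(0, n, n)
  for (i in seq_len(n)) {
    j <- (i - r):(i + r)
    ok <- j >= 1 & j <= n
    Fm[i, j[ok]] <- g[ok]
    Fm[i, ] <- Fm[i, ] / sum(Fm[i, ])
  }
  Fm
}

smooth_volume <- function(v, sigma_vox) {
  if (sigma_vox <= 0) return(v)
  d <- vol_shape(v)
  arr <- v$data
  for (a in 1:3) {
    Fm <- gaussian_kernel_matrix(d[a], sigma_vox)
    arr <- apply_matrix_along(arr, Fm, a)
  }
  out <- v
  out$data <- arr
  out
}

# factor-f downsampling: Gaussian smoothing (sigma = f/2 voxels) then stride
downsample_volume <- function(v, f, smooth = TRUE) {
  if (f == 1L && !smooth) return(v)
  s <- if (smooth) smooth_volume(v, f / 2) else v
  if (f == 1L) return(s)
  d <- vol_shape(v)
  idx <- lapply(d, function(n) seq(1L, n, by = f))
  out <- s
  out$data <- s$data[idx[[1]], idx[[2]], idx[[3]], drop = FALSE]
  out$spacing <- v$spacing * f
  out
}

downsample_stride <- function(v, f) {
  if (f == 1L) return(v)
  d <- vol_shape(v)
  idx <- lapply(d, function(n) seq(1L, n, by = f))
  out <- v
  out$data <- v$data[idx[[1]], idx[[2]], idx[[3]], drop = FALSE]
  out$spacing <- v$spacing * f
  out
}

# ---------------------------------------------------------------------------
# The optimizer

#' Multi-resolution symmetric FFD registration
#'
#' Minimizes the four-term cost by adaptive stochastic gradient descent over
#' three resolution levels (images and FFD grid both coarsened by factors 4,
#' 2, 1). Each iteration draws a fresh random subset of head/neck-mask voxel
#' centers, evaluates the cost terms and their analytic gradients with
#' respect to the B-spline coefficients, and takes a decaying gradient step.
#' Between levels the control lattice is refined by exact B-spline
#' subdivision so optimization continues from the coarse solution. The run
#' is deterministic given `cfg$seed`.
#'
#' @param fixed,moving symmetrized [volume_image()]s (`I_h`, `I_b`).
#' @param fixed_side,moving_side [side_label_image()]s (`S_h`, `S_b`).
#' @param fixed_landmarks,moving_landmarks paired [landmark_set()]s
#'   (`L_h`, `L_b`).
#' @param cfg a [registration_config()].
#' @param mask head/neck [mask_volume()] on the fixed grid; computed with
#'   [segment_head_neck()] when `NULL`.
#' @param affine pre-computed [affine_transform()] initialization; fitted
#'   from `cfg$affine_subset` landmarks when `NULL`.
#' @return An object of class `registration_result`: fields `transform`
#'   (the final [ffd_transform()]), `trace` (per-level data frames of
#'   per-iteration term values and total cost), `final_terms` (NC, SD, D, P
#'   evaluated deterministically over the whole mask), `affine`, `config`.
#' @export
register <- function(fixed, moving, fixed_side, moving_side,
                     fixed_landmarks, moving_landmarks,
                     cfg = registration_config(), mask = NULL,
                     affine = NULL) {
  if (!identical(fixed_landmarks$id, moving_landmarks$id))
    stop("register: landmark sets are not paired")
  if (is.null(mask)) mask <- segment_head_neck(fixed)
  if (is.null(affine)) {
    subset <- intersect(cfg$affine_subset, fixed_landmarks$id)
    affine <- fit_affine_landmarks(fixed_landmarks, moving_landmarks, subset)
  }
  old_seed <- get0(".Random.seed", globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(cfg$seed)

  lm_f <- landmark_points(fixed_landmarks)
  lm_m <- landmark_points(moving_landmarks)
  lattice <- build_symmetric_grid(fixed, cfg$lambda1 * 4, cfg$plane_axis,
                                  pre_affine = affine)
  w <- cfg$weights
  traces <- vector("list", 3L)
  warned_small <- FALSE

  for (lev in 1:3) {
    f <- 2L^(3L - lev)
    fx <- downsample_volume(fixed, f)
    mv <- downsample_volume(moving, f)
    fs <- downsample_stride(fixed_side, f)
    ms <- downsample_stride(moving_side, f)
    mk <- downsample_stride(mask, f)
    centers_all <- voxel_centers(fx)
    sel <- as.vector(mk$data)
    centers <- centers_all[sel, , drop = FALSE]
    fvals_all <- as.vector(fx$data)[sel]
    fside_all <- as.vector(fs$data)[sel]
    nmask <- nrow(centers)
    ns <- cfg$samples_per_iter
    replacing <- ns > nmask
    if (replacing && !warned_small) {
      warning("register: mask smaller than samples_per_iter; ",
              "sampling with replacement")
      warned_small <- TRUE
    }
    mv_data <- as.vector(mv$data)
    ms_data <- as.vector(ms$data)
    alpha <- w$alpha; beta <- w$beta[lev]; gamma <- w$gamma[lev]
    iters <- cfg$iterations[lev]
    tr <- matrix(NA_real_, iters, 5L,
                 dimnames = list(NULL, c("cost", "NC", "SD", "D", "P")))

    # cost terms + analytic coefficient gradient for a coefficient matrix,
    # on one drawn sample of mask points
    eval_grad <- function(coefs, pts, fv, fsd) {
      tp <- transform_points(lattice$pre_affine, pts) +
        cpp_ffd_disp(pts, lattice$control_origin, lattice$control_spacing,
                     lattice$control_shape, coefs)
      ib <- cpp_trilerp(mv_data, dim(mv$data), mv$spacing, mv$origin, tp,
                        -1000, TRUE)
      m <- ib$value
      # NC = -cor(f, m) and its gradient in m
      fc <- fv - mean(fv); mc <- m - mean(m)
      nsam <- length(fv)
      sf <- sqrt(sum(fc^2) / nsam); sm <- sqrt(sum(mc^2) / nsam)
      if (sf > 0 && sm > 0) {
        corr <- sum(fc * mc) / (nsam * sf * sm)
        nc <- -corr
        dnc <- -(fc / (nsam * sf * sm) - corr * mc / (nsam * sm^2))
      } else {
        nc <- 0; dnc <- numeric(nsam)
      }
      U <- ib$grad * dnc

      sb <- cpp_trilerp(ms_data, dim(ms$data), ms$spacing, ms$origin, tp,
                        0, TRUE)
      sdv <- mean((fsd - sb$value)^2)
      U <- U + sb$grad * (alpha * (-2 / nsam) * (fsd - sb$value))

      G <- cpp_ffd_backprop(pts, U, lattice$control_origin,
                            lattice$control_spacing, lattice$control_shape)

      tl <- transform_points(lattice$pre_affine, lm_f) +
        cpp_ffd_disp(lm_f, lattice$control_origin, lattice$control_spacing,
                     lattice$control_shape, coefs)
      dl <- sqrt(rowSums((tl - lm_m)^2))
      dterm <- mean(dl)
      if (beta != 0) {
        ulm <- (tl - lm_m) / (pmax(dl, 1e-12) * length(dl)) * beta
        ulm[dl <= 1e-12, ] <- 0
        G <- G + cpp_ffd_backprop(lm_f, ulm, lattice$control_origin,
                                  lattice$control_spacing,
                                  lattice$control_shape)
      }

      bend <- cpp_ffd_bend(pts, lattice$control_origin,
                           lattice$control_spacing, lattice$control_shape,
                           coefs, gamma != 0)
      if (gamma != 0) G <- G + gamma * bend$grad
      list(G = G, cost = nc + alpha * sdv + beta * dterm +
             gamma * bend$energy,
           terms = c(nc, sdv, dterm, bend$energy))
    }

    gain <- NA_real_
    for (t in seq_len(iters)) {
      idx <- sample.int(nmask, ns, replace = replacing)
      pts <- centers[idx, , drop = FALSE]
      fv <- fvals_all[idx]
      fsd <- fside_all[idx]
      e <- eval_grad(lattice$coefficients, pts, fv, fsd)
      if (!is.finite(e$cost))
        stop("register: cost diverged (NaN/Inf) at level ", lev,
             " iteration ", t)
      tr[t, ] <- c(e$cost, e$terms)

      if (t == 1L) {
        # Auto-scale the gain so the first step moves the largest
        # coefficient by step_delta. At a perfect optimum the gradient is
        # numerically zero, which would inflate the gain without bound, so
        # the reference magnitude also probes the gradient at a small
        # random perturbation of the coefficients.
        probe <- lattice$coefficients +
          matrix(stats::rnorm(length(lattice$coefficients), sd = 0.5),
                 ncol = 3)
        gp <- eval_grad(probe, pts, fv, fsd)
        gref <- max(max(abs(e$G)), max(abs(gp$G)), 1e-12)
        gain <- cfg$step_delta * (cfg$step_A + 1)^cfg$step_alpha / gref
      }
      step <- gain / (cfg$step_A + t)^cfg$step_alpha
      # trust region: never move a coefficient more than 2 * step_delta
      gmax <- max(abs(e$G))
      if (step * gmax > 2 * cfg$step_delta)
        step <- 2 * cfg$step_delta / gmax
      lattice$coefficients <- lattice$coefficients - step * e$G
    }
    traces[[lev]] <- as.data.frame(tr)
    if (lev < 3L) lattice <- subdivide_ffd(lattice)
  }

  # deterministic final term values over the whole mask
  mask_pts <- domain_points(mask)
  final <- total_cost(lattice, fixed, moving, fixed_side, moving_side,
                      fixed_landmarks, moving_landmarks,
                      alpha = w$alpha, beta = w$beta[3], gamma = w$gamma[3],
                      sample_points = mask_pts, bend_domain = mask_pts)
  structure(list(transform = lattice, trace = traces,
                 final_terms = attr(final, "terms"), final_cost = as.numeric(final),
                 affine = affine, config = cfg),
            class = "registration_result")
}

#' @export
print.registration_result <- function(x, ...) {
  ft <- x$final_terms
  cat(sprintf(paste0("<registration_result> final cost %.4f ",
                     "(NC %.4f, SD %.4f, D %.3f mm, P %.3g)\n"),
              x$final_cost, ft["NC"], ft["SD"], ft["D"], ft["P"]))
  invisible(x)
}

#' Mid-sagittal asymmetry score of a volume
#'
#' Mean absolute difference between a volume and its mirror across the
#' central voxel plane, optionally restricted to a mask. Zero for an exactly
#' symmetric volume.
#'
#' @param volume a [volume_image()].
#' @param plane_axis mirror axis (1..3).
#' @param mask optional [mask_volume()] restricting the average.
#' @return scalar score (intensity units).
#' @export
asymmetry_score <- function(volume, plane_axis = 1L, mask = NULL) {
  m <- mirror(volume, plane_axis)
  d <- abs(volume$data - m$data)
  if (!is.null(mask)) {
    sel <- mask$data & mirror(mask, plane_axis)$data
    mean(d[sel])
  } else mean(d)
}
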