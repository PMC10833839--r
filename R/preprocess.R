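#' Mid-sagittal plane specification from three points
#'
#' Three manually selected, non-collinear points describing the mid-sagittal
#' plane and its normal. The points are not anatomical landmarks; they are
#' chosen for their efficacy in the symmetrization.
#'
#' @param points 3 x 3 matrix, one point (mm) per row.
#' @return An object of class `plane_spec` with fields `points`, `normal`
#'   (unit) and `point` (a point on the plane).
#' @export
plane_spec <- function(points) {
  points <- as.matrix(points)
  if (!all(dim(points) == c(3, 3))) stop("plane_spec: need a 3x3 point matrix")
  v1 <- points[2, ] - points[1, ]
  v2 <- points[3, ] - points[1, ]
  n <- c(v1[2] * v2[3] - v1[3] * v2[2],
         v1[3] * v2[1] - v1[1] * v2[3],
         v1[1] * v2[2] - v1[2] * v2[1])
  nn <- sqrt(sum(n^2))
  if (nn < 1e-10 * max(sqrt(sum(v1^2)), sqrt(sum(v2^2)), 1))
    stop("plane_spec: points are collinear (degenerate plane)")
  structure(list(points = points, normal = n / nn, point = points[1, ]),
            class = "plane_spec")
}

#' Preprocessing configuration
#'
#' @param air_threshold HU threshold slightly above air (-1000 HU) used for
#'   head/neck segmentation; default -900.
#' @param bone_threshold HU threshold separating soft tissue from bone for
#'   bone-only volumes; default +200 (soft tissue < 100 HU, cortical and
#'   cancellous bone well above).
#' @param closing_radius morphological closing ball radius (voxels); fills
#'   internal cavities (oral/nasal) smaller than this scale. Default 3.
#' @param dilation_radius dilation ball radius (voxels) applied after
#'   closing. Default 1.
#' @param hyoid_mask optional [mask_volume()] of the hyoid bone, removed from
#'   bone-only volumes (the hyoid does not fossilize).
#' @return An object of class `preprocess_config`.
#' @export
preprocess_config <- function(air_threshold = -900, bone_threshold = 200,
                              closing_radius = 3L, dilation_radius = 1L,
                              hyoid_mask = NULL) {
  if (air_threshold <= -1000) stop("air_threshold must be > -1000 HU")
  if (bone_threshold <= air_threshold)
    stop("bone_threshold must be > air_threshold")
  if (closing_radius < 0 || dilation_radius < 0) stop("radii must be >= 0")
  structure(list(air_threshold = air_threshold,
                 bone_threshold = bone_threshold,
                 closing_radius = as.integer(closing_radius),
                 dilation_radius = as.integer(dilation_radius),
                 hyoid_mask = hyoid_mask),
            class = "preprocess_config")
}

# ---------------------------------------------------------------------------
# Rigid alignment of the mid-sagittal plane with a grid axis

rodrigues_to <- function(from, to) {
  from <- from / sqrt(sum(from^2)); to <- to / sqrt(sum(to^2))
  v <- c(from[2] * to[3] - from[3] * to[2],
         from[3] * to[1] - from[1] * to[3],
         from[1] * to[2] - from[2] * to[1])
  c0 <- sum(from * to)
  s2 <- sum(v^2)
  if (s2 < 1e-24) {
    if (c0 > 0) return(diag(3))
    # antiparallel: rotate pi about any axis perpendicular to `from`
    p <- if (abs(from[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    ax <- p - sum(p * from) * from
    ax <- ax / sqrt(sum(ax^2))
    return(2 * (ax %o% ax) - diag(3))
  }
  Vx <- rbind(c(0, -v[3], v[2]), c(v[3], 0, -v[1]), c(-v[2], v[1], 0))
  diag(3) + Vx + Vx %*% Vx * ((1 - c0) / s2)
}

#' Rigidly align a volume so a given plane becomes its central voxel plane
#'
#' Applies the rotation + translation that maps the specified plane onto the
#' central voxel plane of `plane_axis` and brings the volume center to the
#' world origin, then resamples onto a grid of the same shape and spacing
#' centered at the origin. The rigid map is returned as the `"transform"`
#' attribute so landmarks can be carried through it with
#' [transform_points()].
#'
#' @param volume a [volume_image()].
#' @param plane a [plane_spec()].
#' @param plane_axis target axis for the plane normal (1..3); default 1.
#' @param fill out-of-bounds fill (HU); default -1000.
#' @return the aligned [volume_image()] with attribute `transform`
#'   (an [affine_transform()], the forward rigid map input -> output world).
#' @export
align_to_plane <- function(volume, plane, plane_axis = 1L, fill = -1000) {
  e <- numeric(3); e[plane_axis] <- 1
  if (abs(sum(plane$normal * e)) < 1e-12)
    stop("align_to_plane: plane normal orthogonal to the target axis")
  n <- plane$normal
  if (sum(n * e) < 0) n <- -n # choose the rotation with the smaller angle
  R <- rodrigues_to(n, e)
  d <- vol_shape(volume)
  center <- volume$origin + (d - 1) / 2 * volume$spacing
  tr <- -as.vector(R %*% center)
  # exact plane constraint along the target axis
  tr[plane_axis] <- -as.vector(R %*% plane$point)[plane_axis]
  g <- affine_transform(R, tr)
  out_origin <- -(d - 1) / 2 * volume$spacing
  ref <- volume_image(array(0, d), volume$spacing, out_origin)
  ginv <- affine_transform(t(R), -as.vector(t(R) %*% tr))
  out <- resample(volume, ginv, ref, fill = fill)
  attr(out, "transform") <- g
  out
}

#' Symmetrize a plane-aligned volume about its central voxel plane
#'
#' One designated half is copied onto the other by reflection, so the output
#' is an exact fixed point of [mirror()]. Also returns the side-label image
#' marking each voxel's side of the mid-sagittal plane (1 on the kept side).
#' Which half is kept is arbitrary (the anatomical left/right naming is a
#' convention); for an even-sized axis the reflection plane lies between the
#' two central layers, so no voxel sits on it.
#'
#' @param volume a plane-aligned [volume_image()].
#' @param plane_axis axis of the mid-sagittal plane normal (1..3).
#' @param keep `"upper"` (higher indices, default) or `"lower"`.
#' @return list with elements `volume` (symmetric [volume_image()]) and
#'   `side` (a [side_label_image()]).
#' @export
symmetrize <- function(volume, plane_axis = 1L, keep = c("upper", "lower")) {
  keep <- match.arg(keep)
  d <- vol_shape(volume)
  n <- d[plane_axis]
  m <- mirror(volume, plane_axis)
  idx_all <- seq_len(n)
  # indices strictly on the replaced side
  replaced <- if (keep == "upper") idx_all[idx_all < (n + 1) / 2]
              else idx_all[idx_all > (n + 1) / 2]
  out <- volume
  sel <- rep(list(quote(expr = )), 3)
  sel[[plane_axis]] <- replaced
  out$data <- do.call(`[<-`, c(list(volume$data), sel,
                               list(do.call(`[`, c(list(m$data), sel,
                                                   list(drop = FALSE))))))
  lab <- array(0, d)
  onside <- if (keep == "upper") idx_all[idx_all >= (n + 1) / 2]
            else idx_all[idx_all <= (n + 1) / 2]
  sel[[plane_axis]] <- onside
  lab <- do.call(`[<-`, c(list(lab), sel, list(1)))
  list(volume = out,
       side = side_label_image(lab, volume$spacing, volume$origin,
                               plane_axis = plane_axis))
}

# ---------------------------------------------------------------------------
# Binary morphology (Euclidean-ball structuring elements, FFT convolution)

ball_kernel <- function(radius) {
  r <- as.integer(radius)
  if (r == 0L) return(array(1, c(1, 1, 1)))
  ax <- -r:r
  g <- expand.grid(x = ax, y = ax, z = ax)
  k <- array(as.numeric(g$x^2 + g$y^2 + g$z^2 <= radius^2),
             c(2L * r + 1L, 2L * r + 1L, 2L * r + 1L))
  k
}

conv3d <- function(x, k) {
  dx <- dim(x); dk <- dim(k)
  ds <- dx + dk - 1L
  X <- array(0, ds); X[seq_len(dx[1]), seq_len(dx[2]), seq_len(dx[3])] <- x
  K <- array(0, ds); K[seq_len(dk[1]), seq_len(dk[2]), seq_len(dk[3])] <- k
  out <- Re(stats::fft(stats::fft(X) * stats::fft(K), inverse = TRUE)) / prod(ds)
  off <- (dk - 1L) %/% 2L
  out[off[1] + seq_len(dx[1]), off[2] + seq_len(dx[2]),
      off[3] + seq_len(dx[3]), drop = FALSE]
}

binary_dilate <- function(mask, radius) {
  if (radius == 0L) return(mask)
  k <- ball_kernel(radius)
  conv3d(array(as.numeric(mask), dim(mask)), k) > 0.5
}

binary_erode <- function(mask, radius) {
  # out-of-bounds is treated as foreground (duality with dilation), so a
  # closing never eats the set at the array border
  if (radius == 0L) return(mask)
  !binary_dilate(!mask, radius)
}

binary_close <- function(mask, radius) {
  binary_erode(binary_dilate(mask, radius), radius)
}

#' Segment the head and neck region
#'
#' Thresholds the volume slightly above air, then applies morphological
#' closing (to fill internal air cavities such as the oral and nasal
#' cavities) and dilation, both with Euclidean-ball structuring elements.
#' The mask only gates where image similarity is sampled during
#' registration; air-tissue interfaces inside the region stay present in the
#' intensity volume itself.
#'
#' @param volume a [volume_image()] in HU.
#' @param cfg a [preprocess_config()].
#' @return a [mask_volume()].
#' @export
segment_head_neck <- function(volume, cfg = preprocess_config()) {
  m <- volume$data > cfg$air_threshold
  if (!any(m))
    stop("segment_head_neck: empty region (volume is all air?)")
  m <- binary_close(m, cfg$closing_radius)
  m <- binary_dilate(m, cfg$dilation_radius)
  mask_volume(m, volume$spacing, volume$origin)
}

#' Strip soft tissue, keeping bone only
#'
#' Replaces every voxel below `bone_threshold` with -1000 HU (air), emulating
#' the information available from fossilized remains. Voxels inside
#' `hyoid_mask` (if present in `cfg`) are also set to air regardless of
#' intensity, since the hyoid does not fossilize. Idempotent.
#'
#' @param volume a [volume_image()] in HU.
#' @param cfg a [preprocess_config()].
#' @return the bone-only [volume_image()].
#' @export
bone_only <- function(volume, cfg = preprocess_config()) {
  out <- volume
  out$data[out$data < cfg$bone_threshold] <- -1000
  if (!is.null(cfg$hyoid_mask)) {
    if (!all(vol_shape(cfg$hyoid_mask) == vol_shape(volume)))
      stop("bone_only: hyoid mask grid does not match the volume")
    out$data[cfg$hyoid_mask$data] <- -1000
  }
  out
}
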