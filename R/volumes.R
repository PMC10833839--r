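#' @useDynLib tonguemorph, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' 3D scalar volume with grid metadata
#'
#' A `volume_image` is a 3D scalar array (CT-like, Hounsfield-unit semantics)
#' together with its voxel spacing (mm) and world origin (mm). The world
#' coordinate of 0-based voxel index `i` is `origin + i * spacing`; grids are
#' axis-aligned (symmetrized volumes are axis-aligned by construction, so no
#' orientation matrix is carried).
#'
#' @param data 3D numeric array of intensities (finite values only).
#' @param spacing numeric 3-vector, mm per voxel, all components > 0.
#' @param origin numeric 3-vector, world position (mm) of voxel `[1,1,1]`.
#' @return An object of class `volume_image`.
#' @export
volume_image <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  if (length(dim(data)) != 3L)
    stop("volume_image: `data` must be a 3D array")
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("volume_image: `spacing` must be 3 positive finite numbers")
  if (length(origin) != 3L || any(!is.finite(origin)))
    stop("volume_image: `origin` must be 3 finite numbers")
  if (!all(is.finite(data)))
    stop("volume_image: intensities must be finite")
  structure(list(data = data, spacing = spacing, origin = origin),
            class = "volume_image")
}

#' Binary mask on a volume grid
#'
#' Same grid conventions as [volume_image()]; `data` is logical.
#'
#' @param data 3D logical array.
#' @param spacing,origin grid metadata as in [volume_image()].
#' @return An object of class `c("mask_volume", "volume_image")`.
#' @export
mask_volume <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  if (length(dim(data)) != 3L || !is.logical(data))
    stop("mask_volume: `data` must be a 3D logical array")
  v <- volume_image(array(as.numeric(data), dim(data)), spacing, origin)
  v$data <- data
  class(v) <- c("mask_volume", "volume_image")
  v
}

#' Side-label image (mid-sagittal foreground/background)
#'
#' Binary image labelling each voxel by its side of the mid-sagittal voxel
#' plane (exactly two label values, 0 and 1).
#'
#' @param data 3D array of 0/1 labels.
#' @param spacing,origin grid metadata as in [volume_image()].
#' @param plane_axis axis index (1..3) perpendicular to the labelling plane.
#' @return An object of class `c("side_label_image", "volume_image")`.
#' @export
side_label_image <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0),
                             plane_axis = 1L) {
  vals <- sort(unique(as.vector(data)))
  if (!all(vals %in% c(0, 1)))
    stop("side_label_image: labels must be 0/1")
  v <- volume_image(array(as.numeric(data), dim(data)), spacing, origin)
  v$plane_axis <- as.integer(plane_axis)
  class(v) <- c("side_label_image", "volume_image")
  v
}

#' @export
print.volume_image <- function(x, ...) {
  cat(sprintf("<%s> %s voxels, spacing %s mm, origin %s mm, range [%g, %g]\n",
              class(x)[1], paste(dim(x$data), collapse = "x"),
              paste(signif(x$spacing, 4), collapse = ", "),
              paste(signif(x$origin, 4), collapse = ", "),
              min(x$data), max(x$data)))
  invisible(x)
}

vol_shape <- function(v) dim(v$data)

#' World coordinates of all voxel centers
#'
#' @param v a [volume_image()].
#' @return N x 3 matrix of world coordinates (mm), voxels in column-major
#'   (array storage) order.
#' @export
voxel_centers <- function(v) {
  d <- vol_shape(v)
  ax <- lapply(1:3, function(a) v$origin[a] + (seq_len(d[a]) - 1) * v$spacing[a])
  cbind(rep(ax[[1]], times = d[2] * d[3]),
        rep(rep(ax[[2]], each = d[1]), times = d[3]),
        rep(ax[[3]], each = d[1] * d[2]))
}

#' World bounds of a volume
#'
#' @param v a [volume_image()].
#' @return 2 x 3 matrix: first row the minimum corner voxel center, second row
#'   the maximum (mm).
#' @export
volume_bounds <- function(v) {
  d <- vol_shape(v)
  rbind(v$origin, v$origin + (d - 1) * v$spacing)
}

#' Coordinate of the central voxel plane along an axis
#'
#' For an odd-sized axis this is the center voxel layer; for an even-sized
#' axis it is the plane between the two central layers.
#'
#' @param v a [volume_image()].
#' @param axis axis index (1..3).
#' @return world coordinate (mm) of the plane.
#' @export
mid_plane_coord <- function(v, axis) {
  n <- vol_shape(v)[axis]
  v$origin[axis] + (n - 1) / 2 * v$spacing[axis]
}

#' Ordered set of named anatomical landmarks
#'
#' @param id integer ids (unique).
#' @param name character names.
#' @param points N x 3 matrix of world coordinates (mm).
#' @return A data frame of class `landmark_set` with columns
#'   `id, name, x, y, z`.
#' @export
landmark_set <- function(id, name, points) {
  id <- as.integer(id)
  if (anyDuplicated(id)) stop("landmark_set: ids must be unique")
  points <- as.matrix(points)
  if (ncol(points) != 3L || nrow(points) != length(id))
    stop("landmark_set: `points` must be length(id) x 3")
  structure(data.frame(id = id, name = as.character(name),
                       x = points[, 1], y = points[, 2], z = points[, 3],
                       stringsAsFactors = FALSE),
            class = c("landmark_set", "data.frame"))
}

landmark_points <- function(l) unname(as.matrix(l[, c("x", "y", "z")]))

#' Read landmarks from CSV (`id,name,x,y,z`, mm)
#' @param path file path.
#' @return a [landmark_set()].
#' @export
read_landmarks <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("id", "name", "x", "y", "z")
  if (!all(need %in% names(d)))
    stop("landmark CSV must have header id,name,x,y,z")
  landmark_set(d$id, d$name, as.matrix(d[, c("x", "y", "z")]))
}

#' Write landmarks to CSV (`id,name,x,y,z`, mm)
#' @param l a [landmark_set()].
#' @param path file path.
#' @export
write_landmarks <- function(l, path) {
  utils::write.csv(as.data.frame(unclass(l)), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

# ---------------------------------------------------------------------------
# Volume I/O: NIfTI via RNifti, MetaImage via the in-package reader/writer.

guess_volume_format <- function(path) {
  if (grepl("\\.nii(\\.gz)?$", path)) "nifti"
  else if (grepl("\\.(mha|mhd)$", path)) "metaimage"
  else stop("cannot guess volume format from extension: ", path)
}

#' Read a 3D volume (NIfTI or MetaImage)
#'
#' Grid metadata (spacing, origin) is preserved exactly; intensities are read
#' unchanged. Only axis-aligned 3D volumes are supported.
#'
#' @param path file path (`.nii`, `.nii.gz`, `.mha`, `.mhd`).
#' @param format `"nifti"` or `"metaimage"`; guessed from the extension by
#'   default.
#' @return a [volume_image()].
#' @export
read_volume <- function(path, format = guess_volume_format(path)) {
  format <- match.arg(format, c("nifti", "metaimage"))
  if (!file.exists(path)) stop("no such file: ", path)
  if (format == "nifti") {
    img <- RNifti::readNifti(path)
    data <- unclass(as.array(img))
    attributes(data) <- list(dim = dim(data))
    if (length(dim(data)) != 3L)
      stop("read_volume: payload is not 3D (dims: ",
           paste(dim(data), collapse = "x"), ")")
    pd <- RNifti::pixdim(img)
    xf <- RNifti::xform(img)
    # axis-aligned grids only (oblique orientation matrices are out of scope);
    # volumes written by write_volume carry a plain diagonal xform
    volume_image(data, spacing = abs(pd[1:3]), origin = xf[1:3, 4])
  } else {
    read_metaimage(path)
  }
}

#' Write a 3D volume (NIfTI or MetaImage)
#'
#' @param v a [volume_image()].
#' @param path output path; extension selects the container.
#' @param format `"nifti"` or `"metaimage"`.
#' @return `path`, invisibly.
#' @export
write_volume <- function(v, path, format = guess_volume_format(path)) {
  format <- match.arg(format, c("nifti", "metaimage"))
  data <- v$data
  if (is.logical(data)) data <- array(as.numeric(data), dim(data))
  if (format == "nifti") {
    img <- RNifti::asNifti(data)
    RNifti::pixdim(img) <- v$spacing
    mat <- diag(c(v$spacing, 1))
    mat[1:3, 4] <- v$origin
    RNifti::qform(img) <- structure(mat, code = 2L)
    RNifti::writeNifti(img, path, datatype = "double")
  } else {
    write_metaimage(v, path)
  }
  invisible(path)
}

# ---------------------------------------------------------------------------
# Resampling and mirroring

#' Resample a moving volume through a transform onto a reference grid
#'
#' The output lives on the reference grid; the value at reference voxel center
#' `x` is the interpolated value of `moving` at `T(x)`. Points mapping outside
#' the moving volume's bounds receive `fill`.
#'
#' @param moving a [volume_image()] to sample from.
#' @param transform a point map from the reference domain to the moving
#'   domain: `NULL` (identity), a function `pts -> pts`, an
#'   [affine_transform()], or an [ffd_transform()].
#' @param reference_grid a [volume_image()] defining the output grid.
#' @param fill out-of-bounds value; defaults to -1000 (air).
#' @param interpolation `"linear"` for intensities or `"nearest"` for
#'   masks/labels.
#' @return a [volume_image()] on the reference grid.
#' @export
resample <- function(moving, transform = NULL, reference_grid = moving,
                     fill = -1000, interpolation = c("linear", "nearest")) {
  interpolation <- match.arg(interpolation)
  pts <- voxel_centers(reference_grid)
  tp <- transform_points(transform, pts)
  vals <- interp_volume(moving, tp, fill = fill,
                        interpolation = interpolation)
  out <- array(vals, vol_shape(reference_grid))
  volume_image(out, reference_grid$spacing, reference_grid$origin)
}

# interpolate a volume at arbitrary world points
interp_volume <- function(v, pts, fill = -1000,
                          interpolation = c("linear", "nearest"),
                          want_grad = FALSE) {
  interpolation <- match.arg(interpolation)
  data <- v$data
  if (is.logical(data)) data <- array(as.numeric(data), dim(data))
  if (interpolation == "nearest") {
    d <- vol_shape(v)
    idx <- sweep(sweep(pts, 2, v$origin), 2, v$spacing, "/")
    ii <- round(idx) + 1
    inside <- ii[, 1] >= 1 & ii[, 1] <= d[1] &
              ii[, 2] >= 1 & ii[, 2] <= d[2] &
              ii[, 3] >= 1 & ii[, 3] <= d[3]
    vals <- rep(fill, nrow(pts))
    if (any(inside)) {
      lin <- (ii[inside, 1]) + d[1] * (ii[inside, 2] - 1) +
             d[1] * d[2] * (ii[inside, 3] - 1)
      vals[inside] <- as.vector(data)[lin]
    }
    return(vals)
  }
  r <- cpp_trilerp(as.vector(data), dim(data), v$spacing, v$origin,
                   pts, fill, want_grad)
  if (want_grad) r else r$value
}

#' Mirror a volume across its central voxel plane
#'
#' Reflection along `plane_axis` about the central plane (for an even-sized
#' axis, the plane between the two central layers, so no voxel lies on it).
#' `mirror(mirror(v))` is the identity and the intensity histogram is
#' preserved.
#'
#' @param volume a [volume_image()].
#' @param plane_axis axis index (1..3).
#' @return the reflected [volume_image()].
#' @export
mirror <- function(volume, plane_axis = 1L) {
  d <- vol_shape(volume)
  idx <- rep(list(quote(expr = )), 3)
  idx[[plane_axis]] <- rev(seq_len(d[plane_axis]))
  out <- volume
  out$data <- do.call(`[`, c(list(volume$data), idx, list(drop = FALSE)))
  out
}
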