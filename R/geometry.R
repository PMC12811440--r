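## Patient-space plane arithmetic.
##
## Convention throughout the package: LPS patient coordinates in millimetres,
## 0-based voxel indices, voxel-centre sampling; a NIfTI-style affine maps
## (i, j, k, 1) to patient mm.

.unit <- function(v) {
  n <- sqrt(sum(v^2))
  if (n < 1e-12) stop("cannot normalize a zero-length vector", call. = FALSE)
  v / n
}

.cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Construct an image plane
#'
#' A plane is the patient-space placement of one image slice: an origin (the
#' patient position of voxel (0,0)), a unit normal, and two orthonormal
#' in-plane axes (the column and row directions).
#'
#' @param origin Numeric length-3, patient mm.
#' @param axis1,axis2 In-plane direction vectors (normalized internally; must
#'   be non-parallel). The normal is `axis1 x axis2`.
#' @return An object of class `"lv_plane"` with elements `origin`, `normal`,
#'   `axes` (3x2 matrix of orthonormal in-plane axes).
#' @export
plane <- function(origin, axis1, axis2) {
  stopifnot(length(origin) == 3, length(axis1) == 3, length(axis2) == 3)
  u <- .unit(axis1)
  v2 <- axis2 - sum(axis2 * u) * u   # Gram-Schmidt
  if (sqrt(sum(v2^2)) < 1e-9)
    stop("degenerate geometry: in-plane axes are parallel", call. = FALSE)
  v <- .unit(v2)
  structure(list(origin = as.numeric(origin),
                 normal = .cross(u, v),
                 axes = cbind(u, v, deparse.level = 0)),
            class = "lv_plane")
}

#' Extract the plane of one slice from a NIfTI-style affine
#'
#' @param affine 4x4 affine mapping 0-based voxel indices to patient mm.
#' @param k Slice index (0-based) along the third voxel axis.
#' @return An `"lv_plane"`.
#' @export
plane_from_affine <- function(affine, k = 0) {
  stopifnot(is.matrix(affine), all(dim(affine) == c(4, 4)))
  o <- as.numeric(affine %*% c(0, 0, k, 1))[1:3]
  plane(o, affine[1:3, 1], affine[1:3, 2])
}

#' Signed distance from points to a plane
#'
#' @param p An `"lv_plane"` or list with `origin`/`normal`.
#' @param x Numeric length-3 point or an n x 3 matrix of points.
#' @return Signed distances (positive on the normal side), mm.
#' @export
plane_distance <- function(p, x) {
  o <- if (is.null(p$origin)) p$point else p$origin
  if (is.matrix(x)) {
    sweep(x, 2, o) %*% p$normal
  } else {
    sum((x - o) * p$normal)
  }
}

#' Intersect two planes
#'
#' @param p,q `"lv_plane"` objects.
#' @return List with `point` (on both planes) and unit `direction`.
#' @export
intersect_planes <- function(p, q) {
  d <- .cross(p$normal, q$normal)
  nd <- sqrt(sum(d^2))
  if (nd <= 1e-8)
    stop("degenerate geometry: planes are parallel", call. = FALSE)
  d <- d / nd
  ## Solve for the point nearest the two origins lying on both planes:
  ## rows n_p, n_q, d with rhs the plane offsets and 0 along the line.
  A <- rbind(p$normal, q$normal, d)
  b <- c(sum(p$normal * p$origin), sum(q$normal * q$origin), 0)
  point <- as.numeric(solve(A, b))
  list(point = point, direction = d)
}

#' Intersect three planes in a point
#'
#' @param p,q,r `"lv_plane"` objects with linearly independent normals.
#' @return Patient-mm point lying on all three planes.
#' @export
three_plane_point <- function(p, q, r) {
  A <- rbind(p$normal, q$normal, r$normal)
  if (abs(det(A)) <= 1e-8)
    stop("degenerate geometry: plane normals are not independent", call. = FALSE)
  b <- c(sum(p$normal * p$origin), sum(q$normal * q$origin), sum(r$normal * r$origin))
  as.numeric(solve(A, b))
}

#' Spatial-normalization transform for one short-axis slice
#'
#' Builds the in-plane rigid+scale transform that (i) places the intersection
#' point of the short-axis, 2-chamber and 4-chamber planes at the image
#' centre, (ii) rotates the slice so the 2-chamber/short-axis intersection
#' line is parallel to the image y-axis, and (iii) rescales to 1 mm pixels.
#' The y-direction sign is chosen so that the 4-chamber/short-axis
#' intersection direction has a positive x-component after rotation.
#'
#' @param sax `"lv_plane"` of the short-axis slice.
#' @param spacing In-plane pixel spacing of the source slice, mm (length 1 or 2).
#' @param ch2,ch4 `"lv_plane"` of the long-axis views.
#' @param size Output frame side length in pixels (default 160).
#' @param source_size Optional source image size in pixels (length 1 or 2);
#'   when given, `translation` is reported relative to the source image
#'   centre pixel (zero for an already-centred slice), otherwise relative to
#'   the slice origin.
#' @return An object of class `"lv_normtransform"`: `centre` (the three-plane
#'   point), `axes` (3x2 patient-space x/y axes of the normalized frame),
#'   `translation` (in-plane mm offset of the centre, see `source_size`),
#'   `rotation_deg`, `scale` (source mm per pixel, length 2), `size`.
#' @export
normalization_transform <- function(sax, spacing, ch2, ch4, size = 160,
                                    source_size = NULL) {
  spacing <- rep(as.numeric(spacing), length.out = 2)
  if (any(spacing <= 0)) stop("scale must be strictly positive", call. = FALSE)
  centre <- three_plane_point(sax, ch2, ch4)
  l2 <- intersect_planes(sax, ch2)
  l4 <- intersect_planes(sax, ch4)
  ey <- l2$direction                       # new image y axis (sign fixed below)
  ex <- .cross(ey, sax$normal)             # in-plane, orthogonal to ey
  if (sum(ex * l4$direction) < 0) {        # 4ch line must point to +x
    ex <- -ex
    ey <- -ey
  }
  ## rotation of the slice row axis into the new x axis, about the slice normal
  cosr <- sum(sax$axes[, 1] * ex)
  sinr <- sum(.cross(sax$axes[, 1], ex) * sax$normal)
  rot <- atan2(sinr, cosr) * 180 / pi
  tr <- as.numeric(crossprod(sax$axes, centre - sax$origin))  # in-plane mm
  if (!is.null(source_size)) {
    half <- rep(source_size, length.out = 2) / 2
    tr <- tr - half * spacing
  }
  structure(list(centre = centre, axes = cbind(ex, ey, deparse.level = 0),
                 translation = tr, rotation_deg = rot,
                 scale = spacing, size = as.integer(size)),
            class = "lv_normtransform")
}

#' Patient coordinates of normalized-frame pixels
#'
#' Pixel (size/2, size/2) (0-based) is the three-plane point; pixels are 1 mm.
#'
#' @param t An `"lv_normtransform"`.
#' @param px,py 0-based pixel coordinates (vectors of equal length).
#' @return n x 3 matrix of patient-mm positions.
#' @export
norm_frame_points <- function(t, px, py) {
  half <- t$size / 2
  dx <- px - half
  dy <- py - half
  cbind(t$centre[1] + dx * t$axes[1, 1] + dy * t$axes[1, 2],
        t$centre[2] + dx * t$axes[2, 1] + dy * t$axes[2, 2],
        t$centre[3] + dx * t$axes[3, 1] + dy * t$axes[3, 2])
}

#' Fit the mitral annular plane from long-axis landmarks
#'
#' Least-squares plane through the mitral valve insertion points picked on the
#' 2-chamber and 4-chamber views (two points per view). The normal is oriented
#' so that the apex lies on its positive side.
#'
#' @param mv_2ch,mv_4ch 2x3 matrices of patient-mm landmark points.
#' @param apex_hint Patient-mm point known to lie apically of the annulus.
#' @return An object of class `"lv_mitralplane"`: `point` (centroid), unit
#'   `normal` (apex side positive), `residual_rms` (mm).
#' @export
fit_mitral_plane <- function(mv_2ch, mv_4ch, apex_hint) {
  pts <- rbind(mv_2ch, mv_4ch)
  stopifnot(ncol(pts) == 3, nrow(pts) >= 3)
  ctr <- colMeans(pts)
  X <- sweep(pts, 2, ctr)
  sv <- svd(X)
  if (sv$d[2] <= 1e-8 * max(sv$d[1], 1))
    stop("degenerate geometry: landmark points are collinear", call. = FALSE)
  n <- sv$v[, 3]
  if (sum((apex_hint - ctr) * n) < 0) n <- -n
  res <- as.numeric(X %*% n)
  structure(list(point = ctr, normal = n,
                 residual_rms = sqrt(mean(res^2))),
            class = "lv_mitralplane")
}

#' @export
print.lv_mitralplane <- function(x, ...) {
  cat("Mitral annular plane\n")
  cat(sprintf("  point : (%.2f, %.2f, %.2f) mm\n", x$point[1], x$point[2], x$point[3]))
  cat(sprintf("  normal: (%.4f, %.4f, %.4f) (apex side positive)\n",
              x$normal[1], x$normal[2], x$normal[3]))
  cat(sprintf("  landmark residual RMS: %.4f mm\n", x$residual_rms))
  invisible(x)
}
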