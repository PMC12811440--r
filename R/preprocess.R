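## Intensity normalization and resampling into the 1 mm normalized frame.

#' Clip-and-rescale intensity normalization
#'
#' Clips the image at its 99th centile (inverse-ECDF order statistic) and
#' rescales linearly so the minimum maps to 0 and the centile to 1. The
#' order-statistic centile makes the operation exactly idempotent: a second
#' application is the identity.
#'
#' @param x Numeric array (any shape) of finite values.
#' @param centile Clipping centile in (0, 1]; default 0.99.
#' @return Array of the same shape with values in [0, 1]. A constant input
#'   returns all zeros with attribute `degenerate = TRUE`.
#' @export
normalize_intensity <- function(x, centile = 0.99) {
  if (length(x) == 0) stop("empty image", call. = FALSE)
  if (!all(is.finite(x))) stop("image contains non-finite values", call. = FALSE)
  lo <- min(x)
  hi <- sort(x, partial = ceiling(centile * length(x)))[ceiling(centile * length(x))]
  if (hi <= lo) {
    out <- array(0, dim(x) %||% length(x))
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  out <- pmin((x - lo) / (hi - lo), 1)
  if (!is.null(dim(x))) dim(out) <- dim(x)
  attr(out, "degenerate") <- FALSE
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## bilinear sample of matrix M at continuous 0-based voxel coords (i, j);
## outside the grid returns `fill`
.bilinear <- function(M, i, j, fill = 0) {
  nx <- nrow(M); ny <- ncol(M)
  i0 <- floor(i); j0 <- floor(j)
  fi <- i - i0; fj <- j - j0
  get <- function(ii, jj) {
    ok <- ii >= 0 & ii <= nx - 1 & jj >= 0 & jj <= ny - 1
    v <- rep(fill, length(ii))
    v[ok] <- M[cbind(ii[ok] + 1, jj[ok] + 1)]
    v
  }
  (1 - fi) * (1 - fj) * get(i0, j0) +
    fi * (1 - fj) * get(i0 + 1, j0) +
    (1 - fi) * fj * get(i0, j0 + 1) +
    fi * fj * get(i0 + 1, j0 + 1)
}

## nearest-neighbour sample (labels)
.nearest <- function(M, i, j, fill = 0L) {
  nx <- nrow(M); ny <- ncol(M)
  ii <- round(i); jj <- round(j)
  ok <- ii >= 0 & ii <= nx - 1 & jj >= 0 & jj <= ny - 1
  v <- rep(fill, length(ii))
  v[ok] <- M[cbind(ii[ok] + 1, jj[ok] + 1)]
  v
}

#' Resample a slice into the normalized frame
#'
#' Maps one acquired slice into the spatially normalized frame defined by an
#' [normalization_transform()]: 1 mm pixels, the three-plane intersection
#' point at the image centre, the 2-chamber intersection line along +y.
#' Intensities are sampled bilinearly; pixels outside the acquired field of
#' view are 0.
#'
#' @param slice 2-D numeric matrix (one slice's pixel data).
#' @param affine 4x4 affine of that slice (0-based voxel index to patient mm).
#' @param t An `"lv_normtransform"` for the slice.
#' @return An object of class `"lv_normimage"`: `data` (size x size matrix),
#'   `transform`, `plane` (the normalized frame as an `"lv_plane"`),
#'   `pixel_mm = 1`.
#' @export
to_normalized_frame <- function(slice, affine, t) {
  stopifnot(inherits(t, "lv_normtransform"))
  n <- t$size
  px <- rep(seq_len(n) - 1, times = n)
  py <- rep(seq_len(n) - 1, each = n)
  pts <- norm_frame_points(t, px, py)
  inv <- solve(affine)
  vox <- cbind(pts, 1) %*% t(inv)
  vals <- .bilinear(slice, vox[, 1], vox[, 2])
  org <- as.numeric(norm_frame_points(t, 0, 0))
  structure(list(data = matrix(vals, n, n),
                 transform = t,
                 plane = plane(org, t$axes[, 1], t$axes[, 2]),
                 pixel_mm = 1),
            class = "lv_normimage")
}

#' Myocardial bounding-box crop
#'
#' Computes the tight bounding box of the myocardium labels of a rounded
#' segmentation, dilates it by a fixed margin, squares it by expanding the
#' short side symmetrically, and resamples image and mask to the coupling
#' resolution (80 x 80 by default; bilinear for intensities, nearest
#' neighbour for labels). The window mapping is recorded so that labels
#' decided on the crop can be mapped back to the full frame.
#'
#' @param rounded_mask Integer label matrix (0 background, 1 blood,
#'   2 myocardium), style rounded.
#' @param image Numeric matrix of the same size (the normalized image).
#' @param margin Margin in normalized pixels added around the tight box.
#' @param target Output side length in pixels.
#' @return An object of class `"lv_cropwindow"`: `x0`, `y0` (0-based window
#'   origin), `side` (window side, pixels), `scale` (window pixels per crop
#'   pixel), `image` (target x target), `mask` (target x target), `padded`
#'   (TRUE when the window had to be clipped at the image edge).
#' @export
myocardial_bounding_box <- function(rounded_mask, image, margin = 8, target = 80) {
  stopifnot(all(dim(rounded_mask) == dim(image)))
  idx <- which(rounded_mask == 2L, arr.ind = TRUE)
  if (nrow(idx) == 0)
    stop("empty myocardium: cannot define a bounding box", call. = FALSE)
  nx <- nrow(rounded_mask); ny <- ncol(rounded_mask)
  x0 <- min(idx[, 1]) - 1 - margin; x1 <- max(idx[, 1]) - 1 + margin
  y0 <- min(idx[, 2]) - 1 - margin; y1 <- max(idx[, 2]) - 1 + margin
  wx <- x1 - x0 + 1; wy <- y1 - y0 + 1
  if (wx < wy) { d <- wy - wx; x0 <- x0 - floor(d / 2); x1 <- x1 + ceiling(d / 2) }
  if (wy < wx) { d <- wx - wy; y0 <- y0 - floor(d / 2); y1 <- y1 + ceiling(d / 2) }
  padded <- x0 < 0 || y0 < 0 || x1 > nx - 1 || y1 > ny - 1
  side <- x1 - x0 + 1
  scale <- side / target
  ## crop-pixel centres in full-frame 0-based coords
  cc <- x0 + (seq_len(target) - 0.5) * scale - 0.5
  rr <- y0 + (seq_len(target) - 0.5) * scale - 0.5
  ci <- rep(cc, times = target); cj <- rep(rr, each = target)
  img80 <- matrix(.bilinear(image, ci, cj), target, target)
  msk80 <- matrix(.nearest(rounded_mask, ci, cj), target, target)
  structure(list(x0 = x0, y0 = y0, side = side, scale = scale,
                 image = img80, mask = msk80, padded = padded),
            class = "lv_cropwindow")
}
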