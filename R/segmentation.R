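## Deterministic threshold-based reference segmenters.
##
## These stand in for trained networks: a "rounded" segmenter that draws a
## smooth endocardial contour (trabeculae and papillary muscles counted as
## blood) and a "trabecular" segmenter coupled through the rounded stage that
## relabels sub-threshold pixels inside the rounded blood pool as myocardium.
## The coupling guarantees, pixel by pixel, trabecular blood subset-of rounded
## blood and trabecular myocardium superset-of rounded myocardium.

#' Otsu automatic threshold
#'
#' Maximizes the between-class variance over candidate thresholds taken at
#' midpoints between distinct sorted values (exact Otsu criterion on the
#' value multiset, no binning). A bimodality guard rejects regions of
#' interest whose density has no valley at the optimum.
#'
#' @param x Numeric vector/array of intensities.
#' @param roi_mask Optional logical mask selecting the region of interest.
#' @param check_bimodal Apply the valley test (default TRUE).
#' @return Threshold value; pixels strictly above it belong to the upper class.
#' @export
auto_threshold <- function(x, roi_mask = NULL, check_bimodal = TRUE) {
  v <- if (is.null(roi_mask)) as.numeric(x) else as.numeric(x)[as.logical(roi_mask)]
  v <- v[is.finite(v)]
  if (length(v) < 2 || max(v) - min(v) < 1e-12)
    stop("ROI is constant/unimodal; supply an explicit threshold", call. = FALSE)
  sv <- sort(v)
  n <- length(sv)
  ## between-class variance at split after index k: w1*w2*(m1-m2)^2
  cs <- cumsum(sv)
  k <- seq_len(n - 1)
  m1 <- cs[k] / k
  m2 <- (cs[n] - cs[k]) / (n - k)
  bcv <- (k / n) * ((n - k) / n) * (m1 - m2)^2
  kb <- which.max(bcv)
  thr <- (sv[kb] + sv[kb + 1]) / 2
  if (check_bimodal) {
    d <- stats::density(v, n = 256)
    at <- function(q) d$y[which.min(abs(d$x - q))]
    pk_lo <- max(d$y[d$x <= thr]); pk_hi <- max(d$y[d$x >= thr])
    if (at(thr) > 0.8 * min(pk_lo, pk_hi))
      stop("ROI appears unimodal; supply an explicit threshold", call. = FALSE)
  }
  thr
}

## two-threshold (3-class) Otsu on a 256-bin histogram: exhaustive search of
## the (t1, t2) pair maximizing between-class variance; returns the two
## thresholds (bg/myocardium and myocardium/blood for a cine frame)
.otsu2 <- function(x, nbins = 256) {
  v <- as.numeric(x)
  v <- v[is.finite(v)]
  rng <- range(v)
  if (diff(rng) < 1e-12) stop("constant image", call. = FALSE)
  br <- seq(rng[1], rng[2], length.out = nbins + 1)
  h <- tabulate(findInterval(v, br, rightmost.closed = TRUE), nbins)
  mid <- (br[-1] + br[-(nbins + 1)]) / 2
  p <- h / sum(h)
  cw <- cumsum(p); cm <- cumsum(p * mid)
  best <- -Inf; b1 <- 1; b2 <- 2
  for (i in seq_len(nbins - 2)) {
    w1 <- cw[i]
    if (w1 <= 0) next
    m1 <- cm[i] / w1
    j <- (i + 1):(nbins - 1)
    w2 <- cw[j] - cw[i]
    w3 <- 1 - cw[j]
    ok <- w2 > 0 & w3 > 0
    if (!any(ok)) next
    m2 <- (cm[j] - cm[i]) / w2
    m3 <- (cm[nbins] - cm[j]) / w3
    mt <- cm[nbins]
    s <- w1 * (m1 - mt)^2 + w2 * (m2 - mt)^2 + w3 * (m3 - mt)^2
    s[!ok] <- -Inf
    k <- which.max(s)
    if (s[k] > best) { best <- s[k]; b1 <- i; b2 <- j[k] }
  }
  c(br[b1 + 1], br[b2 + 1])
}

## fill the convex deficiency of the TRUE pixels of a logical matrix toward
## their centroid: the boundary radius is linearly interpolated (in polar
## coordinates about the centroid) between the convex-hull vertices, so the
## smoothed contour passes through the outermost tissue tips (trabecular
## crests) without the chord deficit of a Cartesian hull polygon
.convex_fill <- function(mask) {
  idx <- which(mask, arr.ind = TRUE)
  if (nrow(idx) < 3) return(mask)
  h <- grDevices::chull(idx[, 1], idx[, 2])
  cx <- mean(idx[, 1]); cy <- mean(idx[, 2])
  th <- atan2(idx[h, 2] - cy, idx[h, 1] - cx)
  rr <- sqrt((idx[h, 1] - cx)^2 + (idx[h, 2] - cy)^2)
  ## one radius per angle, periodic continuation for interpolation
  o <- order(th)
  th <- th[o]; rr <- rr[o]
  keep <- c(TRUE, diff(th) > 1e-9)
  th <- th[keep]; rr <- rr[keep]
  thp <- c(th - 2 * pi, th, th + 2 * pi)
  rrp <- c(rr, rr, rr)
  x0 <- max(1, floor(cx - max(rr))); x1 <- min(nrow(mask), ceiling(cx + max(rr)))
  y0 <- max(1, floor(cy - max(rr))); y1 <- min(ncol(mask), ceiling(cy + max(rr)))
  xs <- seq(x0, x1); ys <- seq(y0, y1)
  px <- rep(xs, times = length(ys)); py <- rep(ys, each = length(xs))
  pth <- atan2(py - cy, px - cx)
  pr <- sqrt((px - cx)^2 + (py - cy)^2)
  renv <- stats::approx(thp, rrp, xout = pth, rule = 2)$y
  out <- mask
  inside <- pr <= renv
  out[cbind(px[inside], py[inside])] <- TRUE
  out
}

## connected component (8-connexity) of `mask` containing the pixel nearest
## the image centre among TRUE pixels; empty matrix when mask is empty
.central_component <- function(mask) {
  if (!any(mask)) return(mask & FALSE)
  lab <- EBImage::bwlabel(mask * 1)
  ctr <- (dim(mask) + 1) / 2
  clab <- lab[round(ctr[1]), round(ctr[2])]
  if (clab == 0) {
    ## nearest labelled pixel to the centre decides the component
    idx <- which(lab > 0, arr.ind = TRUE)
    d2 <- (idx[, 1] - ctr[1])^2 + (idx[, 2] - ctr[2])^2
    clab <- lab[idx[which.min(d2), , drop = FALSE]]
  }
  lab == as.numeric(clab)
}

#' Rounded (smooth-contour) segmentation
#'
#' Emulates a semi-automated threshold tool with contour smoothing: blood is
#' the bright central connected component, morphologically closed and filled
#' to its convex deficiency so that papillary and trabecular pixels inside
#' the cavity are labelled blood; myocardium is the shell between that
#' rounded endocardial contour and the outer (epicardial) threshold boundary.
#'
#' @param norm_image An `"lv_normimage"` or a plain numeric matrix in [0, 1].
#' @param threshold Blood/myocardium threshold, or `"auto"` (Otsu inside the
#'   tissue region).
#' @param tissue_threshold Tissue/background threshold, or `"auto"`.
#' @param smoothing_radius_mm Radius of the morphological closing, mm.
#' @param min_component_px Minimum size of the central tissue component;
#'   smaller components raise an empty-segmentation error.
#' @return Integer label matrix (0 background, 1 LV blood, 2 LV myocardium)
#'   of class `"lv_labelmask"` with attributes `style = "rounded"` and
#'   `degenerate` (TRUE when no blood pool was found, myocardium-only mask).
#' @export
segment_rounded <- function(norm_image, threshold = "auto",
                            tissue_threshold = "auto",
                            smoothing_radius_mm = 3,
                            min_component_px = 200) {
  img <- if (inherits(norm_image, "lv_normimage")) norm_image$data else norm_image
  pixel_mm <- if (inherits(norm_image, "lv_normimage")) norm_image$pixel_mm else 1
  if (identical(tissue_threshold, "auto")) tissue_threshold <- auto_threshold(img)
  tissue <- img > tissue_threshold
  epi <- .central_component(tissue)
  if (sum(epi) < min_component_px)
    stop("empty segmentation: no tissue component at the image centre", call. = FALSE)
  epi <- EBImage::fillHull(epi * 1) > 0
  degenerate <- FALSE
  if (identical(threshold, "auto"))
    threshold <- tryCatch(auto_threshold(img, roi_mask = epi),
                          error = function(e) NA_real_)
  r_px <- max(1, round(smoothing_radius_mm / pixel_mm))
  brush <- EBImage::makeBrush(2 * r_px + 1, shape = "disc")
  ## grayscale closing fills dark ridges/papillary slivers narrower than the
  ## smoothing element with the surrounding blood intensity while leaving
  ## smooth edges invariant, so the threshold then traces the smoothed
  ## (envelope) endocardial contour rather than the trabeculated one
  img_s <- EBImage::closing(img, brush)
  if (is.na(threshold) || !any(img_s > threshold & epi)) {
    blood <- epi & FALSE
    degenerate <- TRUE
  } else {
    blood_raw <- .central_component(img_s > threshold & epi)
    if (!any(blood_raw)) {
      blood <- epi & FALSE
      degenerate <- TRUE
    } else {
      closed <- EBImage::closing(blood_raw * 1, brush) > 0
      blood <- .convex_fill(closed) & epi
    }
  }
  mask <- matrix(0L, nrow(img), ncol(img))
  mask[epi] <- 2L
  mask[blood] <- 1L
  structure(mask, class = c("lv_labelmask", class(mask)),
            style = "rounded", degenerate = degenerate,
            thresholds = c(tissue = tissue_threshold,
                           blood = if (is.na(threshold)) NA_real_ else threshold))
}

#' Trabecular segmentation coupled through the rounded stage
#'
#' Within the rounded blood pool, pixels whose intensity (sampled from the
#' 80 x 80 myocardial crop) falls at or below the blood/myocardium threshold
#' are relabelled myocardium; all labels outside the rounded blood pool are
#' kept. The output therefore satisfies, pixelwise, trabecular blood
#' subset-of rounded blood and trabecular myocardium superset-of rounded
#' myocardium. A failure of the rounded stage propagates.
#'
#' @param crop An `"lv_cropwindow"` from [myocardial_bounding_box()] (the
#'   coupling resolution at which intensities are read).
#' @param rounded_mask The full-frame rounded `"lv_labelmask"`.
#' @param threshold Blood/trabeculae threshold or `"auto"` (Otsu over the
#'   crop pixels lying inside the rounded blood pool).
#' @return Full-frame `"lv_labelmask"` with `style = "trabecular"`; the
#'   80 x 80 crop-frame mask is attached as attribute `crop_mask`.
#' @export
segment_trabecular <- function(crop, rounded_mask, threshold = "auto") {
  stopifnot(inherits(crop, "lv_cropwindow"))
  if (!any(rounded_mask == 1L))
    stop("empty segmentation: rounded blood pool is empty (propagated)", call. = FALSE)
  in_blood80 <- crop$mask == 1L
  if (identical(threshold, "auto"))
    threshold <- auto_threshold(crop$image, roi_mask = in_blood80)
  ## decide on the crop, then map the decision back to the full frame
  idx <- which(rounded_mask == 1L, arr.ind = TRUE)
  ci <- (idx[, 1] - 1 - crop$x0 + 0.5) / crop$scale - 0.5
  cj <- (idx[, 2] - 1 - crop$y0 + 0.5) / crop$scale - 0.5
  vals <- .bilinear(crop$image, ci, cj)
  out <- rounded_mask
  dark <- vals <= threshold
  out[idx[dark, , drop = FALSE]] <- 2L
  crop80 <- crop$mask
  crop80[in_blood80 & crop$image <= threshold] <- 2L
  structure(unclass(out), class = class(rounded_mask),
            style = "trabecular",
            degenerate = isTRUE(attr(rounded_mask, "degenerate")),
            crop_mask = crop80, threshold = threshold)
}
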