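## Mitral-plane-clipped Simpson volumetry.
##
## Each short-axis slice is treated as a slab of thickness equal to the
## slice spacing centred on the slice plane. Labelled in-plane pixels
## contribute pixel area x slab height x the fraction of the slab's
## thickness interval lying on the apex (ventricular) side of the mitral
## annular plane; the fraction is computed per pixel column, linear in the
## plane offset (partial inclusion of basal voxels).

#' Ventricular fraction of a slab interval at given in-plane positions
#'
#' For voxel columns centred at `points` on a slice with unit `normal` and
#' slab thickness `height`, returns the fraction of the thickness interval
#' `[-height/2, +height/2]` (along the normal) lying on the apex side of the
#' mitral plane: 0 if fully atrial, 1 if fully ventricular, linear in the
#' plane offset in between.
#'
#' @param points n x 3 matrix (or length-3 vector) of column centres, mm.
#' @param normal Unit stack normal.
#' @param height Slab thickness, mm (> 0).
#' @param mp An `"lv_mitralplane"` (normal oriented toward the apex).
#' @return Numeric vector of fractions in [0, 1].
#' @export
clip_fraction <- function(points, normal, height, mp) {
  if (height <= 0) stop("slab height must be > 0", call. = FALSE)
  if (is.null(dim(points))) points <- matrix(points, ncol = 3)
  d0 <- as.numeric(plane_distance(mp, points))      # signed, apex side > 0
  slope <- sum(normal * mp$normal)                  # d along the slab axis
  d1 <- d0 - slope * height / 2
  d2 <- d0 + slope * height / 2
  lo <- pmin(d1, d2); hi <- pmax(d1, d2)
  ## length of {t in [lo, hi] : t > 0} / (hi - lo); constant d -> 0/1 step
  ifelse(abs(hi - lo) < 1e-12, as.numeric(d0 > 0),
         pmin(pmax(hi, 0) - pmax(lo, 0), hi - lo) / (hi - lo))
}

#' Stack volume of one label with mitral-plane clipping
#'
#' @param masks List of per-slice label masks (`"lv_labelmask"` or plain
#'   integer matrices).
#' @param planes List of per-slice `"lv_plane"` objects (same length),
#'   giving each pixel grid's patient-space placement.
#' @param pixel_mm In-plane pixel size, mm (isotropic in the normalized frame).
#' @param slab_mm Slab thickness (slice spacing), mm.
#' @param mp `"lv_mitralplane"`, or `NULL` for no clipping.
#' @param label Which label to integrate: 1 (blood) or 2 (myocardium).
#' @return Volume in mL.
#' @export
stack_volume <- function(masks, planes, pixel_mm, slab_mm, mp, label) {
  if (length(masks) != length(planes))
    stop("masks and planes must pair one to one", call. = FALSE)
  if (slab_mm <= 0) stop("slab height must be > 0", call. = FALSE)
  total <- 0
  for (i in seq_along(masks)) {
    idx <- which(masks[[i]] == label, arr.ind = TRUE)
    if (nrow(idx) == 0) next
    pl <- planes[[i]]
    pts <- cbind(pl$origin[1] + (idx[, 1] - 1) * pixel_mm * pl$axes[1, 1] +
                   (idx[, 2] - 1) * pixel_mm * pl$axes[1, 2],
                 pl$origin[2] + (idx[, 1] - 1) * pixel_mm * pl$axes[2, 1] +
                   (idx[, 2] - 1) * pixel_mm * pl$axes[2, 2],
                 pl$origin[3] + (idx[, 1] - 1) * pixel_mm * pl$axes[3, 1] +
                   (idx[, 2] - 1) * pixel_mm * pl$axes[3, 2])
    frac <- if (is.null(mp)) rep(1, nrow(idx)) else clip_fraction(pts, pl$normal, slab_mm, mp)
    total <- total + sum(frac) * pixel_mm^2 * slab_mm
  }
  total / 1000
}

#' Body surface area (Mosteller)
#'
#' @param height_cm,weight_kg Positive height (cm) and weight (kg).
#' @return BSA in m^2: `sqrt(height * weight / 3600)`.
#' @export
bsa <- function(height_cm, weight_kg) {
  if (any(height_cm <= 0) || any(weight_kg <= 0))
    stop("height and weight must be > 0", call. = FALSE)
  sqrt(height_cm * weight_kg / 3600)
}

#' Clinical LV metric set from per-phase volumes
#'
#' End-diastole and end-systole are the phases of maximal and minimal blood
#' volume. Mass is myocardial volume at ED times 1.05 g/mL.
#'
#' @param blood_ml Per-phase blood-pool volumes, mL (length >= 2).
#' @param myo_ml Per-phase myocardial volumes, mL (same length).
#' @param bsa_m2 Body surface area, m^2.
#' @param method `"rounded"` or `"trabecular"`.
#' @return An object of class `"lv_metrics"` (a one-row data frame): `EDV_ml`,
#'   `ESV_ml`, `SV_ml`, `EF_pct`, `LVM_g`, `BSA_m2`, `EDVi`, `ESVi`, `SVi`,
#'   `LVMi`, `method`.
#' @export
lv_metrics <- function(blood_ml, myo_ml, bsa_m2, method = c("rounded", "trabecular")) {
  method <- match.arg(method)
  if (length(blood_ml) < 2)
    stop("at least two phases are required", call. = FALSE)
  if (length(myo_ml) != length(blood_ml))
    stop("blood and myocardial volumes must cover the same phases", call. = FALSE)
  edv <- max(blood_ml); esv <- min(blood_ml)
  if (edv <= 0) stop("end-diastolic volume is zero", call. = FALSE)
  sv <- edv - esv
  ef <- 100 * sv / edv
  lvm <- myo_ml[which.max(blood_ml)] * 1.05
  out <- data.frame(method = method,
                    EDV_ml = edv, ESV_ml = esv, SV_ml = sv, EF_pct = ef,
                    LVM_g = lvm, BSA_m2 = bsa_m2,
                    EDVi = edv / bsa_m2, ESVi = esv / bsa_m2,
                    SVi = sv / bsa_m2, LVMi = lvm / bsa_m2)
  class(out) <- c("lv_metrics", "data.frame")
  out
}

#' @export
print.lv_metrics <- function(x, ...) {
  for (i in seq_len(nrow(x))) {
    cat(sprintf("LV metrics (%s segmentation)\n", x$method[i]))
    cat(sprintf("  EDV %.1f mL  ESV %.1f mL  SV %.1f mL  EF %.1f%%  LVM %.1f g\n",
                x$EDV_ml[i], x$ESV_ml[i], x$SV_ml[i], x$EF_pct[i], x$LVM_g[i]))
    cat(sprintf("  indexed (BSA %.2f m2): EDVi %.1f  ESVi %.1f  SVi %.1f  LVMi %.1f\n",
                x$BSA_m2[i], x$EDVi[i], x$ESVi[i], x$SVi[i], x$LVMi[i]))
  }
  invisible(x)
}
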