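## Synthetic cardiac phantom with known rounded and trabecular ground truth.
##
## Anatomy model (phantom "LV frame", mm): the left ventricle is a
## thick-walled shell whose apical half is a truncated ellipsoid and whose
## basal half is a cylinder. +z points from apex to base; the epicardial apex
## sits at z = -c. Trabeculae are sinusoidal radial ridges of the endocardial
## surface; papillary muscles are two cylinders inside the cavity. The
## "rounded" truth uses the smooth (ridge-free) endocardial surface with
## papillaries counted as blood; the "trabecular" truth uses the ridged
## surface with papillaries counted as myocardium. End-systole contracts the
## cavity radially by es_cavity_scale; intermediate phases interpolate the
## scale cosinusoidally. The mitral annular plane sits at 0.4*c above the
## ellipsoid centre, tilted by base_tilt_deg about the x-axis; anatomy
## continues 8 mm past it (into the atrio-ventricular junction) so that
## volumetry must clip at the plane rather than at the end of the anatomy.

.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Phantom specification
#'
#' Geometric and acquisition parameters of the synthetic left-ventricle
#' phantom. Defaults describe a healthy-sized LV (rounded EDV about 105 mL,
#' EF about 64%, mass about 100 g) with modest trabeculation.
#'
#' @param epi_semi_axes mm triple (a, a, c): in-plane and long-axis semi-axes
#'   of the epicardial ellipsoid.
#' @param wall_thickness Myocardial wall thickness, mm.
#' @param trabecular_amplitude Radial depth of the endocardial ridges, mm
#'   (0 = smooth endocardium).
#' @param trabecular_count Number of ridges around the circumference.
#' @param papillary_radius Radius of the two papillary cylinders, mm (0 = none).
#' @param es_cavity_scale Radial cavity scale at end-systole, in (0, 1).
#' @param n_slices,slice_spacing Short-axis stack geometry (count, mm).
#' @param in_plane_spacing Acquired pixel size, mm.
#' @param base_tilt_deg Tilt of the mitral annular plane about the x-axis,
#'   degrees.
#' @param intensity_blood,intensity_myo,intensity_bg Tissue intensities,
#'   arbitrary units.
#' @param noise_sd Additive Gaussian noise SD, arbitrary units.
#' @param n_phases Number of cardiac phases (>= 2); phase 0 is end-diastole
#'   and phase n_phases/2 end-systole.
#' @param truth_res_mm Isotropic voxel size of the ground-truth voxelization
#'   oracle, mm.
#' @return An object of class `"lv_phantomspec"`.
#' @export
phantom_spec <- function(epi_semi_axes = c(33, 33, 55),
                         wall_thickness = 8,
                         trabecular_amplitude = 2.2,
                         trabecular_count = 16,
                         papillary_radius = 4,
                         es_cavity_scale = 0.6,
                         n_slices = 12,
                         slice_spacing = 8,
                         in_plane_spacing = 1.25,
                         base_tilt_deg = 12,
                         intensity_blood = 0.85,
                         intensity_myo = 0.35,
                         intensity_bg = 0.05,
                         noise_sd = 0.02,
                         n_phases = 2,
                         truth_res_mm = 0.25) {
  spec <- list(epi_semi_axes = as.numeric(epi_semi_axes),
               wall_thickness = as.numeric(wall_thickness),
               trabecular_amplitude = as.numeric(trabecular_amplitude),
               trabecular_count = as.integer(trabecular_count),
               papillary_radius = as.numeric(papillary_radius),
               es_cavity_scale = as.numeric(es_cavity_scale),
               n_slices = as.integer(n_slices),
               slice_spacing = as.numeric(slice_spacing),
               in_plane_spacing = as.numeric(in_plane_spacing),
               base_tilt_deg = as.numeric(base_tilt_deg),
               intensity_blood = as.numeric(intensity_blood),
               intensity_myo = as.numeric(intensity_myo),
               intensity_bg = as.numeric(intensity_bg),
               noise_sd = as.numeric(noise_sd),
               n_phases = as.integer(n_phases),
               truth_res_mm = as.numeric(truth_res_mm))
  class(spec) <- "lv_phantomspec"
  validate_phantom_spec(spec)
  spec
}

#' @rdname phantom_spec
#' @param spec An `"lv_phantomspec"`.
#' @export
validate_phantom_spec <- function(spec) {
  fail <- function(field, msg) stop(sprintf("invalid phantom spec: field '%s' %s", field, msg),
                                    call. = FALSE)
  a <- spec$epi_semi_axes
  if (length(a) != 3 || any(a <= 0)) fail("epi_semi_axes", "must be 3 positive values")
  if (abs(a[1] - a[2]) > 1e-9) fail("epi_semi_axes", "must be circular in-plane (a, a, c)")
  if (spec$wall_thickness <= 0) fail("wall_thickness", "must be > 0")
  if (spec$wall_thickness >= min(a)) fail("wall_thickness", "must be smaller than the semi-axes")
  if (spec$es_cavity_scale <= 0 || spec$es_cavity_scale >= 1)
    fail("es_cavity_scale", "must lie strictly in (0, 1)")
  cav_r <- spec$es_cavity_scale * (a[1] - spec$wall_thickness)
  if (spec$trabecular_amplitude < 0) fail("trabecular_amplitude", "must be >= 0")
  if (spec$trabecular_amplitude >= cav_r)
    fail("trabecular_amplitude", "must be smaller than the end-systolic cavity radius")
  if (spec$trabecular_count < 1) fail("trabecular_count", "must be >= 1")
  if (spec$papillary_radius < 0) fail("papillary_radius", "must be >= 0")
  if (spec$papillary_radius > 0 && spec$papillary_radius >= 0.5 * cav_r)
    fail("papillary_radius", "must be smaller than half the end-systolic cavity radius")
  if (spec$n_slices < 1) fail("n_slices", "must be >= 1")
  if (spec$slice_spacing <= 0) fail("slice_spacing", "must be > 0")
  if (spec$in_plane_spacing <= 0) fail("in_plane_spacing", "must be > 0")
  if (spec$noise_sd < 0) fail("noise_sd", "must be >= 0")
  if (spec$n_phases < 2) fail("n_phases", "must be >= 2")
  if (spec$truth_res_mm <= 0) fail("truth_res_mm", "must be > 0")
  invisible(spec)
}

## derived geometry constants of a spec
.lv_geom <- function(spec) {
  a <- spec$epi_semi_axes[1]; c_ <- spec$epi_semi_axes[3]; w <- spec$wall_thickness
  list(a = a, c = c_, w = w, ri = a - w, ci = c_ - w,
       z_base = 0.4 * c_,                      # mitral plane centre height
       z_cap = 0.4 * c_ + 8,                   # geometric truncation of anatomy
       pap_az = c(100, 260) * pi / 180,        # papillary azimuths
       pap_z = c(-0.45 * (c_ - w), 0.55 * 0.4 * c_))
}

## cavity scale of phase p (0-based); ED at p = 0, ES at p = n/2
.phase_scale <- function(spec, p) {
  s <- spec$es_cavity_scale
  s + (1 - s) * (1 + cos(2 * pi * p / spec$n_phases)) / 2
}

## smooth (rounded) endocardial radius at height z, cavity scale s
.r_endo <- function(g, z, s) {
  r <- ifelse(z < 0, ifelse(z <= -g$ci, 0, g$ri * sqrt(pmax(0, 1 - (z / g$ci)^2))), g$ri)
  ifelse(z > g$z_cap, 0, s * r)
}

## epicardial radius at height z
.r_epi <- function(g, z) {
  r <- ifelse(z < 0, ifelse(z <= -g$c, 0, g$a * sqrt(pmax(0, 1 - (z / g$c)^2))), g$a)
  ifelse(z > g$z_cap, 0, r)
}

## classify LV-frame points at cavity scale s; returns logical vectors
.lv_classify <- function(spec, x, y, z, s) {
  g <- .lv_geom(spec)
  r2 <- x^2 + y^2
  re <- .r_epi(g, z)
  in_epi <- r2 <= re^2 & re > 0
  rr <- .r_endo(g, z, s)
  blood_round <- r2 < rr^2 & rr > 0
  th <- atan2(y, x)
  ridge <- spec$trabecular_amplitude * (1 + sin(spec$trabecular_count * th)) / 2
  rt <- pmax(rr - ridge, 0)
  blood_trab <- r2 < rt^2 & rt > 0
  if (spec$papillary_radius > 0) {
    rho <- 0.5 * s * g$ri
    for (az in g$pap_az) {
      cx <- rho * cos(az); cy <- rho * sin(az)
      pap <- (x - cx)^2 + (y - cy)^2 <= spec$papillary_radius^2 &
        z >= g$pap_z[1] & z <= g$pap_z[2]
      blood_trab <- blood_trab & !pap
    }
  }
  list(in_epi = in_epi, blood_round = blood_round, blood_trab = blood_trab)
}

## mitral plane in LV frame: point + apex-pointing unit normal
.mitral_lv <- function(spec) {
  g <- .lv_geom(spec)
  t <- spec$base_tilt_deg * pi / 180
  ## rotate (0,0,-1) about the x-axis by the tilt
  list(point = c(0, 0, g$z_base), normal = c(0, sin(t), -cos(t)))
}

## voxel-counting core of the truth oracle: volumes (mL) of the four truth
## compartments at cavity scale s, clipped to the apex side of plane mp
.voxelize_volumes <- function(spec, s, mp, res_mm) {
  g <- .lv_geom(spec)
  xs <- seq(-g$a - 1, g$a + 1, by = res_mm)
  zs <- seq(-g$c - 1, g$z_cap + 1, by = res_mm)
  xg <- rep(xs, times = length(xs))
  yg <- rep(xs, each = length(xs))
  acc <- c(cr = 0, ct = 0, mr = 0, mt = 0)
  for (z in zs) {
    ## apex side of the mitral plane (normal points apically)
    keep <- (xg - mp$point[1]) * mp$normal[1] +
      (yg - mp$point[2]) * mp$normal[2] +
      (z - mp$point[3]) * mp$normal[3] > 0
    if (!any(keep)) next
    cl <- .lv_classify(spec, xg[keep], yg[keep], z, s)
    acc["cr"] <- acc["cr"] + sum(cl$blood_round)
    acc["ct"] <- acc["ct"] + sum(cl$blood_trab)
    acc["mr"] <- acc["mr"] + sum(cl$in_epi & !cl$blood_round)
    acc["mt"] <- acc["mt"] + sum(cl$in_epi & !cl$blood_trab)
  }
  acc * res_mm^3 / 1000
}

#' Ground-truth phantom volumes by fine voxelization
#'
#' Voxelizes the analytic phantom anatomy on an isotropic grid and counts
#' voxel centres, clipping to the apex side of the mitral annular plane.
#' This is the in-repo oracle for all downstream volumetry.
#'
#' @param spec An `"lv_phantomspec"`.
#' @param res_mm Isotropic grid resolution (default `spec$truth_res_mm`).
#' @return An object of class `"lv_phantomtruth"`: a data frame with one row
#'   per phase and columns `phase`, `cavity_scale`, `cavity_volume_rounded_ml`,
#'   `cavity_volume_trabecular_ml`, `myo_volume_rounded_ml`,
#'   `myo_volume_trabecular_ml`; the LV-frame mitral plane is attached as
#'   attribute `mitral_plane_lv`.
#' @export
phantom_truth <- function(spec, res_mm = spec$truth_res_mm) {
  validate_phantom_spec(spec)
  mp <- .mitral_lv(spec)
  out <- vector("list", spec$n_phases)
  for (p in seq_len(spec$n_phases) - 1L) {
    s <- .phase_scale(spec, p)
    acc <- .voxelize_volumes(spec, s, mp, res_mm) * 1000 / res_mm^3
    vox_ml <- res_mm^3 / 1000
    out[[p + 1L]] <- data.frame(phase = p, cavity_scale = s,
                                cavity_volume_rounded_ml = acc[["cr"]] * vox_ml,
                                cavity_volume_trabecular_ml = acc[["ct"]] * vox_ml,
                                myo_volume_rounded_ml = acc[["mr"]] * vox_ml,
                                myo_volume_trabecular_ml = acc[["mt"]] * vox_ml)
  }
  truth <- do.call(rbind, out)
  attr(truth, "mitral_plane_lv") <- mp
  attr(truth, "res_mm") <- res_mm
  class(truth) <- c("lv_phantomtruth", "data.frame")
  truth
}

## default rigid placement of the LV frame in patient (LPS mm) space
.lv_placement <- function() {
  rz <- function(d) { t <- d * pi / 180; matrix(c(cos(t), sin(t), 0, -sin(t), cos(t), 0, 0, 0, 1), 3, 3) }
  rx <- function(d) { t <- d * pi / 180; matrix(c(1, 0, 0, 0, cos(t), sin(t), 0, -sin(t), cos(t)), 3, 3) }
  list(R = rz(15) %*% rx(-20), t = c(-35, 30, -60))
}

## rotation matrix about an arbitrary unit axis
.rot_axis <- function(axis, deg) {
  u <- .unit(axis); t <- deg * pi / 180
  K <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
  diag(3) + sin(t) * K + (1 - cos(t)) * (K %*% K)
}

## render one view: plane given in LV frame (centre, axes, normal), pixel
## grid n x n, spacing sp; returns intensity matrix (noise added by caller)
.render_view <- function(spec, centre, u, v, n, sp, s) {
  off <- (seq_len(n) - 1 - (n - 1) / 2) * sp
  px <- rep(off, times = n); py <- rep(off, each = n)
  x <- centre[1] + px * u[1] + py * v[1]
  y <- centre[2] + px * u[2] + py * v[2]
  z <- centre[3] + px * u[3] + py * v[3]
  cl <- .lv_classify(spec, x, y, z, s)
  val <- rep(spec$intensity_bg, n * n)
  val[cl$in_epi] <- spec$intensity_myo
  val[cl$blood_trab] <- spec$intensity_blood
  matrix(val, n, n)
}

#' Generate a synthetic cine acquisition of the phantom
#'
#' Renders a short-axis cine stack plus 2-chamber and 4-chamber long-axis
#' views with consistent patient-space affines, mitral valve landmarks lying
#' exactly on the phantom's mitral plane, and the voxelization ground truth.
#'
#' @param spec An `"lv_phantomspec"`.
#' @param seed Integer seed controlling the image noise.
#' @param jitter Optional acquisition repositioning: a list with
#'   `slice_offset_mm` (shift of the stack along its normal), `rotation_deg`
#'   and `rotation_axis` (rigid rotation of the acquisition frame about the
#'   mid-stack point). The anatomy (and hence the truth) is unchanged.
#' @param truth Optional precomputed `"lv_phantomtruth"` (reused across
#'   rescan acquisitions); computed at `spec$truth_res_mm` when `NULL`.
#' @return An object of class `"lv_phantom"`: lists `sax`, `ch2`, `ch4` (one
#'   element per phase, each with `data` array and 4x4 `affine`), `landmarks`
#'   (`mv_2ch`, `mv_4ch`: 2x3 patient-mm matrices), `mitral_plane` (patient
#'   frame), `truth`, `spec`, `seed`.
#' @export
make_phantom <- function(spec, seed = 1L, jitter = NULL, truth = NULL) {
  validate_phantom_spec(spec)
  g <- .lv_geom(spec)
  pl <- .lv_placement()
  if (is.null(truth)) truth <- phantom_truth(spec)
  if (identical(truth, FALSE)) truth <- NULL

  ## acquisition frame in LV coordinates (before jitter): SAX normal +z
  span <- g$c + g$z_cap
  z0 <- -g$c + (span - (spec$n_slices - 1) * spec$slice_spacing) / 2
  zc <- z0 + (spec$n_slices - 1) * spec$slice_spacing / 2   # mid-stack point
  ax_u <- c(1, 0, 0); ax_v <- c(0, 1, 0); ax_w <- c(0, 0, 1)
  if (!is.null(jitter)) {
    dz <- if (is.null(jitter$slice_offset_mm)) 0 else jitter$slice_offset_mm
    rdeg <- if (is.null(jitter$rotation_deg)) 0 else jitter$rotation_deg
    raxis <- if (is.null(jitter$rotation_axis)) c(1, 0, 0) else jitter$rotation_axis
    if (abs(dz) >= spec$slice_spacing)
      warning("jitter slice offset is >= slice spacing; aliasing risk")
    if (rdeg != 0) {
      Rj <- .rot_axis(raxis, rdeg)
      ax_u <- as.numeric(Rj %*% ax_u); ax_v <- as.numeric(Rj %*% ax_v)
      ax_w <- as.numeric(Rj %*% ax_w)
    }
    z0 <- z0 + dz
  }
  slice_centres <- lapply(seq_len(spec$n_slices) - 1L, function(i)
    c(0, 0, zc) + (z0 - zc + i * spec$slice_spacing) * ax_w)

  ## long-axis views contain the LV long axis; azimuths 0 (2ch) and 75 (4ch)
  lax <- function(az_deg) {
    t <- az_deg * pi / 180
    list(normal = c(cos(t), sin(t), 0), u = c(-sin(t), cos(t), 0), v = c(0, 0, 1))
  }
  ch2g <- lax(0); ch4g <- lax(75)

  n_sax <- as.integer(round((2 * g$a + 70) / spec$in_plane_spacing))
  n_lax <- as.integer(round((2 * max(g$a, g$c) + 70) / spec$in_plane_spacing))

  to_pat <- function(x) as.numeric(pl$R %*% x + pl$t)
  affine_of <- function(origin_lv, u, v, w, sp, step) {
    A <- diag(4)
    A[1:3, 1] <- pl$R %*% (u * sp); A[1:3, 2] <- pl$R %*% (v * sp)
    A[1:3, 3] <- pl$R %*% (w * step); A[1:3, 4] <- to_pat(origin_lv)
    A
  }

  .with_seed(seed, {
    sax <- ch2 <- ch4 <- vector("list", spec$n_phases)
    for (p in seq_len(spec$n_phases) - 1L) {
      s <- .phase_scale(spec, p)
      stack <- array(0, c(n_sax, n_sax, spec$n_slices))
      for (i in seq_len(spec$n_slices))
        stack[, , i] <- .render_view(spec, slice_centres[[i]], ax_u, ax_v,
                                     n_sax, spec$in_plane_spacing, s)
      if (spec$noise_sd > 0)
        stack <- stack + array(stats::rnorm(length(stack), 0, spec$noise_sd), dim(stack))
      o1 <- slice_centres[[1]] -
        ((n_sax - 1) / 2) * spec$in_plane_spacing * (ax_u + ax_v)
      sax[[p + 1L]] <- list(data = stack,
                            affine = affine_of(o1, ax_u, ax_v, ax_w,
                                               spec$in_plane_spacing, spec$slice_spacing))
      for (vw in list(list(geom = ch2g, slot = "ch2"), list(geom = ch4g, slot = "ch4"))) {
        gm <- vw$geom
        lax_ctr <- c(0, 0, (g$z_cap - g$c) / 2)
        im <- .render_view(spec, lax_ctr, gm$u, gm$v,
                           n_lax, spec$in_plane_spacing, s)
        if (spec$noise_sd > 0)
          im <- im + matrix(stats::rnorm(length(im), 0, spec$noise_sd), nrow(im))
        ol <- lax_ctr -
          ((n_lax - 1) / 2) * spec$in_plane_spacing * (gm$u + gm$v)
        rec <- list(data = array(im, c(n_lax, n_lax, 1)),
                    affine = affine_of(ol, gm$u, gm$v, gm$normal,
                                       spec$in_plane_spacing, 1))
        if (vw$slot == "ch2") ch2[[p + 1L]] <- rec else ch4[[p + 1L]] <- rec
      }
    }

    ## mitral valve landmarks: intersection of the mitral plane with each
    ## long-axis plane, at the end-diastolic endocardial radius
    mp <- .mitral_lv(spec)
    lm <- function(gm) {
      d <- .unit(.cross(mp$normal, gm$normal))
      tt <- g$ri / sqrt(d[1]^2 + d[2]^2)
      rbind(mp$point + tt * d, mp$point - tt * d)
    }
    mv2 <- t(apply(lm(ch2g), 1, to_pat))
    mv4 <- t(apply(lm(ch4g), 1, to_pat))

    structure(list(sax = sax, ch2 = ch2, ch4 = ch4,
                   landmarks = list(mv_2ch = mv2, mv_4ch = mv4),
                   mitral_plane = list(point = to_pat(mp$point),
                                       normal = as.numeric(pl$R %*% mp$normal)),
                   apex = to_pat(c(0, 0, -g$c)),
                   truth = truth, spec = spec, seed = seed),
              class = "lv_phantom")
  })
}

#' Generate a scan-rescan acquisition pair of one phantom
#'
#' Two acquisitions of the same anatomy (one shared ground truth), differing
#' only in acquisition grid position/orientation and voxel noise, emulating
#' same-day repositioning between repeat scans.
#'
#' @param spec An `"lv_phantomspec"`.
#' @param jitter List: `slice_offset_sd_mm`, `rotation_sd_deg` (SDs of the
#'   drawn repositioning), `reseed_noise` (logical; `FALSE` replays the same
#'   noise stream on the rescan).
#' @param seed Integer seed.
#' @param compute_truth Compute the shared voxelization truth (default TRUE;
#'   precision studies that only compare measurements can skip it).
#' @return List with elements `scan1`, `scan2` (class `"lv_phantom"`, sharing
#'   one `truth`) and `jitter_drawn`.
#' @export
make_rescan_pair <- function(spec,
                             jitter = list(slice_offset_sd_mm = 2,
                                           rotation_sd_deg = 2,
                                           reseed_noise = TRUE),
                             seed = 1L, compute_truth = TRUE) {
  validate_phantom_spec(spec)
  dz_sd <- if (is.null(jitter$slice_offset_sd_mm)) 0 else jitter$slice_offset_sd_mm
  rot_sd <- if (is.null(jitter$rotation_sd_deg)) 0 else jitter$rotation_sd_deg
  reseed <- if (is.null(jitter$reseed_noise)) TRUE else isTRUE(jitter$reseed_noise)
  draws <- .with_seed(seed + 2L, {
    ax <- stats::rnorm(3); if (all(ax == 0)) ax <- c(1, 0, 0)
    list(slice_offset_mm = stats::rnorm(1, 0, 1) * dz_sd,
         rotation_deg = stats::rnorm(1, 0, 1) * rot_sd,
         rotation_axis = .unit(ax))
  })
  truth <- if (compute_truth) phantom_truth(spec) else FALSE
  scan1 <- make_phantom(spec, seed = seed, truth = truth)
  j2 <- if (dz_sd == 0 && rot_sd == 0) NULL else draws
  scan2 <- make_phantom(spec, seed = if (reseed) seed + 1L else seed,
                        jitter = j2, truth = truth)
  list(scan1 = scan1, scan2 = scan2, jitter_drawn = draws)
}

#' Simulate a two-observer segmentation-error audit
#'
#' Each case has a latent error status with the given prevalence; each of two
#' blinded observers overlooks a true error independently with probability
#' `(1 - observer_agreement) / 2` and never reports an error on a clean case,
#' so `observer_agreement = 1` reproduces the latent labels exactly and zero
#' prevalence yields all-zero labels.
#'
#' @param n_cases Number of cases (>= 2).
#' @param error_prevalence Probability a case truly contains an error.
#' @param observer_agreement Reliability in [0, 1]; 1 = perfect agreement.
#' @param seed Integer seed.
#' @return Integer matrix `n_cases` x 2 of 0/1 labels, columns `obs1`, `obs2`;
#'   attribute `degenerate` is `TRUE` when no errors were generated.
#' @export
simulate_error_audit <- function(n_cases, error_prevalence, observer_agreement, seed = 1L) {
  if (n_cases < 2) stop("n_cases must be >= 2", call. = FALSE)
  if (error_prevalence < 0 || error_prevalence > 1)
    stop("error_prevalence must lie in [0, 1]", call. = FALSE)
  if (observer_agreement < 0 || observer_agreement > 1)
    stop("observer_agreement must lie in [0, 1]", call. = FALSE)
  .with_seed(seed, {
    truth <- stats::rbinom(n_cases, 1, error_prevalence)
    eps <- (1 - observer_agreement) / 2
    o1 <- truth * (stats::runif(n_cases) >= eps)
    o2 <- truth * (stats::runif(n_cases) >= eps)
    m <- cbind(obs1 = as.integer(o1), obs2 = as.integer(o2))
    attr(m, "degenerate") <- sum(m) == 0
    m
  })
}

#' Simulate a survival cohort with hazard log-linear in LV metrics
#'
#' Event times are drawn from an exponential proportional-hazards model,
#' `rate_i = baseline_rate * exp(sum(beta * x_i))`, with administrative
#' censoring at `censor_horizon`.
#'
#' @param spec List with `n_subjects`, `beta_per_covariate` (named or
#'   unnamed numeric, log-hazard per unit of each covariate),
#'   `baseline_rate` (> 0, events per unit time), `censor_horizon`, `seed`.
#' @param covariates Numeric matrix or data frame, `n_subjects` rows, one
#'   column per covariate.
#' @return Data frame `time`, `event` plus the covariate columns; attribute
#'   `degenerate` is `TRUE` when every subject is censored.
#' @export
simulate_cohort_survival <- function(spec, covariates) {
  covariates <- as.data.frame(covariates)
  if (spec$n_subjects < 2) stop("n_subjects must be >= 2", call. = FALSE)
  if (spec$baseline_rate <= 0) stop("baseline_rate must be > 0", call. = FALSE)
  if (nrow(covariates) != spec$n_subjects)
    stop("covariates must have one row per subject", call. = FALSE)
  X <- as.matrix(covariates)
  beta <- rep(as.numeric(spec$beta_per_covariate), length.out = ncol(X))
  .with_seed(spec$seed, {
    rate <- spec$baseline_rate * exp(as.numeric(X %*% beta))
    tt <- stats::rexp(spec$n_subjects, rate)
    event <- as.integer(tt <= spec$censor_horizon)
    out <- data.frame(time = pmin(tt, spec$censor_horizon), event = event)
    out <- cbind(out, covariates)
    if (all(event == 0)) {
      warning("all subjects censored; survival fits will be degenerate")
      attr(out, "degenerate") <- TRUE
    } else attr(out, "degenerate") <- FALSE
    out
  })
}

#' @export
print.lv_phantomspec <- function(x, ...) {
  g <- .lv_geom(x)
  cat("LV phantom spec\n")
  cat(sprintf("  epicardium (a,a,c): (%g, %g, %g) mm; wall %g mm\n",
              x$epi_semi_axes[1], x$epi_semi_axes[2], x$epi_semi_axes[3], x$wall_thickness))
  cat(sprintf("  trabeculae: %d ridges, %g mm deep; papillary radius %g mm\n",
              x$trabecular_count, x$trabecular_amplitude, x$papillary_radius))
  cat(sprintf("  ES cavity scale %g over %d phases; mitral plane at z=%g mm, tilt %g deg\n",
              x$es_cavity_scale, x$n_phases, g$z_base, x$base_tilt_deg))
  cat(sprintf("  stack: %d slices x %g mm; pixels %g mm; noise SD %g\n",
              x$n_slices, x$slice_spacing, x$in_plane_spacing, x$noise_sd))
  invisible(x)
}
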