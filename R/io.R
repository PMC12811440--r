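## Study I/O (NIfTI + JSON sidecars) and pipeline orchestration.

#' Write a phantom study to disk
#'
#' One NIfTI file per view per phase (sform affine, patient mm, LPS
#' convention), a JSON landmark sidecar and a JSON ground-truth file.
#'
#' @param phantom An `"lv_phantom"`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_study <- function(phantom, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wr <- function(rec, name) {
    im <- RNifti::asNifti(rec$data)
    RNifti::sform(im) <- structure(rec$affine, code = 2L)
    RNifti::writeNifti(im, file.path(dir, name))
  }
  for (p in seq_along(phantom$sax)) {
    wr(phantom$sax[[p]], sprintf("sax_phase%02d.nii", p - 1))
    wr(phantom$ch2[[p]], sprintf("ch2_phase%02d.nii", p - 1))
    wr(phantom$ch4[[p]], sprintf("ch4_phase%02d.nii", p - 1))
  }
  lm <- phantom$landmarks
  jsonlite::write_json(list(mv_2ch = unname(split(lm$mv_2ch, row(lm$mv_2ch))),
                            mv_4ch = unname(split(lm$mv_4ch, row(lm$mv_4ch)))),
                       file.path(dir, "landmarks.json"),
                       auto_unbox = FALSE, digits = NA)
  if (!is.null(phantom$truth)) {
    tr <- as.data.frame(phantom$truth)
    jsonlite::write_json(list(truth = tr,
                              mitral_plane = phantom$mitral_plane,
                              seed = phantom$seed),
                         file.path(dir, "truth.json"), digits = NA)
  }
  invisible(dir)
}

.read_nifti_rec <- function(path) {
  if (!file.exists(path)) stop(sprintf("missing image file '%s'", path), call. = FALSE)
  im <- RNifti::readNifti(path)
  aff <- matrix(as.numeric(RNifti::xform(im, useQuaternionFirst = FALSE)), 4, 4)
  ## validate the rotation block: direction cosines must be orthonormal
  B <- aff[1:3, 1:3]
  sc <- sqrt(colSums(B^2))
  if (any(sc <= 0)) stop(sprintf("degenerate affine in '%s'", path), call. = FALSE)
  Rm <- sweep(B, 2, sc, "/")
  if (max(abs(crossprod(Rm) - diag(3))) > 1e-4)
    stop(sprintf("invalid affine in '%s': rotation block is not orthonormal", path),
         call. = FALSE)
  a <- as.array(im)
  if (length(dim(a)) == 2) dim(a) <- c(dim(a), 1)
  list(data = a, affine = aff)
}

#' Read a study directory
#'
#' @param dir Directory written by [write_study()] (or laid out the same
#'   way: `sax_phaseNN.nii`, `ch2_phaseNN.nii`, `ch4_phaseNN.nii`,
#'   `landmarks.json`, optional `truth.json`).
#' @return A list shaped like an `"lv_phantom"`: `sax`, `ch2`, `ch4`,
#'   `landmarks`, and `truth`/`mitral_plane` when the truth file is present.
#' @export
read_study <- function(dir) {
  saxf <- sort(list.files(dir, "^sax_phase[0-9]+\\.nii$", full.names = TRUE))
  if (length(saxf) == 0) stop(sprintf("no short-axis images found in '%s'", dir), call. = FALSE)
  phases <- seq_along(saxf)
  get <- function(stem) lapply(phases, function(p)
    .read_nifti_rec(file.path(dir, sprintf("%s_phase%02d.nii", stem, p - 1))))
  lmf <- file.path(dir, "landmarks.json")
  if (!file.exists(lmf)) stop("missing landmark sidecar 'landmarks.json'", call. = FALSE)
  lm <- jsonlite::read_json(lmf, simplifyVector = TRUE)
  for (key in c("mv_2ch", "mv_4ch"))
    if (is.null(lm[[key]]))
      stop(sprintf("landmark sidecar is missing key '%s'", key), call. = FALSE)
  tomat <- function(x) {
    m <- if (is.matrix(x)) x else do.call(rbind, x)
    matrix(as.numeric(m), nrow = nrow(m))
  }
  out <- list(sax = get("sax"), ch2 = get("ch2"), ch4 = get("ch4"),
              landmarks = list(mv_2ch = tomat(lm$mv_2ch), mv_4ch = tomat(lm$mv_4ch)))
  trf <- file.path(dir, "truth.json")
  if (file.exists(trf)) {
    tr <- jsonlite::read_json(trf, simplifyVector = TRUE)
    out$truth <- tr$truth
    out$mitral_plane <- list(point = as.numeric(tr$mitral_plane$point),
                             normal = as.numeric(tr$mitral_plane$normal))
  }
  class(out) <- "lv_phantom"
  out
}

## ---------------------------------------------------------------------------
## quantification chain for one study

## segment one normalized slice with both styles; returns list(rounded, trab)
.segment_slice <- function(nim, t_tissue, t_round, t_trab, smoothing_radius_mm = 3) {
  rounded <- tryCatch(
    segment_rounded(nim, threshold = t_round, tissue_threshold = t_tissue,
                    smoothing_radius_mm = smoothing_radius_mm),
    error = function(e) NULL)
  if (is.null(rounded)) {
    empty <- matrix(0L, nrow(nim$data), ncol(nim$data))
    return(list(rounded = empty, trab = empty))
  }
  trab <- if (any(rounded == 1L) && any(rounded == 2L)) {
    tryCatch({
      crop <- myocardial_bounding_box(rounded, nim$data)
      segment_trabecular(crop, rounded, threshold = t_trab)
    }, error = function(e) rounded)
  } else rounded
  list(rounded = rounded, trab = trab)
}

#' Run the full quantification chain on one study
#'
#' Spatial normalization (1 mm frame centred on the three-plane intersection
#' point), stack-wise intensity normalization, rounded and coupled
#' trabecular segmentation of every slice, mitral-plane fitting from the
#' landmark sidecar, and mitral-plane-clipped Simpson volumetry for both
#' styles at every phase.
#'
#' @param study An `"lv_phantom"` (from [make_phantom()] or [read_study()]).
#' @param height_cm,weight_kg Subject body habitus for BSA indexing.
#' @param smoothing_radius_mm Rounded-contour smoothing radius.
#' @param keep_masks Keep per-slice label masks in the result.
#' @param fail_rounded Fault injection: raise an error in the rounded stage
#'   (used to exercise coupled-failure propagation).
#' @return An object of class `"lv_analysis"`: `metrics` (two-row data
#'   frame, methods rounded and trabecular), `volumes` (per phase x style
#'   blood/myo volumes), `mitral` (fitted `"lv_mitralplane"`),
#'   `thresholds`, optionally `masks`.
#' @export
analyze_study <- function(study, height_cm = 170, weight_kg = 70,
                          smoothing_radius_mm = 3, keep_masks = FALSE,
                          fail_rounded = FALSE) {
  if (fail_rounded)
    stop("rounded segmentation failed (injected fault)", call. = FALSE)
  n_phases <- length(study$sax)
  ch2pl <- plane_from_affine(study$ch2[[1]]$affine, 0)
  ch4pl <- plane_from_affine(study$ch4[[1]]$affine, 0)

  all_masks <- vector("list", n_phases)
  all_planes <- vector("list", n_phases)
  thresholds <- NULL
  slab <- NULL
  for (p in seq_len(n_phases)) {
    sax <- study$sax[[p]]
    n_slices <- dim(sax$data)[3]
    slab <- sqrt(sum(sax$affine[1:3, 3]^2))
    spacing <- sqrt(colSums(sax$affine[1:3, 1:2, drop = FALSE]^2))
    norm_stack <- normalize_intensity(sax$data)
    ## 3-class Otsu split, refined to midpoints of the class intensity modes
    ## (density peaks of pure tissue) so that boundary placement is unbiased
    ## at tissue interfaces under symmetric noise and partial voluming
    th2 <- .otsu2(norm_stack)
    cls <- findInterval(norm_stack, th2)
    mu <- vapply(0:2, function(g) {
      v <- norm_stack[cls == g]
      d <- stats::density(v, n = 512)
      d$x[which.max(d$y)]
    }, numeric(1))
    t_tissue <- (mu[1] + mu[2]) / 2
    ## rounded endocardial cut: inclusive 30% point between the myocardial
    ## and blood modes -- the rounded convention assigns predominantly-blood
    ## partial-volume pixels (trabecular crests) to the blood pool
    t_round <- mu[2] + 0.3 * (mu[3] - mu[2])
    ## trabecular relabelling cut: unbiased midpoint of the tissue modes
    t_trab <- (mu[2] + mu[3]) / 2
    thresholds <- c(tissue = t_tissue, rounded = t_round, trabecular = t_trab)
    masks <- vector("list", n_slices)
    planes <- vector("list", n_slices)
    for (k in seq_len(n_slices)) {
      sl_aff <- sax$affine
      sl_aff[1:3, 4] <- sl_aff[1:3, 4] + (k - 1) * sl_aff[1:3, 3]
      sl_plane <- plane_from_affine(sax$affine, k - 1)
      tr <- normalization_transform(sl_plane, spacing, ch2pl, ch4pl)
      nim <- to_normalized_frame(norm_stack[, , k], sl_aff, tr)
      seg <- .segment_slice(nim, t_tissue, t_round, t_trab, smoothing_radius_mm)
      masks[[k]] <- seg
      planes[[k]] <- nim$plane
    }
    all_masks[[p]] <- masks
    all_planes[[p]] <- planes
  }

  ## apex hint: blood centroid of the median non-empty slice of phase 1
  m1 <- all_masks[[1]]
  nz <- which(vapply(m1, function(m) sum(m$rounded == 1L) > 0, logical(1)))
  if (length(nz) == 0) stop("no blood pool found in any slice", call. = FALSE)
  kmid <- nz[ceiling(length(nz) / 2)]
  idx <- which(m1[[kmid]]$rounded == 1L, arr.ind = TRUE)
  pl <- all_planes[[1]][[kmid]]
  ctr_px <- colMeans(idx) - 1
  apex_hint <- pl$origin + ctr_px[1] * pl$axes[, 1] + ctr_px[2] * pl$axes[, 2]
  mitral <- fit_mitral_plane(study$landmarks$mv_2ch, study$landmarks$mv_4ch,
                             apex_hint)

  vols <- do.call(rbind, lapply(seq_len(n_phases), function(p) {
    msk <- all_masks[[p]]; pls <- all_planes[[p]]
    data.frame(phase = p - 1,
               blood_rounded = stack_volume(lapply(msk, `[[`, "rounded"), pls, 1, slab, mitral, 1L),
               myo_rounded = stack_volume(lapply(msk, `[[`, "rounded"), pls, 1, slab, mitral, 2L),
               blood_trab = stack_volume(lapply(msk, `[[`, "trab"), pls, 1, slab, mitral, 1L),
               myo_trab = stack_volume(lapply(msk, `[[`, "trab"), pls, 1, slab, mitral, 2L))
  }))
  b <- bsa(height_cm, weight_kg)
  metrics <- rbind(lv_metrics(vols$blood_rounded, vols$myo_rounded, b, "rounded"),
                   lv_metrics(vols$blood_trab, vols$myo_trab, b, "trabecular"))
  out <- list(metrics = metrics, volumes = vols, mitral = mitral,
              thresholds = thresholds)
  if (keep_masks) { out$masks <- all_masks; out$planes <- all_planes }
  class(out) <- "lv_analysis"
  out
}

#' @export
print.lv_analysis <- function(x, ...) {
  cat("LV quantification\n")
  print(as.data.frame(x$metrics)[, c("method", "EDV_ml", "ESV_ml", "SV_ml",
                                     "EF_pct", "LVM_g")],
        row.names = FALSE, digits = 4)
  invisible(x)
}

## ---------------------------------------------------------------------------
## pipeline orchestration

.config_hash <- function(config) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA, force = TRUE), f)
  unname(tools::md5sum(f))
}

.write_output <- function(df, path, hash, seed) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# config_hash=%s seed=%d", hash, seed), con)
  utils::write.csv(df, con, row.names = FALSE)
  path
}

#' Default pipeline configuration
#'
#' @param n_subjects Phantom cohort size for the metrics stage.
#' @param n_rescan Scan-rescan pairs for the precision stage (0 disables).
#' @param n_audit Cases for the simulated two-observer error audit.
#' @param n_cohort Subjects for the simulated survival cohort.
#' @param seed Master seed; every stage derives its randomness from it.
#' @param truth_res_mm Ground-truth voxelization resolution for the cohort.
#' @param n_boot Bootstrap resamples for precision statistics.
#' @param out_dir Output directory, or `NULL` to skip writing files.
#' @param inject_rounded_failure Subject indices whose rounded stage fails
#'   (fault-injection; the trabecular stage reports a propagated failure).
#' @return A `"lv_runconfig"` list.
#' @export
pipeline_config <- function(n_subjects = 10, n_rescan = 0, n_audit = 533,
                            n_cohort = 300, seed = 1L, truth_res_mm = 0.5,
                            n_boot = 2000, out_dir = NULL,
                            inject_rounded_failure = integer(0)) {
  structure(list(n_subjects = n_subjects, n_rescan = n_rescan,
                 n_audit = n_audit, n_cohort = n_cohort,
                 seed = as.integer(seed), truth_res_mm = truth_res_mm,
                 n_boot = n_boot, out_dir = out_dir,
                 inject_rounded_failure = inject_rounded_failure),
            class = "lv_runconfig")
}

## draw a subject-varied phantom spec (anatomical spread of a cohort)
.draw_spec <- function(truth_res_mm = 0.5) {
  phantom_spec(epi_semi_axes = c(1, 1, 0) * stats::runif(1, 30, 36) +
                 c(0, 0, stats::runif(1, 50, 60)),
               wall_thickness = stats::runif(1, 7, 10),
               trabecular_amplitude = stats::runif(1, 1.5, 3),
               trabecular_count = sample(12:20, 1),
               papillary_radius = stats::runif(1, 3, 5),
               es_cavity_scale = stats::runif(1, 0.55, 0.7),
               base_tilt_deg = stats::runif(1, 5, 15),
               truth_res_mm = truth_res_mm)
}

#' Run the end-to-end evaluation pipeline
#'
#' Simulates a phantom cohort, runs the quantification chain with both
#' segmentation styles, and produces the evaluation tables: per-subject
#' metrics, rounded-vs-trabecular differences (Bland-Altman, EF
#' reclassification), scan-rescan precision, a simulated two-observer error
#' audit (Cohen's kappa), and a simulated survival cohort with Cox model
#' comparison. Deterministic given the config seed; outputs (when written)
#' carry the config hash and seed.
#'
#' @param config An `"lv_runconfig"` from [pipeline_config()].
#' @return An object of class `"lv_run"`: `metrics`, `status` (per subject x
#'   stage), `bland_altman` (per metric), `reclassification`, `precision`
#'   (when `n_rescan > 0`), `audit` (kappa), `prognosis` (Cox comparison
#'   tables), `config`, `config_hash`.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "lv_runconfig"))
  ## hash the scientific parameters only, not the output location
  hash <- .config_hash(unclass(config)[setdiff(names(config), "out_dir")])
  seed <- config$seed

  ## --- metrics stage: phantom cohort, both styles -------------------------
  rows <- list(); status <- list()
  specs <- .with_seed(seed, lapply(seq_len(config$n_subjects), function(i)
    .draw_spec(config$truth_res_mm)))
  hw <- .with_seed(seed + 1L, data.frame(height = stats::rnorm(config$n_subjects, 170, 10),
                                         weight = stats::rnorm(config$n_subjects, 75, 12)))
  for (i in seq_len(config$n_subjects)) {
    ph <- make_phantom(specs[[i]], seed = seed + 10L + i, truth = FALSE)
    res <- tryCatch(
      analyze_study(ph, height_cm = hw$height[i], weight_kg = hw$weight[i],
                    fail_rounded = i %in% config$inject_rounded_failure),
      error = function(e) e)
    if (inherits(res, "error")) {
      status[[i]] <- data.frame(subject_id = i,
                                stage = c("rounded", "trabecular"),
                                status = c("failed", "propagated_failure"),
                                message = conditionMessage(res))
    } else {
      status[[i]] <- data.frame(subject_id = i, stage = c("rounded", "trabecular"),
                                status = "ok", message = "")
      m <- res$metrics
      m$subject_id <- i
      rows[[i]] <- m[, c("subject_id", "method", "EDV_ml", "ESV_ml", "SV_ml",
                         "EF_pct", "LVM_g", "BSA_m2", "EDVi", "ESVi", "SVi", "LVMi")]
    }
  }
  metrics <- do.call(rbind, rows)
  status <- do.call(rbind, status)

  out <- list(metrics = metrics, status = status, config = config,
              config_hash = hash)

  if (!is.null(metrics) && nrow(metrics) >= 4) {
    r <- metrics[metrics$method == "rounded", ]
    t <- metrics[metrics$method == "trabecular", ]
    t <- t[match(r$subject_id, t$subject_id), ]
    out$bland_altman <- lapply(c(EDV = "EDV_ml", ESV = "ESV_ml",
                                 LVM = "LVM_g", EF = "EF_pct"),
                               function(cl) bland_altman(r[[cl]], t[[cl]]))
    out$reclassification <- ef_reclassification(r$EF_pct, t$EF_pct)
  }

  ## --- precision stage ----------------------------------------------------
  if (config$n_rescan > 0) {
    rspecs <- .with_seed(seed + 2L, lapply(seq_len(config$n_rescan), function(i)
      .draw_spec(config$truth_res_mm)))
    prs <- lapply(seq_len(config$n_rescan), function(i) {
      pr <- make_rescan_pair(rspecs[[i]], seed = seed + 1000L + 7L * i,
                             compute_truth = FALSE)
      a1 <- analyze_study(pr$scan1); a2 <- analyze_study(pr$scan2)
      cbind(scan1 = a1$metrics[, -1], scan2 = a2$metrics[, -1],
            method = a1$metrics$method)
    })
    prec <- do.call(rbind, lapply(c("EDV_ml", "ESV_ml", "SV_ml", "EF_pct", "LVM_g"),
      function(cl) {
        do.call(rbind, lapply(c("rounded", "trabecular"), function(me) {
          x1 <- vapply(prs, function(d) d[d$method == me, paste0("scan1.", cl)], numeric(1))
          x2 <- vapply(prs, function(d) d[d$method == me, paste0("scan2.", cl)], numeric(1))
          cbind(data.frame(metric = cl, method = me),
                precision_report(x1, x2, n_boot = config$n_boot, seed = seed))
        }))
      }))
    out$precision <- prec
  }

  ## --- agreement stage ----------------------------------------------------
  if (config$n_audit >= 2) {
    aud <- simulate_error_audit(config$n_audit, error_prevalence = 0.028,
                                observer_agreement = 0.67, seed = seed + 5L)
    tab <- table(factor(aud[, 1], 0:1), factor(aud[, 2], 0:1))
    out$audit <- c(list(table = tab), cohen_kappa(tab))
  }

  ## --- prognosis stage ----------------------------------------------------
  if (config$n_cohort >= 10) {
    ## survival cohort on a synthetic metric distribution whose hazard is
    ## log-linear in the (rounded) EDVi; the trabecular EDVi is the same
    ## quantity measured with the systematic offset seen in the metrics stage
    edvi_r <- .with_seed(seed + 6L, stats::rnorm(config$n_cohort, 75, 14))
    edvi_t <- .with_seed(seed + 7L, 0.92 * edvi_r + stats::rnorm(config$n_cohort, 0, 2))
    surv <- simulate_cohort_survival(
      list(n_subjects = config$n_cohort, beta_per_covariate = 0.02,
           baseline_rate = 0.01, censor_horizon = 5.5, seed = seed + 8L),
      data.frame(edvi_rounded = edvi_r))
    surv$edvi_trabecular <- edvi_t
    fa <- fit_cox(surv, "edvi_rounded")
    fb <- fit_cox(surv, "edvi_trabecular")
    out$prognosis <- list(rounded = fa, trabecular = fb,
                          comparison = compare_models(fa, fb, seed = seed + 9L),
                          schoenfeld_p = c(rounded = schoenfeld_global(fa),
                                           trabecular = schoenfeld_global(fb)))
  }

  ## --- outputs ------------------------------------------------------------
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    if (!is.null(out$metrics))
      .write_output(out$metrics, file.path(config$out_dir, "metrics.csv"), hash, seed)
    .write_output(out$status, file.path(config$out_dir, "status.csv"), hash, seed)
    if (!is.null(out$precision))
      .write_output(out$precision, file.path(config$out_dir, "precision.csv"), hash, seed)
    if (!is.null(out$reclassification))
      .write_output(out$reclassification,
                    file.path(config$out_dir, "reclassification.csv"), hash, seed)
  }
  class(out) <- "lv_run"
  out
}

#' @export
print.lv_run <- function(x, ...) {
  cat(sprintf("Pipeline run (seed %d, config %s)\n", x$config$seed, x$config_hash))
  cat(sprintf("  subjects analysed: %d ok, %d failed\n",
              sum(x$status$status == "ok") / 2,
              sum(x$status$status == "failed")))
  if (!is.null(x$metrics)) {
    agg <- stats::aggregate(cbind(EDV_ml, EF_pct, LVM_g) ~ method, x$metrics, mean)
    print(agg, row.names = FALSE, digits = 4)
  }
  invisible(x)
}
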