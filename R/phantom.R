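#' Synthetic head-CT phantom specification
#'
#' Describes a synthetic non-contrast head CT with exact ground truth: an
#' ellipsoidal skull shell around a brain compartment of white matter, a
#' cortical grey-matter shell and a thin subarachnoid CSF rim; paired lateral
#' ventricles with frontal horns plus a midline septum/third-ventricle slab;
#' basal cisterns as an annulus around a brainstem cylinder at the skull base;
#' optional hyperdense lesions of prescribed volume; an optional 1-voxel
#' parasagittal hyperdense sheet emulating the falx/venous-sinus "false
#' lesion"; and a configurable rigid lateral displacement of the midline
#' structures producing a known midline shift.
#'
#' @param grid_shape integer length-3 voxel grid.
#' @param spacing voxel size in mm (length 3).
#' @param skull_hu,gm_hu,wm_hu,csf_hu,lesion_hu mean attenuation per class (HU).
#' @param noise_sigma additive Gaussian noise standard deviation (HU).
#' @param induced_shift signed lateral displacement of the ventricles and
#'   septum in mm (+x); must lie within ±20 mm.
#' @param lesion_volumes list of lesions, each `list(volume_ml=, side=)` with
#'   side `"left"` or `"right"` (image side); a bare numeric vector is
#'   interpreted as volumes with alternating sides.
#' @param cistern_volume target basal-cistern volume in mL.
#' @param decoy_falx logical; add the hyperdense midline decoy sheet (60 HU).
#' @param seed integer RNG seed; identical spec + seed gives bit-identical
#'   phantoms.
#' @return an object of class `phantom_spec`.
#' @export
phantom_spec <- function(grid_shape = c(144L, 168L, 128L),
                         spacing = c(1, 1, 1),
                         skull_hu = 1000, gm_hu = 40, wm_hu = 30,
                         csf_hu = 8, lesion_hu = 70,
                         noise_sigma = 3,
                         induced_shift = 0,
                         lesion_volumes = list(),
                         cistern_volume = 10,
                         decoy_falx = FALSE,
                         seed = 1L) {
  if (is.numeric(lesion_volumes)) {
    sides <- rep(c("right", "left"), length.out = length(lesion_volumes))
    lesion_volumes <- Map(function(v, s) list(volume_ml = v, side = s),
                          lesion_volumes, sides)
  }
  spec <- structure(list(
    grid_shape = as.integer(grid_shape), spacing = as.numeric(spacing),
    skull_hu = skull_hu, gm_hu = gm_hu, wm_hu = wm_hu, csf_hu = csf_hu,
    lesion_hu = lesion_hu, noise_sigma = noise_sigma,
    induced_shift = induced_shift, lesion_volumes = lesion_volumes,
    cistern_volume = cistern_volume, decoy_falx = isTRUE(decoy_falx),
    seed = as.integer(seed)), class = "phantom_spec")
  validate_phantom_spec(spec)
  spec
}

#' @noRd
validate_phantom_spec <- function(spec) {
  stopifnot(length(spec$grid_shape) == 3, length(spec$spacing) == 3)
  if (any(spec$spacing <= 0)) stop("spacing must be > 0")
  if (abs(spec$induced_shift) > 20) stop("induced_shift must be within ±20 mm")
  vols <- vapply(spec$lesion_volumes, function(l) l$volume_ml, numeric(1))
  if (any(vols < 0)) stop("lesion volumes must be >= 0")
  if (spec$cistern_volume < 0) stop("cistern_volume must be >= 0")
  if (spec$noise_sigma < 0) stop("noise_sigma must be >= 0")
  invisible(spec)
}

#' @export
print.phantom_spec <- function(x, ...) {
  cat(sprintf("<phantom_spec> grid %s @ %s mm, shift %.2f mm, %d lesion(s), cisterns %.1f mL, seed %d\n",
              paste(x$grid_shape, collapse = "x"),
              paste(signif(x$spacing, 3), collapse = "x"),
              x$induced_shift, length(x$lesion_volumes), x$cistern_volume, x$seed))
  invisible(x)
}

# Internal geometry model, all in mm.  Every structure is parameterized
# relative to the inner-skull (cranial cavity) semi-axes so that phantoms at
# any grid/spacing share their topology.  `jitter` scales the semi-axes
# per axis (used to create anatomical variability for the atlas cohort).
#' @noRd
phantom_geometry <- function(spec, jitter = c(1, 1, 1)) {
  fov <- spec$grid_shape * spec$spacing
  centre <- (spec$grid_shape - 1) / 2 * spec$spacing
  # >= 10 mm air margin on every side at the default grid, so that the
  # full head stays in the field of view under atlas-scale translations
  outer <- c(0.42, 0.43, 0.40) * fov * jitter
  shell <- max(3, 0.045 * fov[1])
  inner <- pmax(outer - shell, outer * 0.5)
  list(fov = fov, centre = centre, outer = outer, inner = inner)
}

# Squared normalized ellipsoidal radius field for given centre/semi-axes.
#' @noRd
ellipsoid_r2 <- function(dims, spacing, centre, semi) {
  x2 <- (((seq_len(dims[1]) - 1) * spacing[1] - centre[1]) / semi[1])^2
  y2 <- (((seq_len(dims[2]) - 1) * spacing[2] - centre[2]) / semi[2])^2
  z2 <- (((seq_len(dims[3]) - 1) * spacing[3] - centre[3]) / semi[3])^2
  outer(outer(x2, y2, "+"), z2, "+")
}

#' Generate a synthetic head-CT phantom
#'
#' Voxel values are the per-class mean HU plus Gaussian noise; midline
#' structures (ventricles, septum) are rigidly displaced laterally by
#' `induced_shift` with CSF/tissue backfill, so the true midline shift is
#' exactly known.  Lesions are grown voxel-by-voxel inside the brain
#' parenchyma (excluding CSF structures) to match the requested volume.
#'
#' @param spec a [phantom_spec()].
#' @param jitter internal per-axis semi-axis multipliers (anatomical
#'   variability for atlas construction).
#' @return an object of class `phantom_case`: fields `ct` (a [ct_volume()]),
#'   binary truth volumes `truth_brain`, `truth_gm`, `truth_wm`, `truth_csf`,
#'   `truth_ventricles`, `truth_cisterns`, `truth_lesions`, the scalar
#'   `truth_mls` (mm), and the generating `spec`.
#' @export
generate_phantom <- function(spec, jitter = c(1, 1, 1)) {
  validate_phantom_spec(spec)
  with_seed(spec$seed, {
    dims <- spec$grid_shape; sp <- spec$spacing
    g <- phantom_geometry(spec, jitter)
    cc <- g$centre; a <- g$inner
    s <- spec$induced_shift

    r2_out <- ellipsoid_r2(dims, sp, cc, g$outer)
    r2_in <- ellipsoid_r2(dims, sp, cc, a)
    head <- r2_out <= 1
    cavity <- r2_in <= 1

    # base tissue: WM core, GM cortical shell, thin subarachnoid CSF rim
    gm <- cavity & r2_in > 0.88^2 & r2_in <= 0.97^2
    rim <- cavity & r2_in > 0.97^2
    wm <- cavity & !gm & !rim

    # lateral ventricles: paired bodies + frontal horns + midline septum slab,
    # all translated by the induced shift
    vent <- array(FALSE, dims)
    for (side in c(-1, 1)) {
      body_c <- cc + c(side * 0.17 * a[1] + s, -0.03 * a[2], 0.22 * a[3])
      vent <- vent | (ellipsoid_r2(dims, sp, body_c,
                                   c(0.085 * a[1], 0.37 * a[2], 0.16 * a[3])) <= 1)
      horn_c <- cc + c(side * 0.20 * a[1] + s, -0.45 * a[2], 0.19 * a[3])
      vent <- vent | (ellipsoid_r2(dims, sp, horn_c,
                                   c(0.10 * a[1], 0.16 * a[2], 0.14 * a[3])) <= 1)
    }
    sept_c <- cc + c(s, -0.10 * a[2], 0.17 * a[3])
    vent <- vent | (ellipsoid_r2(dims, sp, sept_c,
                                 c(2.5, 0.22 * a[2], 0.15 * a[3])) <= 1)
    vent <- vent & cavity

    # brainstem cylinder + basal cistern annulus around it
    xv <- (seq_len(dims[1]) - 1) * sp[1]
    yv <- (seq_len(dims[2]) - 1) * sp[2]
    zv <- (seq_len(dims[3]) - 1) * sp[3]
    stem_xy <- c(cc[1], cc[2] + 0.08 * a[2])
    rxy2 <- outer((xv - stem_xy[1])^2, (yv - stem_xy[2])^2, "+")
    r_stem <- 0.15 * a[1]
    zidx_stem <- zv >= cc[3] - 0.85 * a[3] & zv <= cc[3] - 0.15 * a[3]
    stem <- array(FALSE, dims)
    stem[, , zidx_stem] <- rxy2 <= r_stem^2
    stem <- stem & cavity

    cist <- array(FALSE, dims)
    if (spec$cistern_volume > 0) {
      h <- 0.38 * a[3]
      zidx_c <- zv >= cc[3] - 0.62 * a[3] & zv <= cc[3] - 0.62 * a[3] + h
      eligible <- array(FALSE, dims)
      eligible[, , zidx_c] <- rxy2 > r_stem^2
      eligible <- eligible & cavity & r2_in <= 0.9^2
      k <- as.integer(round(spec$cistern_volume * 1000 / prod(sp)))
      if (sum(eligible) < k)
        stop("cistern volume does not fit around the brainstem")
      # grow the annulus radially to the exact voxel count; radius ties are
      # mirror-symmetric groups (<= 8 voxels), kept or dropped whole so the
      # phantom stays left-right symmetric
      rxy_full <- array(rxy2, dims)
      dall <- rxy_full[eligible]
      thr <- sort(dall, partial = k)[k]
      n_incl <- sum(dall <= thr)
      n_excl <- sum(dall < thr)
      use_thr <- if (abs(n_incl - k) <= abs(n_excl - k)) thr else thr * (1 - 1e-12)
      cist <- eligible & rxy_full <= use_thr
      dim(cist) <- dims
    }

    # class codes: 0 air, 1 skull, 2 wm, 3 gm, 4 csf, 5 lesion, 6 falx
    cls <- array(0L, dims)
    cls[head & !cavity] <- 1L
    cls[wm] <- 2L
    cls[gm] <- 3L
    cls[rim] <- 4L
    cls[stem] <- 2L
    cls[vent] <- 4L
    cls[cist] <- 4L

    # fixed anatomical landmarks that anchor orientation during
    # registration: an air-filled frontal sinus in the anterior skull shell,
    # and pineal + paired choroid-plexus calcifications (at skull
    # attenuation, as calcified tissue) inside the posterior brain
    shell_w <- g$outer[2] - a[2]
    shell <- head & !cavity
    sinus <- ellipsoid_r2(dims, sp, cc + c(0, -(a[2] + 0.5 * shell_w), 0.1 * a[3]),
                          c(11, 0.75 * shell_w, 10)) <= 1
    cls[sinus & shell] <- 0L
    # occipital protuberance: posterior midline skull thickening
    bump <- ellipsoid_r2(dims, sp, cc + c(0, a[2] + 0.2 * shell_w, -0.15 * a[3]),
                         c(13, 2.2 * shell_w, 13)) <= 1
    cls[bump & head] <- 1L
    # petrous ridges: paired dense wedges at the lateral skull base
    for (side in c(-1, 1)) {
      pet <- ellipsoid_r2(dims, sp,
                          cc + c(side * 0.52 * a[1], 0.12 * a[2], -0.78 * a[3]),
                          c(16, 11, 9)) <= 1
      cls[pet & shell] <- 1L
    }
    calc <- ellipsoid_r2(dims, sp, cc + c(0, 0.18 * a[2], 0.18 * a[3]),
                         c(2.5, 2.5, 2.5)) <= 1
    for (side in c(-1, 1))
      calc <- calc | (ellipsoid_r2(dims, sp,
                                   cc + c(side * 0.19 * a[1] + s, 0.28 * a[2], 0.20 * a[3]),
                                   c(2.2, 2.2, 2.2)) <= 1)
    calc <- calc & cavity
    cls[calc] <- 1L

    falx <- array(FALSE, dims)
    if (spec$decoy_falx) {
      ix <- round(cc[1] / sp[1]) + 1
      yidx <- yv >= cc[2] + 0.05 * a[2] & yv <= cc[2] + 0.72 * a[2]
      zidx <- zv >= cc[3] - 0.05 * a[3] & zv <= cc[3] + 0.75 * a[3]
      sheet <- array(FALSE, dims)
      sheet[ix, yidx, zidx] <- TRUE
      falx <- sheet & cavity & r2_in <= 0.97^2 & cls != 4L
      cls[falx] <- 6L
    }

    # lesions grown to the requested voxel count inside parenchyma
    lesions <- array(FALSE, dims)
    voxvol <- prod(sp)
    if (length(spec$lesion_volumes)) {
      for (les in spec$lesion_volumes) {
        if (les$volume_ml <= 0) next
        k <- max(1L, as.integer(round(les$volume_ml * 1000 / voxvol)))
        side <- if (identical(les$side, "left")) -1 else 1
        seed_pt <- les$centre %||%
          (cc + c(side * 0.55 * a[1], 0.08 * a[2], 0.25 * a[3]))
        allowed <- (cls == 2L | cls == 3L) & !lesions
        if (sum(allowed) < k)
          stop(sprintf("lesion of %.1f mL does not fit inside the cranial cavity",
                       les$volume_ml))
        w <- c(1.25, 0.8, 1.0)  # mild anisotropy: lesions elongated along y
        d2 <- ellipsoid_r2(dims, sp, seed_pt, 1 / sqrt(w))
        dall <- d2[allowed]
        thr <- sort(dall, partial = k)[k]
        sel <- allowed & d2 <= thr
        if (sum(sel) > k) {  # trim ties deterministically
          extra <- which(sel & d2 == thr)
          sel[extra[seq_len(sum(sel) - k)]] <- FALSE
        }
        lesions <- lesions | sel
        cls[sel] <- 5L
      }
    }

    hu <- c(-1000, spec$skull_hu, spec$wm_hu, spec$gm_hu, spec$csf_hu,
            spec$lesion_hu, 60)
    data <- array(hu[cls + 1L], dims)
    if (spec$noise_sigma > 0)
      data <- data + array(rnorm(length(data), 0, spec$noise_sigma), dims)

    structure(list(
      ct = ct_volume(data, sp),
      truth_brain = cavity,
      truth_gm = cls == 3L, truth_wm = cls == 2L, truth_csf = cls == 4L,
      truth_ventricles = vent & cls == 4L,
      truth_cisterns = cist & cls == 4L,
      truth_lesions = lesions,
      truth_mls = abs(s),
      spec = spec), class = "phantom_case")
  })
}

#' @export
print.phantom_case <- function(x, ...) {
  cat(sprintf("<phantom_case> %s voxels, true MLS %.2f mm, lesions %.2f mL, cisterns %.2f mL\n",
              paste(dim(x$ct$data), collapse = "x"), x$truth_mls,
              mask_volume_ml(x$truth_lesions, x$ct$spacing),
              mask_volume_ml(x$truth_cisterns, x$ct$spacing)))
  invisible(x)
}

#' Build a synthetic atlas bundle from unshifted phantoms
#'
#' Generates `n_subjects` lesion-free, unshifted phantoms with small random
#' anatomical variability, and aggregates them into an atlas: the template is
#' the voxelwise mean CT, the tissue priors are voxelwise class frequencies
#' (renormalized to sum to 1 inside the template brain), the ventricle and
#' cistern priors are majority votes, and the two axial landmark planes
#' (foramen-of-Monro level and roof of the lateral ventricles) are the
#' inferior and superior extent of the ventricle prior.
#'
#' @param spec a [phantom_spec()] giving grid, spacing and tissue contrast.
#' @param n_subjects number of cohort subjects (>= 1).
#' @param seed RNG seed for the cohort.
#' @return an object of class `atlas_bundle`.
#' @export
generate_atlas <- function(spec, n_subjects = 10, seed = 1L) {
  if (n_subjects < 1) stop("n_subjects must be >= 1")
  base <- spec
  base$induced_shift <- 0
  base$lesion_volumes <- list()
  base$decoy_falx <- FALSE
  dims <- base$grid_shape
  acc <- list(ct = array(0, dims), gm = array(0, dims), wm = array(0, dims),
              csf = array(0, dims), vent = array(0, dims), cist = array(0, dims),
              brain = array(0, dims))
  with_seed(seed, {
    for (i in seq_len(n_subjects)) {
      jit <- if (n_subjects > 1) runif(3, 0.97, 1.03) else c(1, 1, 1)
      sub <- base
      sub$seed <- sample.int(.Machine$integer.max, 1)
      case <- generate_phantom(sub, jitter = jit)
      acc$ct <- acc$ct + case$ct$data
      acc$gm <- acc$gm + case$truth_gm
      acc$wm <- acc$wm + case$truth_wm
      acc$csf <- acc$csf + case$truth_csf
      acc$vent <- acc$vent + case$truth_ventricles
      acc$cist <- acc$cist + case$truth_cisterns
      acc$brain <- acc$brain + case$truth_brain
    }
  })
  brain <- acc$brain / n_subjects >= 0.5
  pg <- acc$gm / n_subjects; pw <- acc$wm / n_subjects; pc <- acc$csf / n_subjects
  tot <- pg + pw + pc
  inside <- brain & tot > 0
  pg[inside] <- pg[inside] / tot[inside]
  pw[inside] <- pw[inside] / tot[inside]
  pc[inside] <- pc[inside] / tot[inside]
  deg <- brain & tot == 0
  pg[deg] <- pw[deg] <- pc[deg] <- 1 / 3
  pg[!brain] <- pw[!brain] <- pc[!brain] <- 0
  vent <- acc$vent / n_subjects >= 0.5
  cist <- acc$cist / n_subjects >= 0.5
  zs <- which(apply(vent, 3, any))
  if (!length(zs)) stop("atlas ventricle prior is empty")
  structure(list(
    template = ct_volume(acc$ct / n_subjects, base$spacing),
    prior_gm = pg, prior_wm = pw, prior_csf = pc,
    prior_ventricles = vent, prior_cisterns = cist,
    brain_mask = brain,
    landmark_z_monro = min(zs), landmark_z_roof = max(zs),
    n_subjects = n_subjects, seed = seed), class = "atlas_bundle")
}

#' @export
print.atlas_bundle <- function(x, ...) {
  cat(sprintf("<atlas_bundle> %s voxels, %d subject(s), landmark planes z=[%d, %d]\n",
              paste(dim(x$template$data), collapse = "x"), x$n_subjects,
              x$landmark_z_monro, x$landmark_z_roof))
  invisible(x)
}

#' Sample a reproducible cohort of phantoms
#'
#' Draws phantom specifications uniformly within the supplied ranges and
#' generates the cases.  Recognized range names: `induced_shift`,
#' `lesion_volume` (a single lesion, random side), `cistern_volume`,
#' `noise_sigma`; each is `c(lo, hi)` in the field's units.
#'
#' @param n cohort size (>= 1).
#' @param ranges named list of `c(lo, hi)` ranges.
#' @param seed RNG seed.
#' @param base_spec the [phantom_spec()] providing all non-sampled fields.
#' @param decoy_falx add the falx decoy to every case.
#' @return list of `phantom_case`.
#' @export
generate_cohort <- function(n, ranges, seed = 1L, base_spec = phantom_spec(),
                            decoy_falx = FALSE) {
  if (n < 1) stop("n must be >= 1")
  if (!length(ranges)) stop("ranges must not be empty")
  known <- c("induced_shift", "lesion_volume", "cistern_volume", "noise_sigma")
  if (!all(names(ranges) %in% known))
    stop("unknown range name(s): ", paste(setdiff(names(ranges), known), collapse = ", "))
  for (r in ranges) {
    if (length(r) != 2 || r[2] < r[1]) stop("each range must be c(lo, hi) with hi >= lo")
  }
  with_seed(seed, {
    lapply(seq_len(n), function(i) {
      sp <- base_spec
      if (!is.null(ranges$induced_shift))
        sp$induced_shift <- runif(1, ranges$induced_shift[1], ranges$induced_shift[2])
      if (!is.null(ranges$cistern_volume))
        sp$cistern_volume <- runif(1, ranges$cistern_volume[1], ranges$cistern_volume[2])
      if (!is.null(ranges$noise_sigma))
        sp$noise_sigma <- runif(1, ranges$noise_sigma[1], ranges$noise_sigma[2])
      if (!is.null(ranges$lesion_volume)) {
        side <- sample(c("left", "right"), 1)
        sp$lesion_volumes <- list(list(
          volume_ml = runif(1, ranges$lesion_volume[1], ranges$lesion_volume[2]),
          side = side))
      }
      sp$decoy_falx <- isTRUE(decoy_falx)
      sp$seed <- sample.int(.Machine$integer.max, 1)
      generate_phantom(sp)
    })
  })
}

#' Write a phantom case to disk
#'
#' The CT and each truth mask are written as NIfTI-1 volumes next to a JSON
#' sidecar holding the generating spec, seed and true midline shift.
#'
#' @param case a `phantom_case`.
#' @param dir output directory (created if needed).
#' @param stem file-name stem.
#' @return the directory, invisibly.
#' @export
write_phantom_case <- function(case, dir, stem = "case") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_ct_volume(case$ct, file.path(dir, paste0(stem, "_ct.nii.gz")))
  for (m in c("truth_brain", "truth_csf", "truth_ventricles", "truth_cisterns",
              "truth_lesions")) {
    write_mask_nifti(case[[m]], file.path(dir, paste0(stem, "_", m, ".nii.gz")),
                     case$ct$spacing)
  }
  sidecar <- list(spec = unclass(case$spec), truth_mls = case$truth_mls,
                  seed = case$spec$seed)
  jsonlite::write_json(sidecar, file.path(dir, paste0(stem, ".json")),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
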