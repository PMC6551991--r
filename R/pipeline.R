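#' Pipeline configuration
#'
#' Single configuration object for the end-to-end run: pre-processing
#' (brain-extraction method, isotropic target spacing), registration
#' settings, EM settings, cistern morphology parameters, the
#' lesion-probability threshold and the ventricle-prior relaxation used for
#' the midline-shift measurement.  Can be read from a YAML file with
#' [read_pipeline_config()].
#'
#' @param target_spacing isotropic working spacing in mm.
#' @param extract_method `"morphological"` or `"unet2d"`.
#' @param do_cisterns,do_lesions,do_mls stage toggles.
#' @param registration list of [register_affine()] arguments.
#' @param cistern list of [segment_cisterns()] parameters.
#' @param prior_relax list with `epsilon` and `sigma_mm` passed to
#'   [relax_priors()] before the EM stage.
#' @param mls_prior_dilation_mm dilation (mm) of the warped ventricle prior
#'   when building the ventricle mask for the MLS measurement; larger than
#'   the locate-stage default so that laterally displaced ventricles stay
#'   inside the candidate region.
#' @param lesion a [lesion_model_config()].
#' @param seed seed recorded in every output.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(target_spacing = 1, extract_method = "morphological",
                            do_cisterns = TRUE, do_lesions = FALSE, do_mls = TRUE,
                            registration = list(maxit = c(150L, 15L),
                                                polish_restarts = 1L),
                            cistern = list(p_csf = 0.5, k = 3L, sigma_mm = 1),
                            prior_relax = list(epsilon = 0.1, sigma_mm = 3),
                            mls_prior_dilation_mm = 15,
                            lesion = lesion_model_config(),
                            seed = 1L) {
  structure(list(target_spacing = target_spacing, extract_method = extract_method,
                 do_cisterns = do_cisterns, do_lesions = do_lesions,
                 do_mls = do_mls, registration = registration,
                 cistern = cistern, prior_relax = prior_relax,
                 mls_prior_dilation_mm = mls_prior_dilation_mm,
                 lesion = lesion, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param path YAML file with fields named as the [pipeline_config()]
#'   arguments.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$lesion)) y$lesion <- do.call(lesion_model_config, y$lesion)
  do.call(pipeline_config, y)
}

#' @noRd
stage_run <- function(stage, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("stage %s: %s", stage, conditionMessage(e)), call. = FALSE))
}

#' Run the quantification pipeline on one CT volume
#'
#' Executes pre-processing (brain extraction, resampling to isotropic
#' spacing, intensity normalization), affine atlas registration, EM tissue
#' segmentation with warped priors, structure localisation, and the enabled
#' quantification stages: cistern segmentation, lesion segmentation (when a
#' trained model is supplied) and midline-shift estimation.  Any stage
#' error aborts with a stage-tagged message.  The run is deterministic for
#' a fixed configuration and seed.
#'
#' @param ct input [ct_volume()] (HU), or a NIfTI file path.
#' @param atlas an `atlas_bundle`.
#' @param cfg a [pipeline_config()].
#' @param lesion_model optional trained `lesion_model`.
#' @param extractor optional trained `brain_extractor` (for
#'   `extract_method = "unet2d"`).
#' @param out_dir optional output directory for masks and the JSON report.
#' @return object of class `case_report` with the headline quantities
#'   (`lesion_volume_ml`, `cistern_volume_ml`, `mls_mm`), per-slice MLS
#'   detail, intermediate masks, and provenance (config hash, seed,
#'   package version).
#' @export
run_pipeline <- function(ct, atlas, cfg = pipeline_config(),
                         lesion_model = NULL, extractor = NULL,
                         out_dir = NULL) {
  if (is.character(ct)) ct <- read_ct_volume(ct)
  stopifnot(inherits(ct, "ct_volume"), inherits(atlas, "atlas_bundle"))
  if (cfg$do_lesions && is.null(lesion_model))
    stop("stage lesions: enabled but no trained lesion model supplied")

  res <- list()
  stage_run("preprocess", {
    brain0 <- extract_brain(ct, cfg$extract_method, model = extractor)
    ctr <- resample_to_isotropic(ct, cfg$target_spacing)
    brain <- resample_mask(brain0, cfg$target_spacing)
    res$ct <- ctr
    res$brain <- brain
    res$norm <- normalize_intensities(ctr, brain)
  })
  stage_run("register", {
    res$transform <- do.call(register_affine,
                              c(list(res$ct, atlas), cfg$registration))
  })
  stage_run("tissues", {
    priors <- list(
      gm = warp_to_subject(atlas$prior_gm, res$transform, res$ct,
                           atlas$template$spacing),
      wm = warp_to_subject(atlas$prior_wm, res$transform, res$ct,
                           atlas$template$spacing),
      csf = warp_to_subject(atlas$prior_csf, res$transform, res$ct,
                            atlas$template$spacing))
    priors <- relax_priors(priors, res$brain,
                           epsilon = cfg$prior_relax$epsilon,
                           sigma_mm = cfg$prior_relax$sigma_mm,
                           spacing = res$ct$spacing)
    res$tissues <- segment_tissues_em(res$norm, res$brain, priors)
  })
  stage_run("locate", {
    res$located <- locate_structures(res$tissues, atlas, res$transform, res$ct)
  })
  if (cfg$do_cisterns) stage_run("cisterns", {
    cm <- segment_cisterns(res$located$cisterns, res$tissues$post_csf,
                           res$brain, res$located$ventricles,
                           p_csf = cfg$cistern$p_csf, k = cfg$cistern$k,
                           sigma_mm = cfg$cistern$sigma_mm,
                           spacing = res$ct$spacing)
    res$cisterns <- cm
  })
  if (cfg$do_lesions) stage_run("lesions", {
    res$lesions <- predict_lesions(lesion_model, res$norm, res$brain,
                                    cfg$lesion)
  })
  if (cfg$do_mls) stage_run("mls", {
    dil <- max(1L, as.integer(round(cfg$mls_prior_dilation_mm /
                                      res$ct$spacing[1])))
    loc <- suppressWarnings(
      locate_structures(res$tissues, atlas, res$transform, res$ct,
                        dilate_ventricles = dil))
    res$mls <- estimate_mls(loc$ventricles, res$brain, NULL, res$transform,
                             atlas, res$ct$spacing)
  })

  report <- structure(list(
    lesion_volume_ml = if (cfg$do_lesions)
      mask_volume_ml(res$lesions$mask, res$ct$spacing) else NULL,
    cistern_volume_ml = if (cfg$do_cisterns) res$cisterns$volume_ml else NULL,
    mls_mm = if (cfg$do_mls) res$mls$mls else NULL,
    mls_per_slice = if (cfg$do_mls) res$mls$per_slice else NULL,
    intermediates = res,
    provenance = list(config_hash = config_hash(cfg), seed = cfg$seed,
                      version = as.character(utils::packageVersion("tbiq")))),
    class = "case_report")

  if (!is.null(out_dir)) write_case_report(report, out_dir)
  report
}

#' @export
print.case_report <- function(x, ...) {
  cat("<case_report>\n")
  if (!is.null(x$lesion_volume_ml))
    cat(sprintf("  acute lesion volume: %.2f mL\n", x$lesion_volume_ml))
  if (!is.null(x$cistern_volume_ml))
    cat(sprintf("  cistern volume:      %.2f mL\n", x$cistern_volume_ml))
  if (!is.null(x$mls_mm))
    cat(sprintf("  midline shift:       %.2f mm\n", x$mls_mm))
  invisible(x)
}

#' @noRd
write_case_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  res <- report$intermediates
  sp <- res$ct$spacing
  write_mask_nifti(res$brain, file.path(dir, "brain_mask.nii.gz"), sp)
  if (!is.null(res$cisterns))
    write_mask_nifti(res$cisterns$mask, file.path(dir, "cisterns.nii.gz"), sp)
  if (!is.null(res$lesions))
    write_mask_nifti(res$lesions$mask, file.path(dir, "lesions.nii.gz"), sp)
  write_affine_matrix(res$transform, file.path(dir, "transform.txt"))
  js <- report[c("lesion_volume_ml", "cistern_volume_ml", "mls_mm")]
  js$per_slice <- report$mls_per_slice
  js$provenance <- report$provenance
  jsonlite::write_json(js, file.path(dir, "report.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, dataframe = "rows")
  invisible(dir)
}

#' Serialize / load an affine transform as a 4x4 text matrix
#'
#' @param t an `affine_transform`.
#' @param path text file path.
#' @return `read_affine_matrix` returns an `affine_transform` (parameters
#'   are not recovered from the matrix).
#' @export
write_affine_matrix <- function(t, path) {
  write(t(t$matrix), path, ncolumns = 4)
  invisible(path)
}

#' @rdname write_affine_matrix
#' @export
read_affine_matrix <- function(path) {
  M <- matrix(scan(path, quiet = TRUE), 4, 4, byrow = TRUE)
  structure(list(matrix = M, inverse = solve(M), params = NULL),
            class = "affine_transform")
}

#' Serialize / load an atlas bundle
#'
#' The template and probability priors are written as NIfTI volumes, the
#' binary priors as uint8 NIfTI, and the landmarks plus metadata as a JSON
#' manifest.
#'
#' @param atlas an `atlas_bundle`.
#' @param dir directory.
#' @return `read_atlas` returns an `atlas_bundle`.
#' @export
write_atlas <- function(atlas, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sp <- atlas$template$spacing
  write_ct_volume(atlas$template, file.path(dir, "template.nii.gz"))
  for (nm in c("prior_gm", "prior_wm", "prior_csf")) {
    img <- RNifti::asNifti(atlas[[nm]])
    RNifti::pixdim(img) <- sp
    RNifti::writeNifti(img, file.path(dir, paste0(nm, ".nii.gz")))
  }
  for (nm in c("prior_ventricles", "prior_cisterns"))
    write_mask_nifti(atlas[[nm]], file.path(dir, paste0(nm, ".nii.gz")), sp)
  write_mask_nifti(atlas$brain_mask, file.path(dir, "brain_mask.nii.gz"), sp)
  manifest <- list(landmark_z_monro = atlas$landmark_z_monro,
                   landmark_z_roof = atlas$landmark_z_roof,
                   n_subjects = atlas$n_subjects, seed = atlas$seed,
                   spacing = sp)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' @rdname write_atlas
#' @export
read_atlas <- function(dir) {
  man <- jsonlite::read_json(file.path(dir, "manifest.json"),
                             simplifyVector = TRUE)
  tpl <- read_ct_volume(file.path(dir, "template.nii.gz"))
  rd <- function(nm) {
    img <- RNifti::readNifti(file.path(dir, paste0(nm, ".nii.gz")))
    arr <- as.array(img)
    attributes(arr) <- list(dim = dim(img)[1:3])
    arr
  }
  rb <- function(nm) {
    a <- rd(nm) > 0.5
    a
  }
  structure(list(template = tpl,
                 prior_gm = rd("prior_gm"), prior_wm = rd("prior_wm"),
                 prior_csf = rd("prior_csf"),
                 prior_ventricles = rb("prior_ventricles"),
                 prior_cisterns = rb("prior_cisterns"),
                 brain_mask = rb("brain_mask"),
                 landmark_z_monro = man$landmark_z_monro,
                 landmark_z_roof = man$landmark_z_roof,
                 n_subjects = man$n_subjects, seed = man$seed),
            class = "atlas_bundle")
}

#' Cohort-level agreement evaluation
#'
#' Computes the full agreement suite between paired predicted and reference
#' cases: per-case volume differences, Dice/precision/sensitivity, and
#' cohort summaries (median and 25th-75th percentiles, absolute-agreement
#' ICC of the volume and shift series, classification accuracy at the 25 mL
#' largest-lesion and 5 mm shift cutoffs).  Cistern overlap statistics are
#' additionally summarized over the stratum of reference cistern volume
#' above `cistern_stratum_ml`.
#'
#' @param pred list of per-case predictions: each a list with any of
#'   `lesion_mask`, `cistern_mask`, `mls`.
#' @param truth paired list with `lesion_mask`, `cistern_mask`, `mls`.
#' @param spacing voxel spacing (mm) shared by the masks.
#' @param lesion_cutoff_ml,mls_cutoff_mm classification cutoffs.
#' @param cistern_stratum_ml reporting stratum for cistern overlap.
#' @return object of class `cohort_report`: `per_case` data frame and
#'   `summary` list.
#' @export
evaluate_cohort <- function(pred, truth, spacing,
                            lesion_cutoff_ml = 25, mls_cutoff_mm = 5,
                            cistern_stratum_ml = 5) {
  if (!length(pred)) stop("empty cohort")
  if (length(pred) != length(truth)) stop("pred and truth cohorts are unpaired")
  n <- length(pred)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    p <- pred[[i]]; tr <- truth[[i]]
    row <- list(case = i)
    for (what in c("lesion", "cistern")) {
      pm <- p[[paste0(what, "_mask")]]
      tm <- tr[[paste0(what, "_mask")]]
      if (inherits(pm, "cistern_mask")) pm <- pm$mask
      if (!is.null(pm) && !is.null(tm)) {
        ov <- overlap_metrics(tm, pm)
        va <- volume_agreement(tm, pm, spacing)
        row[[paste0(what, "_ref_ml")]] <- mask_volume_ml(tm, spacing)
        row[[paste0(what, "_pred_ml")]] <- mask_volume_ml(pm, spacing)
        row[[paste0(what, "_volume_diff_ml")]] <- va$volume_diff_ml
        row[[paste0(what, "_abs_volume_diff_ml")]] <- va$abs_volume_diff_ml
        row[[paste0(what, "_dice")]] <- ov$dice
        row[[paste0(what, "_precision")]] <- ov$precision
        row[[paste0(what, "_sensitivity")]] <- ov$sensitivity
      }
    }
    if (!is.null(p$mls) && !is.null(tr$mls)) {
      sa <- shift_agreement(tr$mls, p$mls)
      row$mls_ref_mm <- tr$mls
      row$mls_pred_mm <- p$mls
      row$mls_diff_mm <- sa$difference_in_shift_mm
      row$mls_abs_diff_mm <- sa$abs_difference_in_shift_mm
    }
    rows[[i]] <- as.data.frame(row)
  }
  per_case <- do.call(rbind, rows)

  summ <- list()
  add_block <- function(prefix, label) {
    if (!paste0(prefix, "_ref_ml") %in% names(per_case)) return()
    blk <- list(
      volume_difference_ml = median_iqr(per_case[[paste0(prefix, "_volume_diff_ml")]]),
      absolute_volume_difference_ml = median_iqr(per_case[[paste0(prefix, "_abs_volume_diff_ml")]]),
      dice = median_iqr(per_case[[paste0(prefix, "_dice")]]),
      precision = median_iqr(per_case[[paste0(prefix, "_precision")]]),
      sensitivity = median_iqr(per_case[[paste0(prefix, "_sensitivity")]]))
    if (n >= 3)
      blk$icc <- tryCatch(
        icc_absolute(per_case[[paste0(prefix, "_ref_ml")]],
                     per_case[[paste0(prefix, "_pred_ml")]]),
        error = function(e) NA_real_)
    summ[[label]] <<- blk
  }
  add_block("lesion", "acute_intracranial_lesions")
  add_block("cistern", "cisterns")
  if ("lesion_ref_ml" %in% names(per_case)) {
    ca <- classification_accuracy(per_case$lesion_ref_ml, per_case$lesion_pred_ml,
                                  lesion_cutoff_ml)
    summ$acute_intracranial_lesions$classification_accuracy <- ca$accuracy
    summ$acute_intracranial_lesions$kappa <- ca$kappa
  }
  if ("cistern_ref_ml" %in% names(per_case)) {
    st <- per_case$cistern_ref_ml > cistern_stratum_ml
    if (any(st)) {
      summ$cisterns$stratum_over_cutoff <- list(
        n = sum(st),
        dice = median_iqr(per_case$cistern_dice[st]),
        precision = median_iqr(per_case$cistern_precision[st]),
        sensitivity = median_iqr(per_case$cistern_sensitivity[st]))
    }
  }
  if ("mls_ref_mm" %in% names(per_case)) {
    blk <- list(
      difference_in_shift_mm = median_iqr(per_case$mls_diff_mm),
      absolute_difference_in_shift_mm = median_iqr(per_case$mls_abs_diff_mm))
    if (n >= 3)
      blk$icc <- tryCatch(icc_absolute(per_case$mls_ref_mm, per_case$mls_pred_mm),
                          error = function(e) NA_real_)
    ca <- classification_accuracy(per_case$mls_ref_mm, per_case$mls_pred_mm,
                                  mls_cutoff_mm)
    blk$classification_accuracy <- ca$accuracy
    blk$kappa <- ca$kappa
    summ$midline_shift <- blk
  }
  structure(list(per_case = per_case, summary = summ), class = "cohort_report")
}

#' @export
print.cohort_report <- function(x, ...) {
  cat(sprintf("<cohort_report> %d case(s); blocks: %s\n", nrow(x$per_case),
              paste(names(x$summary), collapse = ", ")))
  invisible(x)
}

#' Write a cohort report as CSV + JSON
#'
#' @param report a `cohort_report`.
#' @param dir output directory.
#' @return the directory, invisibly.
#' @export
write_cohort_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write.csv(report$per_case, file.path(dir, "per_case.csv"), row.names = FALSE)
  jsonlite::write_json(report$summary, file.path(dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
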