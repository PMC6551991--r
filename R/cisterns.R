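#' Basal cistern segmentation by constrained morphology
#'
#' Refines the located cistern candidates in three steps: (1) constrained
#' dilation — `k` iterations of 1-voxel dilation accepted only where the CSF
#' posterior is at least `p_csf`; (2) smoothing — a morphological closing
#' followed by Gaussian smoothing of the binary indicator at `sigma` voxels
#' and re-thresholding at 0.5; (3) nonoverlap — voxels claimed by the
#' ventricle mask are removed from the cistern border.  Empty candidates
#' yield an empty mask (volume 0) without error.
#'
#' @param candidates logical cistern candidate mask (see
#'   [locate_structures()]).
#' @param csf_posterior numeric CSF posterior probability array.
#' @param brain logical brain mask.
#' @param ventricles logical ventricle mask enforced as non-overlapping
#'   (may be `NULL`).
#' @param p_csf CSF-posterior acceptance threshold for dilation.
#' @param k constrained-dilation iterations.
#' @param sigma_mm Gaussian smoothing width in mm.
#' @param spacing voxel spacing in mm.
#' @return object of class `cistern_mask` with fields `mask` and
#'   `volume_ml`.
#' @export
segment_cisterns <- function(candidates, csf_posterior, brain,
                             ventricles = NULL, p_csf = 0.5, k = 3L,
                             sigma_mm = 1, spacing = c(1, 1, 1)) {
  check_same_dim(candidates, brain)
  check_same_dim(candidates, csf_posterior)
  dims <- dim(candidates)
  if (!any(candidates)) {
    empty <- array(FALSE, dims)
    return(structure(list(mask = empty, volume_ml = 0), class = "cistern_mask"))
  }
  m <- candidates & brain
  accept <- csf_posterior >= p_csf & brain
  for (i in seq_len(k)) {
    m <- cpp_dilate(m, 1L) & accept | m
    dim(m) <- dims
  }
  # closing, then smooth the indicator and re-threshold
  m <- cpp_erode(cpp_dilate(m, 1L), 1L)
  g <- cpp_gauss3d(array(as.numeric(m), dims), sigma_mm / spacing)
  m <- g >= 0.5
  dim(m) <- dims
  m <- m & brain
  if (!is.null(ventricles)) m <- m & !ventricles
  dim(m) <- dims
  structure(list(mask = m, volume_ml = mask_volume_ml(m, spacing)),
            class = "cistern_mask")
}

#' @export
print.cistern_mask <- function(x, ...) {
  cat(sprintf("<cistern_mask> %.2f mL (%d voxels)\n", x$volume_ml, sum(x$mask)))
  invisible(x)
}

#' Cistern volume in mL
#'
#' Voxel count times voxel volume, reported in millilitres.
#'
#' @param mask a `cistern_mask` or logical array.
#' @param spacing voxel spacing in mm (taken from the object if absent).
#' @return volume in mL.
#' @export
cistern_volume <- function(mask, spacing = NULL) {
  if (inherits(mask, "cistern_mask")) {
    if (is.null(spacing)) return(mask$volume_ml)
    mask <- mask$mask
  }
  if (is.null(spacing)) stop("spacing required for a plain mask")
  mask_volume_ml(mask, spacing)
}
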