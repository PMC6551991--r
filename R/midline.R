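#' Axial slice range for midline-shift measurement
#'
#' Maps the two atlas landmark planes (foramen-of-Monro level and roof of
#' the lateral ventricles) through the inverse of the subject-to-atlas
#' transform to subject axial indices, defining the slice range over which
#' the shift is measured.
#'
#' @param t subject-to-atlas `affine_transform`.
#' @param atlas an `atlas_bundle` with landmark plane indices.
#' @param grid subject grid (a [ct_volume()] or list with `dims`,
#'   `spacing`).
#' @return inclusive 1-based `c(z_lo, z_hi)` subject slice range.
#' @export
slice_range <- function(t, atlas, grid) {
  dims <- if (inherits(grid, "ct_volume")) dim(grid$data) else grid$dims
  sp <- if (inherits(grid, "ct_volume")) grid$spacing else grid$spacing
  asp <- atlas$template$spacing
  adim <- dim(atlas$template$data)
  map_z <- function(zidx) {
    wa <- c((adim[1:2] - 1) / 2 * asp[1:2], (zidx - 1) * asp[3], 1)
    ws <- (t$inverse %*% wa)[1:3]
    ws[3] / sp[3] + 1
  }
  z1 <- map_z(atlas$landmark_z_monro)
  z2 <- map_z(atlas$landmark_z_roof)
  if (z2 <= z1) stop("landmark plane order violated after mapping to subject space")
  lo <- max(1L, as.integer(ceiling(z1 - 1e-6)))
  hi <- min(dims[3], as.integer(floor(z2 + 1e-6)))
  if (hi < lo) stop("slice range collapses to fewer than one slice")
  c(lo, hi)
}

#' Midline shift on one axial slice
#'
#' Implements the geometric rule: B is the maximal left-right inner-skull
#' width on the slice and C the distance from the inner table to the middle
#' of the frontal part of the ventricles, measured along the same left-right
#' line (B and C share their starting x-coordinate, taken on the side
#' opposite the shift); the shift is |B/2 - C|.  The "middle of the frontal
#' part" is the midpoint of the centroids of the left and right
#' anterior-third ventricle components (the centroid of the anterior third
#' of a single merged component).
#'
#' @param skull_inner logical inner-skull (cranial cavity) slice, x by y.
#' @param ventricles logical ventricle slice on the same grid.
#' @param z slice index (recorded in the result).
#' @param spacing in-plane voxel spacing `c(sx, sy)` in mm.
#' @return a list: `measurable`, `z`, `B_bar`, `C_bar`, `shift` (mm) and
#'   `start_x`; non-measurable slices (no ventricle voxels) return
#'   `measurable = FALSE`.
#' @export
measure_slice_shift <- function(skull_inner, ventricles, z = NA_integer_,
                                spacing = c(1, 1)) {
  if (!any(skull_inner)) stop("empty inner-skull slice")
  not_measurable <- list(measurable = FALSE, z = z, B_bar = NA_real_,
                         C_bar = NA_real_, shift = NA_real_, start_x = NA_real_)
  if (!any(ventricles)) return(not_measurable)
  vi <- which(ventricles, arr.ind = TRUE)
  yr <- range(vi[, 2])
  front <- vi[vi[, 2] <= yr[1] + (yr[2] - yr[1]) / 3, , drop = FALSE]
  if (!nrow(front)) return(not_measurable)
  sub <- array(FALSE, c(dim(ventricles), 1L))
  sub[cbind(front, 1L)] <- TRUE
  lab <- cpp_label6(sub)
  sizes <- tabulate(lab)
  if (length(sizes) >= 2) {
    top2 <- order(sizes, decreasing = TRUE)[1:2]
    cents <- vapply(top2, function(l) {
      idx <- which(lab == l, arr.ind = TRUE)
      c(mean(idx[, 1]), mean(idx[, 2]))
    }, numeric(2))
    mid <- rowMeans(cents)
  } else {
    idx <- which(lab == 1, arr.ind = TRUE)
    mid <- c(mean(idx[, 1]), mean(idx[, 2]))
  }
  y0 <- as.integer(round(mid[2]))
  xs <- integer(0)
  for (dy in c(0, -1, 1, -2, 2)) {
    yy <- y0 + dy
    if (yy < 1 || yy > dim(skull_inner)[2]) next
    xs <- which(skull_inner[, yy])
    if (length(xs)) { y0 <- yy; break }
  }
  if (!length(xs)) return(not_measurable)
  x_lo <- min(xs); x_hi <- max(xs)
  B <- (x_hi - x_lo) * spacing[1]
  centre_x <- (x_lo + x_hi) / 2
  if (mid[1] >= centre_x) {  # shift towards +x: start from the -x inner table
    start_x <- x_lo
    C <- (mid[1] - x_lo) * spacing[1]
  } else {
    start_x <- x_hi
    C <- (x_hi - mid[1]) * spacing[1]
  }
  C <- min(max(C, 0), B)
  list(measurable = TRUE, z = z, B_bar = B, C_bar = C,
       shift = abs(B / 2 - C), start_x = start_x)
}

#' Midline-shift estimate for a volume
#'
#' Measures the shift on every measurable axial slice in the
#' landmark-bounded range and reports the maximum as the patient-level MLS
#' (ties broken towards the most inferior slice).
#'
#' @param ventricle_mask logical ventricle mask on the subject grid.
#' @param brain logical brain mask.
#' @param skull_inner logical inner-skull (cavity) mask; defaults to the
#'   hole-filled brain mask.
#' @param t subject-to-atlas `affine_transform`.
#' @param atlas an `atlas_bundle`.
#' @param spacing voxel spacing in mm.
#' @return object of class `mls_result`: `mls` (mm), `argmax_z` and the
#'   `per_slice` data frame.
#' @export
estimate_mls <- function(ventricle_mask, brain, skull_inner = NULL, t, atlas,
                         spacing = c(1, 1, 1)) {
  check_same_dim(ventricle_mask, brain)
  if (is.null(skull_inner)) skull_inner <- fill_holes(brain)
  zr <- slice_range(t, atlas, list(dims = dim(brain), spacing = spacing))
  rows <- list()
  for (z in zr[1]:zr[2]) {
    m <- measure_slice_shift(skull_inner[, , z], ventricle_mask[, , z], z,
                             spacing[1:2])
    if (m$measurable) rows[[length(rows) + 1L]] <- m
  }
  if (!length(rows)) stop("no measurable slice in the landmark range")
  per_slice <- do.call(rbind, lapply(rows, function(m)
    data.frame(z = m$z, B_bar = m$B_bar, C_bar = m$C_bar, shift = m$shift,
               start_x = m$start_x)))
  best <- which.max(per_slice$shift)  # first maximum = most inferior slice
  structure(list(mls = per_slice$shift[best], argmax_z = per_slice$z[best],
                 per_slice = per_slice, slice_range = zr),
            class = "mls_result")
}

#' @export
print.mls_result <- function(x, ...) {
  cat(sprintf("<mls_result> MLS %.2f mm at slice z=%d (%d measurable slice(s), range %d-%d)\n",
              x$mls, x$argmax_z, nrow(x$per_slice), x$slice_range[1],
              x$slice_range[2]))
  invisible(x)
}
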