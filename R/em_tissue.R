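#' EM tissue segmentation with atlas priors
#'
#' Classifies in-mask voxels of the normalized, skull-stripped CT into grey
#' matter, white matter and CSF by a Gaussian-mixture model with spatially
#' varying atlas priors, fitted by expectation-maximization.  The E-step
#' posterior is proportional to prior x Gaussian likelihood (computed in the
#' log domain); the M-step re-estimates class means and variances from the
#' posteriors.  Class means/variances are initialized from prior-weighted
#' statistics.  Iterations stop when the relative log-likelihood change
#' falls below `tol` or after `max_iter` iterations; the log-likelihood is
#' non-decreasing across iterations.  Variances below `var_floor` are
#' floored and flagged.
#'
#' @param ct normalized brain [ct_volume()] (see [normalize_intensities()]).
#' @param mask logical brain mask.
#' @param priors list with numeric arrays `gm`, `wm`, `csf` on the subject
#'   grid (warped atlas priors) summing to 1 inside the mask.
#' @param tol relative log-likelihood tolerance.
#' @param max_iter maximum EM iterations.
#' @param var_floor variance floor (normalized-intensity units squared).
#' @return object of class `tissue_seg`: posterior arrays `post_gm`,
#'   `post_wm`, `post_csf`, integer `hard_labels` (0 outside mask, 1 = GM,
#'   2 = WM, 3 = CSF; argmax ties go to the lowest class index), the fitted
#'   `means`/`variances`, `loglik_history` and `variance_floored`.
#' @export
segment_tissues_em <- function(ct, mask, priors, tol = 1e-5, max_iter = 50L,
                               var_floor = 1e-8) {
  stopifnot(inherits(ct, "ct_volume"))
  check_same_dim(ct$data, mask)
  classes <- c("gm", "wm", "csf")
  P <- vapply(classes, function(k) {
    check_same_dim(priors[[k]], mask, "priors")
    priors[[k]][mask]
  }, numeric(sum(mask)))
  if (sum(colSums(P) > 0) < 2) stop("need >= 2 classes with nonzero prior mass")
  rs <- rowSums(P)
  zero <- rs <= 0
  P[zero, ] <- 1 / 3
  P[!zero, ] <- P[!zero, , drop = FALSE] / rs[!zero]
  y <- ct$data[mask]

  wsum <- colSums(P)
  mu <- colSums(P * y) / wsum
  v <- colSums(P * (y - rep(mu, each = length(y)))^2) / wsum
  floored <- any(v < var_floor)
  v <- pmax(v, var_floor)

  logP <- log(P)  # -Inf where the prior is exactly 0 (prior dominance)
  ll_hist <- numeric(0)
  post <- NULL
  for (it in seq_len(max_iter)) {
    lphi <- sapply(seq_along(classes), function(k)
      logP[, k] + dnorm(y, mu[k], sqrt(v[k]), log = TRUE))
    m <- pmax(lphi[, 1], lphi[, 2], lphi[, 3])
    lse <- m + log(rowSums(exp(lphi - m)))
    ll <- sum(lse)
    ll_hist <- c(ll_hist, ll)
    post <- exp(lphi - lse)
    wsum <- colSums(post)
    mu_new <- colSums(post * y) / wsum
    v_new <- colSums(post * (y - rep(mu_new, each = length(y)))^2) / wsum
    if (any(v_new < var_floor)) floored <- TRUE
    v_new <- pmax(v_new, var_floor)
    mu_new[wsum == 0] <- mu[wsum == 0]
    v_new[wsum == 0] <- v[wsum == 0]
    mu <- mu_new; v <- v_new
    if (it > 1) {
      rel <- (ll - ll_hist[it - 1]) / abs(ll_hist[it - 1])
      if (is.finite(rel) && rel < tol) break
    }
  }

  dims <- dim(ct$data)
  out <- list()
  for (k in seq_along(classes)) {
    arr <- array(0, dims)
    arr[mask] <- post[, k]
    out[[paste0("post_", classes[k])]] <- arr
  }
  hard <- array(0L, dims)
  hard[mask] <- max.col(post, ties.method = "first")
  structure(c(out, list(hard_labels = hard, means = mu, variances = v,
                        loglik_history = ll_hist,
                        variance_floored = floored, mask = mask)),
            class = "tissue_seg")
}

#' @export
print.tissue_seg <- function(x, ...) {
  cat(sprintf("<tissue_seg> %d EM iteration(s), means (GM, WM, CSF) = (%.3f, %.3f, %.3f)%s\n",
              length(x$loglik_history), x$means[1], x$means[2], x$means[3],
              if (x$variance_floored) " [variance floored]" else ""))
  invisible(x)
}

#' Relax warped tissue priors
#'
#' Smooths each warped prior with a Gaussian kernel and mixes in a uniform
#' floor, then renormalizes the three classes inside the mask:
#' `P' = (1 - epsilon) * smooth(P) + epsilon / 3`.  A strictly zero atlas
#' prior is an absolute veto in the EM posterior; after pathology
#' (mass effect, midline shift) tissue can sit outside its atlas support,
#' so the pipeline relaxes the priors before the EM stage to let intensity
#' evidence override the atlas there.
#'
#' @param priors list of numeric arrays `gm`, `wm`, `csf`.
#' @param mask logical brain mask.
#' @param epsilon uniform mixing weight in [0, 1).
#' @param sigma_mm Gaussian smoothing width in mm.
#' @param spacing voxel spacing in mm.
#' @return list of relaxed priors summing to 1 inside the mask.
#' @export
relax_priors <- function(priors, mask, epsilon = 0.1, sigma_mm = 3,
                         spacing = c(1, 1, 1)) {
  out <- lapply(priors[c("gm", "wm", "csf")], function(p) {
    if (sigma_mm > 0) p <- cpp_gauss3d(p, sigma_mm / spacing)
    (1 - epsilon) * p + epsilon / 3
  })
  tot <- out$gm + out$wm + out$csf
  for (nm in names(out)) {
    out[[nm]] <- out[[nm]] / tot
    out[[nm]][!mask] <- 0
    dim(out[[nm]]) <- dim(mask)
  }
  out
}

#' Locate ventricles and cisterns from binary atlas priors
#'
#' Intersects the CSF hard labels with the warped binary structure priors.
#' The warped priors are dilated (default 2 voxels) before intersection to
#' tolerate residual registration error.  An empty intersection returns an
#' empty mask with a warning (clinically: an obliterated cistern).
#'
#' @param seg a `tissue_seg` from [segment_tissues_em()].
#' @param atlas an `atlas_bundle`.
#' @param t the subject-to-atlas `affine_transform`.
#' @param grid subject grid (a [ct_volume()]).
#' @param dilate_ventricles,dilate_cisterns prior dilation in voxels.
#' @return list with logical masks `ventricles` and `cisterns`.
#' @export
locate_structures <- function(seg, atlas, t, grid, dilate_ventricles = 2L,
                              dilate_cisterns = 2L) {
  csf <- seg$hard_labels == 3L
  dims <- dim(csf)
  out <- list()
  for (nm in c("ventricles", "cisterns")) {
    prior <- warp_to_subject(atlas[[paste0("prior_", nm)]], t, grid,
                             atlas$template$spacing)
    dl <- if (nm == "ventricles") dilate_ventricles else dilate_cisterns
    if (dl > 0) prior <- cpp_dilate(prior, as.integer(dl))
    cand <- csf & prior & seg$mask
    dim(cand) <- dims
    if (!any(cand))
      warning(sprintf("empty %s candidates (structure may be obliterated)", nm))
    out[[nm]] <- cand
  }
  out
}
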