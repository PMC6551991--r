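#' Affine transform between subject and atlas space
#'
#' A 12-parameter affine (translation mm, rotation deg, per-axis scale,
#' shears) acting in world coordinates, centred on the atlas grid centre:
#' `T = Tr(centre + t) R(z)R(y)R(x) Shear Scale Tr(-centre)`, mapping
#' subject world coordinates to atlas world coordinates.
#'
#' @param translation,rotation,scale,shear parameter vectors (3 each).
#' @param centre rotation centre in world mm.
#' @return object of class `affine_transform` with fields `matrix`,
#'   `inverse` and `params`.
#' @export
affine_transform <- function(translation = c(0, 0, 0), rotation = c(0, 0, 0),
                             scale = c(1, 1, 1), shear = c(0, 0, 0),
                             centre = c(0, 0, 0)) {
  M <- compose_affine(translation, rotation, scale, shear, centre)
  structure(list(matrix = M, inverse = solve(M),
                 params = list(translation = translation, rotation = rotation,
                               scale = scale, shear = shear, centre = centre)),
            class = "affine_transform")
}

#' @noRd
compose_affine <- function(t, r, s, sh, centre) {
  rad <- r * pi / 180
  cx <- cos(rad[1]); sx <- sin(rad[1])
  cy <- cos(rad[2]); sy <- sin(rad[2])
  cz <- cos(rad[3]); sz <- sin(rad[3])
  Rx <- rbind(c(1, 0, 0), c(0, cx, -sx), c(0, sx, cx))
  Ry <- rbind(c(cy, 0, sy), c(0, 1, 0), c(-sy, 0, cy))
  Rz <- rbind(c(cz, -sz, 0), c(sz, cz, 0), c(0, 0, 1))
  Sh <- rbind(c(1, sh[1], sh[2]), c(0, 1, sh[3]), c(0, 0, 1))
  A <- Rz %*% Ry %*% Rx %*% Sh %*% diag(s)
  M <- diag(4)
  M[1:3, 1:3] <- A
  M[1:3, 4] <- centre + t - A %*% centre
  M
}

#' @export
print.affine_transform <- function(x, ...) {
  p <- x$params
  cat(sprintf("<affine_transform> t=(%.2f, %.2f, %.2f) mm, r=(%.2f, %.2f, %.2f) deg, s=(%.3f, %.3f, %.3f)\n",
              p$translation[1], p$translation[2], p$translation[3],
              p$rotation[1], p$rotation[2], p$rotation[3],
              p$scale[1], p$scale[2], p$scale[3]))
  invisible(x)
}

# Normalized mutual information (H(A)+H(B))/H(A,B) from a joint histogram.
#' @noRd
nmi_score <- function(a, b, nbins = 32L, range_a, range_b) {
  ok <- is.finite(a) & is.finite(b)
  a <- a[ok]; b <- b[ok]
  if (!length(a)) return(0)
  ia <- pmin(pmax(floor((a - range_a[1]) / diff(range_a) * nbins), 0), nbins - 1)
  ib <- pmin(pmax(floor((b - range_b[1]) / diff(range_b) * nbins), 0), nbins - 1)
  joint <- tabulate(ia + nbins * ib + 1, nbins * nbins)
  p <- joint / sum(joint)
  pa <- rowSums(matrix(p, nbins)); pb <- colSums(matrix(p, nbins))
  ent <- function(q) { q <- q[q > 0]; -sum(q * log(q)) }
  hj <- ent(p)
  if (hj <= 0) return(2)
  (ent(pa) + ent(pb)) / hj
}

#' @noRd
downsample_grid <- function(data, spacing, factor) {
  if (factor == 1L) return(list(data = data, spacing = spacing))
  dims <- dim(data)
  newdims <- pmax(1L, as.integer(floor(dims / factor)))
  M <- cbind(diag(factor, 3), (factor - 1) / 2 * c(1, 1, 1))
  list(data = cpp_resample_affine(data, M, newdims, 0L, NA_real_),
       spacing = spacing * factor)
}

# First and second moments (centre of mass, per-axis spread) of the
# above-threshold intensity distribution, in world mm.  The spread ratio
# between template and subject initializes the per-axis scale.
#' @noRd
moments_world <- function(data, spacing, thresh = -200) {
  w <- pmax(data - thresh, 0)
  tot <- sum(w)
  dims <- dim(data)
  xs <- (seq_len(dims[1]) - 1) * spacing[1]
  ys <- (seq_len(dims[2]) - 1) * spacing[2]
  zs <- (seq_len(dims[3]) - 1) * spacing[3]
  wx <- rowSums(w, dims = 1)
  wy <- rowSums(colSums(w, dims = 1))
  wz <- colSums(w, dims = 2)
  com <- c(sum(wx * xs), sum(wy * ys), sum(wz * zs)) / tot
  spread <- sqrt(c(sum(wx * (xs - com[1])^2), sum(wy * (ys - com[2])^2),
                   sum(wz * (zs - com[3])^2)) / tot)
  list(com = com, spread = spread)
}

#' Affine registration of a subject CT to the atlas template
#'
#' Estimates the 12-dof affine (subject world to atlas world) maximizing
#' normalized mutual information over the template head region, with a
#' multi-resolution search: centre-of-mass initialization, restarted
#' Nelder-Mead on the NMI at the coarse level (rigid parameters first, then
#' all 12), and a gradient-based least-squares polish at the fine level for
#' sub-voxel precision (both images share the HU scale).  Registration is
#' driven by the full head (skull and brain intensities).  If the optimum
#' does not improve the fine-level NMI over the identity, a warning is
#' raised and the identity transform is returned with `converged = FALSE`.
#'
#' @param subject a [ct_volume()].
#' @param atlas an `atlas_bundle` (see [generate_atlas()]).
#' @param levels downsampling factors `c(coarse, fine)`.
#' @param maxit iteration budget: Nelder-Mead iterations at the coarse
#'   level, BFGS iterations for the fine-level polish.
#' @param nbins joint-histogram bins.
#' @param polish_restarts restarted BFGS rounds in the polish stage.
#' @param multi_start run rotation-nudged polish starts (robust for
#'   arbitrarily oriented subjects; can be disabled for near-aligned ones).
#' @return an `affine_transform` with extra fields `similarity`,
#'   `similarity_identity` and `converged`.
#' @export
register_affine <- function(subject, atlas, levels = c(4L, 1L),
                            maxit = c(300L, 80L), nbins = 32L,
                            polish_restarts = 2L, multi_start = TRUE) {
  stopifnot(inherits(subject, "ct_volume"), inherits(atlas, "atlas_bundle"))
  tpl <- atlas$template
  centre <- (dim(tpl$data) - 1) / 2 * tpl$spacing
  rng_f <- range(tpl$data)
  rng_m <- range(subject$data)

  mom_s <- moments_world(subject$data, subject$spacing)
  mom_a <- moments_world(tpl$data, tpl$spacing)
  p0 <- c(mom_a$com - mom_s$com, rep(0, 3),
          100 * log(mom_a$spread / mom_s$spread), rep(0, 3))

  unpack <- function(p) list(t = p[1:3], r = p[4:6], s = exp(p[7:9] / 100),
                             sh = p[10:12] / 100)
  # fixed evaluation points: template head voxels (air carries no alignment
  # information and would dilute the score) at a given pyramid level,
  # optionally strided down to cap the per-evaluation cost.  The level-grid
  # origin sits (factor - 1) / 2 source voxels into the full grid.
  make_level <- function(factor, max_points = Inf, src = tpl$data) {
    lv <- downsample_grid(src, tpl$spacing, factor)
    keep <- which(lv$data > -500)
    if (length(keep) > max_points)
      keep <- keep[seq(1, length(keep), length.out = max_points)]
    pts <- arrayInd(keep, dim(lv$data)) - 1L
    list(spacing = lv$spacing, fixed = lv$data[keep], pts = t(pts),
         origin = (factor - 1) / 2 * tpl$spacing)
  }
  sample_level <- function(lv, p, moving = subject$data) {
    u <- unpack(p)
    Tm <- compose_affine(u$t, u$r, u$s, u$sh, centre)
    # atlas voxel (level grid) -> atlas world -> subject world -> subject voxel;
    # out-of-field points get the air value so the sample domain stays fixed
    M4 <- diag(1 / subject$spacing, 4); M4[4, 4] <- 1
    A4 <- diag(c(lv$spacing, 1)); A4[1:3, 4] <- lv$origin
    Mm <- (M4 %*% solve(Tm) %*% A4)[1:3, ]
    cpp_resample_points(moving, Mm, lv$pts, 0L, rng_m[1])
  }
  nmi_level <- function(lv, p) {
    nmi_score(lv$fixed, sample_level(lv, p), nbins, rng_f, rng_m)
  }

  p <- p0
  rigid <- 1:6
  # global search: NMI by restarted Nelder-Mead on the coarse level,
  # rigid parameters first, then the full 12 degrees of freedom
  lvc <- make_level(levels[1])
  objc <- function(pp) {
    if (any(!is.finite(pp)) || max(abs(pp)) > 60) return(1e9)
    -nmi_level(lvc, pp)
  }
  r6 <- optim(p[rigid], function(p6) objc(c(p6, p[7:12])),
              method = "Nelder-Mead",
              control = list(maxit = maxit[1], parscale = rep(2, 6)))
  p[rigid] <- r6$par
  # deterministic grid probes catch gross basin misses that the simplex
  # cannot recover from: rotations first, then per-axis log-scale
  probe <- function(idx, offsets) {
    grid <- as.matrix(expand.grid(offsets, offsets, offsets))
    best <- objc(p)
    p_best <- p
    for (g in seq_len(nrow(grid))) {
      pp <- p
      pp[idx] <- pp[idx] + grid[g, ]
      v <- objc(pp)
      if (v < best) { best <- v; p_best <- pp }
    }
    p <<- p_best
  }
  probe(4:6, c(-6, 0, 6))
  probe(7:9, c(-3, 0, 3))
  probe(4:6, c(-3, 0, 3))
  for (restart in 1:2) {
    res <- optim(p, objc, method = "Nelder-Mead",
                 control = list(maxit = maxit[1], parscale = rep(1, 12)))
    p <- res$par
  }
  # local polish: both images share the HU scale, so a least-squares
  # criterion on Gaussian-smoothed images (sigma 2 mm; widens the basins
  # and cancels interpolation blur at the skull/air boundary) gives a
  # smooth, sharply peaked objective for gradient-based sub-voxel
  # refinement at the fine level
  subj_s <- cpp_gauss3d(subject$data, 2 / subject$spacing)
  tpl_smooth <- cpp_gauss3d(tpl$data, 2 / tpl$spacing)
  lvf <- make_level(levels[length(levels)], max_points = 50000L,
                    src = tpl_smooth)
  lvp <- make_level(levels[1], max_points = 20000L, src = tpl_smooth)
  p_anchor <- p
  ssd_at <- function(lv, pp, moving = subj_s) {  # trust region around coarse
    if (any(!is.finite(pp)) || any(abs(pp - p_anchor) > 25)) return(1e9)
    mean((sample_level(lv, pp, moving) - lv$fixed)^2)
  }
  # the near-ellipsoidal head admits rotation-shear compensation, so the
  # polish alternates: shear-free refinement of the 9 rigid+scale
  # parameters (coarse level first, then fine), a short shear-only fit,
  # then a final rigid+scale pass
  bfgs_idx <- function(lv, idx, iters, moving = subj_s) {
    obj <- function(v) { pp <- p; pp[idx] <- v; ssd_at(lv, pp, moving) }
    res <- optim(p[idx], obj, method = "BFGS",
                 control = list(maxit = iters, ndeps = rep(5e-4, length(idx)),
                                reltol = 1e-14))
    if (res$value <= ssd_at(lv, p, moving)) p[idx] <<- res$par
  }
  p[10:12] <- 0
  m2 <- maxit[length(maxit)]
  if (multi_start) {
    # multi-start guards against wrinkles in the shallow rotation valley:
    # polish rotation-nudged starts at the cheap coarse level, rank them by
    # fine-level residual, then refine the two best at the fine level
    p_c <- p
    cand <- list()
    for (nudge in c(0, -3, 3)) {
      p <- p_c
      p[4:6] <- p[4:6] + nudge
      bfgs_idx(lvp, 1:9, m2)
      cand[[length(cand) + 1L]] <- p
    }
    ord <- order(vapply(cand, function(pp) ssd_at(lvf, pp), numeric(1)))
    refined <- lapply(cand[ord[1:2]], function(pp) {
      p <<- pp
      bfgs_idx(lvf, 1:9, m2)
      p
    })
    p <- refined[[which.min(vapply(refined, function(pp) ssd_at(lvf, pp),
                                   numeric(1)))]]
  } else {
    bfgs_idx(lvp, 1:9, m2)
    bfgs_idx(lvf, 1:9, m2)
  }
  for (restart in seq_len(polish_restarts - 1L)) bfgs_idx(lvf, 1:9, m2)
  bfgs_idx(lvf, 10:12, 10L)
  bfgs_idx(lvf, 1:9, m2)
  # last pass on the unsmoothed images: the sharp skull/air boundary pins
  # down the scale to a fraction of a voxel
  lv0 <- make_level(1L, max_points = 50000L)
  bfgs_idx(lv0, 1:9, min(40L, m2), moving = subject$data)
  bfgs_idx(lv0, 7:9, min(20L, m2), moving = subject$data)  # scale decoupled
  bfgs_idx(lv0, 1:6, min(20L, m2), moving = subject$data)
  bfgs_idx(lv0, 1:9, min(40L, m2), moving = subject$data)

  lvn <- make_level(levels[length(levels)], max_points = 50000L)
  sim_id <- nmi_level(lvn, rep(0, 12))
  sim <- nmi_level(lvn, p)
  if (sim < sim_id) {
    warning("registration failed to improve on identity; returning identity")
    tr <- affine_transform(centre = centre)
    tr$similarity <- sim_id
    tr$similarity_identity <- sim_id
    tr$converged <- FALSE
    return(tr)
  }
  u <- unpack(p)
  tr <- affine_transform(u$t, u$r, u$s, u$sh, centre)
  tr$similarity <- sim
  tr$similarity_identity <- sim_id
  tr$converged <- TRUE
  tr
}

#' Warp an atlas-space volume onto the subject grid
#'
#' Resamples an atlas prior (probability or binary) through the inverse of
#' the subject-to-atlas transform onto the subject voxel grid; trilinear for
#' probabilities, nearest neighbour for binary priors.  Values are clamped
#' to [0, 1].
#'
#' @param prior numeric or logical atlas-space array.
#' @param t an `affine_transform` (subject to atlas).
#' @param grid a [ct_volume()] defining the subject grid, or a list with
#'   `dims` and `spacing`.
#' @param atlas_spacing voxel spacing of the atlas grid.
#' @param mode `"trilinear"` or `"nearest"` (default chosen from the prior
#'   type).
#' @return array on the subject grid (numeric, or logical for binary input).
#' @export
warp_to_subject <- function(prior, t, grid, atlas_spacing, mode = NULL) {
  binary <- is.logical(prior)
  if (is.null(mode)) mode <- if (binary) "nearest" else "trilinear"
  dims <- if (inherits(grid, "ct_volume")) dim(grid$data) else grid$dims
  sp <- if (inherits(grid, "ct_volume")) grid$spacing else grid$spacing
  # subject voxel -> subject world -> atlas world -> atlas voxel
  A4 <- diag(1 / atlas_spacing, 4); A4[4, 4] <- 1
  S4 <- diag(c(sp, 1))
  Mm <- (A4 %*% t$matrix %*% S4)[1:3, ]
  src <- if (binary) array(as.numeric(prior), dim(prior)) else prior
  out <- cpp_resample_affine(src, Mm, as.integer(dims), if (mode == "nearest") 1L else 0L, 0)
  out <- pmin(pmax(out, 0), 1)
  dim(out) <- dims
  if (binary) {
    out <- out > 0.5
    dim(out) <- dims
  }
  out
}
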