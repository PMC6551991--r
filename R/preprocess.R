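#' Brain extraction from head CT
#'
#' Two methods are provided.  The reference `"morphological"` extractor is
#' deterministic: it keeps voxels in the soft-tissue/fluid window
#' [-20, 100] HU, applies a binary opening (2 iterations of 6-connected
#' erosion and dilation) to detach scalp remnants, keeps the largest
#' connected component and fills interior holes.  The `"unet2d"` method runs
#' a trained per-slice 2D U-Net (see [train_brain_extractor()]) followed by
#' the same largest-component and hole-filling cleanup.
#'
#' @param ct a [ct_volume()] in Hounsfield units.
#' @param method `"morphological"` or `"unet2d"`.
#' @param model a trained extractor (required for `"unet2d"`).
#' @param hu_window low/high HU bounds of the morphological tissue window.
#' @param open_iters binary-opening iterations.
#' @return logical brain mask array with a `spacing` attribute.
#' @export
extract_brain <- function(ct, method = c("morphological", "unet2d"),
                          model = NULL, hu_window = c(-20, 100),
                          open_iters = 2L) {
  method <- match.arg(method)
  stopifnot(inherits(ct, "ct_volume"))
  if (method == "morphological") {
    m <- ct$data >= hu_window[1] & ct$data <= hu_window[2]
    if (!any(m)) stop("no brain found: no voxels in the brain HU range")
    m <- cpp_erode(m, open_iters)
    m <- cpp_dilate(m, open_iters)
  } else {
    if (is.null(model)) stop("method 'unet2d' requires a trained extractor model")
    m <- predict_brain_slices(model, ct)
  }
  if (!any(m)) stop("no brain found: mask empty after morphology")
  lab <- cpp_label6(m)
  sizes <- tabulate(lab)
  keep <- which.max(sizes)
  m <- lab == keep
  dim(m) <- dim(ct$data)
  m <- fill_holes(m)
  # the mask must exclude bone-density voxels (intracranial calcifications
  # re-enclosed by the hole fill) and background air
  m <- m & ct$data <= hu_window[2] & ct$data >= -200
  dim(m) <- dim(ct$data)
  attr(m, "spacing") <- ct$spacing
  m
}

# Fill cavities: background components not touching the grid border.
#' @noRd
fill_holes <- function(mask) {
  inv <- !mask
  lab <- cpp_label6(inv)
  d <- dim(mask)
  border <- unique(c(lab[c(1, d[1]), , ], lab[, c(1, d[2]), ],
                     lab[, , c(1, d[3])]))
  border <- border[border > 0]
  hole <- inv & !(lab %in% border)
  dim(hole) <- d
  out <- mask | hole
  dim(out) <- d
  out
}

#' Intensity normalization inside the brain mask
#'
#' Rescales the extracted brain to zero mean and unit standard deviation,
#' computed strictly inside the mask; voxels outside the mask are set to 0.
#'
#' @param ct a [ct_volume()].
#' @param mask logical brain mask on the same grid.
#' @return a [ct_volume()] of normalized intensities.
#' @export
normalize_intensities <- function(ct, mask) {
  stopifnot(inherits(ct, "ct_volume"))
  check_same_dim(ct$data, mask)
  if (!any(mask)) stop("mask is empty")
  v <- ct$data[mask]
  s <- sd(v)
  if (!is.finite(s) || s < 1e-8)
    stop("zero variance inside mask: cannot normalize constant region")
  out <- array(0, dim(ct$data))
  out[mask] <- (v - mean(v)) / s
  ct_volume(out, ct$spacing, ct$affine)
}

#' Resample a volume to isotropic spacing
#'
#' Trilinear interpolation for intensity volumes, nearest neighbour for
#' masks.  The world extent of the grid is preserved; if the input is
#' already at the target spacing it is returned unchanged.
#'
#' @param ct a [ct_volume()] (or a logical mask array with `spacing`
#'   attribute for `resample_mask`).
#' @param target_spacing target isotropic voxel size (mm), > 0.
#' @return a resampled [ct_volume()] (or logical mask).
#' @export
resample_to_isotropic <- function(ct, target_spacing = 1) {
  stopifnot(inherits(ct, "ct_volume"))
  if (target_spacing <= 0) stop("target_spacing must be > 0")
  if (abs(det(ct$affine)) < 1e-12) stop("affine is not invertible")
  sp <- ct$spacing
  if (all(abs(sp - target_spacing) < 1e-9)) return(ct)
  dims <- dim(ct$data)
  newdims <- pmax(1L, as.integer(round(dims * sp / target_spacing)))
  M <- cbind(diag(target_spacing / sp, 3), c(0, 0, 0))
  out <- cpp_resample_affine(ct$data, M, newdims, 0L, -1000)
  ct_volume(out, rep(target_spacing, 3))
}

#' @rdname resample_to_isotropic
#' @param mask logical mask with a `spacing` attribute (as returned by
#'   [extract_brain()]).
#' @export
resample_mask <- function(mask, target_spacing = 1) {
  sp <- attr(mask, "spacing")
  if (is.null(sp)) stop("mask has no spacing attribute")
  if (all(abs(sp - target_spacing) < 1e-9)) return(mask)
  dims <- dim(mask)
  newdims <- pmax(1L, as.integer(round(dims * sp / target_spacing)))
  M <- cbind(diag(target_spacing / sp, 3), c(0, 0, 0))
  arr <- array(as.numeric(mask), dims)
  out <- cpp_resample_affine(arr, M, newdims, 1L, 0) > 0.5
  dim(out) <- newdims
  attr(out, "spacing") <- rep(target_spacing, 3)
  out
}

#' 2D U-Net brain-extractor configuration
#'
#' Architecture and training hyper-parameters for the per-slice brain
#' extractor: a U-Net of `depth` resolution levels with 3x3 kernels,
#' `base_filters` filters in the first level (doubling per level), trained
#' with Adadelta on axial slice / brain-mask pairs.
#'
#' @param depth resolution levels (>= 2).
#' @param base_filters filters in the first level (>= 1).
#' @param epochs training epochs.
#' @param batch_size slices per optimizer step (only 1 is supported).
#' @param lr,rho,eps Adadelta parameters.
#' @param seed RNG seed for weight initialization and slice order.
#' @return an object of class `brain_extractor_config`.
#' @export
brain_extractor_config <- function(depth = 5L, base_filters = 64L, epochs = 5L,
                                   batch_size = 1L, lr = 1.0, rho = 0.95,
                                   eps = 1e-6, seed = 1L) {
  if (depth < 2) stop("depth must be >= 2")
  if (base_filters < 1) stop("base_filters must be >= 1")
  structure(list(depth = as.integer(depth), base_filters = as.integer(base_filters),
                 epochs = as.integer(epochs), batch_size = as.integer(batch_size),
                 lr = lr, rho = rho, eps = eps, seed = as.integer(seed)),
            class = "brain_extractor_config")
}

# CT intensities scaled for the extractor: clamp to [-100, 300] HU and map
# to roughly unit scale; keeps skull/brain/air contrast without HU outliers.
#' @noRd
scale_for_extractor <- function(data) {
  pmin(pmax(data, -100), 300) / 100
}

#' Train the 2D U-Net brain extractor on phantom cases
#'
#' Builds per-slice training pairs (axial CT slice, axial brain-truth slice)
#' from the cases and trains a 2-class valid-convolution U-Net with
#' mirror-padded inputs under Adadelta.  Training is deterministic given the
#' config seed.
#'
#' @param cases list of `phantom_case` (>= 1).
#' @param cfg a [brain_extractor_config()].
#' @return an object of class `brain_extractor` with fields `net`,
#'   `cfg` and `loss_history` (one entry per optimizer step).
#' @export
train_brain_extractor <- function(cases, cfg = brain_extractor_config()) {
  if (!length(cases)) stop("empty case list")
  net_cfg <- unet_config(depth = cfg$depth,
                         first_filters = c(cfg$base_filters, 2L * cfg$base_filters),
                         n_classes = 2L, ndim = 2L)
  slices <- list()
  for (case in cases) {
    dat <- scale_for_extractor(case$ct$data)
    for (z in seq_len(dim(dat)[3])) {
      slices[[length(slices) + 1L]] <-
        list(img = dat[, , z], lab = case$truth_brain[, , z])
    }
  }
  with_seed(cfg$seed, {
    net <- unet_init(net_cfg)
    state <- adadelta_init(net$params)
    loss_hist <- numeric(0)
    for (ep in seq_len(cfg$epochs)) {
      ord <- sample.int(length(slices))
      for (si in ord) {
        sl <- slices[[si]]
        step <- extractor_step(net, sl$img, sl$lab)
        upd <- adadelta_update(net$params, step$grads, state, cfg$lr, cfg$rho, cfg$eps)
        net$params <- upd$params
        state <- upd$state
        loss_hist <- c(loss_hist, step$loss)
      }
    }
    structure(list(net = net, cfg = cfg, loss_history = loss_hist),
              class = "brain_extractor")
  })
}

# One forward/backward pass on a single axial slice, handling the
# valid-convolution padding arithmetic.
#' @noRd
extractor_step <- function(net, img, lab) {
  pads <- extractor_pad(net$cfg, dim(img))
  x <- mirror_pad_2d(img, pads$input)
  dim(x) <- c(dim(x), 1L, 1L)
  fw <- unet_forward(net, x)
  labs <- extractor_labels(lab, pads)
  ce <- cpp_softmax_ce(fw$logits, labs)
  grads <- unet_backward(net, fw$cache, ce$grad)
  list(loss = ce$loss, grads = grads)
}

# Given slice dims, find the smallest valid input size whose output covers
# the slice, and the crop of the output back onto the slice.
#' @noRd
extractor_pad <- function(cfg, sdim) {
  insz <- vapply(sdim, function(n) {
    sz <- n
    repeat {
      out <- tryCatch(shape_trace(sz, cfg$depth), error = function(e) -1L)
      if (out >= n) return(sz)
      sz <- sz + 1L
    }
  }, integer(1))
  out <- vapply(insz, shape_trace, integer(1), depth = cfg$depth)
  list(input = insz, output = out, slice = as.integer(sdim))
}

#' @noRd
mirror_pad_2d <- function(img, target) {
  d <- dim(img)
  lo <- (target - d) %/% 2
  ix <- reflect_index(seq_len(target[1]) - lo[1], d[1])
  iy <- reflect_index(seq_len(target[2]) - lo[2], d[2])
  img[ix, iy, drop = FALSE]
}

# Labels on the output grid: slice labels where the output voxel maps into
# the slice, -1 (ignored) elsewhere.
#' @noRd
extractor_labels <- function(lab, pads) {
  out <- pads$output; sl <- pads$slice
  lo <- (out - sl) %/% 2
  full <- matrix(-1L, out[1], out[2])
  full[lo[1] + seq_len(sl[1]), lo[2] + seq_len(sl[2])] <- as.integer(lab)
  as.integer(full)
}

#' @noRd
predict_brain_slices <- function(model, ct) {
  dat <- scale_for_extractor(ct$data)
  d <- dim(dat)
  pads <- extractor_pad(model$net$cfg, d[1:2])
  out <- array(FALSE, d)
  lo <- (pads$output - pads$slice) %/% 2
  for (z in seq_len(d[3])) {
    x <- mirror_pad_2d(dat[, , z], pads$input)
    dim(x) <- c(dim(x), 1L, 1L)
    fw <- unet_forward(model$net, x)
    probs <- cpp_softmax(fw$logits)
    cpp_unet_release(fw$cache)
    p <- probs[, , 1, 2]
    out[, , z] <- p[lo[1] + seq_len(d[1]), lo[2] + seq_len(d[2])] >= 0.5
  }
  out
}
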