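#' Lesion-segmentation training configuration
#'
#' Optimization hyper-parameters for the patch-based 3D U-Net: Adam with
#' learning rate 1e-5 and decay 0, categorical cross entropy, batch size 1,
#' random augmentation (flips, translations, rotations, Gaussian noise).
#' Patches are sampled lesion-centred with probability `lesion_patch_prob`
#' and uniformly inside the brain otherwise (stage 2 additionally samples
#' false-lesion-centred patches with probability `false_patch_prob`).
#'
#' @param optimizer only `"adam"` is supported.
#' @param lr learning rate (> 0).
#' @param decay learning-rate decay factor.
#' @param loss only `"categorical_crossentropy"` is supported.
#' @param batch_size patches per optimizer step (>= 1; only 1 is used).
#' @param epochs training epochs; each epoch draws `patches_per_case`
#'   patches from every case.
#' @param patches_per_case optimizer steps per case per epoch.
#' @param seed RNG seed making training fully deterministic.
#' @param augment an [augment_config()], or `NULL` to disable augmentation.
#' @param lesion_patch_prob,false_patch_prob patch-sampling mixture.
#' @return object of class `training_config`.
#' @export
training_config <- function(optimizer = "adam", lr = 1e-5, decay = 0,
                            loss = "categorical_crossentropy", batch_size = 1L,
                            epochs = 10L, patches_per_case = 1L, seed = 1L,
                            augment = NULL,
                            lesion_patch_prob = 0.5, false_patch_prob = 0.3) {
  if (lr <= 0) stop("learning_rate must be > 0")
  if (batch_size < 1) stop("batch_size must be >= 1")
  stopifnot(identical(optimizer, "adam"),
            identical(loss, "categorical_crossentropy"))
  structure(list(optimizer = optimizer, lr = lr, decay = decay, loss = loss,
                 batch_size = as.integer(batch_size), epochs = as.integer(epochs),
                 patches_per_case = as.integer(patches_per_case),
                 seed = as.integer(seed), augment = augment,
                 lesion_patch_prob = lesion_patch_prob,
                 false_patch_prob = false_patch_prob),
            class = "training_config")
}

#' Lesion-probability thresholding configuration
#'
#' @param probability_threshold probability above which a voxel is called
#'   lesion; the operating point is 0.7.
#' @return object of class `lesion_model_config`.
#' @export
lesion_model_config <- function(probability_threshold = 0.7) {
  if (probability_threshold <= 0 || probability_threshold >= 1)
    stop("probability_threshold must be in (0, 1)")
  structure(list(probability_threshold = probability_threshold),
            class = "lesion_model_config")
}

# Accepts either a phantom_case (uses truth brain + lesion masks and
# normalizes the CT inside the brain) or a pre-built list with
# img / brain / lesions.
#' @noRd
prepare_lesion_case <- function(case) {
  if (inherits(case, "phantom_case")) {
    img <- normalize_intensities(case$ct, case$truth_brain)$data
    list(img = img, brain = case$truth_brain, lesions = case$truth_lesions,
         spacing = case$ct$spacing)
  } else {
    stopifnot(all(c("img", "brain", "lesions") %in% names(case)))
    case
  }
}

#' @noRd
sample_patch_box <- function(dims, out_sz, target_voxel) {
  ctr <- arrayInd(target_voxel, dims)
  lo <- pmin(pmax(as.integer(ctr) - out_sz %/% 2L, 1L), dims - out_sz + 1L)
  list(lo = lo, hi = lo + out_sz - 1L)
}

#' @noRd
extract_input_patch <- function(img, box, offset) {
  d <- dim(img)
  ix <- reflect_index((box$lo[1] - offset):(box$hi[1] + offset), d[1])
  iy <- reflect_index((box$lo[2] - offset):(box$hi[2] + offset), d[2])
  iz <- reflect_index((box$lo[3] - offset):(box$hi[3] + offset), d[3])
  img[ix, iy, iz, drop = FALSE]
}

# One training step: sample a patch, augment, forward/backward.
#' @noRd
lesion_train_step <- function(net, prep, labels, out_sz, offset, train_cfg) {
  r <- runif(1)
  pool <- NULL
  if (r < train_cfg$lesion_patch_prob) {
    pool <- which(labels == 1L)
  } else if (net$cfg$n_classes >= 3L &&
             r < train_cfg$lesion_patch_prob + train_cfg$false_patch_prob) {
    pool <- which(labels == 2L)
  }
  if (!length(pool)) pool <- which(prep$brain)
  vox <- pool[sample.int(length(pool), 1L)]
  box <- sample_patch_box(dim(prep$img), rep(out_sz, 3L), vox)
  x <- extract_input_patch(prep$img, box, offset)
  if (!is.null(train_cfg$augment)) {
    # augment image and label on the input grid (congruent patches), then
    # crop the label back to the output region
    lab_full <- extract_input_patch(labels, box, offset)
    aug <- augment_patch(x, lab_full, train_cfg$augment)
    x <- aug$img
    ctr <- offset + seq_len(out_sz)
    lab <- aug$lab[ctr, ctr, ctr]
  } else {
    lab <- labels[box$lo[1]:box$hi[1], box$lo[2]:box$hi[2], box$lo[3]:box$hi[3]]
  }
  dim(x) <- c(dim(x)[1:3], 1L)
  fw <- unet_forward(net, x)
  ce <- cpp_softmax_ce(fw$logits, as.integer(lab))
  grads <- unet_backward(net, fw$cache, ce$grad)
  list(loss = ce$loss, grads = grads)
}

# Initialize the final-layer bias at the log class frequencies inside the
# brain, so early training does not have to spend steps learning the class
# prior before it can learn features.
#' @noRd
prior_bias_init <- function(net, labels, preps) {
  k <- net$cfg$n_classes
  counts <- numeric(k)
  for (i in seq_along(labels)) {
    tab <- tabulate(labels[[i]][preps[[i]]$brain] + 1L, k)
    counts <- counts + tab
  }
  freq <- (counts + 1) / sum(counts + 1)
  net$params[["final.b"]] <- log(freq)
  net
}

#' @noRd
run_training <- function(net, preps, labels, net_cfg, train_cfg) {
  out_sz <- net_cfg$output_patch
  offset <- (net_cfg$input_patch - out_sz) %/% 2L
  for (p in preps) {
    if (any(dim(p$img) < out_sz))
      stop("case volume smaller than the output patch; use a smaller patch or coarser grid")
  }
  state <- adam_init(net$params)
  loss_hist <- numeric(0)
  ppc <- train_cfg$patches_per_case %||% 1L
  for (ep in seq_len(train_cfg$epochs)) {
    ord <- rep(sample.int(length(preps)), ppc)
    for (ci in ord) {
      st <- lesion_train_step(net, preps[[ci]], labels[[ci]], out_sz, offset, train_cfg)
      upd <- adam_update(net$params, st$grads, state, train_cfg$lr,
                         decay = train_cfg$decay)
      net$params <- upd$params
      state <- upd$state
      loss_hist <- c(loss_hist, st$loss)
    }
  }
  list(net = net, loss_history = loss_hist)
}

#' Stage-1 lesion-segmentation training
#'
#' Trains the 3D U-Net to separate acute intracranial lesions from
#' background on intensity-normalized extracted-brain patches.  Each epoch
#' draws one patch per case, lesion-centred with probability
#' `lesion_patch_prob` and uniform inside the brain otherwise.  Training is
#' deterministic given the config seed.
#'
#' @param cases list of `phantom_case` (or prepared lists with
#'   `img`/`brain`/`lesions`).
#' @param net_cfg a [unet_config()] with `input_patch` set and
#'   `n_classes = 2`.
#' @param train_cfg a [training_config()].
#' @return object of class `lesion_model` (fields `net`, `net_cfg`,
#'   `train_cfg`, `loss_history`, `stage`).
#' @export
train_stage1 <- function(cases, net_cfg, train_cfg = training_config()) {
  if (!length(cases)) stop("empty case list")
  if (is.null(net_cfg$input_patch)) stop("net_cfg must set input_patch")
  preps <- lapply(cases, prepare_lesion_case)
  if (!any(vapply(preps, function(p) any(p$lesions), logical(1))))
    stop("no lesion voxels in any training case")
  labels <- lapply(preps, function(p) {
    l <- array(0L, dim(p$img)); l[p$lesions] <- 1L; l
  })
  cfg2 <- net_cfg; cfg2$n_classes <- 2L
  with_seed(train_cfg$seed, {
    net <- unet_init(cfg2)
    net <- prior_bias_init(net, labels, preps)
    tr <- run_training(net, preps, labels, cfg2, train_cfg)
    structure(list(net = tr$net, net_cfg = cfg2, train_cfg = train_cfg,
                   loss_history = tr$loss_history, stage = 1L),
              class = "lesion_model")
  })
}

#' @export
print.lesion_model <- function(x, ...) {
  cat(sprintf("<lesion_model> stage %d, %d classes, %d training step(s), final loss %.4f\n",
              x$stage, x$net$cfg$n_classes, length(x$loss_history),
              if (length(x$loss_history)) x$loss_history[length(x$loss_history)] else NA))
  invisible(x)
}

#' False-lesion mask from the stage-1 segmentation
#'
#' The voxels the stage-1 model called lesion that are not lesion in the
#' ground truth; disjoint from the truth by construction.
#'
#' @param stage1_seg logical stage-1 predicted mask.
#' @param truth logical ground-truth lesion mask on the same grid.
#' @return logical false-lesion mask.
#' @export
compute_false_lesion_mask <- function(stage1_seg, truth) {
  check_same_dim(stage1_seg, truth)
  m <- stage1_seg & !truth
  dim(m) <- dim(truth)
  m
}

#' Stage-2 retraining with the false-lesion class
#'
#' Retrains the network with the false-lesion mask as an additional class,
#' forcing it to separate true lesions from lesion-like structures (falx,
#' venous sinus).  Weights are warm-started from stage 1; the final
#' classification layer is re-shaped for three classes, keeping the trained
#' background and lesion columns and initializing only the new
#' false-lesion column.  At inference only the lesion-class probability is
#' thresholded.
#'
#' @param model the stage-1 `lesion_model`.
#' @param cases training cases (as in [train_stage1()]).
#' @param false_masks list of false-lesion masks, one per case; must not
#'   overlap the ground-truth lesions.
#' @param net_cfg network configuration (defaults to the stage-1 config).
#' @param train_cfg a [training_config()].
#' @return a `lesion_model` with `stage = 2` and 3 classes.
#' @export
train_stage2 <- function(model, cases, false_masks, net_cfg = model$net_cfg,
                         train_cfg = training_config()) {
  if (length(cases) != length(false_masks)) stop("cases and false_masks must be paired")
  preps <- lapply(cases, prepare_lesion_case)
  for (i in seq_along(preps)) {
    check_same_dim(false_masks[[i]], preps[[i]]$lesions, "false mask")
    if (any(false_masks[[i]] & preps[[i]]$lesions))
      stop("false-lesion mask overlaps the ground-truth lesions")
  }
  labels <- Map(function(p, fm) {
    l <- array(0L, dim(p$img)); l[p$lesions] <- 1L; l[fm] <- 2L; l
  }, preps, false_masks)
  cfg3 <- net_cfg; cfg3$n_classes <- 3L
  with_seed(train_cfg$seed, {
    net <- unet_init(cfg3)
    for (nm in names(net$params)) {  # warm start everything from stage 1;
      if (!startsWith(nm, "final.")) net$params[[nm]] <- model$net$params[[nm]]
    }
    # the final layer is re-shaped for 3 classes: the trained background and
    # lesion columns carry over, only the new false-lesion column is fresh
    net$params[["final.W"]][, 1:2] <- model$net$params[["final.W"]]
    net$params[["final.b"]][1:2] <- model$net$params[["final.b"]]
    fb <- prior_bias_init(net, labels, preps)$params[["final.b"]]
    net$params[["final.b"]][3] <- fb[3]
    tr <- run_training(net, preps, labels, cfg3, train_cfg)
    structure(list(net = tr$net, net_cfg = cfg3, train_cfg = train_cfg,
                   loss_history = tr$loss_history, stage = 2L),
              class = "lesion_model")
  })
}

#' Predict lesion probabilities and mask for a volume
#'
#' Tiles the brain with non-overlapping output patches (valid-convolution
#' tiling with stride equal to the output patch size; inputs are
#' mirror-padded at the borders), so every brain voxel is predicted exactly
#' once.  The lesion-class probability is thresholded at the configured
#' operating point (0.7) and restricted to the brain mask.
#'
#' @param model a trained `lesion_model`.
#' @param ct normalized brain [ct_volume()] (or plain array).
#' @param brain logical brain mask.
#' @param cfg a [lesion_model_config()].
#' @param return_coverage also return the per-voxel prediction count (for
#'   tiling verification).
#' @return list with `prob` (lesion-probability array, 0 outside brain),
#'   `mask` (logical) and optionally `coverage`.
#' @export
predict_lesions <- function(model, ct, brain, cfg = lesion_model_config(),
                            return_coverage = FALSE) {
  img <- if (inherits(ct, "ct_volume")) ct$data else ct
  check_same_dim(img, brain)
  net_cfg <- model$net_cfg
  out_sz <- net_cfg$output_patch
  offset <- (net_cfg$input_patch - out_sz) %/% 2L
  dims <- dim(img)
  if (any(dims < out_sz))
    stop("volume smaller than the output patch; tiling cannot cover it")
  if (!any(brain)) stop("empty brain mask")
  bb <- apply(which(brain, arr.ind = TRUE), 2, range)
  prob <- array(0, dims)
  cover <- if (return_coverage) array(0L, dims) else NULL
  lesion_ch <- 2L  # class order: background, lesion(, false lesion)
  starts <- lapply(1:3, function(ax) seq(bb[1, ax], bb[2, ax], by = out_sz))
  for (sx in starts[[1]]) for (sy in starts[[2]]) for (sz in starts[[3]]) {
    lo <- c(sx, sy, sz)
    hi <- pmin(lo + out_sz - 1L, dims)
    box <- list(lo = lo, hi = lo + out_sz - 1L)
    x <- extract_input_patch(img, box, offset)
    dim(x) <- c(dim(x)[1:3], 1L)
    fw <- unet_forward(model$net, x)
    probs <- cpp_softmax(fw$logits)
    cpp_unet_release(fw$cache)
    keep <- hi - lo + 1L
    prob[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] <-
      probs[seq_len(keep[1]), seq_len(keep[2]), seq_len(keep[3]), lesion_ch]
    if (return_coverage)
      cover[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] <-
        cover[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] + 1L
  }
  prob[!brain] <- 0
  mask <- prob >= cfg$probability_threshold & brain
  dim(mask) <- dims
  out <- list(prob = prob, mask = mask)
  if (return_coverage) out$coverage <- cover
  out
}
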