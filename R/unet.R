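#' Valid-convolution U-Net shape trace
#'
#' Computes the output patch edge length of the valid-convolution U-Net for
#' one axis: on the contracting path each of `depth - 1` levels applies two
#' unpadded 3-voxel convolutions (-4) followed by 2x pooling (requiring an
#' even size); the bottom level applies two convolutions; on the expanding
#' path each level applies 2x upsampling then two convolutions (x2 - 4).
#' At the reference configuration (input 132, depth 4) the output is 44 and
#' the input-output offset is 88.
#'
#' @param input_size input patch edge length in voxels (one axis).
#' @param depth number of resolution levels (>= 1).
#' @return integer output edge length; invalid inputs (non-positive or odd
#'   before pooling) raise an error naming the first failing level.
#' @export
shape_trace <- function(input_size, depth) {
  stopifnot(length(input_size) == 1, length(depth) == 1, depth >= 1)
  s <- as.integer(input_size)
  for (l in seq_len(depth - 1)) {
    s <- s - 4L
    if (s <= 0L)
      stop(sprintf("invalid input %d: size %d not positive after convolutions at level %d",
                   input_size, s, l))
    if (s %% 2L)
      stop(sprintf("invalid input %d: odd size %d before pooling at level %d",
                   input_size, s, l))
    s <- s %/% 2L
  }
  s <- s - 4L
  if (s <= 0L)
    stop(sprintf("invalid input %d: size %d not positive at the bottom level (depth %d)",
                 input_size, s, depth))
  for (l in rev(seq_len(depth - 1))) {
    s <- 2L * s - 4L
    if (s <= 0L)
      stop(sprintf("invalid input %d: size %d not positive on the expanding path at level %d",
                   input_size, s, l))
  }
  s
}

#' U-Net architecture configuration
#'
#' Describes the valid-convolution U-Net: `depth` resolution levels, two
#' convolutions per level with ReLU, 2x max pooling / upsampling, shortcut
#' crop-and-concatenate connections, and a final 1x1x1 convolution with
#' softmax.  The two convolutions of the first level have
#' `first_filters = c(f1, f2)` filters; both double at each deeper level.
#' On the expanding path both convolutions of level l have the same filter
#' count as the second contracting convolution of that level.
#'
#' @param depth resolution levels (>= 1).
#' @param first_filters length-2 filter counts of the first level.
#' @param input_patch optional input patch edge length; validated through
#'   [shape_trace()] when given.
#' @param n_classes output classes (2 for lesion/background, 3 with the
#'   false-lesion class).
#' @param ndim 3 for volumetric patches, 2 for per-slice networks (kernels
#'   3x3x1, pooling 2x2x1).
#' @param synthesis `"full"` gives the expanding-path convolutions the same
#'   filter count as the second contracting convolution of their level;
#'   `"light"` uses the first count (halving the widest layers, for
#'   CPU-scale training).
#' @return object of class `unet_config`; `$output_patch` is filled in when
#'   `input_patch` is given.
#' @export
unet_config <- function(depth = 4L, first_filters = c(32L, 64L),
                        input_patch = NULL, n_classes = 2L, ndim = 3L,
                        synthesis = c("full", "light")) {
  stopifnot(depth >= 1, length(first_filters) == 2, all(first_filters >= 1),
            n_classes >= 2, ndim %in% c(2L, 3L))
  synthesis <- match.arg(synthesis)
  cfg <- structure(list(
    depth = as.integer(depth), first_filters = as.integer(first_filters),
    input_patch = if (is.null(input_patch)) NULL else as.integer(input_patch),
    n_classes = as.integer(n_classes), ndim = as.integer(ndim),
    synthesis = synthesis,
    kernel = if (ndim == 3L) c(3L, 3L, 3L) else c(3L, 3L, 1L),
    pool = if (ndim == 3L) c(2L, 2L, 2L) else c(2L, 2L, 1L)),
    class = "unet_config")
  if (!is.null(cfg$input_patch))
    cfg$output_patch <- shape_trace(cfg$input_patch, cfg$depth)
  cfg
}

# Filter counts of the two convolutions at a contracting level.
#' @noRd
level_filters <- function(cfg, l) cfg$first_filters * 2L^(l - 1L)

#' Initialize an untrained U-Net
#'
#' He-initialized weights; deterministic given the seed.
#'
#' @param cfg a [unet_config()].
#' @param seed RNG seed (NULL leaves the caller's RNG in charge).
#' @return object of class `unet_model` with `cfg` and flat `params`.
#' @export
unet_init <- function(cfg, seed = NULL) {
  k3 <- prod(cfg$kernel)
  he <- function(nin, nout, k = k3) {
    matrix(rnorm(k * nin * nout, 0, sqrt(2 / (k * nin))), k * nin, nout)
  }
  build <- function() {
    P <- list()
    in_ch <- 1L
    for (l in seq_len(cfg$depth)) {
      f <- level_filters(cfg, l)
      P[[sprintf("a%d.W1", l)]] <- he(in_ch, f[1])
      P[[sprintf("a%d.b1", l)]] <- numeric(f[1])
      P[[sprintf("a%d.W2", l)]] <- he(f[1], f[2])
      P[[sprintf("a%d.b2", l)]] <- numeric(f[2])
      in_ch <- f[2]
    }
    syn_out <- function(l) {
      f <- level_filters(cfg, l)
      if (identical(cfg$synthesis %||% "full", "light")) f[1] else f[2]
    }
    for (l in rev(seq_len(cfg$depth - 1L))) {
      f <- level_filters(cfg, l)
      deeper <- if (l == cfg$depth - 1L) level_filters(cfg, cfg$depth)[2] else syn_out(l + 1L)
      so <- syn_out(l)
      P[[sprintf("s%d.W1", l)]] <- he(f[2] + deeper, so)
      P[[sprintf("s%d.b1", l)]] <- numeric(so)
      P[[sprintf("s%d.W2", l)]] <- he(so, so)
      P[[sprintf("s%d.b2", l)]] <- numeric(so)
    }
    P[["final.W"]] <- he(if (cfg$depth > 1L) syn_out(1L) else level_filters(cfg, 1L)[2],
                         cfg$n_classes, k = 1L)
    P[["final.b"]] <- numeric(cfg$n_classes)
    P
  }
  params <- if (is.null(seed)) build() else with_seed(seed, build())
  structure(list(cfg = cfg, params = params), class = "unet_model")
}

#' @export
print.unet_model <- function(x, ...) {
  np <- sum(vapply(x$params, length, numeric(1)))
  cat(sprintf("<unet_model> depth %d, first filters (%d, %d), %d classes, %s, %d parameters\n",
              x$cfg$depth, x$cfg$first_filters[1], x$cfg$first_filters[2],
              x$cfg$n_classes, sprintf("%dD", x$cfg$ndim), np))
  invisible(x)
}

#' @noRd
concat_channels <- function(a, b) {
  da <- dim(a); db <- dim(b)
  out <- c(a, b)
  dim(out) <- c(da[1:3], da[4] + db[4])
  out
}

#' U-Net forward pass
#'
#' Runs the float-native compiled network.  The activation cache is held on
#' the C++ side and returned as an external pointer for [unet_backward()].
#'
#' @param net a `unet_model`.
#' @param x input array (X, Y, Z, C); for 2D networks Z = 1.
#' @return list with `logits` (per-class scores on the output patch) and the
#'   `cache` required by [unet_backward()].
#' @export
unet_forward <- function(net, x) {
  if (length(dim(x)) == 3L) dim(x) <- c(dim(x), 1L)
  cpp_unet_fw(net$params, x, net$cfg)
}

#' U-Net backward pass
#'
#' @param net a `unet_model`.
#' @param cache forward cache from [unet_forward()].
#' @param dlogits gradient of the loss with respect to the logits.
#' @return flat list of gradients aligned with `net$params`.
#' @export
unet_backward <- function(net, cache, dlogits) {
  g <- cpp_unet_bw(net$params, cache, dlogits, net$cfg)
  g[names(net$params)]
}

# ---- optimizers ------------------------------------------------------------

#' @noRd
adam_init <- function(params) {
  z <- lapply(params, function(p) p * 0)
  list(m = z, v = z, t = 0L)
}

#' @noRd
adam_update <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                        eps = 1e-8, decay = 0) {
  state$t <- state$t + 1L
  if (decay > 0) lr <- lr / (1 + decay * state$t)
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(params = params, state = state)
}

#' @noRd
adadelta_init <- function(params) {
  z <- lapply(params, function(p) p * 0)
  list(Eg = z, Ed = z)
}

#' @noRd
adadelta_update <- function(params, grads, state, lr = 1, rho = 0.95, eps = 1e-6) {
  for (nm in names(params)) {
    g <- grads[[nm]]
    state$Eg[[nm]] <- rho * state$Eg[[nm]] + (1 - rho) * g * g
    dx <- -sqrt(state$Ed[[nm]] + eps) / sqrt(state$Eg[[nm]] + eps) * g
    state$Ed[[nm]] <- rho * state$Ed[[nm]] + (1 - rho) * dx * dx
    params[[nm]] <- params[[nm]] + lr * dx
  }
  list(params = params, state = state)
}

# ---- augmentation ----------------------------------------------------------

#' Patch augmentation configuration
#'
#' Random flips (probability `flip_prob` per enabled axis), integer
#' translations up to `max_translate` voxels (mirror-filled), in-plane
#' rotations up to `max_rotate` degrees about the z axis (trilinear for the
#' image, nearest neighbour for labels), and additive Gaussian noise on the
#' image only (`noise_sd`, normalized-intensity units).
#'
#' @param flip,translate,rotate,noise logical switches.
#' @param flip_prob per-axis flip probability.
#' @param flip_axes axes eligible for flipping (subset of 1:3).
#' @param max_translate maximum shift in voxels.
#' @param max_rotate maximum rotation in degrees.
#' @param noise_sd noise standard deviation.
#' @return object of class `augment_config`.
#' @export
augment_config <- function(flip = TRUE, translate = TRUE, rotate = TRUE,
                           noise = TRUE, flip_prob = 0.5, flip_axes = 1:3,
                           max_translate = 10, max_rotate = 10,
                           noise_sd = 0.1) {
  structure(list(flip = flip, translate = translate, rotate = rotate,
                 noise = noise, flip_prob = flip_prob, flip_axes = flip_axes,
                 max_translate = max_translate, max_rotate = max_rotate,
                 noise_sd = noise_sd), class = "augment_config")
}

#' @noRd
flip_axis <- function(arr, ax) {
  idx <- rep(list(quote(expr = )), length(dim(arr)))
  idx[[ax]] <- rev(seq_len(dim(arr)[ax]))
  do.call(`[`, c(list(arr), idx, list(drop = FALSE)))
}

#' @noRd
shift_mirror <- function(arr, shift) {
  d <- dim(arr)[1:3]
  ix <- reflect_index(seq_len(d[1]) - shift[1], d[1])
  iy <- reflect_index(seq_len(d[2]) - shift[2], d[2])
  iz <- reflect_index(seq_len(d[3]) - shift[3], d[3])
  if (length(dim(arr)) == 4) arr[ix, iy, iz, , drop = FALSE]
  else arr[ix, iy, iz, drop = FALSE]
}

#' Augment an image/label patch pair
#'
#' The same random geometric transform is applied to the image and label
#' patch; noise is applied to the image only; label values are preserved
#' (nearest-neighbour resampling).  With all switches off, the pair is
#' returned unchanged.
#'
#' @param img numeric image patch (3D, or 4D with a channel axis).
#' @param lab label patch congruent with `img` (3D).
#' @param cfg an [augment_config()].
#' @param seed optional seed for the draw.
#' @return list with transformed `img` and `lab`.
#' @export
augment_patch <- function(img, lab, cfg = augment_config(), seed = NULL) {
  di <- dim(img)[1:3]
  if (!all(di == dim(lab)[1:3])) stop("image and label patches are not congruent")
  run <- function() {
    if (cfg$flip) {
      for (ax in cfg$flip_axes) {
        if (runif(1) < cfg$flip_prob) {
          img <- flip_axis(img, ax)
          lab <- flip_axis(lab, ax)
        }
      }
    }
    if (cfg$translate && cfg$max_translate > 0) {
      sh <- sample(seq(-cfg$max_translate, cfg$max_translate), 3, replace = TRUE)
      img <- shift_mirror(img, sh)
      lab <- shift_mirror(lab, sh)
    }
    if (cfg$rotate && cfg$max_rotate > 0) {
      ang <- runif(1, -cfg$max_rotate, cfg$max_rotate) * pi / 180
      cen <- (di - 1) / 2
      R <- rbind(c(cos(ang), -sin(ang), 0), c(sin(ang), cos(ang), 0), c(0, 0, 1))
      M <- cbind(R, cen - R %*% cen)
      img3 <- img; had4 <- length(dim(img)) == 4
      if (had4) dim(img3) <- di
      img3 <- cpp_resample_affine(img3, M, di, 0L, 0)
      if (had4) dim(img3) <- dim(img)
      img <- img3
      lab3 <- array(as.numeric(lab), di)
      lab <- cpp_resample_affine(lab3, M, di, 1L, 0)
      storage.mode(lab) <- "integer"
      dim(lab) <- di
    }
    if (cfg$noise && cfg$noise_sd > 0)
      img <- img + rnorm(length(img), 0, cfg$noise_sd)
    list(img = img, lab = lab)
  }
  if (is.null(seed)) run() else with_seed(seed, run())
}
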