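test_that("shape trace reproduces the reference architecture arithmetic", {
  expect_equal(shape_trace(132, 4), 44)
  expect_equal(132 - shape_trace(132, 4), 88)   # receptive-field offset
  expect_equal(shape_trace(116, 4), 28)
  expect_equal(shape_trace(60, 2), 44)
  expect_equal(shape_trace(12, 1), 8)           # single level: two convs only

  # odd size before pooling
  expect_error(shape_trace(118, 4), "odd")
  # collapses to non-positive size
  expect_error(shape_trace(8, 2), "not positive")
  expect_error(shape_trace(4, 1), "not positive")
})

# Independent brute-force trace oracle: simulate the per-axis size through
# the layer sequence explicitly.
trace_oracle <- function(input, depth) {
  s <- input
  path <- c()
  for (l in seq_len(depth - 1)) {
    s <- s - 4
    if (s <= 0 || s %% 2 != 0) return(NA_integer_)
    path <- c(path, s)
    s <- s / 2
  }
  s <- s - 4
  if (s <= 0) return(NA_integer_)
  for (l in seq_len(depth - 1)) {
    s <- 2 * s - 4
    if (s <= 0) return(NA_integer_)
  }
  s
}

test_that("shape trace agrees with the brute-force oracle over a size sweep", {
  for (depth in 1:4) {
    for (input in seq(8, 140, by = 4)) {
      expected <- trace_oracle(input, depth)
      if (is.na(expected)) {
        expect_error(shape_trace(input, depth))
      } else {
        expect_equal(shape_trace(input, depth), expected)
      }
    }
  }
})

test_that("an instantiated network maps input patches to the traced output", {
  cfg <- unet_config(depth = 2, first_filters = c(2, 3), input_patch = 28)
  expect_equal(cfg$output_patch, shape_trace(28, 2))
  net <- unet_init(cfg, seed = 1)
  x <- array(rnorm(28^3), c(28, 28, 28, 1))
  fw <- unet_forward(net, x)
  expect_equal(dim(fw$logits), c(rep(cfg$output_patch, 3), 2))

  probs <- cpp_softmax(fw$logits)
  sums <- apply(probs, 1:3, sum)
  expect_true(all(abs(sums - 1) < 1e-5))

  # deterministic initialization
  net2 <- unet_init(cfg, seed = 1)
  expect_identical(net$params, net2$params)
})

test_that("backpropagation matches finite-difference gradients", {
  set.seed(1)
  cfg <- unet_config(depth = 2, first_filters = c(2, 3), input_patch = 20)
  net <- unet_init(cfg, seed = 1)
  x <- array(rnorm(20^3), c(20, 20, 20, 1))
  lab <- sample(0:1, cfg$output_patch^3, TRUE)
  fw <- unet_forward(net, x)
  ce <- cpp_softmax_ce(fw$logits, as.integer(lab))
  gr <- unet_backward(net, fw$cache, ce$grad)
  for (nm in c("a1.W1", "a2.W2", "s1.W1", "s1.W2", "final.W")) {
    p <- net$params[[nm]]
    i <- sample(length(p), 1)
    eps <- 1e-4
    loss_at <- function(v) {
      n2 <- net; n2$params[[nm]][i] <- v
      cpp_softmax_ce(unet_forward(n2, x)$logits, as.integer(lab))$loss
    }
    fd <- (loss_at(p[i] + eps) - loss_at(p[i] - eps)) / (2 * eps)
    # single-precision convolution arithmetic bounds the attainable agreement
    expect_lt(abs(fd - gr[[nm]][i]), 5e-3 + 0.05 * abs(fd))
  }
})

test_that("augmentation is identity when disabled and involutive for flips", {
  img <- array(rnorm(8^3), c(8, 8, 8))
  lab <- array(sample(0:1, 8^3, TRUE), c(8, 8, 8))

  off <- augment_config(flip = FALSE, translate = FALSE, rotate = FALSE,
                        noise = FALSE)
  out <- augment_patch(img, lab, off, seed = 1)
  expect_identical(out$img, img)
  expect_identical(out$lab, lab)

  flip_only <- augment_config(flip = TRUE, flip_prob = 1, flip_axes = 1,
                              translate = FALSE, rotate = FALSE, noise = FALSE)
  once <- augment_patch(img, lab, flip_only, seed = 2)
  expect_equal(sum(once$lab), sum(lab))   # labels conserved under flips
  twice <- augment_patch(once$img, once$lab, flip_only, seed = 3)
  expect_identical(twice$img, img)
  expect_identical(twice$lab, lab)

  expect_error(augment_patch(img, lab[1:4, , ], off), "congruent")
})

test_that("false-lesion masks are the stage-1 / truth set difference", {
  d <- c(10, 10, 5)
  truth <- array(FALSE, d); truth[1:50] <- TRUE
  seg <- truth
  expect_equal(sum(compute_false_lesion_mask(seg, truth)), 0)

  seg2 <- truth; seg2[101:200] <- TRUE
  fm <- compute_false_lesion_mask(seg2, truth)
  expect_equal(sum(fm), 100)
  expect_false(any(fm & truth))

  none <- array(FALSE, d)
  expect_equal(sum(compute_false_lesion_mask(seg2, none)), sum(seg2))
  expect_error(compute_false_lesion_mask(seg2, array(FALSE, c(10, 10, 4))),
               "grids")
})

# A model with zeroed weights and a chosen final bias emits a constant
# class probability everywhere.
constant_prob_model <- function(p_lesion, input_patch = 20, depth = 1) {
  cfg <- unet_config(depth = depth, first_filters = c(2, 3),
                     input_patch = input_patch)
  net <- unet_init(cfg, seed = 1)
  for (nm in names(net$params)) net$params[[nm]][] <- 0
  net$params[["final.b"]] <- c(0, log(p_lesion / (1 - p_lesion)))
  structure(list(net = net, net_cfg = cfg,
                 loss_history = numeric(0), stage = 1L),
            class = "lesion_model")
}

test_that("prediction thresholds constant-probability models as expected", {
  case <- generate_phantom(tiny_spec(seed = 31))
  img <- normalize_intensities(case$ct, case$truth_brain)$data
  m8 <- constant_prob_model(0.8)
  out <- predict_lesions(m8, img, case$truth_brain, return_coverage = TRUE)
  expect_identical(out$mask, case$truth_brain)
  # tiling covers every brain voxel exactly once
  expect_true(all(out$coverage[case$truth_brain] == 1L))

  m5 <- constant_prob_model(0.5)
  out5 <- predict_lesions(m5, img, case$truth_brain)
  expect_equal(sum(out5$mask), 0)

  # monotone in the threshold: a higher threshold gives a subset mask
  set.seed(4)
  mr <- constant_prob_model(0.5)
  mr$net$params[["final.W"]][] <- rnorm(length(mr$net$params[["final.W"]]))
  lo <- predict_lesions(mr, img, case$truth_brain, lesion_model_config(0.55))
  hi <- predict_lesions(mr, img, case$truth_brain, lesion_model_config(0.85))
  expect_true(all(lo$mask[hi$mask]))
})

test_that("stage-1 training is deterministic and records one loss per step", {
  case <- generate_phantom(tiny_spec(lesion_volumes = 8, seed = 33))
  cfg <- unet_config(depth = 1, first_filters = c(2, 4), input_patch = 24)
  tc <- training_config(lr = 1e-3, epochs = 1, seed = 7)
  m1 <- train_stage1(list(case), cfg, tc)
  expect_length(m1$loss_history, 1)   # 1 case x 1 epoch = 1 optimizer step

  tc2 <- training_config(lr = 1e-3, epochs = 3, seed = 7,
                         augment = augment_config(max_translate = 2,
                                                  max_rotate = 5))
  m2 <- train_stage1(list(case), cfg, tc2)
  m3 <- train_stage1(list(case), cfg, tc2)
  expect_identical(m2$loss_history, m3$loss_history)
  expect_identical(m2$net$params, m3$net$params)

  nol <- generate_phantom(tiny_spec(seed = 34))
  expect_error(train_stage1(list(nol), cfg, tc), "no lesion voxels")
})

test_that("stage-2 refuses false masks that overlap the truth", {
  case <- generate_phantom(tiny_spec(lesion_volumes = 8, seed = 35))
  cfg <- unet_config(depth = 1, first_filters = c(2, 4), input_patch = 24)
  tc <- training_config(lr = 1e-3, epochs = 1, seed = 7)
  m1 <- train_stage1(list(case), cfg, tc)
  bad <- case$truth_lesions
  expect_error(train_stage2(m1, list(case), list(bad), cfg, tc), "overlaps")

  fm <- array(FALSE, dim(case$ct$data))
  fm[1:20] <- TRUE
  m2 <- train_stage2(m1, list(case), list(fm), cfg, tc)
  expect_equal(m2$stage, 2L)
  expect_equal(m2$net$cfg$n_classes, 3L)
  m2b <- train_stage2(m1, list(case), list(fm), cfg, tc)
  expect_identical(m2$net$params, m2b$net$params)
})
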