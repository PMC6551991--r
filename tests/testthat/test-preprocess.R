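test_that("morphological brain extraction recovers the phantom brain", {
  case <- generate_phantom(small_spec(noise_sigma = 0, seed = 41))
  mask <- extract_brain(case$ct)
  ov <- overlap_metrics(case$truth_brain, mask)
  expect_gte(ov$dice, 0.95)
  # never intersects skull-density voxels in a noiseless phantom
  expect_false(any(case$ct$data[mask] > 300))

  noisy <- generate_phantom(small_spec(seed = 42))
  ov2 <- overlap_metrics(noisy$truth_brain, extract_brain(noisy$ct))
  expect_gte(ov2$dice, 0.95)

  air <- ct_volume(array(-1000, c(20, 20, 20)), c(1, 1, 1))
  expect_error(extract_brain(air), "no brain found")
})

test_that("intensity normalization has its defining in-mask moments", {
  case <- small_case()
  mask <- case$truth_brain
  nrm <- normalize_intensities(case$ct, mask)
  expect_lt(abs(mean(nrm$data[mask])), 1e-6)
  expect_lt(abs(sd(nrm$data[mask]) - 1), 1e-6)
  expect_true(all(nrm$data[!mask] == 0))

  # idempotence and invariance to affine HU rescaling
  again <- normalize_intensities(nrm, mask)
  expect_equal(again$data, nrm$data, tolerance = 1e-9)
  rescaled <- ct_volume(2.5 * case$ct$data + 100, case$ct$spacing)
  nrm2 <- normalize_intensities(rescaled, mask)
  expect_equal(nrm2$data, nrm$data, tolerance = 1e-9)

  flat <- ct_volume(array(40, dim(mask)), case$ct$spacing)
  expect_error(normalize_intensities(flat, mask), "variance")
  expect_error(normalize_intensities(case$ct, array(FALSE, dim(mask))),
               "empty")
})

test_that("isotropic resampling preserves geometry and mask volume", {
  case <- small_case()   # 2 mm isotropic
  same <- resample_to_isotropic(case$ct, 2)
  expect_identical(same$data, case$ct$data)

  fine <- resample_to_isotropic(case$ct, 1)
  expect_equal(dim(fine$data), dim(case$ct$data) * 2L)

  m <- case$truth_brain
  attr(m, "spacing") <- case$ct$spacing
  m1 <- resample_mask(m, 1)
  v0 <- mask_volume_ml(case$truth_brain, c(2, 2, 2))
  v1 <- mask_volume_ml(m1, c(1, 1, 1))
  expect_lt(abs(v1 - v0) / v0, 0.02)

  # thick slices: the z extent in mm is preserved within one slice
  thick <- phantom_spec(grid_shape = c(58L, 68L, 26L), spacing = c(2.5, 2.5, 5))
  tc <- generate_phantom(thick)
  iso <- resample_to_isotropic(tc$ct, 1)
  expect_equal(dim(iso$data)[3] * 1, dim(tc$ct$data)[3] * 5, tolerance = 5)
  tm <- tc$truth_brain; attr(tm, "spacing") <- thick$spacing
  tm1 <- resample_mask(tm, 1)
  zext_src <- diff(range(which(apply(tm, 3, any)))) * 5
  zext_dst <- diff(range(which(apply(tm1, 3, any)))) * 1
  expect_lte(abs(zext_dst - zext_src), 5)

  expect_error(resample_to_isotropic(case$ct, -1), "> 0")
})

test_that("the 2D U-Net extractor learns brain masks on coarse phantoms", {
  # quarter-resolution phantoms keep per-slice training light
  coarse <- function(seed) {
    generate_phantom(phantom_spec(grid_shape = c(36L, 42L, 32L),
                                  spacing = c(4, 4, 4), seed = seed))
  }
  train <- lapply(1:8, coarse)
  held <- lapply(9:10, coarse)
  cfg <- brain_extractor_config(depth = 2, base_filters = 4, epochs = 5,
                                seed = 3)
  ext <- train_brain_extractor(train, cfg)
  expect_gt(length(ext$loss_history), 0)
  n <- length(ext$loss_history)
  k <- n %/% 5
  expect_lt(mean(ext$loss_history[(n - k + 1):n]),
            mean(ext$loss_history[1:k]))
  for (case in held) {
    m <- extract_brain(case$ct, method = "unet2d", model = ext)
    expect_gte(overlap_metrics(case$truth_brain, m)$dice, 0.90)
  }
})

test_that("extractor training is deterministic given the seed", {
  case <- generate_phantom(phantom_spec(grid_shape = c(36L, 42L, 32L),
                                        spacing = c(4, 4, 4), seed = 50))
  cfg <- brain_extractor_config(depth = 2, base_filters = 2, epochs = 1,
                                seed = 9)
  e1 <- train_brain_extractor(list(case), cfg)
  e2 <- train_brain_extractor(list(case), cfg)
  expect_identical(e1$net$params, e2$net$params)
  expect_equal(length(e1$loss_history), dim(case$ct$data)[3])  # 1 step/slice
  expect_error(train_brain_extractor(list(), cfg), "empty")
})
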