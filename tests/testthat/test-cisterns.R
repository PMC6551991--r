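test_that("cistern volume is voxel count times voxel volume", {
  m <- array(FALSE, c(20, 20, 10))
  m[1:1000] <- TRUE
  expect_equal(cistern_volume(m, c(1, 1, 1)), 1.0)
  expect_equal(cistern_volume(array(FALSE, c(5, 5, 5)), c(1, 1, 1)), 0.0)
  expect_equal(cistern_volume(m, c(2, 2, 2)), 8.0)

  case <- small_case()
  tv <- cistern_volume(case$truth_cisterns, case$ct$spacing)
  expect_lt(abs(tv - case$spec$cistern_volume) / case$spec$cistern_volume,
            0.05)
})

test_that("empty candidates give an empty mask without error", {
  dims <- c(16, 16, 8)
  out <- segment_cisterns(array(FALSE, dims), array(0.9, dims),
                          array(TRUE, dims))
  expect_equal(out$volume_ml, 0)
  expect_false(any(out$mask))
})

test_that("segmentation recovers the phantom cisterns and avoids ventricles", {
  case <- generate_phantom(small_spec(cistern_volume = 10, seed = 71))
  atl <- small_atlas()
  st <- run_tissue_stage(case, atl)
  loc <- locate_structures(st$seg, atl, st$t, case$ct)
  cm <- segment_cisterns(loc$cisterns, st$seg$post_csf, st$brain,
                         loc$ventricles, spacing = case$ct$spacing)
  truth_ml <- cistern_volume(case$truth_cisterns, case$ct$spacing)
  expect_lt(abs(cm$volume_ml - truth_ml) / truth_ml, 0.2)
  expect_gte(overlap_metrics(case$truth_cisterns, cm$mask)$dice, 0.6)
  expect_false(any(cm$mask & loc$ventricles))
})

test_that("estimated volume decreases when the cisterns are compressed", {
  atl <- small_atlas()
  vols <- vapply(c(4, 10), function(v) {
    case <- generate_phantom(small_spec(cistern_volume = v, seed = 72))
    st <- run_tissue_stage(case, atl)
    loc <- suppressWarnings(locate_structures(st$seg, atl, st$t, case$ct))
    segment_cisterns(loc$cisterns, st$seg$post_csf, st$brain,
                     loc$ventricles, spacing = case$ct$spacing)$volume_ml
  }, numeric(1))
  expect_lt(vols[1], vols[2])
  expect_gte(vols[1], 0)
})
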