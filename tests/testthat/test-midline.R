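test_that("slice range maps atlas landmark planes through the transform", {
  atl <- small_atlas()
  grid <- list(dims = dim(atl$template$data), spacing = atl$template$spacing)
  t_id <- identity_transform(atl)
  zr <- slice_range(t_id, atl, grid)
  expect_equal(zr, c(atl$landmark_z_monro, atl$landmark_z_roof))

  # a pure +10 mm z translation moves the range by 10 mm worth of slices
  t_z <- affine_transform(translation = c(0, 0, 10),
                          centre = t_id$params$centre)
  zr2 <- slice_range(t_z, atl, grid)
  shift_slices <- 10 / atl$template$spacing[3]
  expect_equal(zr2[1], zr[1] - shift_slices, tolerance = 0.6)

  # a z-reflection swaps the landmark order: error
  t_bad <- affine_transform(scale = c(1, 1, -1), centre = t_id$params$centre)
  expect_error(slice_range(t_bad, atl, grid), "order")
})

test_that("the slice formula |B/2 - C| reproduces hand-computed shifts", {
  # inner skull spanning x = 1..101 at 1 mm: B = 100 mm
  sk <- matrix(FALSE, 120, 60)
  sk[1:101, 10:50] <- TRUE
  vent <- matrix(FALSE, 120, 60)
  vent[49:53, 18:22] <- TRUE    # centred blob: midpoint x = 51, C = 50
  m <- measure_slice_shift(sk, vent, z = 1, spacing = c(1, 1))
  expect_equal(m$B_bar, 100)
  expect_equal(m$shift, 0)

  # B = 120, ventricle midpoint 6 mm off centre: shift 6
  sk2 <- matrix(FALSE, 140, 60)
  sk2[1:121, 10:50] <- TRUE     # B = 120, centre x = 61
  vent2 <- matrix(FALSE, 140, 60)
  vent2[53:57, 18:22] <- TRUE   # midpoint x = 55
  m2 <- measure_slice_shift(sk2, vent2, z = 1, spacing = c(1, 1))
  expect_equal(m2$B_bar, 120)
  expect_equal(m2$shift, 6)
  # start_x sits on the side opposite the shift (midpoint left of centre)
  expect_equal(m2$start_x, 121)
  expect_equal(m2$C_bar, 66)    # |120/2 - 66| = 6

  # empty ventricle slice: sentinel, not an error
  m3 <- measure_slice_shift(sk, matrix(FALSE, 120, 60), z = 4)
  expect_false(m3$measurable)
  expect_error(measure_slice_shift(matrix(FALSE, 5, 5), vent), "skull")
})

mls_via_pipeline <- function(case, atl) {
  st <- run_tissue_stage(case, atl)
  dil <- max(1L, as.integer(round(15 / case$ct$spacing[1])))
  loc <- suppressWarnings(
    locate_structures(st$seg, atl, st$t, case$ct, dilate_ventricles = dil))
  estimate_mls(loc$ventricles, st$brain, NULL, st$t, atl,
               spacing = case$ct$spacing)
}

test_that("induced phantom shifts are recovered within a millimetre", {
  atl <- small_atlas()
  for (s in c(2, 5, 10)) {
    case <- generate_phantom(small_spec(induced_shift = s, seed = 80 + s))
    r <- mls_via_pipeline(case, atl)
    expect_lt(abs(r$mls - s), 1)
    expect_equal(r$mls, max(r$per_slice$shift))
  }
})

test_that("midline estimation is left-right antisymmetric and null-safe", {
  atl <- small_atlas()
  case <- generate_phantom(small_spec(induced_shift = 6, seed = 85))
  r1 <- mls_via_pipeline(case, atl)

  mirrored <- case
  d <- dim(case$ct$data)
  mirrored$ct <- ct_volume(case$ct$data[d[1]:1, , ], case$ct$spacing)
  r2 <- mls_via_pipeline(mirrored, atl)
  expect_lt(abs(r1$mls - r2$mls), 0.5)

  null <- generate_phantom(small_spec(induced_shift = 0, seed = 86))
  r0 <- mls_via_pipeline(null, atl)
  expect_lte(r0$mls, 0.5)

  # no measurable slice: ventricle mask empty everywhere
  empty <- array(FALSE, dim(case$ct$data))
  st <- run_tissue_stage(null, atl)
  expect_error(estimate_mls(empty, st$brain, NULL, st$t, atl,
                            spacing = null$ct$spacing), "measurable")
})
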