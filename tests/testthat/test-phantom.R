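test_that("phantom generation is deterministic with exact lesion volumes", {
  sp <- small_spec(lesion_volumes = 30, seed = 5)
  a <- generate_phantom(sp)
  b <- generate_phantom(sp)
  expect_identical(a$ct$data, b$ct$data)
  expect_identical(a$truth_lesions, b$truth_lesions)

  vol <- mask_volume_ml(a$truth_lesions, sp$spacing)
  expect_lt(abs(vol - 30), 1.5)

  # a lesion that cannot fit inside the cranial cavity errors out
  expect_error(generate_phantom(small_spec(lesion_volumes = 2000)), "fit")
})

test_that("noise-free phantoms take exactly the configured HU values", {
  case <- generate_phantom(small_spec(noise_sigma = 0,
                                      lesion_volumes = 20, seed = 3))
  sp <- case$spec
  vals <- sort(unique(as.vector(case$ct$data)))
  expect_setequal(vals, sort(c(-1000, sp$skull_hu, sp$gm_hu, sp$wm_hu,
                               sp$csf_hu, sp$lesion_hu)))
})

test_that("unshifted noiseless phantoms are left-right mirror symmetric", {
  case <- generate_phantom(small_spec(noise_sigma = 0, induced_shift = 0))
  d <- dim(case$ct$data)
  expect_identical(case$ct$data, case$ct$data[d[1]:1, , ])
  expect_equal(case$truth_mls, 0)
})

test_that("tissue truth classes are disjoint and CSF structures nested", {
  case <- generate_phantom(small_spec(lesion_volumes = 15, seed = 9))
  overlap <- case$truth_gm + case$truth_wm + case$truth_csf
  expect_lte(max(overlap), 1)
  expect_true(all(case$truth_csf[case$truth_ventricles]))
  expect_true(all(case$truth_csf[case$truth_cisterns]))
  expect_false(any(case$truth_lesions & case$truth_csf))
  expect_true(all(case$truth_brain[case$truth_csf]))
})

test_that("septum displacement increases strictly with the induced shift", {
  xs <- vapply(c(0, 3, 6, 9), function(s) {
    case <- generate_phantom(small_spec(induced_shift = s, seed = 2))
    idx <- which(case$truth_ventricles, arr.ind = TRUE)
    mean(idx[, 1])
  }, numeric(1))
  expect_true(all(diff(xs) > 0))
  expect_error(phantom_spec(induced_shift = 25), "20 mm")
})

test_that("cohorts are reproducible and respect the sampling ranges", {
  rng <- list(induced_shift = c(0, 10), lesion_volume = c(5.5, 60),
              cistern_volume = c(4, 14))
  co1 <- generate_cohort(5, rng, seed = 3, base_spec = small_spec())
  co2 <- generate_cohort(5, rng, seed = 3, base_spec = small_spec())
  expect_identical(lapply(co1, function(c) c$ct$data),
                   lapply(co2, function(c) c$ct$data))
  for (case in co1) {
    expect_gte(case$truth_mls, 0)
    expect_lte(case$truth_mls, 10)
    lv <- mask_volume_ml(case$truth_lesions, case$ct$spacing)
    expect_gte(lv, 5.5 * 0.95)
    expect_lte(lv, 60 * 1.05)
  }
  expect_error(generate_cohort(5, list(), seed = 1), "empty")
  expect_error(generate_cohort(5, list(induced_shift = c(5, 1))), "hi >= lo")
})

test_that("atlas priors are normalized probabilities with ordered landmarks", {
  atl1 <- generate_atlas(small_spec(), n_subjects = 1, seed = 4)
  tot1 <- atl1$prior_gm + atl1$prior_wm + atl1$prior_csf
  expect_true(all(abs(tot1[atl1$brain_mask] - 1) < 1e-12))
  # single subject: priors are that case's indicator functions
  expect_true(all(atl1$prior_gm %in% c(0, 1 / 3, 1)))

  atl <- small_atlas()
  expect_true(all(atl$prior_gm >= 0 & atl$prior_gm <= 1))
  tot <- atl$prior_gm + atl$prior_wm + atl$prior_csf
  expect_true(all(abs(tot[atl$brain_mask] - 1) < 1e-9))
  expect_lt(atl$landmark_z_monro, atl$landmark_z_roof)
  expect_error(generate_atlas(small_spec(), n_subjects = 0), ">= 1")
})

test_that("phantom cases and atlases survive a NIfTI round trip", {
  dir <- withr::local_tempdir()
  case <- small_case()
  write_phantom_case(case, dir, "c1")
  ct2 <- read_ct_volume(file.path(dir, "c1_ct.nii.gz"))
  expect_equal(ct2$data, case$ct$data, tolerance = 1e-4)
  expect_equal(ct2$spacing, case$ct$spacing)
  side <- jsonlite::read_json(file.path(dir, "c1.json"), simplifyVector = TRUE)
  expect_equal(side$truth_mls, case$truth_mls)

  atl <- tiny_atlas()
  write_atlas(atl, file.path(dir, "atlas"))
  atl2 <- read_atlas(file.path(dir, "atlas"))
  expect_equal(atl2$landmark_z_monro, atl$landmark_z_monro)
  expect_equal(atl2$prior_ventricles, atl$prior_ventricles)
  expect_equal(atl2$prior_gm, atl$prior_gm, tolerance = 1e-6)
})
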