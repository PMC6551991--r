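test_that("self-registration of the template is near identity", {
  atl <- small_atlas()
  est <- suppressWarnings(register_affine(atl$template, atl,
                                          maxit = c(150L, 25L),
                                          polish_restarts = 1L))
  expect_lte(max(abs(est$params$translation)), 0.5)
  expect_lte(max(abs(est$params$rotation)), 0.5)
  expect_true(est$converged)
  expect_gte(est$similarity, est$similarity_identity)
})

test_that("a known translation of the template is recovered within 1 mm", {
  atl <- small_atlas()
  tpl <- atl$template
  centre <- (dim(tpl$data) - 1) / 2 * tpl$spacing
  tt <- affine_transform(translation = c(5, -3, 2), centre = centre)
  A <- diag(c(tpl$spacing, 1))
  M <- (solve(A) %*% tt$matrix %*% A)[1:3, ]
  subj <- ct_volume(cpp_resample_affine(tpl$data, M, dim(tpl$data), 0L, -1000),
                    tpl$spacing)
  est <- suppressWarnings(register_affine(subj, atl, maxit = c(150L, 25L),
                                          polish_restarts = 1L))
  expect_lte(max(abs(est$params$translation - c(5, -3, 2))), 1)
})

test_that("transform composition and warping behave geometrically", {
  centre <- c(10, 12, 8)
  t <- affine_transform(c(2, -1, 3), c(4, -2, 1), c(1.05, 0.97, 1.02),
                        c(0.01, 0, -0.01), centre)
  expect_equal(t$matrix %*% t$inverse, diag(4), tolerance = 1e-8)

  atl <- small_atlas()
  grid <- atl$template
  t_id <- identity_transform(atl)

  # identity warp on the matching grid leaves a binary prior untouched
  w <- warp_to_subject(atl$prior_ventricles, t_id, grid,
                       atl$template$spacing)
  expect_identical(w, atl$prior_ventricles)

  # probability priors stay within [0, 1] under an arbitrary warp
  t2 <- affine_transform(c(3, 2, -2), c(3, 0, 2), c(1.02, 1, 0.98),
                         centre = t_id$params$centre)
  wp <- warp_to_subject(atl$prior_csf, t2, grid, atl$template$spacing)
  expect_true(all(wp >= 0 & wp <= 1))

  # warp then inverse-warp round trip keeps the structure (Dice >= 0.95)
  fwd <- warp_to_subject(atl$prior_ventricles, t2, grid,
                         atl$template$spacing)
  t2inv <- structure(list(matrix = t2$inverse, inverse = t2$matrix,
                          params = NULL), class = "affine_transform")
  back <- warp_to_subject(fwd, t2inv, grid, atl$template$spacing)
  expect_gte(overlap_metrics(atl$prior_ventricles, back)$dice, 0.95)
})
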