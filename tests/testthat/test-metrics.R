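test_that("overlap metrics match their defining formulas on constructed masks", {
  a <- array(FALSE, c(4, 4, 2))
  b <- array(FALSE, c(4, 4, 2))
  a[1:4, 1, 1] <- TRUE          # |ref| = 4
  b[3:4, 1, 1] <- TRUE          # overlap 2
  b[1:2, 2, 1] <- TRUE          # |pred| = 4
  m <- overlap_metrics(a, b)
  expect_equal(m$dice, 0.5)     # 2*2 / (4 + 4)
  expect_equal(m$precision, 0.5)
  expect_equal(m$sensitivity, 0.5)
  expect_equal(c(m$tp, m$fp, m$fn), c(2, 2, 2))

  same <- overlap_metrics(a, a)
  expect_equal(c(same$dice, same$precision, same$sensitivity), c(1, 1, 1))

  disj <- overlap_metrics(a, !a & array(c(TRUE, FALSE), c(4, 4, 2)))
  expect_equal(disj$dice, 0)

  expect_error(overlap_metrics(a, array(FALSE, c(4, 4, 3))), "grids")
})

test_that("empty-mask conventions and dice identities hold", {
  e <- array(FALSE, c(3, 3, 3))
  f <- e; f[1] <- TRUE
  both <- overlap_metrics(e, e)
  expect_equal(c(both$dice, both$precision, both$sensitivity), c(1, 1, 1))
  m <- overlap_metrics(e, f)   # empty reference, non-empty prediction
  expect_true(is.nan(m$sensitivity))
  expect_equal(m$precision, 0)
  expect_equal(m$dice, 0)
  m2 <- overlap_metrics(f, e)
  expect_true(is.nan(m2$precision))
  expect_equal(m2$sensitivity, 0)

  # symmetry and the F1 identity on random masks
  set.seed(42)
  for (i in 1:10) {
    x <- array(runif(200) < 0.3, c(10, 10, 2))
    y <- array(runif(200) < 0.3, c(10, 10, 2))
    mx <- overlap_metrics(x, y)
    my <- overlap_metrics(y, x)
    expect_equal(mx$dice, my$dice)
    if (!is.nan(mx$precision) && !is.nan(mx$sensitivity) &&
        (mx$precision + mx$sensitivity) > 0) {
      expect_equal(mx$dice, 2 * mx$precision * mx$sensitivity /
                     (mx$precision + mx$sensitivity))
    }
  }
})

test_that("volume difference follows the undersegmentation sign convention", {
  sp <- c(1, 1, 1)
  ref <- array(FALSE, c(40, 40, 40)); ref[1:30000] <- TRUE   # 30 mL
  prd <- array(FALSE, c(40, 40, 40)); prd[1:20000] <- TRUE   # 20 mL
  va <- volume_agreement(ref, prd, sp)
  expect_equal(va$volume_diff_ml, 10)    # positive = undersegmentation
  expect_equal(va$abs_volume_diff_ml, 10)
  expect_equal(volume_agreement(ref, ref, sp)$volume_diff_ml, 0)
  prd2 <- array(FALSE, c(40, 40, 40)); prd2[1:18000] <- TRUE
  ref2 <- array(FALSE, c(40, 40, 40)); ref2[1:10000] <- TRUE
  va2 <- volume_agreement(ref2, prd2, sp)
  expect_equal(va2$volume_diff_ml, -8)
  expect_equal(va2$abs_volume_diff_ml, 8)
})

test_that("absolute-agreement ICC matches the ANOVA mean-squares oracle", {
  set.seed(7)
  x <- rnorm(20)
  expect_equal(icc_absolute(x, x), 1)

  # a systematic offset lowers absolute agreement, monotonically in the offset
  prev <- 1
  for (c in c(0.5, 1, 2, 4)) {
    v <- icc_absolute(x, x + c)
    expect_lt(v, prev)
    prev <- v
  }

  for (i in 1:25) {
    n <- sample(5:40, 1)
    x <- rnorm(n, sd = runif(1, 0.5, 3))
    y <- 0.5 * x + rnorm(n)
    expect_equal(icc_absolute(x, y), icc_aov_oracle(x, y), tolerance = 1e-10)
  }

  set.seed(8)
  a <- rnorm(1000); b <- rnorm(1000)
  expect_lt(abs(icc_absolute(a, b)), 0.1)

  expect_error(icc_absolute(rep(1, 5), rep(1, 5)), "variance")
  expect_error(icc_absolute(1:2, 1:2), "at least 3")
})

test_that("cutoff classification accuracy and kappa behave as specified", {
  r <- c(10, 30, 40, 2)
  ca <- classification_accuracy(r, r, 25)
  expect_equal(ca$accuracy, 1)
  expect_equal(ca$kappa, 1)

  # 36 of 39 agree at the cutoff
  ref <- c(rep(30, 20), rep(10, 19))
  prd <- ref; prd[1:3] <- 10
  ca2 <- classification_accuracy(ref, prd, 25)
  expect_equal(ca2$accuracy, 36 / 39)

  # degenerate all-one-class table: kappa undefined
  expect_warning(ca3 <- classification_accuracy(rep(1, 5), rep(2, 5), 25),
                 "degenerate")
  expect_equal(ca3$accuracy, 1)
  expect_true(is.nan(ca3$kappa))

  # values exactly at the cutoff are classified as the low class
  ca4 <- classification_accuracy(25, 26, 25)
  expect_equal(ca4$accuracy, 0)
})

test_that("shift agreement reproduces the reported example differences", {
  s <- shift_agreement(5.60, 5.95)
  expect_equal(s$difference_in_shift_mm, -0.35)
  expect_equal(s$abs_difference_in_shift_mm, 0.35)
  expect_equal(shift_agreement(1.10, 1.91)$difference_in_shift_mm, -0.81)
  expect_equal(shift_agreement(3, 3)$difference_in_shift_mm, 0)
  expect_error(shift_agreement(NA, 1), "finite")
})
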