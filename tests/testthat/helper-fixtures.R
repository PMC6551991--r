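# Shared fixtures, built once per test run and cached.
#
# Unit tests run on half-scale phantoms (2 mm voxels, same 144x168x128 mm
# field of view as the default 1 mm phantom); network tests use quarter-ish
# scale (2.5 mm).  The acceptance tests build their own cohorts at the
# package-default resolution.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, maker) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- maker()
  .fixtures[[name]]
}

small_spec <- function(...) {
  phantom_spec(grid_shape = c(72L, 84L, 64L), spacing = c(2, 2, 2), ...)
}

tiny_spec <- function(...) {
  phantom_spec(grid_shape = c(58L, 68L, 52L), spacing = c(2.5, 2.5, 2.5), ...)
}

small_atlas <- function() {
  fixture("small_atlas", function() generate_atlas(small_spec(), n_subjects = 6,
                                                   seed = 11))
}

tiny_atlas <- function() {
  fixture("tiny_atlas", function() generate_atlas(tiny_spec(), n_subjects = 4,
                                                  seed = 12))
}

small_case <- function() {
  fixture("small_case", function() generate_phantom(small_spec(seed = 21)))
}

# Independent oracle: ICC(2,1) assembled from the two-way ANOVA table that
# stats::aov produces on the long-format data.
icc_aov_oracle <- function(x, y) {
  n <- length(x)
  d <- data.frame(value = c(x, y),
                  subj = factor(rep(seq_len(n), 2)),
                  rater = factor(rep(1:2, each = n)))
  tab <- summary(stats::aov(value ~ subj + rater, data = d))[[1]]
  msr <- tab["subj", "Mean Sq"]
  msc <- tab["rater", "Mean Sq"]
  mse <- tab["Residuals", "Mean Sq"]
  (msr - mse) / (msr + mse + 2 * (msc - mse) / n)
}

# identity transform centred on an atlas grid
identity_transform <- function(atlas) {
  affine_transform(centre = (dim(atlas$template$data) - 1) / 2 *
                     atlas$template$spacing)
}

# preprocess + EM + locate on a phantom against an atlas with a given
# transform; the light path shared by several structural tests
run_tissue_stage <- function(case, atlas, t = identity_transform(atlas),
                             relax = TRUE) {
  brain <- extract_brain(case$ct)
  norm <- normalize_intensities(case$ct, brain)
  priors <- list(
    gm = warp_to_subject(atlas$prior_gm, t, case$ct, atlas$template$spacing),
    wm = warp_to_subject(atlas$prior_wm, t, case$ct, atlas$template$spacing),
    csf = warp_to_subject(atlas$prior_csf, t, case$ct, atlas$template$spacing))
  if (relax)
    priors <- relax_priors(priors, brain, spacing = case$ct$spacing)
  seg <- segment_tissues_em(norm, brain, priors)
  list(brain = brain, norm = norm, seg = seg, t = t)
}
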