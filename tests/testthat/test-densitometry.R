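make_vol <- function(values, spacing = c(1, 1, 1), mask = NULL) {
  scan_volume(array(values, c(length(values), 1, 1)), spacing,
              lung_mask = if (!is.null(mask)) array(mask, c(length(values), 1, 1)))
}

test_that("lung volume is voxel count times voxel volume", {
  expect_equal(lung_volume(array(TRUE, c(10, 10, 10)), c(1, 1, 1)), 0.001)
  expect_equal(lung_volume(array(TRUE, c(100, 100, 100)), c(1, 1, 1)), 1)
  m <- array(FALSE, c(100, 100, 50))
  m[seq_len(437500)] <- TRUE
  expect_equal(lung_volume(m, c(2, 2, 2)), 3.5)
  # additivity over disjoint masks
  m1 <- array(FALSE, c(10, 10, 10)); m1[1:200] <- TRUE
  m2 <- array(FALSE, c(10, 10, 10)); m2[301:500] <- TRUE
  expect_equal(lung_volume(m1 | m2, c(3, 3, 3)),
               lung_volume(m1, c(3, 3, 3)) + lung_volume(m2, c(3, 3, 3)))
  expect_error(lung_volume(array(FALSE, c(4, 4, 4)), c(1, 1, 1)), "empty")
})

test_that("mean lung density and the E/I ratio follow their definitions", {
  v <- make_vol(rep(-850, 8))
  expect_equal(mean_lung_density(v, array(TRUE, c(8, 1, 1))), -850)
  v2 <- make_vol(c(rep(-900, 4), rep(-700, 4)))
  expect_equal(mean_lung_density(v2, array(TRUE, c(8, 1, 1))), -800)
  expect_equal(ei_ratio(-800, -850), 100 * 800 / 850)
  expect_equal(ei_ratio(-850, -850), 100)
  expect_equal(ei_ratio(-800, -880), 90.90909, tolerance = 1e-6)
  expect_error(ei_ratio(-800, 0), "undefined")
  expect_warning(ei_ratio(10, -800), "non-physiological")
})

test_that("the low-attenuation fraction uses a strict threshold", {
  v <- make_vol(c(-900, -856, -855, -1000))
  m <- array(TRUE, c(4, 1, 1))
  expect_equal(exp856(v, m), 50) # -856 itself is not counted
  expect_equal(exp856(make_vol(rep(-1000, 5)), array(TRUE, c(5, 1, 1))), 100)
  expect_error(exp856(v, array(FALSE, c(4, 1, 1))), "empty")
})

test_that("masked measures are permutation-invariant and shift-monotone", {
  set.seed(10)
  vals <- rnorm(200, -820, 60)
  m <- array(TRUE, c(200, 1, 1))
  v <- make_vol(vals)
  vp <- make_vol(sample(vals))
  expect_equal(exp856(v, m), exp856(vp, m))
  expect_equal(mean_lung_density(v, m), mean_lung_density(vp, m))
  # adding a positive constant can only reduce the below-threshold fraction
  up <- make_vol(vals + 25)
  expect_lte(exp856(up, m), exp856(v, m))
})

test_that("Gaussian smoothing preserves constants, is identity at sd 0, and damps noise", {
  set.seed(4)
  a <- array(rnorm(20^3, -800, 30), c(20, 20, 20))
  v <- scan_volume(a, c(2, 2, 3)) # anisotropic spacing
  expect_identical(smooth_volume(v, 0)$voxels, a)
  cv <- scan_volume(array(-800, c(12, 12, 12)), c(1, 1, 1))
  expect_equal(smooth_volume(cv, 5)$voxels, cv$voxels, tolerance = 1e-12)
  sm <- smooth_volume(v, 6)
  expect_lt(sd(sm$voxels), sd(a))
  expect_equal(mean(sm$voxels), mean(a), tolerance = 0.5)
})

test_that("smoothing shifts the low-attenuation fraction as a narrower HU spread predicts", {
  # unimodal lungs, interior voxels only (boundary partial-volume excluded):
  # mode above the threshold -> tail shrinks; mode below -> tail grows
  set.seed(11)
  above <- render_expiratory_scan(c(40, 40, 40), c(4, 4, 4), 1.3, 0, -900, -820, 40)
  below <- render_expiratory_scan(c(40, 40, 40), c(4, 4, 4), 1.3, 1, -884, -750, 40)
  for (cfg in list(list(v = above, mu = -820), list(v = below, mu = -884))) {
    im <- interior_mask(cfg$v, 3)
    raw <- exp856(cfg$v, im)
    smo <- exp856(smooth_volume(cfg$v, 3), im)
    predicted <- sign(expected_exp856(0, -1000, cfg$mu, 10) -
                        expected_exp856(0, -1000, cfg$mu, 40))
    expect_equal(sign(smo - raw), predicted)
  }
})

test_that("threshold segmentation recovers the generator mask and fails loudly otherwise", {
  # grid generous enough that the lungs stay clear of the border
  set.seed(60)
  v <- render_expiratory_scan(c(40, 40, 40), c(5, 5, 5), 1.3,
                              f_exp = 0.3, mu_trapped = -900,
                              mu_normal = -760, sigma = 40)
  seg <- segment_lungs(v)
  expect_gt(dice_overlap(seg, v$lung_mask), 0.95)
  # bypass returns the stored mask verbatim
  expect_identical(segment_lungs(v, bypass = TRUE), v$lung_mask)
  # an all-tissue volume has nothing to segment
  solid <- scan_volume(array(50, c(8, 8, 8)), c(5, 5, 5))
  expect_error(segment_lungs(solid), "segmentation failure")
  expect_error(segment_lungs(solid, bypass = TRUE), "no lung mask")
})

test_that("density histogram is consistent with direct voxel measures", {
  co <- generate_cohort(tiny_config())
  ve <- co$subjects[[2]]$visits[[1]]$exp
  h <- density_histogram(ve)
  expect_equal(sum(h$counts), h$total)
  expect_equal(hist_percent_below(h, -856), exp856(ve), tolerance = 0.01)
})

test_that("per-visit measures assemble into the fixed-column cohort table", {
  co <- generate_cohort(tiny_config())
  m <- measure_cohort(co)
  expect_equal(nrow(m), 6)
  expect_named(m, c("subject_id", "visit", "v_insp_L", "v_exp_L",
                    "v_exhaled_L", "mld_insp_hu", "mld_exp_hu",
                    "exp856_pct", "ei_ratio_pct", "flags"))
  expect_equal(m$v_exhaled_L, m$v_insp_L - m$v_exp_L)
  expect_true(all(m$exp856_pct >= 0 & m$exp856_pct <= 100))
  expect_true(all(m$ei_ratio_pct > 0))
  expect_equal(nrow(attr(m, "excluded")), 0)
  # expiratory MLD agrees with the ground-truth mixture expectation
  for (s in co$subjects) {
    t <- s$truth
    r1 <- t$v_exp_visit[1] / t$v_insp_true
    sh <- trapped_share_expiratory(t$f_trapped, r1)
    mix <- sh$f_exp * t$mu_tissue_insp +
      (1 - sh$f_exp) * sponge_hu(t$mu_tissue_insp, sh$k)
    got <- m$mld_exp_hu[m$subject_id == t$subject_id & m$visit == 1]
    expect_lt(abs(got - mix), 3)
  }
})
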