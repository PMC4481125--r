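test_that("enhancement ratio follows 100 * I_sub / I_pre with a guard", {
  d <- c(3, 1, 1)
  g <- volume_grid(d)
  pre <- volume_image(array(c(100, 100, 0), d), g)
  sub <- volume_image(array(c(30, 0, 50), d), g)
  roi <- binary_mask(array(TRUE, d), g)
  em <- enhancement_ratio(pre, sub, roi)
  expect_equal(em$ratio[1, 1, 1], 30)
  expect_equal(em$ratio[2, 1, 1], 0)
  # zero pre-contrast: invalid, never counted, not an infinite ratio
  expect_false(em$valid[3, 1, 1])
  expect_true(is.na(em$ratio[3, 1, 1]))
  expect_equal(sum(bpe_mask(em, roi, 0)$values), 2)

  bad <- volume_image(array(0, c(2, 2, 2)))
  expect_error(enhancement_ratio(bad, bad, roi), "grid")
})

test_that("the BPE threshold is inclusive and monotone", {
  d <- c(3, 1, 1)
  g <- volume_grid(d)
  pre <- volume_image(array(100, d), g)
  sub <- volume_image(array(c(10, 30, 50), d), g)
  roi <- binary_mask(array(TRUE, d), g)
  em <- enhancement_ratio(pre, sub, roi)
  expect_equal(sum(bpe_mask(em, roi, 30)$values), 2)  # 30 and 50
  expect_equal(sum(bpe_mask(em, roi, 0)$values), 3)
  expect_equal(sum(bpe_mask(em, roi, 100.5)$values), 0)
  counts <- vapply(default_cutoffs(),
                   function(ct) sum(bpe_mask(em, roi, ct)$values),
                   numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("enhancement measures are invariant to global intensity scaling", {
  ph <- generate_phantom(identity_small_spec())
  fgt <- ph$truth$fgt_mask_dce
  sub <- derive_subtraction(ph$study, 1)
  em1 <- enhancement_ratio(ph$study$pre, sub, fgt)
  pre_s <- volume_image(ph$study$pre$values * 7.3, ph$study$pre$grid)
  sub_s <- volume_image(sub$values * 7.3, sub$grid)
  em2 <- enhancement_ratio(pre_s, sub_s, fgt)
  expect_equal(em1$ratio, em2$ratio, tolerance = 1e-12)
  for (ct in c(0, 30, 70))
    expect_identical(bpe_mask(em1, fgt, ct)$values,
                     bpe_mask(em2, fgt, ct)$values)
})

test_that("with truth masks and no noise the pipeline reduces to arithmetic", {
  sp <- identity_small_spec(
    t1_intensities = list(fat = 200, fgt = 80, muscle = 60, noise_sd = 0),
    dce_intensities = list(fgt_pre = 100, fat_pre = 20, muscle_pre = 40,
                           noise_sd = 0))
  ph <- generate_phantom(sp)
  fgt <- ph$truth$fgt_mask_dce
  for (k in c(1, 3)) {
    em <- enhancement_ratio(ph$study$pre, derive_subtraction(ph$study, k),
                            fgt)
    for (ct in default_cutoffs()) {
      est <- mask_volume_cc(bpe_mask(em, fgt, ct))
      expect_equal(est, true_bpe_cc(ph$truth, k, ct), tolerance = 1e-9)
    }
  }
})

test_that("quantify_scan returns the full sweep with its invariants", {
  ph <- generate_phantom(identity_small_spec())
  q <- quantify_scan(ph$t1, ph$study, sub_indices = c(1, 3),
                     params = quantify_params(skip_registration = TRUE))
  # 2 SUB time points x 11 cutoffs
  expect_equal(nrow(q$bpe), 22)
  expect_equal(q$fgt_pct, 100 * q$fgt_cc / q$breast_cc)
  expect_lte(q$fgt_cc, q$breast_cc)
  expect_true(all(q$bpe$bpe_cc <= q$fgt_cc + 1e-9))
  expect_equal(q$bpe$bpe_pct, 100 * q$bpe$bpe_cc / q$breast_cc)
  for (k in c(1, 3)) {
    b <- q$bpe$bpe_cc[q$bpe$sub_index == k]
    expect_true(all(diff(b) <= 1e-12))
  }
  # delayed uptake exceeds early uptake at every cutoff
  b1 <- q$bpe$bpe_cc[q$bpe$sub_index == 1]
  b3 <- q$bpe$bpe_cc[q$bpe$sub_index == 3]
  expect_true(all(b3 >= b1 - 1e-12))
})

test_that("quantify_scan names missing time points and bad cutoffs", {
  ph <- generate_phantom(identity_small_spec())
  expect_error(quantify_scan(ph$t1, ph$study, sub_indices = c(1, 5)),
               "SUB 5|5")
  expect_error(quantify_scan(ph$t1, ph$study, cutoffs = c(30, 10)),
               "ascending")
})
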