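test_that("peak detection integrates planted gaussians accurately", {
  one <- synth_chromatogram(data.frame(rt = 300, conc = 50), response = 2,
                            noise_sd = 0, area_cv = 0, seed = 1)
  pk <- detect_peaks(one)
  expect_equal(nrow(pk), 1)
  expect_equal(pk$area, 100, tolerance = 0.01)
  expect_equal(pk$rt, 300, tolerance = 2)
  expect_true(pk$left < pk$rt && pk$right > pk$rt)

  flat <- synth_chromatogram(data.frame(rt = numeric(0),
                                        conc = numeric(0))[0, ],
                             seed = 2)
  expect_equal(nrow(detect_peaks(flat)), 0)

  two <- synth_chromatogram(data.frame(rt = c(200, 420), conc = c(30, 80)),
                            response = 2, noise_sd = 0, area_cv = 0, seed = 3)
  pk2 <- detect_peaks(two)
  expect_equal(nrow(pk2), 2)
  expect_equal(pk2$area, c(60, 160), tolerance = 0.02)
})

test_that("calibration fitting is ordinary least squares with r-squared", {
  exact <- fit_calibration(data.frame(conc = c(25, 50, 100),
                                      area = c(50, 100, 200)))
  expect_equal(exact$slope, 2)
  expect_equal(exact$intercept, 0, tolerance = 1e-10)
  expect_equal(exact$r_squared, 1)
  expect_error(fit_calibration(data.frame(conc = 25, area = 50)),
               "2 distinct")
  # noiseless synthetic standards at the published 25/50/100 uM levels
  areas <- vapply(c(25, 50, 100), function(cc) {
    ch <- synth_chromatogram(data.frame(rt = 300, conc = cc), response = 2,
                             noise_sd = 0, area_cv = 0, seed = 1)
    detect_peaks(ch)$area
  }, numeric(1))
  cal <- fit_calibration(data.frame(conc = c(25, 50, 100), area = areas))
  expect_gte(cal$r_squared, 0.999)
})

test_that("quantitation recovers planted concentrations", {
  cal <- fit_calibration(data.frame(conc = c(25, 50, 100),
                                    area = c(50, 100, 200)))
  samp <- synth_chromatogram(data.frame(rt = 300, conc = 50), response = 2,
                             noise_sd = 0, area_cv = 0, seed = 4)
  q <- quantify(samp, cal, rt_window = c(280, 320))
  expect_true(q$detected)
  expect_equal(q$conc_uM, 50, tolerance = 0.02)
  # no peak in the window
  q2 <- quantify(samp, cal, rt_window = c(500, 560))
  expect_false(q2$detected)
  expect_equal(q2$conc_uM, 0)
  # area below the intercept clips at zero with a warning
  cal2 <- fit_calibration(data.frame(conc = c(25, 50, 100),
                                     area = c(250, 300, 400)))
  expect_warning(q3 <- quantify(samp, cal2, rt_window = c(280, 320)),
                 "clipping")
  expect_equal(q3$conc_uM, 0)
})

test_that("median quantitation error stays below 3% across the corpus", {
  cal_areas <- vapply(c(25, 50, 100), function(cc)
    detect_peaks(synth_chromatogram(
      data.frame(rt = 300, conc = cc), response = 2, noise_sd = 0.005,
      area_cv = 0.01, seed = 1000 + cc))$area[1], numeric(1))
  cal <- fit_calibration(data.frame(conc = c(25, 50, 100), area = cal_areas))
  set.seed(42)
  concs <- stats::runif(200, 5, 100)
  rel_err <- vapply(seq_along(concs), function(i) {
    ch <- synth_chromatogram(data.frame(rt = 300, conc = concs[i]),
                             response = 2, noise_sd = 0.005, area_cv = 0.01,
                             seed = 2000 + i)
    q <- quantify(ch, cal, rt_window = c(280, 320), min_prominence = 0.05)
    abs(q$conc_uM - concs[i]) / concs[i]
  }, numeric(1))
  expect_lt(stats::median(rel_err), 0.03)
})

test_that("ascorbate-oxidase treatment confirms peak identity", {
  samp <- synth_chromatogram(data.frame(rt = 300, conc = 40), response = 2,
                             noise_sd = 0, area_cv = 0, seed = 5)
  gone <- synth_chromatogram(data.frame(rt = 300, conc = 0), response = 2,
                             noise_sd = 0, area_cv = 0, seed = 5)
  half <- synth_chromatogram(data.frame(rt = 300, conc = 20), response = 2,
                             noise_sd = 0, area_cv = 0, seed = 5)
  expect_true(confirm_identity_ao(samp, gone, c(280, 320))$confirmed)
  expect_false(confirm_identity_ao(samp, samp, c(280, 320))$confirmed)
  expect_false(confirm_identity_ao(samp, half, c(280, 320))$confirmed)
})

test_that("per-individual conversion follows dimensional analysis", {
  # independent oracle: 16 umol/L * 176.12 g/mol = 2.818 mg/L = 2.818 ug/ml
  oracle <- 16.0 * 1e-6 * 176.12 * 1e6 * 1e-3 / 25
  expect_equal(per_individual_amount(16.0, 25), oracle)
  expect_equal(round(per_individual_amount(16.0, 25), 4), 0.1127)
  expect_equal(per_individual_amount(0, 25), 0)
  expect_equal(per_individual_amount(16, 12.5),
               2 * per_individual_amount(16, 25))
  expect_equal(per_individual_amount(32, 25),
               2 * per_individual_amount(16, 25))
})

test_that("group comparison is a two-tailed unpaired t-test", {
  expect_equal(compare_groups(c(1, 2, 3), c(1, 2, 3))$t, 0)
  expect_equal(compare_groups(c(1, 2, 3), c(1, 2, 3))$p, 1)
  set.seed(9)
  a <- rnorm(10, 0, 1); b <- rnorm(10, 10, 1)
  res <- compare_groups(a, b)
  expect_lt(res$p, 0.001)
  # agrees with the pooled-variance closed form
  sp <- sqrt(((9 * var(a)) + (9 * var(b))) / 18)
  t_manual <- (mean(a) - mean(b)) / (sp * sqrt(1 / 10 + 1 / 10))
  expect_equal(res$t, t_manual)
  expect_equal(res$p, 2 * stats::pt(-abs(t_manual), 18))
  expect_error(compare_groups(1, c(1, 2)), "at least 2")
})
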