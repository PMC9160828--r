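# Generator contracts: determinism, degenerate cases, band effects against a
# direct FFT-bin oracle, class exchangeability, cohort/MMSE consistency.

small_cfg <- function(...) {
  synthetic_config(n_pos = 2, n_neg = 2, n_channels = 4, fs = 200,
                   duration_s = 30, seed = 11, ...)
}

test_that("same config and seed reproduce identical samples", {
  cfg <- small_cfg()
  r1 <- generate_recording(cfg, "TMS+", 77)
  r2 <- generate_recording(cfg, "TMS+", 77)
  expect_identical(r1$data, r2$data)
  c1 <- generate_cohort(small_cfg())
  c2 <- generate_cohort(small_cfg())
  expect_identical(c1$recordings[[3]]$data, c2$recordings[[3]]$data)
  expect_identical(c1$subjects, c2$subjects)
})

test_that("all-zero gains and zero pink noise give the all-zero signal", {
  cfg <- small_cfg(
    band_gains_pos = c(delta = 0, theta = 0, alpha = 0, beta = 0, gamma = 0),
    band_gains_neg = c(delta = 0, theta = 0, alpha = 0, beta = 0, gamma = 0),
    pink_noise_sd = 0)
  rec <- generate_recording(cfg, "TMS+", 5)
  expect_equal(max(abs(rec$data)), 0)
  expect_equal(dim(rec$data), c(4, 200 * 30))
})

test_that("a theta gain difference shows up in the FFT-bin band-power oracle", {
  # class A theta gain 1, class B theta gain 0, everything else equal;
  # oracle powers averaged over >= 100 one-second epochs
  gains_a <- c(delta = 1, theta = 1, alpha = 1, beta = 1, gamma = 1)
  gains_b <- c(delta = 1, theta = 0, alpha = 1, beta = 1, gamma = 1)
  cfg <- synthetic_config(n_pos = 1, n_neg = 1, n_channels = 2, fs = 200,
                          duration_s = 120, band_gains_pos = gains_a,
                          band_gains_neg = gains_b, pink_noise_sd = 0.5,
                          subject_band_sd = 0, seed = 3)
  ra <- generate_recording(cfg, "TMS+", 21)
  rb <- generate_recording(cfg, "TMS-", 22)
  epoch_oracle <- function(rec) {
    n_ep <- 120
    mean(vapply(seq_len(n_ep), function(e) {
      seg <- rec$data[1, ((e - 1) * 200 + 1):(e * 200)]
      fft_band_power_oracle(seg, 200, 4, 7)
    }, numeric(1)))
  }
  pa <- epoch_oracle(ra); pb <- epoch_oracle(rb)
  expect_gt(pa, pb)
  # theta component has unit variance, so the oracle difference must be
  # near 1 uV^2 (averaged over 120 epochs)
  expect_gt(pa - pb, 0.6)
  expect_lt(pa - pb, 1.5)
})

test_that("identical class gains make the classes exchangeable (KS test)", {
  cfg <- synthetic_config(
    n_pos = 1, n_neg = 1, n_channels = 2, fs = 200, duration_s = 220,
    band_gains_pos = c(delta = 1, theta = 1, alpha = 1, beta = 1, gamma = 1),
    band_gains_neg = c(delta = 1, theta = 1, alpha = 1, beta = 1, gamma = 1),
    subject_band_sd = 0, seed = 9)
  ra <- generate_recording(cfg, "TMS+", 31)
  rb <- generate_recording(cfg, "TMS-", 32)
  powers <- function(rec) {
    x <- band_filter_fft(rec$data[1, ], 200, band_definition("theta", 4, 7))
    windowed_power(x, 200, 1)        # >= 200 epochs
  }
  pa <- powers(ra); pb <- powers(rb)
  expect_gte(length(pa), 200)
  expect_gt(stats::ks.test(pa, pb)$p.value, 0.01)
})

test_that("the between-class theta power gap grows with the gain ratio", {
  gap_for <- function(ratio) {
    cfg <- synthetic_config(
      n_pos = 1, n_neg = 1, n_channels = 2, fs = 200, duration_s = 60,
      band_gains_pos = c(delta = 1, theta = ratio, alpha = 1, beta = 1, gamma = 1),
      band_gains_neg = c(delta = 1, theta = 1, alpha = 1, beta = 1, gamma = 1),
      subject_band_sd = 0, pink_noise_sd = 0.5, seed = 17)
    ra <- generate_recording(cfg, "TMS+", 41)
    rb <- generate_recording(cfg, "TMS-", 42)
    oc <- function(r) fft_band_power_oracle(r$data[1, ], 200, 4, 7)
    oc(ra) - oc(rb)
  }
  gaps <- vapply(c(1, 1.5, 2, 3), gap_for, numeric(1))
  expect_true(all(diff(gaps) > 0))
})

test_that("cohorts have the requested composition and label-consistent MMSE", {
  cfg <- synthetic_config(n_pos = 8, n_neg = 6, n_channels = 2, fs = 200,
                          duration_s = 2, seed = 4)
  co <- generate_cohort(cfg)
  expect_equal(nrow(co$subjects), 14)
  expect_equal(sum(co$subjects$label == "TMS+"), 8)
  expect_equal(length(co$recordings), 14)
  # the labeling rule on the MMSE table reproduces the intended labels
  relabeled <- label_subjects(co$subjects[, c("subject_id", "mmse_pre", "mmse_post")])
  expect_equal(relabeled$label, co$subjects$label)
  # default tie fraction: some TMS+ subjects keep a constant score
  ties <- co$subjects$mmse_pre == co$subjects$mmse_post
  expect_true(all(co$subjects$label[ties] == "TMS+"))
  expect_equal(sum(ties), round(0.25 * 8))
  co2 <- generate_cohort(synthetic_config(n_pos = 1, n_neg = 1, n_channels = 2,
                                          fs = 200, duration_s = 2, seed = 5))
  expect_setequal(unique(co2$subjects$label), c("TMS-", "TMS+"))
})

test_that("constant-score rule: delta 0 for all TMS+ yields pre == post and TMS+", {
  rule <- default_mmse_rule(tie_fraction = 1)
  cfg <- synthetic_config(n_pos = 3, n_neg = 2, n_channels = 2, fs = 200,
                          duration_s = 2, mmse_rule = rule, seed = 6)
  co <- generate_cohort(cfg)
  pos <- co$subjects$label == "TMS+"
  expect_true(all(co$subjects$mmse_pre[pos] == co$subjects$mmse_post[pos]))
  relabeled <- label_subjects(co$subjects)
  expect_true(all(relabeled$label[pos] == "TMS+"))
})

test_that("invalid configurations are rejected", {
  expect_error(synthetic_config(band_gains_pos = c(sigma = 1)), "invalid band")
  expect_error(synthetic_config(fs = 90), "twice the highest band edge")
  expect_error(synthetic_config(band_gains_pos = c(theta = -1)), ">= 0")
  expect_error(generate_recording(small_cfg(), "maybe", 1), "TMS")
})
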