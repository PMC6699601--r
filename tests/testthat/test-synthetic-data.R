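test_that("configuration and epoch validation reject bad inputs", {
  expect_error(synth_config(duration_s = 60), ">= 120")
  expect_error(gt_epoch(1, 100, 100, level = 3), "non-empty")
  expect_error(gt_epoch(1, 10, 20, level = 2), "-1, 1, 3")
  expect_error(gt_epoch(1, 10, 20, occupancy = 0.2), "occupancy")
  expect_error(synth_config(duration_s = 200,
                            epochs = list(gt_epoch(1, 150, 250))),
               "outside")
  expect_error(synth_config(n_members = 2, duration_s = 200,
                            epochs = list(gt_epoch(3, 10, 20))),
               "team size")
})

test_that("no-epoch background discretizes into balanced levels", {
  cfg <- synth_config(n_members = 1, sensors = "F3", bins = 1L,
                      duration_s = 10000L, seed = 7)
  g <- generate_power_tensor(cfg)
  lv <- discretize_power(g$tensor)
  freqs <- as.numeric(table(factor(lv$level, levels = c(-1, 1, 3)))) / 10000
  expect_true(all(abs(freqs - 1 / 3) <= 0.02))
})

test_that("generation is byte-identical under a fixed seed", {
  cfg <- synth_config(n_members = 2, sensors = c("F3", "P3"), bins = 1:3,
                      duration_s = 150,
                      epochs = list(gt_epoch(1, 50, 90, level = -1,
                                             occupancy = 0.8)),
                      seed = 123)
  g1 <- generate_power_tensor(cfg)
  g2 <- generate_power_tensor(cfg)
  expect_identical(g1$tensor, g2$tensor)
  expect_identical(g1$epochs, cfg$epochs)
})

test_that("missing spans become NA markers, never zeros", {
  cfg <- synth_config(n_members = 2, sensors = "F3", bins = 1L,
                      duration_s = 200,
                      missing_spans = list(list(member = 2, start_s = 100,
                                                end_s = 150)),
                      seed = 3)
  g <- generate_power_tensor(cfg)
  t2 <- g$tensor[g$tensor$member == 2, ]
  expect_true(all(is.na(t2$power[t2$second %in% 100:149])))
  expect_false(anyNA(t2$power[!t2$second %in% 100:149]))
  expect_false(anyNA(g$tensor$power[g$tensor$member == 1]))
  expect_false(any(g$tensor$power == 0, na.rm = TRUE))
})

test_that("forced epochs occupy their tertile and drive the member NI peak", {
  cfg <- synth_config(n_members = 1, sensors = "F3", bins = 1:2,
                      duration_s = 800,
                      epochs = list(gt_epoch(1, 300, 400, level = 3,
                                             occupancy = 1)),
                      seed = 21)
  g <- generate_power_tensor(cfg)
  lv <- discretize_power(g$tensor)
  in_epoch <- lv$level[lv$second >= 300 & lv$second < 400]
  expect_equal(mean(in_epoch == 3L), 1)
  tr <- member_ni(lv, 1)
  peak <- tr$second[which.max(tr$ni)]
  expect_gte(peak, 300)
  expect_lt(peak, 460)   # 60-s window trails the epoch
})

test_that("member NI peak height grows with epoch occupancy", {
  heights <- vapply(c(0.5, 0.75, 1.0), function(occ) {
    peaks <- vapply(1:8, function(seed) {
      cfg <- synth_config(n_members = 1, sensors = "F3", bins = 1L,
                          duration_s = 400,
                          epochs = list(gt_epoch(1, 200, 300, level = 3,
                                                 occupancy = occ)),
                          seed = seed)
      lv <- discretize_power(generate_power_tensor(cfg)$tensor)
      max(member_ni(lv, 1)$ni, na.rm = TRUE)
    }, 0)
    mean(peaks)
  }, 0)
  expect_true(all(diff(heights) > 0))
})

test_that("AR(1) backgrounds still discretize near-uniformly", {
  cfg <- synth_config(n_members = 1, sensors = "F3", bins = 1L,
                      duration_s = 5000, noise_model = "ar1-lognormal",
                      seed = 11)
  lv <- discretize_power(generate_power_tensor(cfg)$tensor)
  freqs <- as.numeric(table(factor(lv$level, levels = c(-1, 1, 3)))) / 5000
  expect_true(all(abs(freqs - 1 / 3) <= 0.03))
})

test_that("coupling preconditions are enforced", {
  cfg <- synth_config(n_members = 2, sensors = "F3", bins = 1L,
                      duration_s = 200, seed = 1)
  g <- generate_power_tensor(cfg)
  expect_error(inject_coupling(g$tensor, 1, 1, 2, c(0, 100)), "differ")
  expect_error(inject_coupling(g$tensor, 1, 2, 10, c(100, 105)),
               "smaller than the interval")
  expect_error(inject_coupling(g$tensor, 1, 3, 2, c(0, 100)), "not present")
})

test_that("zero-lag coupling replicates leader levels exactly", {
  cfg <- synth_config(n_members = 2, sensors = c("F3", "P3"), bins = 1L,
                      duration_s = 300, seed = 5)
  g <- generate_power_tensor(cfg)
  coupled <- inject_coupling(g$tensor, 1, 2, 0, c(50, 250))
  thr <- attr(coupled, "coupling_thresholds")
  for (sn in c("F3", "P3")) {
    lead <- g$tensor[g$tensor$member == 1 & g$tensor$sensor == sn, ]
    lead_lev <- discretize_stream(lead$power, tertile_thresholds(lead$power))
    fol <- coupled[coupled$member == 2 & coupled$sensor == sn, ]
    th <- thr[thr$sensor == sn, ]
    frozen <- list(low_cut = th$low_cut, high_cut = th$high_cut,
                   degenerate = th$degenerate)
    fol_lev <- discretize_stream(fol$power, frozen)
    inside <- fol$second >= 50 & fol$second < 250
    expect_equal(fol_lev[inside], lead_lev[inside])
    expect_equal(fol$power[!inside],
                 g$tensor$power[g$tensor$member == 2 &
                                  g$tensor$sensor == sn][!inside])
  }
})

test_that("lagged coupling is recovered by member-NI cross-correlation", {
  cfg <- synth_config(n_members = 2, sensors = c("F3", "P3"), bins = 1:2,
                      duration_s = 600,
                      epochs = list(gt_epoch(1, 200, 300, level = 3)),
                      coupling = list(leader = 1, follower = 2, lag_s = 10,
                                      start_s = 100, end_s = 500),
                      seed = 77)
  g <- generate_power_tensor(cfg)
  lv <- discretize_power(g$tensor)
  cc <- cross_correlate(member_ni(lv, 1), member_ni(lv, 2), max_lag_s = 30)
  expect_lte(abs(cc$lag_s - 10), 2)
  expect_gt(cc$r, 0.5)
})

test_that("raw EEG synthesis is seeded and respects amplitude zero", {
  cfg <- synth_config(n_members = 1, sensors = c("F3", "P3"), bins = c(10L, 20L),
                      duration_s = 120, seed = 2)
  expect_error(generate_raw_eeg(cfg, fs = 64), ">= 128")
  cfg40 <- synth_config(n_members = 1, sensors = "F3", bins = c(10L, 70L),
                        duration_s = 120, seed = 2)
  expect_error(generate_raw_eeg(cfg40, fs = 128), "twice")
  r1 <- generate_raw_eeg(cfg, fs = 128)
  r2 <- generate_raw_eeg(cfg, fs = 128)
  expect_identical(r1[[1]]$samples, r2[[1]]$samples)
  r0 <- generate_raw_eeg(cfg, fs = 128, amplitude = 0, noise_sd = 0)
  expect_true(all(r0[[1]]$samples == 0))
})

test_that("a single pure component concentrates its spectral power", {
  cfg <- synth_config(n_members = 1, sensors = "F3", bins = 10L,
                      duration_s = 120, seed = 3)
  rec <- generate_raw_eeg(cfg, fs = 128, noise_sd = 0)[[1]]
  pt <- band_power_per_second(rec, bins = 1:40, taper = "none")
  frac <- tapply(pt$power, pt$second, function(p) p[10] / sum(p))
  expect_true(all(frac >= 0.9))
})
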