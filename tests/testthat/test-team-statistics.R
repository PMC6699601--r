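test_that("a constantly organized member attains NI = log2(3)", {
  lv <- make_level_tensor(list(rep(3L, 150)))
  tr <- member_ni(lv, 1)
  expect_equal(tr$ni[60:150], rep(log2(3), 91))
})

test_that("an unorganized member sits near the plug-in bias floor", {
  set.seed(19)
  lv <- make_level_tensor(list(random_levels(600)))
  tr <- member_ni(lv, 1)
  expect_lt(mean(tr$ni, na.rm = TRUE), 0.2)  # floor for S = 3, 60-s windows
})

test_that("cross-correlation identifies identity and constructed shifts", {
  set.seed(23)
  a <- data.frame(second = 0:499, ni = runif(500))
  self <- cross_correlate(a, a, max_lag_s = 20)
  expect_equal(self$lag_s, 0L)
  expect_equal(self$r, 1)
  b <- data.frame(second = 0:499, ni = c(rep(NA, 10), a$ni[1:490]))
  cc <- cross_correlate(a, b, max_lag_s = 20)
  expect_equal(cc$lag_s, 10L)
  expect_equal(cc$r, 1)
})

test_that("cross-correlation is antisymmetric in its arguments", {
  set.seed(29)
  a <- data.frame(second = 0:399, ni = runif(400))
  b <- data.frame(second = 0:399,
                  ni = 0.7 * c(rep(NA, 7), a$ni[1:393]) + 0.3 * runif(400))
  ab <- cross_correlate(a, b, max_lag_s = 15)
  ba <- cross_correlate(b, a, max_lag_s = 15)
  expect_equal(ab$lag_s, -ba$lag_s)
  expect_equal(ab$r, ba$r)
})

test_that("cross-correlation needs enough valid overlap", {
  a <- data.frame(second = 0:99, ni = runif(100))
  expect_error(cross_correlate(a, a, max_lag_s = 60), "overlapping")
})

test_that("band schemes agree where their definitions coincide", {
  A <- band_scheme("A")
  B <- band_scheme("B")
  for (bn in c("delta_theta", "alpha", "mu", "low_beta")) {
    expect_identical(A[[bn]], B[[bn]])
  }
  expect_identical(A$high_beta_gamma, 23:40)
  expect_identical(B$gamma, 33:40)
  expect_error(band_scheme(list(a = c(0, 5))), "1-40")
  expect_error(band_scheme(list(a = c(3, 7), b = c(7, 10))), "overlap")
})

test_that("band aggregation averages the right bins", {
  grid <- expand.grid(freq_hz = 1:40, second = 0:9)
  grid$ni <- ifelse(grid$freq_hz %in% 3:7, 1, 0)
  agg <- band_aggregate(grid, "A")
  expect_true(all(agg$ni[agg$band == "delta_theta"] == 1))
  expect_true(all(agg$ni[agg$band != "delta_theta"] == 0))
  set.seed(37)
  grid$ni <- runif(nrow(grid))
  agg <- band_aggregate(grid, "B")
  for (bn in names(band_scheme("B"))) {
    keep <- grid[grid$freq_hz %in% band_scheme("B")[[bn]], ]
    oracle <- tapply(keep$ni, keep$second, mean)
    expect_equal(agg$ni[agg$band == bn], as.numeric(oracle),
                 tolerance = 1e-12)
  }
  expect_error(band_aggregate(grid[grid$freq_hz < 30, ], "B"), "gamma")
})

test_that("banded means reduce to the overall mean for a partition", {
  set.seed(41)
  grid <- expand.grid(freq_hz = 1:40, second = 0:4)
  grid$ni <- runif(nrow(grid))
  parts <- band_scheme(list(lo = c(1, 20), hi = c(21, 40)))
  agg <- band_aggregate(grid, parts)
  overall <- average_ni(grid)
  recombined <- (agg$ni[agg$band == "lo"] + agg$ni[agg$band == "hi"]) / 2
  expect_equal(recombined, overall$ni, tolerance = 1e-12)
})

test_that("region contrast matches the rank-sum oracle on a shifted fixture", {
  set.seed(43)
  ni_ant <- rnorm(200, mean = 1.5)
  ni_post <- ni_ant - 0.6   # constant shift, same sensor count
  ni_set <- rbind(data.frame(sensor = "F3", second = 0:199, ni = ni_ant),
                  data.frame(sensor = "P3", second = 0:199, ni = ni_post))
  res <- region_contrast(ni_set, region_map("simulation"))
  expect_lt(res$p, 0.01)
  expect_gt(res$Z, 0)
  ref <- stats::wilcox.test(ni_ant, ni_post, correct = FALSE)
  expect_equal(res$p, ref$p.value, tolerance = 1e-10)
  expect_gt(res$fold_ratio, 1)
})

test_that("region contrast is null for identical samples", {
  set.seed(47)
  v <- rnorm(100)
  ni_set <- rbind(data.frame(sensor = "F3", second = 0:99, ni = v),
                  data.frame(sensor = "P3", second = 0:99, ni = v))
  res <- region_contrast(ni_set, region_map("simulation"))
  expect_equal(res$fold_ratio, 1)
  expect_gt(res$p, 0.9)
  expect_equal(abs(res$Z), 0, tolerance = 1e-12)
})

test_that("region contrast Z is invariant under common monotone transforms", {
  set.seed(53)
  ni_set <- rbind(data.frame(sensor = "F3", second = 0:149,
                             ni = rlnorm(150, 0.4)),
                  data.frame(sensor = "P3", second = 0:149, ni = rlnorm(150)))
  z1 <- region_contrast(ni_set, region_map("simulation"))$Z
  ni_set$ni <- log(ni_set$ni + 1)
  z2 <- region_contrast(ni_set, region_map("simulation"))$Z
  expect_equal(z1, z2, tolerance = 1e-12)
})

test_that("region contrast names absent sensors in its error", {
  ni_set <- data.frame(sensor = "F3", second = 0:9, ni = runif(10))
  expect_error(region_contrast(ni_set, region_map("simulation")),
               "P3, Pz, P4")
  expect_error(region_contrast(ni_set, region_map("simulation"),
                               regions = c("anterior", "occipital")),
               "not in the region map")
})

test_that("small samples without ties use the exact rank-sum p-value", {
  x <- c(1.1, 2.2, 3.3, 4.4, 5.5)
  y <- c(6.6, 7.7, 8.8, 9.9, 10.1)
  ni_set <- rbind(data.frame(sensor = "F3", second = 0:4, ni = x),
                  data.frame(sensor = "P3", second = 0:4, ni = y))
  res <- region_contrast(ni_set, region_map("simulation"))
  ref <- stats::wilcox.test(x, y, exact = TRUE)
  expect_equal(res$p, ref$p.value)
})

test_that("event bracketing pads, truncates, and flags the core", {
  tr <- data.frame(second = 0:299, ni = runif(300))
  ev <- event_segment("intubation", 100, 140)
  br <- bracket_event(tr, ev, pad_s = 60)
  expect_equal(range(br$second), c(40, 199))
  expect_equal(br$second[br$core], 100:139)
  early <- bracket_event(tr, event_segment("start", 10, 30))
  expect_equal(min(early$second), 0)
  expect_error(bracket_event(tr, event_segment("late", 400, 420)),
               "outside the recording")
})

test_that("level composition reports distributions and contrasts events", {
  lv <- make_level_tensor(list(rep(-1L, 100)))
  ev <- event_segment("all_low", 0, 100)
  res <- level_composition(lv, ev)
  expect_equal(res$composition$p_low, 1)
  expect_equal(res$composition$mean_level, -1)
  expect_null(res$test)

  # four events over identical data: no contrast
  set.seed(59)
  lv2 <- make_level_tensor(list(random_levels(60)))
  evs <- do.call(rbind, lapply(1:4, function(i) {
    event_segment(paste0("e", i), 0, 60)
  }))
  res2 <- level_composition(lv2, evs)
  expect_equal(res2$test$H, 0, tolerance = 1e-10)
  expect_equal(res2$test$p, 1, tolerance = 1e-10)

  # three forced-level events separate decisively
  lv3 <- make_level_tensor(list(c(rep(-1L, 60), rep(1L, 60), rep(3L, 60))))
  evs3 <- rbind(event_segment("low", 0, 60), event_segment("avg", 60, 120),
                event_segment("high", 120, 180))
  res3 <- level_composition(lv3, evs3)
  expect_lt(res3$test$p, 0.01)
  expect_equal(res3$test$df, 2)
  expect_equal(res3$composition$mean_level, c(-1, 1, 3))
})

test_that("Kruskal-Wallis output matches the hand-computed H", {
  set.seed(61)
  lv <- make_level_tensor(list(c(random_levels(50),
                                 rep(3L, 25), random_levels(25))))
  evs <- rbind(event_segment("a", 0, 50), event_segment("b", 50, 100))
  res <- level_composition(lv, evs)
  values <- lv$level[1:100]
  groups <- rep(c("a", "b"), each = 50)
  expect_equal(res$test$H, kruskal_h_oracle(values, groups),
               tolerance = 1e-10)
})

test_that("all-missing events are excluded with a warning", {
  lv <- make_level_tensor(list(random_levels(100)))
  lv$level[lv$second < 50] <- NA
  evs <- rbind(event_segment("gone", 0, 50), event_segment("there", 50, 100))
  expect_warning(res <- level_composition(lv, evs), "gone")
  expect_equal(res$composition$event, "there")
})

test_that("time-frequency maps are dense, consistent matrices", {
  set.seed(67)
  ni_set <- expand.grid(sensor = c("F7", "O2"), freq_hz = 1:5, second = 0:9,
                        stringsAsFactors = FALSE)
  ni_set$ni <- runif(nrow(ni_set))
  m <- time_frequency_map(ni_set, "F7")
  expect_equal(dim(m), c(10L, 5L))
  sub <- ni_set[ni_set$sensor == "F7", ]
  expect_equal(m[cbind(as.character(sub$second), as.character(sub$freq_hz))],
               sub$ni)
  # row means equal singleton-band aggregation per second
  singletons <- band_scheme(stats::setNames(lapply(1:5, function(b) c(b, b)),
                                            paste0("b", 1:5)))
  agg <- band_aggregate(sub, singletons)
  for (b in 1:5) {
    expect_equal(as.numeric(m[, as.character(b)]),
                 agg$ni[agg$band == paste0("b", b)])
  }
  expect_error(time_frequency_map(ni_set, "Cz"), "not present")
})
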