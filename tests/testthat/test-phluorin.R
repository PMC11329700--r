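test_that("rolling-ball subtraction removes offsets and keeps narrow bumps", {
  flat <- matrix(7, 40, 40)
  expect_equal(subtract_background(flat, 10), matrix(0, 40, 40))

  bump <- blob(60, 60, c(30, 30), sigma = 2, amplitude = 50)
  img <- bump + 20
  out <- subtract_background(img, 15)
  expect_true(all(out >= 0))
  expect_equal(max(out), 50, tolerance = 0.01)
  # far from the bump the offset is fully removed
  expect_lt(max(out[1:10, 1:10]), 1e-6)

  expect_error(subtract_background(flat, 40), "too large")
})

test_that("ROI disc traces match brute-force rasterization and track their blob", {
  nr <- 50; nc <- 50; px <- 100  # 100 nm/px
  radius_px <- sqrt(2e6 / pi) / px
  stack <- array(3, dim = c(nr, nc, 4))
  tr <- extract_roi_traces(stack, rbind(c(25, 25)), roi_area = 2,
                           pixel_size = px, stimulus_frame = 2)[[1]]
  expect_equal(tr$values, rep(3, 4))

  # pixel count of the rasterized disc equals direct enumeration
  n_in <- 0L
  for (r in 1:nr) for (c in 1:nc) {
    if ((r - 25)^2 + (c - 25)^2 <= radius_px^2) n_in <- n_in + 1L
  }
  one <- array(0, dim = c(nr, nc, 2))
  one[25, 25, 1] <- 1
  tr1 <- extract_roi_traces(one, rbind(c(25, 25)), 2, px,
                            stimulus_frame = 2)[[1]]
  expect_equal(tr1$values[1], 1 / n_in)

  # two disjoint ROIs on a two-blob movie see only their own blob
  stack2 <- array(0, dim = c(nr, nc, 2))
  stack2[, , 1] <- blob(nr, nc, c(15, 15), 2, 10)
  stack2[, , 2] <- blob(nr, nc, c(35, 35), 2, 10)
  trs <- extract_roi_traces(stack2, rbind(c(15, 15), c(35, 35)), 2, px,
                            stimulus_frame = 2)
  expect_gt(trs[[1]]$values[1], 100 * trs[[1]]$values[2])
  expect_gt(trs[[2]]$values[2], 100 * trs[[2]]$values[1])

  expect_error(extract_roi_traces(stack, rbind(c(2, 2)), 2, px,
                                  stimulus_frame = 2), "ROI 1")
})

test_that("bleach rate estimation recovers closed-form and degenerate inputs", {
  t <- (0:119) / 2
  tr <- fluor_trace(100 * exp(-0.01 * t), 2, 120)
  expect_equal(estimate_bleach_rate(tr)$K, 0.01, tolerance = 1e-6)
  expect_equal(estimate_bleach_rate(fluor_trace(rep(5, 60), 2, 60))$K, 0,
               tolerance = 1e-9)
  expect_error(estimate_bleach_rate(fluor_trace(c(1, -1, 1), 2, 3)))

  # multiplicative noise, many controls: mean K within 5% of truth
  set.seed(31)
  ks <- replicate(20, {
    y <- 100 * exp(-0.008 * t) * (1 + rnorm(120, 0, 0.01))
    estimate_bleach_rate(fluor_trace(y, 2, 120))$K
  })
  expect_equal(mean(ks), 0.008, tolerance = 0.05)
})

test_that("bleach correction is an exact algebraic inverse", {
  t <- (0:99) / 2
  tr <- fluor_trace(80 * exp(-0.02 * t), 2, 50)
  corrected <- bleach_correct(tr, 0.02)
  expect_equal(corrected$values, rep(80, 100))
  # K = 0 is the identity; correct-then-uncorrect returns the input
  expect_identical(bleach_correct(tr, 0)$values, tr$values)
  back <- bleach_correct(corrected, -0.02)
  expect_equal(back$values, tr$values)
})

test_that("normalization anchors pre-stimulus to 0, peak to 1, affine-invariantly", {
  sim <- gen_phluorin_traces(sim_config(6), 1, noise_sd = 0, bleach_K = 0)
  tr <- sim$traces[[1]]
  n1 <- normalize_trace(tr)
  expect_equal(n1$values[tr$stimulus_frame - 1], 0)
  expect_equal(max(n1$values), 1)
  expect_true(all(n1$values[attr(n1, "peak_frame"):length(n1$values)] >= 0 &
                    n1$values[attr(n1, "peak_frame"):length(n1$values)] <= 1))

  tr2 <- tr; tr2$values <- 3.7 * tr$values + 11
  expect_equal(normalize_trace(tr2)$values, n1$values)

  flat <- fluor_trace(rep(1, 40), 2, 11)
  expect_error(normalize_trace(flat), "dynamic range")
})

test_that("decay fits recover closed-form tau and plateau", {
  t <- (0:99) / 2
  tr <- fluor_trace(c(rep(0, 10), exp(-t[1:90] / 15)), 2, 11)
  attr(tr, "peak_frame") <- 11L
  fd <- fit_decay(tr)
  expect_equal(fd$tau, 15, tolerance = 1e-3)
  expect_equal(fd$plateau, 0, tolerance = 1e-3)

  tr2 <- fluor_trace(c(rep(0, 10), 0.7 * exp(-t[1:90] / 20) + 0.3), 2, 11)
  attr(tr2, "peak_frame") <- 11L
  fd2 <- fit_decay(tr2)
  expect_equal(fd2$tau, 20, tolerance = 1e-3)
  expect_equal(fd2$plateau, 0.30, tolerance = 1e-3)

  # constant normalized trace: 100% remaining at 40 s
  tr3 <- fluor_trace(c(rep(0, 10), rep(1, 90)), 2, 11)
  attr(tr3, "peak_frame") <- 11L
  fd3 <- fit_decay(tr3)
  expect_equal(fd3$percent_remaining, 100)
})

test_that("cohort pipeline recovers tau and plateau under study conditions", {
  sim <- gen_phluorin_traces(sim_config(13), n_traces = 50, tau = 15,
                             plateau = 0.3, bleach_K = 0.005,
                             noise_sd = 0.05)
  res <- fit_trace_cohort(sim$traces, bleach_K = 0.005)
  expect_gte(nrow(res$fits), 45)
  expect_lt(abs(median(res$fits$tau) - 15) / 15, 0.05)
  expect_lt(abs(median(res$fits$plateau) - 0.3), 0.05)
})

test_that("bleach correction of a matching no-stim control flattens its trend", {
  sim <- gen_phluorin_traces(sim_config(14), 10, tau = 15, plateau = 0,
                             bleach_K = 0.006, noise_sd = 0.01,
                             amplitude = 0)
  slopes <- vapply(sim$traces, function(tr) {
    cor_tr <- bleach_correct(tr, 0.006)
    t <- (seq_along(cor_tr$values) - 1) / cor_tr$frame_rate
    unname(coef(lm(cor_tr$values ~ t))[2])
  }, numeric(1))
  # mean slope statistically indistinguishable from zero
  expect_lt(abs(mean(slopes)) / (sd(slopes) / sqrt(length(slopes))),
            qt(0.995, length(slopes) - 1))
})
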