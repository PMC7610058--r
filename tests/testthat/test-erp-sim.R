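test_that("montage layout is deterministic, unique and on the disc", {
  m1 <- make_montage(65, seed = 0)
  m2 <- make_montage(65, seed = 0)
  expect_identical(m1$positions, m2$positions)
  expect_equal(length(unique(m1$labels)), 65)
  expect_equal(nrow(unique(m1$positions)), 65)
  expect_true(all(sqrt(rowSums(m1$positions^2)) <= 1))
  expect_equal(length(make_montage(2)$labels), 2)
  expect_error(make_montage(1), "n_channels")
})

test_that("component topographies are average-referenced with sign symmetry", {
  m <- make_montage(65)
  pos_spec <- component_spec("X", +1, 100, 150, 200, 5,
                             rbind(c(0.3, -0.4)), 0.3)
  neg_spec <- component_spec("X", -1, 100, 150, 200, 5,
                             rbind(c(0.3, -0.4)), 0.3)
  tp <- component_topography(m, pos_spec)
  tn <- component_topography(m, neg_spec)
  expect_equal(mean(tp), 0, tolerance = 1e-12)
  expect_equal(max(abs(tp)), 1)
  expect_equal(tn, -tp)
  # dipolar two-lobe map differs from the single-lobe map
  dip <- component_spec("Y", +1, 100, 150, 200, 5,
                        rbind(c(0.3, -0.4, 1), c(-0.3, 0.4, -1)), 0.3)
  td <- component_topography(m, dip)
  expect_lt(spatial_correlation(td, tp), 1)
  expect_error(component_spec("Z", +1, 100, 150, 200, 5,
                              rbind(c(1.5, 0)), 0.3), "off the unit-disc")
})

test_that("waveform envelope is supported exactly on [onset, offset] and peaks right", {
  sp <- component_spec("N2", -1, 175, 233, 292, 5, rbind(c(0.5, -0.6)), 0.3)
  w <- component_waveform(sp, 429, -100, 600)
  tms <- epoch_times(429, -100, 600)
  expect_true(all(w[tms < 175 | tms > 292] == 0))
  expect_true(all(w[tms >= 176 & tms <= 291] > 0))
  expect_equal(max(w), w[which.min(abs(tms - 233))])
  # peak value reaches the amplitude on a grid point placed at the peak
  sp2 <- component_spec("P", +1, 0, 100, 200, 3, rbind(c(0, 0)), 0.3)
  w2 <- sp2$amplitude * erpconsensus:::envelope_at(sp2, seq(0, 200, by = 0.5))
  expect_equal(max(w2), 3)
  expect_error(component_waveform(sp, 429, -100, 250), "outside epoch")
})

test_that("plain raised-cosine envelope integrates to h*w/2", {
  sp <- component_spec("P", +1, 100, 200, 300, 2, rbind(c(0, 0)), 0.3)
  tt <- seq(100, 300, by = 0.01)
  w <- 2 * erpconsensus:::envelope_at(sp, tt)
  integral <- sum(w) * 0.01
  expect_equal(integral, 2 * 200 / 2, tolerance = 1e-3)
})

test_that("signed-area window matches the exhaustive-interval oracle", {
  tms <- epoch_times(429, -100, 600)
  set.seed(42)
  for (rep in 1:5) {
    sp <- component_spec("X", +1, 50 + rep * 10, 180, 320, 4,
                         rbind(c(0, 0)), 0.3,
                         rise_exp = runif(1, 0.7, 1.5),
                         fall_exp = runif(1, 0.7, 1.5))
    w <- component_waveform(sp, 429, -100, 600)
    frac <- runif(1, 0.5, 0.95)
    tw <- signed_area_window(w, +1, c(sp$onset_ms, sp$offset_ms), frac,
                             429, -100)
    idx <- which(tms >= sp$onset_ms & tms <= sp$offset_ms)
    oracle <- signed_area_oracle(w, +1, idx, frac)
    expect_equal(unname(attr(tw, "samples")), oracle)
  }
})

test_that("signed-area window handles rectangles, symmetry and wrong polarity", {
  tms <- epoch_times(429, -100, 600)
  rect <- as.numeric(tms >= 100 & tms <= 200)
  tw <- signed_area_window(rect, +1, c(50, 300), 1, 429, -100)
  s <- attr(tw, "samples")
  expect_equal(range(which(rect > 0)), unname(s))
  # symmetric raised cosine: window symmetric about the peak
  sp <- component_spec("P", +1, 100, 200, 300, 1, rbind(c(0, 0)), 0.3)
  w <- component_waveform(sp, 429, -100, 600)
  tw2 <- signed_area_window(w, +1, c(100, 300), 0.8, 429, -100)
  expect_equal(tw2$start_ms + tw2$end_ms, 2 * 200, tolerance = 2.5)
  expect_error(signed_area_window(-w, +1, c(100, 300), 0.8, 429, -100),
               class = "erp_no_window")
})

test_that("awgn calibration follows the SNR definition", {
  x <- matrix(rnorm(300 * 64), 300, 64)
  x <- x / sqrt(mean(x^2))              # unit power
  expect_identical(add_awgn(x, Inf), x)
  set.seed(1)
  noisy <- add_awgn(x, 20)
  expect_equal(mean((noisy - x)^2), 0.01, tolerance = 0.05 * 0.01 / 0.01)
  set.seed(2)
  noisy0 <- add_awgn(x, 0)
  expect_equal(mean((noisy0 - x)^2), 1, tolerance = 0.05)
})

test_that("simulated study has the right geometry and is reproducible", {
  spec <- study_spec(n_subjects = 2, seed = 9)
  s1 <- simulate_study(spec)
  s2 <- simulate_study(spec)
  expect_equal(dim(s1$subjects[[1]]$concat), c(600, 65))
  expect_identical(s1$subjects[[1]]$concat, s2$subjects[[1]]$concat)
  expect_identical(s1$subjects[[2]]$jitter, s2$subjects[[2]]$jitter)
  # per-subject empirical SNR within 0.5 dB of the target (clean study with
  # identical jitter draws, noise turned off)
  clean <- simulate_study(study_spec(n_subjects = 2, snr_db = Inf, seed = 9))
  for (i in 1:2) {
    noise <- s1$subjects[[i]]$concat - clean$subjects[[i]]$concat
    snr <- 10 * log10(mean(clean$subjects[[i]]$concat^2) / mean(noise^2))
    expect_lt(abs(snr - 20), 0.5)
  }
  # noiseless, jitter-free subjects are identical to each other
  flat <- simulate_study(study_spec(n_subjects = 2, snr_db = Inf,
                                    jitter_max_samples = 0, seed = 9))
  expect_identical(flat$subjects[[1]]$concat, flat$subjects[[2]]$concat)
})

test_that("ground-truth windows are invariant to noise and jitter settings", {
  gt1 <- ground_truth_windows(study_spec(seed = 1, snr_db = 20,
                                         jitter_max_samples = 5))
  gt2 <- ground_truth_windows(study_spec(seed = 77, snr_db = Inf,
                                         jitter_max_samples = 0))
  expect_equal(gt1, gt2)
  expect_named(gt1$Cond1, c("N2", "P3"))
  expect_equal(gt1$Cond1$N2$start_ms, gt1$Cond2$N2$start_ms)
})

test_that("decorrelated topography sets have the target correlation structure", {
  m <- make_montage(65)
  comps <- default_components()
  topo <- vapply(comps, function(cc) component_topography(m, cc),
                 numeric(65))
  dec <- decorrelate_topographies(topo, target_corr = -0.1)
  C <- cor(dec)
  expect_equal(unname(C[upper.tri(C)]), rep(-0.1, sum(upper.tri(C))),
               tolerance = 1e-6)
  expect_equal(unname(colMeans(dec)), rep(0, ncol(dec)), tolerance = 1e-9)
  expect_equal(unname(apply(abs(dec), 2, max)), rep(1, ncol(dec)))
})
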