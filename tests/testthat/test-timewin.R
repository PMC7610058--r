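test_that("contiguous runs are maximal and ordered", {
  r <- contiguous_runs(c(1, 1, 2, 2, 1), 1)
  expect_equal(unname(r), rbind(c(1L, 2L), c(5L, 5L)))
  expect_equal(nrow(contiguous_runs(c(1, 1), 3)), 0)
  r2 <- contiguous_runs(rep(4, 6), 4)
  expect_equal(unname(r2), cbind(1L, 6L))
})

test_that("inner similarity follows the Fisher-z closed form", {
  u <- rnorm(20)
  x <- rbind(u, u * 2, u * 0.5 + 7)   # identical up to scale and offset
  expect_equal(inner_similarity(x, 1:3), 1, tolerance = 1e-6)
  # single pair round-trips through the z transform
  set.seed(1)
  a <- rnorm(50); b <- 0.8 * a + rnorm(50) * sd(a) * sqrt(1 - 0.64)
  r_ab <- cor(a, b)
  expect_equal(inner_similarity(rbind(a, b), 1:2), r_ab)
  # three maps: tanh of the mean z
  x3 <- matrix(rnorm(3 * 30), 3, 30)
  C <- cor(t(x3))
  expected <- tanh(mean(atanh(C[upper.tri(C)])))
  expect_equal(inner_similarity(x3, 1:3), expected)
  expect_warning(v <- inner_similarity(x3, 2), "single")
  expect_equal(v, 1)
  expect_error(inner_similarity(rbind(a, rep(1, 50)), 1:2), "zero-variance")
})

test_that("inner similarity is invariant to scaling and channel offsets", {
  x <- matrix(rnorm(5 * 16), 5, 16)
  base <- inner_similarity(x, 1:5)
  scaled <- x * runif(5, 0.5, 3) + 11
  expect_equal(inner_similarity(scaled, 1:5), base)
})

test_that("noise strictly degrades expected inner similarity", {
  u <- rnorm(32)
  set.seed(7)
  vals <- sapply(c(0.05, 0.5, 2), function(s) {
    mean(replicate(30, {
      x <- matrix(rep(u, 10), 10, byrow = TRUE) +
        matrix(rnorm(320, 0, s), 10)
      inner_similarity(x, 1:10)
    }))
  })
  expect_true(all(diff(vals) < 0))
})

test_that("candidate maps report runs, overlap and exclusions correctly", {
  # 60 samples at 1000 Hz starting at 0 ms; interval 20-39 ms
  lab <- rep(c(1, 2, 3), each = 20)
  u <- rnorm(8)
  x <- outer(rep(1, 60), u) + matrix(rnorm(60 * 8, 0, 0.01), 60)
  cand <- candidate_maps(lab, x, c(20, 39), 1000, 0)
  expect_equal(sort(cand$cluster), 2)          # clusters 1 and 3 are outside
  expect_equal(cand$overlap, 1)
  expect_equal(cand$n_samples, 20)
  # run longer than the interval: overlap = interval coverage
  lab2 <- c(rep(1, 10), rep(2, 40), rep(1, 10))
  cand2 <- candidate_maps(lab2, x, c(20, 39), 1000, 0)
  row2 <- cand2[cand2$cluster == 2, ]
  expect_equal(row2$overlap, 1)
  expect_equal(row2$n_samples, 40)
  expect_error(candidate_maps(lab, x, c(39, 20), 1000, 0), "empty interval")
})

test_that("detect_window filters, scores and errors as specified", {
  set.seed(3)
  u <- rnorm(12); v <- rnorm(12)
  x <- rbind(matrix(rep(u, 30), 30, byrow = TRUE),
             matrix(rep(v, 30), 30, byrow = TRUE)) +
    matrix(rnorm(60 * 12, 0, 0.02), 60)
  lab <- rep(1:2, each = 30)
  w <- detect_window(lab, x, c(10, 49), innsim_min = 0.9, min_dur_ms = 10,
                     sfreq_hz = 1000, epoch_start_ms = 0)
  expect_s3_class(w, "erp_window")
  expect_equal(w$cluster, 1)                  # higher overlap with interval
  expect_equal(w$start_ms, 0)                 # run not clipped to interval
  expect_equal(w$end_ms, 29)
  # impossible threshold -> informative no-window error
  expect_error(
    detect_window(lab, x, c(10, 49), innsim_min = 0.99999999,
                  min_dur_ms = 10, sfreq_hz = 1000, epoch_start_ms = 0),
    class = "erp_no_window")
  err <- tryCatch(
    detect_window(lab, x, c(10, 49), innsim_min = 0.99999999,
                  min_dur_ms = 10, sfreq_hz = 1000, epoch_start_ms = 0),
    erp_no_window = function(e) e)
  expect_match(conditionMessage(err), "nearest miss")
  expect_error(
    detect_window(lab, x, c(10, 49), innsim_min = 2, min_dur_ms = 10,
                  sfreq_hz = 1000, epoch_start_ms = 0), "innsim_min")
})

test_that("noiseless group fixture recovers planted windows within one sample", {
  study <- simulate_study(study_spec(n_subjects = 2, snr_db = Inf,
                                     jitter_max_samples = 0, seed = 13))
  xbar <- grand_average(study)
  fit <- modified_kmeans(xbar, 7, seed = 5, restarts = 8)
  dt <- 1000 / study$sfreq_hz
  for (comp in c("N2", "P3")) {
    cc <- study$spec$conditions$Cond1[[comp]]
    w <- detect_window(fit$labels[1:study$n_t], xbar[1:study$n_t, ],
                       c(cc$onset_ms, cc$offset_ms),
                       min_dur_ms = 55,
                       sfreq_hz = study$sfreq_hz,
                       epoch_start_ms = study$epoch_start_ms)
    gt <- study$ground_truth$Cond1[[comp]]
    expect_lte(abs(w$start_ms - gt$start_ms), dt + 1e-9)
    expect_lte(abs(w$end_ms - gt$end_ms), dt + 1e-9)
    expect_gte(w$inner_similarity, 0.99)
  }
})
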