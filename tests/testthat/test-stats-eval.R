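test_that("mean amplitude averages the window samples and electrodes", {
  labels <- c("A", "B", "C")
  x <- matrix(5, 20, 3)
  w <- time_window(2, 11)
  expect_equal(mean_amplitude(x, w, c("A", "B"), labels, 1000, 0), 5)
  x2 <- x; x2[, 1] <- 1; x2[, 2] <- 3
  expect_equal(mean_amplitude(x2, w, c("A", "B"), labels, 1000, 0), 2)
  x3 <- matrix(0, 20, 3); x3[3:12, 3] <- 0:9   # ramp inside the window
  expect_equal(mean_amplitude(x3, w, "C", labels, 1000, 0), 4.5)
  expect_error(mean_amplitude(x, w, "Z", labels, 1000, 0), "unknown electrode")
})

test_that("tost declares equivalence for near-zero diffs and is exact at the margin", {
  set.seed(5)
  d0 <- rnorm(20, 0, 0.2)
  r0 <- tost(d0, delta = 5)
  expect_lt(max(r0$p1, r0$p2), 1e-6)
  expect_true(r0$equivalent)
  # mean difference exactly at +delta -> p2 = 0.5
  d1 <- c(4, 5, 6, 5)
  r1 <- tost(d1, delta = 5)
  expect_equal(r1$p2, 0.5)
  expect_false(r1$equivalent)
  expect_error(tost(d0, delta = -1), "delta")
  expect_error(tost(c(1, NA)), "n >= 2")
})

test_that("tost p values agree with an independent t-distribution oracle", {
  d <- c(1.5, 2.8, 0.4, 3.1, 2.2, 1.9, 2.6, 2.0, 1.1, 2.9,
         2.4, 1.7, 3.3, 2.1, 0.9, 2.7, 1.3, 2.5, 1.8, 2.3)
  r <- tost(d, delta = 5)
  n <- length(d); m <- mean(d); s <- sd(d)
  tdens <- function(t, df) gamma((df + 1) / 2) / (sqrt(df * pi) * gamma(df / 2)) *
    (1 + t^2 / df)^(-(df + 1) / 2)
  upper_tail <- function(q, df) integrate(tdens, q, Inf, df = df,
                                          rel.tol = 1e-10)$value
  t1 <- (m + 5) / (s / sqrt(n)); t2 <- (m - 5) / (s / sqrt(n))
  expect_equal(r$p1, upper_tail(t1, n - 1), tolerance = 1e-7)
  expect_equal(r$p2, 1 - upper_tail(t2, n - 1), tolerance = 1e-7)
  # 90% CI is the conventional TOST companion
  expect_equal(r$ci[2] - r$ci[1], 2 * qt(0.95, n - 1) * s / sqrt(n))
})

test_that("within-subject ANOVA equals the squared paired t", {
  set.seed(8)
  a <- matrix(rnorm(24), 12, 2)
  a[, 2] <- a[, 2] + 0.8
  res <- rm_anova_2x2(a)
  tt <- t.test(a[, 2], a[, 1], paired = TRUE)
  expect_equal(res$effects$F, unname(tt$statistic)^2)
  expect_equal(res$effects$p, tt$p.value)
  # identical task columns -> F = 0, p = 1
  same <- cbind(rnorm(6), 0)
  same[, 2] <- same[, 1]
  r0 <- rm_anova_2x2(same)
  expect_equal(r0$effects$F, 0)
  expect_equal(r0$effects$p, 1)
})

test_that("mixed 2x2 ANOVA matches the aov split-plot oracle", {
  set.seed(12)
  n <- 16
  groups <- rep(c("g1", "g2"), each = n / 2)
  amp <- matrix(rnorm(2 * n), n, 2)
  amp[groups == "g2", ] <- amp[groups == "g2", ] + 1.2
  amp[, 2] <- amp[, 2] + 0.5
  amp[groups == "g2", 2] <- amp[groups == "g2", 2] + 0.7
  res <- rm_anova_2x2(amp, groups)
  long <- data.frame(
    y = c(amp[, 1], amp[, 2]),
    task = factor(rep(c("t1", "t2"), each = n)),
    grp = factor(rep(groups, 2)),
    id = factor(rep(seq_len(n), 2)))
  fit <- summary(aov(y ~ grp * task + Error(id / task), data = long))
  between <- fit[["Error: id"]][[1]]
  within <- fit[["Error: id:task"]][[1]]
  expect_equal(res$effects$F[res$effects$effect == "group"],
               between["grp", "F value"])
  expect_equal(res$effects$F[res$effects$effect == "task"],
               within["task", "F value"])
  expect_equal(res$effects$F[res$effects$effect == "group:task"],
               within["grp:task", "F value"])
  expect_equal(res$effects$p[res$effects$effect == "group:task"],
               within["grp:task", "Pr(>F)"])
  expect_error(rm_anova_2x2(amp, rep("g1", n)), "two groups")
})

test_that("window accuracy reports signed millisecond differences", {
  truth <- list(Cond1 = list(N2 = time_window(200, 260)))
  est <- data.frame(subject = c("S1", "S2", "S3"), condition = "Cond1",
                    component = "N2",
                    start_ms = c(200, 200 + 2 * 1000 / 429, NA),
                    end_ms = c(260, 260 + 2 * 1000 / 429, NA))
  acc <- tw_accuracy(est, truth)
  expect_equal(acc$d_start, c(0, 4.662, NA), tolerance = 1e-3)
  expect_equal(acc$d_end, c(0, 4.662, NA), tolerance = 1e-3)
  expect_equal(acc$d_duration, c(0, 0, NA))
})

test_that("replicate_runs is degenerate for a deterministic configuration", {
  study <- small_study(n_subjects = 3, seed = 17)
  cfg <- pipeline_config(selected = "aahc", benchmark = "aahc",
                         stabilize = FALSE, seed = 2)
  rob <- suppressWarnings(replicate_runs(study, cfg, n_runs = 3, seed = 9))
  expect_equal(rob$n_runs, 3L)
  expect_true(all(rob$summary$consensus$sd_p == 0))
  expect_equal(nrow(rob$p_values$consensus), 3)
})
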