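#' Mean amplitude inside a time window
#'
#' Mean over the window's samples and the named electrodes of a single
#' condition's epoch matrix.
#'
#' @param x Time-points x channels matrix (one condition).
#' @param window An `erp_time_window` (or list with `start_ms`/`end_ms`).
#' @param electrodes Channel labels to average over.
#' @param channel_labels Labels of the columns of `x`.
#' @param sfreq_hz,epoch_start_ms Sample grid.
#' @return Mean amplitude in microvolt.
#' @export
mean_amplitude <- function(x, window, electrodes, channel_labels,
                           sfreq_hz, epoch_start_ms) {
  cols <- match(electrodes, channel_labels)
  if (anyNA(cols))
    stop(sprintf("unknown electrode(s): %s",
                 paste(electrodes[is.na(cols)], collapse = ", ")), call. = FALSE)
  tms <- ms_of_sample(seq_len(nrow(x)), sfreq_hz, epoch_start_ms)
  rows <- which(tms >= window$start_ms - 1e-9 & tms <= window$end_ms + 1e-9)
  if (!length(rows)) stop("window contains no samples", call. = FALSE)
  mean(x[rows, cols, drop = FALSE])
}

#' Two one-sided tests (TOST) of equivalence
#'
#' Schuirmann's TOST on per-subject differences: rejects
#' `H0_1: mu <= -delta` and `H0_2: mu >= delta` with one-sample t tests at
#' level `alpha`. Equivalence is declared when both are rejected, i.e. the
#' mean difference lies inside `[-delta, delta]`. The 90% confidence interval
#' of the mean difference (the conventional TOST companion interval) is
#' reported.
#'
#' @param diffs Per-subject differences (estimated minus truth), in ms.
#' @param delta Equivalence margin (> 0), default 5 ms.
#' @param alpha Test level, default 0.05.
#' @return A `tost_result`: `p1`, `p2`, `mean_diff`, `sd`, `n`, `delta`,
#'   `ci` (90% CI), `equivalent`.
#' @export
tost <- function(diffs, delta = 5, alpha = 0.05) {
  diffs <- diffs[!is.na(diffs)]
  n <- length(diffs)
  if (n < 2) stop("need n >= 2 non-missing differences", call. = FALSE)
  if (delta <= 0) stop("delta must be > 0", call. = FALSE)
  m <- mean(diffs); s <- stats::sd(diffs)
  if (s == 0) {
    # degenerate: all differences identical
    if (abs(m) < delta) { p1 <- 0; p2 <- 0 } else { p1 <- 1; p2 <- 1 }
    warning("zero variance in differences; TOST p values set by convention",
            call. = FALSE)
    ci <- c(m, m)
  } else {
    se <- s / sqrt(n)
    p1 <- stats::pt((m + delta) / se, df = n - 1, lower.tail = FALSE)
    p2 <- stats::pt((m - delta) / se, df = n - 1, lower.tail = TRUE)
    tcrit <- stats::qt(1 - alpha, df = n - 1)
    ci <- c(m - tcrit * se, m + tcrit * se)
  }
  structure(
    list(p1 = p1, p2 = p2, mean_diff = m, sd = s, n = n, delta = delta,
         alpha = alpha, ci = ci, equivalent = max(p1, p2) < alpha),
    class = "tost_result"
  )
}

#' @export
print.tost_result <- function(x, ...) {
  cat(sprintf("TOST: mean diff %.2f ms, p1 = %.4f, p2 = %.4f -> %s (delta = %g)\n",
              x$mean_diff, x$p1, x$p2,
              if (x$equivalent) "equivalent" else "not equivalent", x$delta))
  invisible(x)
}

#' Balanced 2x2 repeated-measures / mixed ANOVA
#'
#' Within-only design (no `groups`): one within-subject factor with two
#' levels; the task F equals the squared paired t. Mixed design (`groups`
#' with two levels): between-subject factor group, within-subject factor
#' task, and their interaction, by the standard partitioned sums of squares
#' for a balanced design.
#'
#' @param amplitudes Subjects x 2 matrix (columns = task levels).
#' @param groups Optional group label per subject (exactly two levels,
#'   balanced design not required to be equal-sized but both present).
#' @return An `anova_2x2` with an `effects` data.frame (`effect`, `F`,
#'   `df1`, `df2`, `p`) and `design`.
#' @export
rm_anova_2x2 <- function(amplitudes, groups = NULL) {
  amplitudes <- as.matrix(amplitudes)
  if (ncol(amplitudes) != 2)
    stop("amplitudes must have exactly two task columns", call. = FALSE)
  n <- nrow(amplitudes)
  if (is.null(groups)) {
    d <- amplitudes[, 2] - amplitudes[, 1]
    if (n < 2) stop("need >= 2 subjects", call. = FALSE)
    if (stats::sd(d) == 0) {
      # no within-subject variability: a zero effect is exactly zero F
      Fv <- if (mean(d) == 0) 0 else Inf
      p <- if (mean(d) == 0) 1 else 0
    } else {
      tstat <- mean(d) / (stats::sd(d) / sqrt(n))
      Fv <- tstat^2
      p <- stats::pf(Fv, 1, n - 1, lower.tail = FALSE)
    }
    effects <- data.frame(effect = "task", F = Fv, df1 = 1, df2 = n - 1, p = p)
    design <- "within-only"
  } else {
    groups <- as.factor(groups)
    if (nlevels(groups) != 2)
      stop("mixed design needs exactly two groups", call. = FALSE)
    if (length(groups) != n)
      stop("groups length must match subjects", call. = FALSE)
    if (any(table(groups) < 2))
      stop("each group needs >= 2 subjects", call. = FALSE)
    # cell decomposition for the balanced split-plot design
    subj_mean <- rowMeans(amplitudes)
    grand <- mean(amplitudes)
    g_mean <- tapply(subj_mean, groups, mean)
    n_g <- table(groups)
    # between-subject stratum
    ss_group <- sum(2 * n_g * (g_mean - grand)^2)
    ss_subj_within <- sum(2 * (subj_mean - g_mean[groups])^2)
    df_group <- 1; df_subj <- n - 2
    # within-subject stratum
    task_mean <- colMeans(amplitudes)
    ss_task <- n * sum((task_mean - grand)^2)
    cell_mean <- rbind(tapply(amplitudes[, 1], groups, mean),
                       tapply(amplitudes[, 2], groups, mean))
    ss_int <- 0
    for (g in levels(groups)) for (j in 1:2) {
      ss_int <- ss_int + n_g[[g]] *
        (cell_mean[j, g] - g_mean[[g]] - task_mean[j] + grand)^2
    }
    resid <- amplitudes
    for (g in levels(groups)) for (j in 1:2)
      resid[groups == g, j] <- amplitudes[groups == g, j] -
        subj_mean[groups == g] - cell_mean[j, g] + g_mean[[g]]
    ss_err_within <- sum(resid^2)
    df_task <- 1; df_int <- 1; df_err <- n - 2
    F_group <- (ss_group / df_group) / (ss_subj_within / df_subj)
    F_task <- (ss_task / df_task) / (ss_err_within / df_err)
    F_int <- (ss_int / df_int) / (ss_err_within / df_err)
    effects <- data.frame(
      effect = c("group", "task", "group:task"),
      F = c(F_group, F_task, F_int),
      df1 = c(df_group, df_task, df_int),
      df2 = c(df_subj, df_err, df_err),
      p = c(stats::pf(F_group, df_group, df_subj, lower.tail = FALSE),
            stats::pf(F_task, df_task, df_err, lower.tail = FALSE),
            stats::pf(F_int, df_int, df_err, lower.tail = FALSE)))
    design <- "mixed-2x2"
  }
  structure(list(effects = effects, design = design), class = "anova_2x2")
}

#' @export
print.anova_2x2 <- function(x, ...) {
  cat(sprintf("<%s ANOVA>\n", x$design))
  print(x$effects, row.names = FALSE)
  invisible(x)
}

#' Per-subject accuracy of estimated time windows
#'
#' Signed differences (estimated minus ground truth), in ms, for start, end
#' and duration. Missing windows propagate as `NA` and are excluded by the
#' downstream tests.
#'
#' @param estimated `data.frame` with columns `subject`, `condition`,
#'   `component`, `start_ms`, `end_ms` (rows with `NA` = missing window).
#' @param truth Ground-truth windows as returned by
#'   [ground_truth_windows()] (condition -> component -> window).
#' @return `data.frame` with `subject`, `condition`, `component`,
#'   `d_start`, `d_end`, `d_duration` (ms).
#' @export
tw_accuracy <- function(estimated, truth) {
  if (is.null(estimated) || !nrow(estimated))
    return(data.frame(subject = character(), condition = character(),
                      component = character(), d_start = numeric(),
                      d_end = numeric(), d_duration = numeric()))
  rows <- lapply(seq_len(nrow(estimated)), function(i) {
    e <- estimated[i, ]
    tw <- truth[[e$condition]][[e$component]]
    if (is.null(tw)) return(NULL)
    data.frame(subject = e$subject, condition = e$condition,
               component = e$component,
               d_start = e$start_ms - tw$start_ms,
               d_end = e$end_ms - tw$end_ms,
               d_duration = (e$end_ms - e$start_ms) - tw$duration_ms)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(subject = character(), condition = character(),
                      component = character(), d_start = numeric(),
                      d_end = numeric(), d_duration = numeric())
  out
}

#' Robustness of the pipeline over repeated runs
#'
#' Reruns the clustering-to-ANOVA pipeline `n_runs` times with derived seeds
#' on fixed data and summarizes the per-effect p values (mean and SD), for
#' the consensus pipeline and optionally for a single-method comparator run
#' on the same data and seeds. Deterministic pipeline members are computed
#' once and reused across runs.
#'
#' @param study An `erp_study`.
#' @param config Pipeline configuration ([pipeline_config()]).
#' @param n_runs Number of independent runs (default 50).
#' @param seed Master seed; run `r` uses `derive_seed(seed, "run", r)`.
#' @param comparator Optional single base method (e.g. `"kmeans"`) evaluated
#'   on identical data/seeds for comparison.
#' @return An `erp_robustness`: `p_values` (runs x effect, per arm),
#'   `summary` (mean and SD per effect per arm), `n_runs`, `seeds`.
#' @export
replicate_runs <- function(study, config = pipeline_config(), n_runs = 50L,
                           seed = 1L, comparator = NULL) {
  seeds <- vapply(seq_len(n_runs), function(r) derive_seed(seed, "run", r),
                  integer(1))
  arms <- c("consensus", if (!is.null(comparator)) comparator)
  pvals <- lapply(arms, function(a) NULL)
  names(pvals) <- arms
  det_cache <- new.env(parent = emptyenv())
  # data are fixed across runs: freeze the method selection and the
  # stabilization repetition counts once
  if (is.null(config$selected)) {
    sel <- select_methods(study, config$k, candidates = config$candidates,
                          benchmark = config$benchmark,
                          sim_threshold = config$sim_threshold,
                          majority = config$majority,
                          Mr = config$Mr, tau = config$tau, eps = config$eps,
                          seed = derive_seed(seed, "selection"))
    config$selected <- sel$selected
    config$r_opt <- as.list(sel$r_opt)
  } else if (is.null(config$r_opt) && config$stabilize) {
    xbar <- grand_average(study)
    ms <- unique(c(config$benchmark, config$selected))
    config$r_opt <- lapply(stats::setNames(ms, ms), function(m)
      if (m %in% stochastic_methods())
        stabilize_method(xbar, config$k, m, Mr = config$Mr, tau = config$tau,
                         eps = config$eps,
                         seed = derive_seed(seed, "stab", m))$r_opt
      else 1L)
  }
  for (r in seq_len(n_runs)) {
    cfg <- config
    cfg$seed <- seeds[r]
    res <- run_pipeline(study, cfg, .det_cache = det_cache)
    pvals$consensus <- rbind(pvals$consensus, anova_p_row(res))
    if (!is.null(comparator)) {
      cfg2 <- cfg
      cfg2$selected <- character(0)
      cfg2$benchmark <- comparator
      cfg2$stabilize <- FALSE
      cfg2$r_opt <- NULL
      res2 <- run_pipeline(study, cfg2, .det_cache = det_cache)
      pvals[[comparator]] <- rbind(pvals[[comparator]], anova_p_row(res2))
    }
  }
  summaries <- lapply(pvals, function(m) {
    data.frame(effect = colnames(m),
               mean_p = colMeans(m, na.rm = TRUE),
               sd_p = apply(m, 2, stats::sd, na.rm = TRUE))
  })
  structure(list(p_values = pvals, summary = summaries,
                 n_runs = as.integer(n_runs), seeds = seeds),
            class = "erp_robustness")
}

# One row of per-effect ANOVA p values from a pipeline result
anova_p_row <- function(res) {
  out <- c()
  for (comp in names(res$anova)) {
    eff <- res$anova[[comp]]$effects
    v <- stats::setNames(eff$p, paste(comp, eff$effect, sep = "."))
    out <- c(out, v)
  }
  t(out)[1, , drop = TRUE]
}

#' @export
print.erp_robustness <- function(x, ...) {
  cat(sprintf("<erp_robustness: %d runs>\n", x$n_runs))
  for (a in names(x$summary)) {
    cat(sprintf("  arm %s:\n", a))
    print(x$summary[[a]], row.names = FALSE)
  }
  invisible(x)
}
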