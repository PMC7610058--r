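#' Default six-component ERP study components
#'
#' The canonical simulated study: six phasic components (P1, N1, P2, N2, P3,
#' N4) spanning 42-596 ms plus a weak tonic pre-stimulus background state.
#' N2 (right-posterior negative, support 175-292 ms) and P3 (centro-parietal
#' positive, support 240-385 ms) are the measurement targets; their
#' `area_fraction` values (0.89 and 0.92) were solved from the closed-form
#' envelopes so that the clean templates yield the intended signed-area
#' measurement windows (about 201-265 ms and 266-357 ms).
#'
#' @param gain Multiplies every amplitude (used to build a stronger second
#'   condition).
#' @return Named list of [component_spec()] objects.
#' @export
default_components <- function(gain = 1) {
  g <- gain
  list(
    P1 = component_spec("P1", +1,  42,  75, 102, 5 * g,
                        rbind(c(0, -0.82)), 0.28),
    N1 = component_spec("N1", -1,  95, 130, 172, 5 * g,
                        rbind(c(-0.62, -0.35), c(0.62, -0.35)), 0.26),
    P2 = component_spec("P2", +1, 140, 180, 214, 5 * g,
                        rbind(c(0, 0.62)), 0.28),
    N2 = component_spec("N2", -1, 175, 233, 292, 5 * g,
                        rbind(c(0.50, -0.58)), 0.26,
                        fall_exp = 1.3, area_fraction = 0.89),
    P3 = component_spec("P3", +1, 240, 310, 385, 5 * g,
                        rbind(c(0, -0.15)), 0.30,
                        area_fraction = 0.92),
    N4 = component_spec("N4", -1, 320, 420, 596, 5 * g,
                        rbind(c(-0.45, 0.40)), 0.28),
    base = component_spec("base", +1, -100, 0, 48, 1 * g,
                          rbind(c(-0.25, 0.72, 1), c(0.25, 0.72, -0.8)),
                          0.30, shape = "tonic", ramp_ms = 25)
  )
}

#' Decorrelate a set of component topographies
#'
#' Maps the topography matrix onto the nearest set of maps whose pairwise
#' spatial correlations all equal `target_corr`, via a Gram-matrix square-root
#' transform. Average-referenced focal maps are otherwise substantially
#' correlated through the reference "seesaw"; spatially distinct dipolar
#' sources, which the simulator emulates, are not.
#'
#' @param topo Channels x components matrix of topographies.
#' @param target_corr Common pairwise correlation (must exceed
#'   `-1/(m - 1)` for `m` maps).
#' @return Matrix of the same shape; zero channel mean and unit maximum
#'   absolute value per column.
#' @export
decorrelate_topographies <- function(topo, target_corr = -0.1) {
  m <- ncol(topo)
  if (target_corr <= -1 / (m - 1))
    stop("target_corr too negative to be a valid correlation matrix", call. = FALSE)
  ts <- scale(topo, center = FALSE, scale = sqrt(colSums(topo^2)))
  G <- crossprod(ts)
  eg <- eigen(G, symmetric = TRUE)
  G_invhalf <- eg$vectors %*% diag(1 / sqrt(eg$values), m) %*% t(eg$vectors)
  Gt <- (1 - target_corr) * diag(m) + target_corr * matrix(1, m, m)
  eh <- eigen(Gt, symmetric = TRUE)
  Gt_half <- eh$vectors %*% diag(sqrt(eh$values), m) %*% t(eh$vectors)
  out <- ts %*% G_invhalf %*% Gt_half
  out <- sweep(out, 2, colMeans(out))
  out <- sweep(out, 2, apply(abs(out), 2, max), "/")
  dimnames(out) <- dimnames(topo)
  out
}

#' Specify a simulated multi-subject ERP study
#'
#' @param n_subjects Number of subjects (>= 1).
#' @param conditions Named list of condition component lists (each a named
#'   list of [component_spec()]s). The default is the canonical two-condition
#'   study, condition 2 being condition 1 with a global gain of 1.2.
#' @param montage An `erp_montage` (default 65 channels).
#' @param sfreq_hz Sampling rate (default 429 Hz).
#' @param epoch_start_ms,epoch_end_ms Epoch limits (default -100..600 ms).
#' @param snr_db Signal-to-noise ratio of the additive white Gaussian noise,
#'   in dB of whole-dataset signal power (default 20; `Inf` = noiseless).
#' @param jitter_max_samples Maximum per-component latency jitter in samples
#'   (default 5); one uniform integer draw per component per subject, shared
#'   across conditions.
#' @param decorrelate_maps Apply [decorrelate_topographies()] to the
#'   component map set (default TRUE).
#' @param target_corr Pairwise map correlation when decorrelating.
#' @param seed Master seed.
#' @return An object of class `erp_study_spec`.
#' @export
study_spec <- function(n_subjects = 20,
                       conditions = list(Cond1 = default_components(1),
                                         Cond2 = default_components(1.2)),
                       montage = make_montage(65),
                       sfreq_hz = 429,
                       epoch_start_ms = -100, epoch_end_ms = 600,
                       snr_db = 20, jitter_max_samples = 5,
                       decorrelate_maps = TRUE, target_corr = -0.1,
                       seed = 1L) {
  stopifnot(n_subjects >= 1, sfreq_hz > 0, jitter_max_samples >= 0,
            length(conditions) >= 1, !is.null(names(conditions)))
  structure(
    list(n_subjects = as.integer(n_subjects), conditions = conditions,
         montage = montage, sfreq_hz = sfreq_hz,
         epoch_start_ms = epoch_start_ms, epoch_end_ms = epoch_end_ms,
         snr_db = snr_db, jitter_max_samples = as.integer(jitter_max_samples),
         decorrelate_maps = decorrelate_maps, target_corr = target_corr,
         seed = as.integer(seed)),
    class = "erp_study_spec"
  )
}

#' Add calibrated white Gaussian noise
#'
#' Noise variance is `signal_power * 10^(-snr_db / 10)`, with signal power
#' measured as the mean square over the entire matrix.
#'
#' @param x Numeric matrix (time-points x channels).
#' @param snr_db Target SNR in dB; `Inf` returns `x` unchanged.
#' @return Matrix of the same shape with noise added (uses the current RNG
#'   state).
#' @export
add_awgn <- function(x, snr_db) {
  if (is.infinite(snr_db)) return(x)
  p_sig <- mean(x^2)
  sd_n <- sqrt(p_sig * 10^(-snr_db / 10))
  x + matrix(stats::rnorm(length(x), 0, sd_n), nrow(x))
}

# Topography matrix (channels x components) for a condition's component list,
# optionally decorrelated as a set.
condition_topographies <- function(spec, components) {
  topo <- vapply(components, function(cc) component_topography(spec$montage, cc),
                 numeric(length(spec$montage$labels)))
  if (isTRUE(spec$decorrelate_maps) && ncol(topo) > 1)
    topo <- decorrelate_topographies(topo, spec$target_corr)
  topo
}

# Clean (noise-free) epoch matrix for one condition; `jitter` is a named
# vector of sample shifts per component (may be empty for templates).
clean_condition_matrix <- function(spec, components, topo, jitter = NULL) {
  tms <- epoch_times(spec$sfreq_hz, spec$epoch_start_ms, spec$epoch_end_ms)
  dt <- 1000 / spec$sfreq_hz
  X <- matrix(0, length(tms), length(spec$montage$labels))
  for (nm in names(components)) {
    cc <- components[[nm]]
    shift <- if (!is.null(jitter) && nm %in% names(jitter)) jitter[[nm]] * dt else 0
    cs <- cc
    cs$onset_ms <- cc$onset_ms + shift
    cs$peak_ms <- cc$peak_ms + shift
    cs$offset_ms <- cc$offset_ms + shift
    # jitter may push the support past the epoch edge; the envelope is then
    # clipped to the sample grid -- warn when that removes real mass
    if (cs$onset_ms < spec$epoch_start_ms || cs$offset_ms > spec$epoch_end_ms) {
      fine <- seq(cs$onset_ms, cs$offset_ms, by = 1)
      w_all <- envelope_at(cs, fine)
      lost <- sum(w_all[fine < spec$epoch_start_ms | fine > spec$epoch_end_ms])
      if (lost > 0.01 * sum(w_all))
        warning(sprintf("jitter pushed component '%s' support to [%.1f, %.1f]; clipped to epoch",
                        nm, cs$onset_ms, cs$offset_ms), call. = FALSE)
    }
    env <- cc$amplitude * envelope_at(cs, tms)
    X <- X + env %o% topo[, nm]
  }
  X
}

#' Ground-truth measurement windows of a study specification
#'
#' Signed-area windows of the clean, jitter-free component templates, one per
#' measurement-target component (those with a non-`NA` `area_fraction`) and
#' condition. Invariant to `snr_db` and jitter by construction.
#'
#' @param spec An `erp_study_spec`.
#' @return Named list (condition -> component -> `erp_time_window`).
#' @export
ground_truth_windows <- function(spec) {
  out <- list()
  for (cond in names(spec$conditions)) {
    comps <- spec$conditions[[cond]]
    out[[cond]] <- list()
    for (nm in names(comps)) {
      cc <- comps[[nm]]
      if (is.na(cc$area_fraction)) next
      wf <- component_waveform(cc, spec$sfreq_hz,
                               spec$epoch_start_ms, spec$epoch_end_ms)
      out[[cond]][[nm]] <- signed_area_window(
        cc$polarity * wf, cc$polarity,
        c(cc$onset_ms, cc$offset_ms), cc$area_fraction,
        spec$sfreq_hz, spec$epoch_start_ms)
    }
  }
  out
}

#' Simulate a multi-subject ERP study
#'
#' For every subject, each measurement-target component's latency is shifted
#' by an integer drawn uniformly from `[-jitter_max, +jitter_max]` samples
#' (one draw per component, shared across conditions; non-target deflections
#' and the tonic background keep fixed latencies), the clean
#' topography-times-waveform sum is assembled per condition, white Gaussian noise calibrated on the
#' subject's whole concatenated dataset is added once, and conditions are
#' concatenated in their declared order. Fully reproducible from the spec
#' seed.
#'
#' @param spec An `erp_study_spec`.
#' @return An object of class `erp_study`: montage, grid metadata, condition
#'   names, per-subject records (`data` = named list of condition matrices,
#'   `concat` = row-bound matrix, `jitter`), `ground_truth` windows, and the
#'   spec.
#' @export
simulate_study <- function(spec) {
  stopifnot(inherits(spec, "erp_study_spec"))
  cond_names <- names(spec$conditions)
  topo <- lapply(spec$conditions, function(cmp) condition_topographies(spec, cmp))
  comp_names <- names(spec$conditions[[1]])
  n_t <- length(epoch_times(spec$sfreq_hz, spec$epoch_start_ms, spec$epoch_end_ms))
  subjects <- vector("list", spec$n_subjects)
  jittered <- comp_names[vapply(spec$conditions[[1]],
                                function(cc) !is.na(cc$area_fraction), TRUE)]
  for (i in seq_len(spec$n_subjects)) {
    set.seed(derive_seed(spec$seed, "jitter", i))
    # latency jitter moves the target ERPs (the measurement components);
    # the other deflections and the tonic background stay put
    jitter <- stats::setNames(
      sample(seq(-spec$jitter_max_samples, spec$jitter_max_samples),
             length(jittered), replace = TRUE),
      jittered)
    clean <- lapply(cond_names, function(cond)
      clean_condition_matrix(spec, spec$conditions[[cond]], topo[[cond]], jitter))
    names(clean) <- cond_names
    concat_clean <- do.call(rbind, clean)
    set.seed(derive_seed(spec$seed, "noise", i))
    concat <- add_awgn(concat_clean, spec$snr_db)
    data <- lapply(seq_along(cond_names), function(j)
      concat[(j - 1) * n_t + seq_len(n_t), , drop = FALSE])
    names(data) <- cond_names
    subjects[[i]] <- list(id = sprintf("S%02d", i), group = "G1",
                          data = data, concat = concat, jitter = jitter)
  }
  structure(
    list(montage = spec$montage, sfreq_hz = spec$sfreq_hz,
         epoch_start_ms = spec$epoch_start_ms,
         epoch_end_ms = spec$epoch_end_ms,
         n_t = n_t, conditions = cond_names,
         subjects = subjects,
         ground_truth = ground_truth_windows(spec),
         topographies = topo,
         spec = spec),
    class = "erp_study"
  )
}

#' @export
print.erp_study <- function(x, ...) {
  cat(sprintf("<erp_study: %d subjects, %d conditions (%s), %d x %d concatenated>\n",
              length(x$subjects), length(x$conditions),
              paste(x$conditions, collapse = ", "),
              x$n_t * length(x$conditions), length(x$montage$labels)))
  invisible(x)
}

#' Grand-average concatenated matrix of a study
#'
#' @param study An `erp_study`.
#' @return Mean over subjects of the concatenated matrices.
#' @export
grand_average <- function(study) {
  Reduce(`+`, lapply(study$subjects, `[[`, "concat")) / length(study$subjects)
}
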