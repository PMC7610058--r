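#' Pipeline configuration
#'
#' Collects the tunables of the end-to-end consensus pipeline. Defaults
#' follow the canonical simulated study: `k = 7` cluster maps, candidate
#' roster kmeans / correlation hierarchical / AAHC with a modified k-means
#' benchmark, stabilization up to 20 repetitions with `tau = 0.90` and
#' `eps = 0.03`, inner-similarity threshold 0.90, minimum window duration
#' 55 ms (see below), minimum interval overlap 0.3 and a +-5 ms TOST margin.
#'
#' @param k Number of cluster maps.
#' @param candidates Candidate methods entering benchmark selection.
#' @param benchmark Benchmark method, always part of the consensus.
#' @param selected Optional frozen method list; when given, the selection
#'   stage is skipped.
#' @param Mr,tau,eps Stabilization parameters ([stabilize_method()]).
#' @param stabilize Stabilize stochastic methods (default TRUE); when FALSE
#'   every method is run once per subject (single-run comparator mode).
#' @param sim_threshold,majority Selection parameters ([select_methods()]).
#' @param innsim_min,min_dur_ms,min_overlap Window detection parameters
#'   ([detect_window()]). The default minimum duration (55 ms) sits just
#'   below the shortest target component's expected window (~63 ms) so the
#'   filter rejects fragmented runs without knife-edging the target under
#'   single-sample discretization.
#' @param delta_ms,alpha TOST margin and level.
#' @param targets Named list (component -> list(interval_ms, electrodes));
#'   `NULL` derives it from the study's measurement components (interval =
#'   definition interval, electrodes = the two channels with the largest
#'   absolute template value).
#' @param seed Master seed of the pipeline.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(k = 7L,
                            candidates = c("kmeans", "hierarchical_corr", "aahc"),
                            benchmark = "modified_kmeans",
                            selected = NULL,
                            Mr = 20L, tau = 0.90, eps = 0.03,
                            stabilize = TRUE,
                            sim_threshold = 0.8, majority = 0.5,
                            innsim_min = 0.90, min_dur_ms = 55,
                            min_overlap = 0.3,
                            delta_ms = 5, alpha = 0.05,
                            targets = NULL, seed = 1L) {
  structure(
    list(k = as.integer(k), candidates = candidates, benchmark = benchmark,
         selected = selected, Mr = as.integer(Mr), tau = tau, eps = eps,
         stabilize = stabilize, sim_threshold = sim_threshold,
         majority = majority, innsim_min = innsim_min,
         min_dur_ms = min_dur_ms, min_overlap = min_overlap,
         delta_ms = delta_ms, alpha = alpha,
         targets = targets, seed = as.integer(seed)),
    class = "pipeline_config"
  )
}

# Measurement targets: the study's recorded targets (e.g. restored from a
# manifest), else derived from the simulator spec (definition interval and
# the two strongest template channels per measurement component).
default_targets <- function(study) {
  if (!is.null(study$targets)) return(study$targets)
  if (is.null(study$spec))
    stop("study has no measurement targets; supply config$targets",
         call. = FALSE)
  comps <- study$spec$conditions[[1]]
  topo <- study$topographies[[1]]
  out <- list()
  for (nm in names(comps)) {
    cc <- comps[[nm]]
    if (is.na(cc$area_fraction)) next
    ord <- order(abs(topo[, nm]), decreasing = TRUE)[1:2]
    out[[nm]] <- list(interval_ms = c(cc$onset_ms, cc$offset_ms),
                      electrodes = study$montage$labels[ord])
  }
  out
}

condition_rows <- function(study, j) (j - 1) * study$n_t + seq_len(study$n_t)

#' Run the full multi-subject consensus pipeline
#'
#' Stages: stabilization of the stochastic clusterers on the grand average,
#' benchmark-based method selection across subjects, subject-level consensus
#' of the selected (stabilized) methods, group-level consensus across
#' subjects, per-condition time-window detection for every measurement
#' target, and the evaluation layer (per-subject window accuracy, TOST
#' equivalence against the simulator's ground truth, repeated-measures
#' ANOVA of mean amplitudes in the detected windows).
#'
#' @param study An `erp_study` (simulated or read from disk).
#' @param config A [pipeline_config()].
#' @param .det_cache Internal: environment caching deterministic per-subject
#'   partitions across repeated runs on fixed data.
#' @return An `erp_pipeline_result` with elements `selection`,
#'   `subject_partitions`, `group_partition`, `group_windows`,
#'   `subject_windows`, `accuracy`, `tost`, `anova`, `config`.
#' @export
run_pipeline <- function(study, config = pipeline_config(), .det_cache = NULL) {
  stopifnot(inherits(study, "erp_study"))
  k <- config$k
  seed <- config$seed
  targets <- config$targets %||% default_targets(study)
  xbar <- grand_average(study)
  p <- length(study$subjects)

  selection <- NULL
  if (is.null(config$selected)) {
    selection <- select_methods(study, k,
                                candidates = config$candidates,
                                benchmark = config$benchmark,
                                sim_threshold = config$sim_threshold,
                                majority = config$majority,
                                Mr = config$Mr, tau = config$tau,
                                eps = config$eps,
                                seed = derive_seed(seed, "selection"))
    methods_used <- unique(c(config$benchmark, selection$selected))
    subject_partitions <- lapply(seq_len(p), function(i) {
      ps <- selection$partitions[[i]][methods_used]
      if (length(ps) == 1L) ps[[1]] else {
        out <- cspa(ps, k); out$method <- "subject_consensus"; out
      }
    })
  } else {
    methods_used <- unique(c(config$benchmark, config$selected))
    r_opt <- stats::setNames(rep(1L, length(methods_used)), methods_used)
    if (config$stabilize) {
      for (m in methods_used) {
        if (!is.null(config$r_opt[[m]])) {
          r_opt[[m]] <- config$r_opt[[m]]
        } else if (m %in% stochastic_methods()) {
          r_opt[[m]] <- stabilize_method(xbar, k, m, Mr = config$Mr,
                                         tau = config$tau, eps = config$eps,
                                         seed = derive_seed(seed, "stab", m))$r_opt
        }
      }
    }
    subject_partitions <- lapply(seq_len(p), function(i) {
      xi <- study$subjects[[i]]$concat
      ps <- lapply(methods_used, function(m) {
        if (!(m %in% stochastic_methods()) && !is.null(.det_cache)) {
          key <- paste0(m, "|", i)
          if (is.null(.det_cache[[key]]))
            .det_cache[[key]] <- stabilized_partition(xi, k, m, 1L, seed = 0L)
          return(.det_cache[[key]])
        }
        stabilized_partition(xi, k, m, r_opt[[m]],
                             seed = derive_seed(seed, "subject", i, m))
      })
      if (length(ps) == 1L) ps[[1]] else {
        out <- cspa(ps, k); out$method <- "subject_consensus"; out
      }
    })
  }

  group_partition <- group_consensus(subject_partitions, k)

  # window detection: group level on the grand average, subject level on
  # each subject's own data
  detect_for <- function(labels_full, xfull, j, comp) {
    rows <- condition_rows(study, j)
    tryCatch(
      detect_window(labels_full[rows], xfull[rows, , drop = FALSE],
                    targets[[comp]]$interval_ms,
                    innsim_min = config$innsim_min,
                    min_dur_ms = config$min_dur_ms,
                    min_overlap = config$min_overlap,
                    sfreq_hz = study$sfreq_hz,
                    epoch_start_ms = study$epoch_start_ms,
                    condition = study$conditions[j]),
      erp_no_window = function(e) NULL)
  }
  group_windows <- NULL
  for (j in seq_along(study$conditions)) for (comp in names(targets)) {
    w <- detect_for(group_partition$labels, xbar, j, comp)
    group_windows <- rbind(group_windows, data.frame(
      condition = study$conditions[j], component = comp,
      start_ms = if (is.null(w)) NA_real_ else w$start_ms,
      end_ms = if (is.null(w)) NA_real_ else w$end_ms,
      duration_ms = if (is.null(w)) NA_real_ else w$duration_ms,
      cluster = if (is.null(w)) NA_integer_ else w$cluster,
      inner_similarity = if (is.null(w)) NA_real_ else w$inner_similarity,
      overlap = if (is.null(w)) NA_real_ else w$overlap))
  }
  subject_windows <- NULL
  for (i in seq_len(p)) for (j in seq_along(study$conditions))
    for (comp in names(targets)) {
      w <- detect_for(subject_partitions[[i]]$labels,
                      study$subjects[[i]]$concat, j, comp)
      subject_windows <- rbind(subject_windows, data.frame(
        subject = study$subjects[[i]]$id,
        condition = study$conditions[j], component = comp,
        start_ms = if (is.null(w)) NA_real_ else w$start_ms,
        end_ms = if (is.null(w)) NA_real_ else w$end_ms,
        duration_ms = if (is.null(w)) NA_real_ else w$duration_ms,
        inner_similarity = if (is.null(w)) NA_real_ else w$inner_similarity))
    }

  # evaluation layer
  accuracy <- tost_table <- NULL
  if (length(study$ground_truth)) {
    accuracy <- tw_accuracy(subject_windows, study$ground_truth)
    for (comp in unique(accuracy$component))
      for (cond in unique(accuracy$condition)) {
        a <- accuracy[accuracy$component == comp & accuracy$condition == cond, ]
        for (prop in c("d_start", "d_end", "d_duration")) {
          d <- a[[prop]]
          if (sum(!is.na(d)) < 2) next
          tt <- tost(d, delta = config$delta_ms, alpha = config$alpha)
          tost_table <- rbind(tost_table, data.frame(
            component = comp, condition = cond,
            property = sub("^d_", "", prop),
            p1 = tt$p1, p2 = tt$p2, mean_diff = tt$mean_diff,
            ci_lo = tt$ci[1], ci_hi = tt$ci[2], n = tt$n,
            equivalent = tt$equivalent))
        }
      }
  }

  anova <- list()
  if (length(study$conditions) == 2) {
    groups <- vapply(study$subjects, `[[`, "", "group")
    use_groups <- if (length(unique(groups)) == 2) groups else NULL
    for (comp in names(targets)) {
      gw <- group_windows[group_windows$component == comp, ]
      if (any(is.na(gw$start_ms))) next
      amp <- matrix(NA_real_, p, 2)
      for (i in seq_len(p)) for (j in 1:2) {
        win <- list(start_ms = gw$start_ms[gw$condition == study$conditions[j]],
                    end_ms = gw$end_ms[gw$condition == study$conditions[j]])
        amp[i, j] <- mean_amplitude(
          study$subjects[[i]]$data[[study$conditions[j]]], win,
          targets[[comp]]$electrodes, study$montage$labels,
          study$sfreq_hz, study$epoch_start_ms)
      }
      anova[[comp]] <- rm_anova_2x2(amp, groups = use_groups)
    }
  }

  structure(
    list(selection = selection, methods_used = methods_used,
         subject_partitions = subject_partitions,
         group_partition = group_partition,
         group_windows = group_windows, subject_windows = subject_windows,
         accuracy = accuracy, tost = tost_table, anova = anova,
         targets = targets, config = config),
    class = "erp_pipeline_result"
  )
}

#' @export
print.erp_pipeline_result <- function(x, ...) {
  cat("<erp_pipeline_result>\n  methods:",
      paste(x$methods_used, collapse = ", "), "\n")
  cat("  group windows:\n")
  print(x$group_windows, row.names = FALSE)
  invisible(x)
}

#' Check one-to-one isolation of the planted components
#'
#' For every phasic component of a simulated study, reads the group
#' partition's label at the component's peak latency in each condition and
#' checks that the components map onto distinct cluster maps, all different
#' from the pre-stimulus cluster.
#'
#' @param partition Group-level `erp_partition` over the concatenated grid.
#' @param study The simulated `erp_study`.
#' @return List with `labels` (condition x component matrix),
#'   `prestimulus` (modal pre-stimulus label) and `isolated` (logical).
#' @export
component_isolation <- function(partition, study) {
  labels <- as_labels(partition)
  tms <- epoch_times(study$sfreq_hz, study$epoch_start_ms, study$epoch_end_ms)
  comps <- study$spec$conditions[[1]]
  phasic <- names(comps)[vapply(comps, function(cc) cc$shape == "phasic", TRUE)]
  out <- matrix(NA_integer_, length(study$conditions), length(phasic),
                dimnames = list(study$conditions, phasic))
  for (j in seq_along(study$conditions)) {
    rows <- condition_rows(study, j)
    for (nm in phasic) {
      pk <- which.min(abs(tms - comps[[nm]]$peak_ms))
      out[j, nm] <- labels[rows[pk]]
    }
  }
  pre <- which(tms < 0)
  prestim <- as.integer(names(which.max(table(labels[pre]))))
  iso <- all(apply(out, 1, function(v) length(unique(v)) == length(v))) &&
    !(prestim %in% out)
  list(labels = out, prestimulus = prestim, isolated = iso)
}
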