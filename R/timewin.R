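#' Contiguous runs of a cluster in a label sequence
#'
#' @param labels Label vector over consecutive time samples.
#' @param id Cluster id of interest.
#' @return Integer matrix with columns `first`, `last` (1-based sample
#'   indices); zero rows if the id is absent.
#' @export
contiguous_runs <- function(labels, id) {
  r <- rle(labels == id)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  out <- cbind(first = starts, last = ends)[r$values, , drop = FALSE]
  storage.mode(out) <- "integer"
  out
}

#' Inner-similarity of a set of topographies
#'
#' Mean pairwise spatial correlation of the time-points in a candidate
#' cluster map, averaged on the Fisher-z scale: correlations are clipped to
#' `+-(1 - 1e-7)`, transformed with `atanh`, the off-diagonal values
#' averaged, and the mean transformed back with `tanh`. Equals the plain
#' mean correlation when all pairwise correlations are equal.
#'
#' @param x Time-points x channels matrix.
#' @param indices Row indices of the candidate map (>= 2; a singleton
#'   returns 1 with a warning).
#' @return Scalar in `(-1, 1]`.
#' @export
inner_similarity <- function(x, indices) {
  if (length(indices) < 1) stop("empty index set", call. = FALSE)
  if (length(indices) == 1) {
    warning("inner similarity of a single time-point is 1 by convention",
            call. = FALSE)
    return(1)
  }
  xm <- x[indices, , drop = FALSE]
  sds <- apply(xm, 1, stats::sd)
  if (any(sds == 0))
    stop("inner similarity undefined: zero-variance map in the set", call. = FALSE)
  C <- stats::cor(t(xm))
  r <- C[upper.tri(C)]
  clip <- 1 - 1e-7
  z <- atanh(pmin(pmax(r, -clip), clip))
  tanh(mean(z))
}

ms_of_sample <- function(i, sfreq_hz, epoch_start_ms) {
  epoch_start_ms + (i - 1) / sfreq_hz * 1000
}

#' Candidate cluster maps inside an experimental interval
#'
#' For a single condition's label sequence, lists every cluster whose runs
#' intersect the experimental measurement interval. Each cluster contributes
#' its longest interval-intersecting run; the run's inner-similarity and the
#' fraction of the interval it covers are reported.
#'
#' @param labels Condition-slice label vector (one label per sample).
#' @param x Condition-slice data matrix (same rows as `labels`).
#' @param interval_ms Experimental measurement interval `[lo, hi]` in ms.
#' @param sfreq_hz,epoch_start_ms Sample grid of the condition epoch.
#' @return `data.frame` with columns `cluster`, `first`, `last`, `start_ms`,
#'   `end_ms`, `duration_ms`, `inner_similarity`, `overlap`.
#' @export
candidate_maps <- function(labels, x, interval_ms, sfreq_hz, epoch_start_ms) {
  if (interval_ms[1] >= interval_ms[2]) stop("empty interval", call. = FALSE)
  tms <- ms_of_sample(seq_along(labels), sfreq_hz, epoch_start_ms)
  in_int <- which(tms >= interval_ms[1] & tms <= interval_ms[2])
  if (!length(in_int)) stop("interval contains no samples", call. = FALSE)
  ids <- unique(labels[in_int])
  rows <- lapply(ids, function(id) {
    runs <- contiguous_runs(labels, id)
    hit <- runs[runs[, "last"] >= min(in_int) & runs[, "first"] <= max(in_int),
                , drop = FALSE]
    if (!nrow(hit)) return(NULL)
    run <- hit[which.max(hit[, "last"] - hit[, "first"]), ]
    idx <- run["first"]:run["last"]
    # flat (zero-variance) maps carry no topography; drop them from the
    # similarity computation rather than failing the whole candidate table
    informative <- idx[apply(x[idx, , drop = FALSE], 1, stats::sd) > 0]
    isim <- if (length(informative) >= 2)
      suppressWarnings(inner_similarity(x, informative)) else NA_real_
    ov <- length(intersect(idx, in_int)) / length(in_int)
    data.frame(cluster = id, first = run[["first"]], last = run[["last"]],
               start_ms = tms[run[["first"]]], end_ms = tms[run[["last"]]],
               duration_ms = tms[run[["last"]]] - tms[run[["first"]]],
               n_samples = length(idx),
               inner_similarity = isim, overlap = ov)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(cluster = integer(), first = integer(), last = integer(),
                      start_ms = numeric(), end_ms = numeric(),
                      duration_ms = numeric(), n_samples = integer(),
                      inner_similarity = numeric(), overlap = numeric())
  out[order(-out$inner_similarity * out$overlap), , drop = FALSE]
}

#' Detect the measurement time window of an ERP component
#'
#' Filters the candidate cluster maps by inner-similarity (`>= innsim_min`)
#' and run duration (`>= min_dur_ms`), then picks the maximizer of
#' `inner_similarity x overlap`. The returned window is the chosen cluster's
#' run (clipped to the epoch, not to the experimental interval).
#'
#' @inheritParams candidate_maps
#' @param innsim_min Inner-similarity threshold in `(0, 1]` (default 0.90).
#' @param min_dur_ms Minimum run duration in ms (default 60).
#' @param min_overlap Minimum fraction of the experimental interval the run
#'   must cover (default 0.3); a run essentially outside the measurement
#'   area is not a usable measurement window.
#' @param condition Optional condition tag carried into the result.
#' @return An `erp_window`: `start_ms`, `end_ms`, `duration_ms`, `cluster`,
#'   `inner_similarity`, `overlap`, `condition`, and the full `candidates`
#'   audit table.
#' @export
detect_window <- function(labels, x, interval_ms, innsim_min = 0.90,
                          min_dur_ms = 60, min_overlap = 0.3,
                          sfreq_hz, epoch_start_ms,
                          condition = NA_character_) {
  if (!(innsim_min > 0 && innsim_min <= 1))
    stop("innsim_min must be in (0, 1]", call. = FALSE)
  if (min_dur_ms <= 0) stop("min_dur_ms must be > 0", call. = FALSE)
  cand <- candidate_maps(labels, x, interval_ms, sfreq_hz, epoch_start_ms)
  # a run of m samples represents m sampling periods of signal, so the
  # duration filter uses the inclusive span m / sfreq
  span_ms <- cand$n_samples * 1000 / sfreq_hz
  ok <- cand$inner_similarity >= innsim_min & span_ms >= min_dur_ms &
    cand$overlap >= min_overlap
  ok[is.na(ok)] <- FALSE
  if (!any(ok)) {
    near <- if (nrow(cand)) cand[1, ] else NULL
    msg <- if (is.null(near)) "no candidate cluster intersects the interval"
    else sprintf(paste0("no qualifying candidate (nearest miss: cluster %d, ",
                        "inner similarity %.3f, duration %.1f ms)"),
                 near$cluster, near$inner_similarity, near$duration_ms)
    stop(structure(class = c("erp_no_window", "error", "condition"),
                   list(message = msg, call = sys.call(), candidates = cand)))
  }
  keep <- cand[ok, , drop = FALSE]
  best <- keep[which.max(keep$inner_similarity * keep$overlap), ]
  structure(
    list(start_ms = best$start_ms, end_ms = best$end_ms,
         duration_ms = best$duration_ms, cluster = best$cluster,
         inner_similarity = best$inner_similarity, overlap = best$overlap,
         condition = condition, candidates = cand),
    class = "erp_window"
  )
}

#' @export
print.erp_window <- function(x, ...) {
  cat(sprintf("<erp_window: [%.2f, %.2f] ms, cluster %d, InnSim %.3f, overlap %.2f>\n",
              x$start_ms, x$end_ms, x$cluster, x$inner_similarity, x$overlap))
  invisible(x)
}
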