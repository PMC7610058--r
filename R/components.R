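#' Describe one simulated ERP component
#'
#' A component is a scalp topography (sum of spatial Gaussians on the montage
#' layout) multiplied by a temporal envelope. Phasic components use a
#' raised-cosine envelope rising from `onset_ms` to `peak_ms` and falling to
#' `offset_ms`; the rise/fall halves can be sharpened or flattened with power
#' exponents, which lets a component's flanks be asymmetric the way real ERP
#' deflections are. Tonic components (ongoing background states) hold a
#' plateau over their support with short cosine ramps.
#'
#' @param name Component name (`"P1"`, `"N1"`, ..., or any custom label).
#' @param polarity `+1` or `-1`; the sign of the scalp map's main lobe.
#' @param onset_ms,peak_ms,offset_ms Support and peak latency in ms
#'   (`onset < peak < offset` for phasic components).
#' @param amplitude Peak amplitude in microvolt (> 0).
#' @param centers Matrix with columns `x`, `y` and optionally `w` (lobe
#'   weight, default 1): Gaussian lobe centres on the unit-disc layout.
#' @param width Spatial Gaussian width in layout units (> 0).
#' @param rise_exp,fall_exp Power exponents applied to the rising/falling
#'   raised-cosine half (1 = plain raised cosine).
#' @param shape `"phasic"` (default) or `"tonic"` (plateau with cosine ramps).
#' @param ramp_ms Ramp duration for tonic components.
#' @param area_fraction Signed-area fraction used to derive this component's
#'   ground-truth measurement window (`NA` for components that are not
#'   measurement targets).
#' @return An object of class `erp_component`.
#' @seealso [component_waveform()], [component_topography()],
#'   [signed_area_window()]
#' @export
component_spec <- function(name, polarity, onset_ms, peak_ms, offset_ms,
                           amplitude, centers, width,
                           rise_exp = 1, fall_exp = 1,
                           shape = c("phasic", "tonic"), ramp_ms = 20,
                           area_fraction = NA_real_) {
  shape <- match.arg(shape)
  if (!polarity %in% c(-1, 1)) stop("`polarity` must be +1 or -1", call. = FALSE)
  if (amplitude <= 0) stop("`amplitude` must be > 0", call. = FALSE)
  if (width <= 0) stop("`width` must be > 0", call. = FALSE)
  if (shape == "phasic" && !(onset_ms < peak_ms && peak_ms < offset_ms))
    stop("need onset_ms < peak_ms < offset_ms", call. = FALSE)
  if (shape == "tonic" && !(onset_ms < offset_ms))
    stop("need onset_ms < offset_ms", call. = FALSE)
  centers <- as.matrix(centers)
  if (ncol(centers) == 2L) centers <- cbind(centers, 1)
  colnames(centers) <- c("x", "y", "w")
  if (any(sqrt(centers[, 1]^2 + centers[, 2]^2) > 1 + 1e-8))
    stop("topography centre lies off the unit-disc layout", call. = FALSE)
  structure(
    list(name = name, polarity = polarity,
         onset_ms = onset_ms, peak_ms = peak_ms, offset_ms = offset_ms,
         amplitude = amplitude, centers = centers, width = width,
         rise_exp = rise_exp, fall_exp = fall_exp,
         shape = shape, ramp_ms = ramp_ms,
         area_fraction = area_fraction),
    class = "erp_component"
  )
}

#' Sample grid of an epoch
#'
#' Sample `i` (0-based) sits at `epoch_start_ms + i / sfreq_hz * 1000`;
#' the epoch holds `floor((end - start)/1000 * sfreq)` samples.
#'
#' @param sfreq_hz Sampling rate in Hz.
#' @param epoch_start_ms,epoch_end_ms Epoch limits in ms.
#' @return Numeric vector of sample times in ms.
#' @export
epoch_times <- function(sfreq_hz, epoch_start_ms, epoch_end_ms) {
  n_t <- floor((epoch_end_ms - epoch_start_ms) / 1000 * sfreq_hz)
  epoch_start_ms + (seq_len(n_t) - 1) / sfreq_hz * 1000
}

#' Temporal envelope of a component on an epoch grid
#'
#' @param spec An [component_spec()] object.
#' @param sfreq_hz Sampling rate (Hz).
#' @param epoch_start_ms,epoch_end_ms Epoch limits (ms); the component's
#'   support must lie inside the epoch.
#' @return Envelope values (microvolt) per sample; zero outside the support,
#'   peaking at `peak_ms` with value `amplitude`.
#' @export
component_waveform <- function(spec, sfreq_hz, epoch_start_ms, epoch_end_ms) {
  stopifnot(inherits(spec, "erp_component"))
  if (spec$onset_ms < epoch_start_ms || spec$offset_ms > epoch_end_ms)
    stop(sprintf("component '%s' support [%g, %g] outside epoch [%g, %g]",
                 spec$name, spec$onset_ms, spec$offset_ms,
                 epoch_start_ms, epoch_end_ms), call. = FALSE)
  tms <- epoch_times(sfreq_hz, epoch_start_ms, epoch_end_ms)
  spec$amplitude * envelope_at(spec, tms)
}

# Unit-height envelope at arbitrary times (ms); vectorised.
envelope_at <- function(spec, tms) {
  w <- numeric(length(tms))
  if (spec$shape == "tonic") {
    on <- spec$onset_ms; off <- spec$offset_ms; ramp <- spec$ramp_ms
    inside <- tms >= on & tms <= off
    w[inside] <- 1
    r1 <- tms >= on & tms < on + ramp
    w[r1] <- 0.5 * (1 - cos(pi * (tms[r1] - on) / ramp))
    r2 <- tms > off - ramp & tms <= off
    w[r2] <- pmin(w[r2], 0.5 * (1 - cos(pi * (off - tms[r2]) / ramp)))
    return(w)
  }
  rise <- tms >= spec$onset_ms & tms <= spec$peak_ms
  fall <- tms > spec$peak_ms & tms <= spec$offset_ms
  w[rise] <- (0.5 * (1 - cos(pi * (tms[rise] - spec$onset_ms) /
                               (spec$peak_ms - spec$onset_ms))))^spec$rise_exp
  w[fall] <- (0.5 * (1 + cos(pi * (tms[fall] - spec$peak_ms) /
                               (spec$offset_ms - spec$peak_ms))))^spec$fall_exp
  w
}

#' Scalp topography of a component
#'
#' The map is `polarity` times the weighted sum of spatial Gaussians centred
#' at `spec$centers`, re-referenced to the average (zero channel mean) and
#' scaled to unit maximum absolute value. Amplitude scaling lives in the
#' waveform, not the map.
#'
#' @param montage An `erp_montage`.
#' @param spec An `erp_component`.
#' @return Numeric vector, one value per channel.
#' @export
component_topography <- function(montage, spec) {
  stopifnot(inherits(montage, "erp_montage"), inherits(spec, "erp_component"))
  pos <- montage$positions
  v <- numeric(nrow(pos))
  for (j in seq_len(nrow(spec$centers))) {
    d2 <- (pos[, 1] - spec$centers[j, 1])^2 + (pos[, 2] - spec$centers[j, 2])^2
    v <- v + spec$centers[j, 3] * exp(-d2 / (2 * spec$width^2))
  }
  v <- spec$polarity * v
  v <- v - mean(v)
  v / max(abs(v))
}

#' Construct a time window
#'
#' @param start_ms,end_ms Window edges in ms (`start_ms <= end_ms`).
#' @return An `erp_time_window` list with `start_ms`, `end_ms`,
#'   `duration_ms`.
#' @export
time_window <- function(start_ms, end_ms) {
  if (start_ms > end_ms) stop("start_ms must be <= end_ms", call. = FALSE)
  structure(list(start_ms = start_ms, end_ms = end_ms,
                 duration_ms = end_ms - start_ms),
            class = "erp_time_window")
}

#' @export
print.erp_time_window <- function(x, ...) {
  cat(sprintf("[%.2f, %.2f] ms (duration %.2f ms)\n",
              x$start_ms, x$end_ms, x$duration_ms))
  invisible(x)
}

#' Signed-area measurement window of a deflection
#'
#' Finds the shortest contiguous sample interval containing the deflection's
#' extremum whose polarity-signed area reaches `area_fraction` of the total
#' signed area inside `search_interval_ms`. This is the standard signed-area
#' definition of an ERP measurement window and is how the simulator derives
#' ground-truth windows from its clean component templates.
#'
#' @param waveform Sampled waveform (one value per epoch sample).
#' @param polarity `+1` for positive deflections, `-1` for negative.
#' @param search_interval_ms Length-2 vector `[lo, hi]` in ms, inside the
#'   epoch.
#' @param area_fraction Fraction of the total signed area to capture
#'   (`0 < area_fraction <= 1`).
#' @param sfreq_hz,epoch_start_ms Grid parameters of `waveform`.
#' @return An `erp_time_window`; attribute `"samples"` holds the 1-based
#'   first/last sample indices.
#' @export
#' @examples
#' t <- epoch_times(429, -100, 600)
#' w <- as.numeric(t >= 100 & t <= 200)   # rectangular deflection
#' signed_area_window(w, +1, c(50, 300), 1, 429, -100)
signed_area_window <- function(waveform, polarity, search_interval_ms,
                               area_fraction, sfreq_hz, epoch_start_ms) {
  if (!(area_fraction > 0 && area_fraction <= 1))
    stop("`area_fraction` must be in (0, 1]", call. = FALSE)
  tms <- epoch_start_ms + (seq_along(waveform) - 1) / sfreq_hz * 1000
  if (search_interval_ms[1] < tms[1] - 1e-9 ||
      search_interval_ms[2] > tms[length(tms)] + 1e-9)
    stop("search interval outside the epoch", call. = FALSE)
  idx <- which(tms >= search_interval_ms[1] & tms <= search_interval_ms[2])
  v <- polarity * waveform[idx]
  if (max(v) <= 0)
    stop(structure(class = c("erp_no_window", "error", "condition"),
                   list(message = "no deflection of the requested polarity in the search interval",
                        call = sys.call())))
  total <- sum(v)
  ext <- which.max(v)
  cs <- c(0, cumsum(v))
  best <- NULL
  for (a in seq_len(ext)) {
    # earliest b >= ext reaching the target area for this start
    for (b in ext:length(v)) {
      if (cs[b + 1] - cs[a] >= area_fraction * total - 1e-12) {
        len <- b - a + 1
        if (is.null(best) || len < best[3] ||
            (len == best[3] && a < best[1])) best <- c(a, b, len)
        break
      }
    }
  }
  first <- idx[best[1]]; last <- idx[best[2]]
  tw <- time_window(tms[first], tms[last])
  attr(tw, "samples") <- c(first = first, last = last)
  tw
}
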