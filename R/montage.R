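#' Build a synthetic electrode montage on the unit disc
#'
#' Places `n_channels` electrodes quasi-uniformly on a unit-disc head layout
#' using a sunflower (Fibonacci) spiral. The layout is deterministic for a
#' given `(n_channels, seed)`; the seed is kept in the object for provenance.
#'
#' @param n_channels Number of electrodes (>= 2).
#' @param seed Integer recorded with the montage (layout itself is
#'   deterministic).
#' @return An object of class `erp_montage`: list with `labels` (unique
#'   channel names) and `positions` (`n_channels` x 2 matrix of x/y unit-disc
#'   coordinates).
#' @export
#' @examples
#' m <- make_montage(65)
#' nrow(m$positions)
make_montage <- function(n_channels, seed = 0L) {
  if (!is.numeric(n_channels) || length(n_channels) != 1L || n_channels < 2)
    stop("`n_channels` must be a single integer >= 2", call. = FALSE)
  f <- as.integer(n_channels)
  i <- seq_len(f)
  golden <- pi * (3 - sqrt(5))
  r <- sqrt((i - 0.5) / f)
  th <- i * golden
  pos <- cbind(x = r * cos(th), y = r * sin(th))
  labels <- sprintf("E%02d", i)
  structure(
    list(labels = labels, positions = pos, seed = as.integer(seed)),
    class = "erp_montage"
  )
}

#' @export
print.erp_montage <- function(x, ...) {
  cat(sprintf("<erp_montage: %d channels on unit disc>\n", length(x$labels)))
  invisible(x)
}

#' Plot a scalp topography on a montage
#'
#' Basic diagnostic plot: electrodes drawn on the head disc, coloured and
#' sized by voltage.
#'
#' @param montage An `erp_montage`.
#' @param values Per-channel values (same order as `montage$labels`).
#' @param main Plot title.
#' @export
plot_topography <- function(montage, values, main = "") {
  stopifnot(inherits(montage, "erp_montage"),
            length(values) == length(montage$labels))
  pal <- grDevices::colorRampPalette(c("blue", "white", "red"))(101)
  v <- values / max(abs(values), 1e-12)
  idx <- pmin(101L, pmax(1L, as.integer(round((v + 1) / 2 * 100)) + 1L))
  plot(montage$positions, pch = 21, cex = 1 + 1.5 * abs(v),
       bg = pal[idx], xlim = c(-1.2, 1.2), ylim = c(-1.2, 1.2),
       asp = 1, axes = FALSE, xlab = "", ylab = "", main = main)
  th <- seq(0, 2 * pi, length.out = 200)
  graphics::lines(cos(th), sin(th), col = "grey40")
  invisible(NULL)
}
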