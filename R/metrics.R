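#' Spatial correlation of two topographies
#'
#' Pearson correlation across channels; the standard similarity between scalp
#' maps. Invariant to adding a channel-constant and to positive rescaling.
#'
#' @param u,v Numeric vectors of equal length (>= 2) with nonzero variance.
#' @return Value in `[-1, 1]`.
#' @export
spatial_correlation <- function(u, v) {
  if (length(u) != length(v) || length(u) < 2)
    stop("topographies must have equal length >= 2", call. = FALSE)
  if (stats::sd(u) == 0 || stats::sd(v) == 0)
    stop("spatial correlation undefined for a zero-variance map", call. = FALSE)
  stats::cor(u, v)
}

#' Global field power
#'
#' Population standard deviation of a topography across channels.
#'
#' @param u Numeric vector (one topography).
#' @return Nonnegative scalar.
#' @export
gfp <- function(u) {
  sqrt(mean((u - mean(u))^2))
}

#' Global explained variance of a labelled topography series
#'
#' `sum_t (gfp(x_t) * cor(x_t, template[label_t]))^2 / sum_t gfp(x_t)^2`.
#' Templates default to cluster mean maps.
#'
#' @param x Time-points x channels matrix.
#' @param labels Integer cluster label per row.
#' @param templates Optional k x channels matrix of cluster templates.
#' @return Value in `[0, 1]`.
#' @export
gev <- function(x, labels, templates = NULL) {
  g <- apply(x, 1, gfp)
  if (all(g == 0)) stop("GEV undefined for all-zero data", call. = FALSE)
  if (is.null(templates)) {
    ids <- sort(unique(labels))
    templates <- t(vapply(ids, function(j)
      colMeans(x[labels == j, , drop = FALSE]), numeric(ncol(x))))
    labels <- match(labels, ids)
  }
  r <- vapply(seq_len(nrow(x)), function(i) {
    ti <- templates[labels[i], ]
    if (stats::sd(x[i, ]) == 0 || stats::sd(ti) == 0) return(0)
    stats::cor(x[i, ], ti)
  }, numeric(1))
  sum((g * r)^2) / sum(g^2)
}

# Correlation of each row of `x` against each row of `templates`,
# with zero-variance rows mapped to 0 (internal clustering workhorse).
row_template_correlation <- function(x, templates) {
  C <- suppressWarnings(stats::cor(t(x), t(templates)))
  C[!is.finite(C)] <- 0
  C
}
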