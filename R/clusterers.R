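#' Registered base clustering methods
#'
#' @return Character vector of the method names accepted by [run_base()].
#' @export
base_methods <- function() {
  c("kmeans", "hierarchical_corr", "fcm", "som",
    "diffusion_spectral", "modified_kmeans", "aahc")
}

#' Methods whose output depends on the seed
#' @return Character vector.
#' @export
stochastic_methods <- function() {
  c("kmeans", "fcm", "som", "diffusion_spectral", "modified_kmeans")
}

#' Parameters of a base clustering method
#'
#' @param method One of [base_methods()].
#' @param restarts Random restarts for methods that use them.
#' @param max_iter Iteration cap.
#' @param fuzziness Fuzzy c-means fuzziness exponent.
#' @param polarity_invariant Modified k-means: treat a map and its negation
#'   as the same state (eigenvector templates, squared-correlation
#'   assignment). Off by default: polarity is informative in ERPs.
#' @param som_epochs Training epochs of the 1-D SOM.
#' @param diffusion_time Diffusion time of the spectral embedding.
#' @return A `method_params` list.
#' @export
method_params <- function(method, restarts = 5L, max_iter = 100L,
                          fuzziness = 2, polarity_invariant = FALSE,
                          som_epochs = 10L, diffusion_time = 1) {
  method <- match.arg(method, base_methods())
  stopifnot(restarts >= 1, max_iter >= 1, fuzziness > 1)
  structure(list(method = method, restarts = as.integer(restarts),
                 max_iter = as.integer(max_iter), fuzziness = fuzziness,
                 polarity_invariant = polarity_invariant,
                 som_epochs = as.integer(som_epochs),
                 diffusion_time = diffusion_time),
            class = "method_params")
}

#' Canonicalize cluster labels
#'
#' Relabels clusters in order of first occurrence so that partitions can be
#' compared with plain equality.
#'
#' @param labels Integer (or factor) label vector.
#' @return Integer vector with labels `1..k` in first-occurrence order.
#' @export
canonicalize_labels <- function(labels) {
  match(labels, unique(labels))
}

new_partition <- function(labels, k, method, seed = NA_integer_) {
  structure(list(labels = canonicalize_labels(labels), k = as.integer(k),
                 method = method, seed = seed),
            class = "erp_partition")
}

#' @export
print.erp_partition <- function(x, ...) {
  cat(sprintf("<erp_partition: n = %d, k = %d, method = %s>\n",
              length(x$labels), x$k, x$method))
  invisible(x)
}

# Accept erp_partition or a bare label vector.
as_labels <- function(p) {
  if (inherits(p, "erp_partition")) p$labels else canonicalize_labels(p)
}

#' Run one base clustering method
#'
#' Hard-partitions the rows of `x` (time-points) into `k` clusters.
#' Correlation-based methods (`hierarchical_corr`, `modified_kmeans`, `aahc`)
#' operate on average-referenced rows, Euclidean methods on raw rows.
#' Deterministic given `(x, k, seed, params)`.
#'
#' @param x Time-points x channels matrix.
#' @param k Number of clusters (`2 <= k <= nrow(x)`).
#' @param method Method name or a [method_params()] object.
#' @param seed Seed for stochastic methods.
#' @return An `erp_partition`.
#' @export
run_base <- function(x, k, method = "kmeans", seed = 1L) {
  params <- if (inherits(method, "method_params")) method else method_params(method)
  if (k < 2 || k > nrow(x)) stop("need 2 <= k <= nrow(x)", call. = FALSE)
  if (!all(is.finite(x))) stop("`x` must be finite", call. = FALSE)
  labels <- switch(params$method,
    kmeans = cluster_kmeans(x, k, seed, params),
    hierarchical_corr = cluster_hierarchical_corr(x, k),
    fcm = cluster_fcm(x, k, seed, params),
    som = cluster_som(x, k, seed, params),
    diffusion_spectral = cluster_diffusion_spectral(x, k, seed, params),
    modified_kmeans = modified_kmeans(x, k, seed,
                                      polarity_invariant = params$polarity_invariant,
                                      restarts = params$restarts,
                                      max_iter = params$max_iter)$labels,
    aahc = aahc(x, k)$labels
  )
  new_partition(labels, k, params$method, as.integer(seed))
}

cluster_kmeans <- function(x, k, seed, params) {
  set.seed(seed)
  stats::kmeans(x, centers = k, nstart = params$restarts,
                iter.max = params$max_iter)$cluster
}

avg_reference_rows <- function(x) x - rowMeans(x)

cluster_hierarchical_corr <- function(x, k) {
  xr <- avg_reference_rows(x)
  C <- suppressWarnings(stats::cor(t(xr)))
  C[!is.finite(C)] <- 0
  d <- stats::as.dist(1 - C)
  stats::cutree(stats::hclust(d, method = "average"), k)
}

cluster_fcm <- function(x, k, seed, params) {
  set.seed(seed)
  fit <- e1071::cmeans(x, centers = k, iter.max = params$max_iter,
                       m = params$fuzziness)
  apply(fit$membership, 1, which.max)
}

# 1 x k linear self-organizing map, online training with a Gaussian
# neighbourhood shrinking over epochs; each unit is one cluster.
cluster_som <- function(x, k, seed, params) {
  set.seed(seed)
  n <- nrow(x)
  W <- x[sample.int(n, k), , drop = FALSE]
  n_ep <- params$som_epochs
  lr0 <- 0.5; sig0 <- k / 2
  for (ep in seq_len(n_ep)) {
    lr <- lr0 * (1 - ep / n_ep) + 0.01
    sig <- max(sig0 * (1 - ep / n_ep), 0.5)
    for (i in sample.int(n)) {
      d <- colSums((t(W) - x[i, ])^2)
      b <- which.min(d)
      h <- exp(-((seq_len(k) - b)^2) / (2 * sig^2))
      W <- W + lr * h * (matrix(x[i, ], k, ncol(x), byrow = TRUE) - W)
    }
  }
  apply(x, 1, function(row) which.min(colSums((t(W) - row)^2)))
}

cluster_diffusion_spectral <- function(x, k, seed, params) {
  set.seed(seed)
  D <- as.matrix(stats::dist(x))
  sig <- stats::median(D[upper.tri(D)])
  if (sig == 0) sig <- 1
  W <- exp(-D^2 / (2 * sig^2))
  diag(W) <- 0
  dg <- pmax(rowSums(W), .Machine$double.eps)
  S <- W / sqrt(dg %o% dg)
  ev <- eigen(S, symmetric = TRUE)
  U <- ev$vectors[, seq_len(k), drop = FALSE] / sqrt(dg)
  U <- U * rep(ev$values[seq_len(k)]^params$diffusion_time, each = nrow(U))
  stats::kmeans(U, centers = k, nstart = 5,
                iter.max = params$max_iter)$cluster
}

#' Microstate (modified) k-means
#'
#' Correlation-driven k-means on topographies: assignment maximizes the
#' spatial correlation with the cluster template (its square when
#' `polarity_invariant`); templates are updated as cluster mean maps, or as
#' the dominant eigenvector of the cluster's channelwise scatter when
#' `polarity_invariant`. Best of `restarts` random starts by GEV. Empty
#' clusters are re-seeded from the worst-fit time-point.
#'
#' @param x Time-points x channels matrix.
#' @param k Number of template maps.
#' @param seed RNG seed.
#' @param polarity_invariant Ignore map polarity (classical microstate form).
#' @param restarts,max_iter Restart count and iteration cap.
#' @return List with `labels`, `templates` (k x channels), `gev`, `k`.
#' @export
modified_kmeans <- function(x, k, seed = 1L, polarity_invariant = FALSE,
                            restarts = 5L, max_iter = 100L) {
  set.seed(seed)
  n <- nrow(x)
  xr <- avg_reference_rows(x)
  best <- NULL
  for (r in seq_len(restarts)) {
    tmpl <- xr[sample.int(n, k), , drop = FALSE]
    labels <- rep(0L, n)
    for (it in seq_len(max_iter)) {
      C <- row_template_correlation(xr, tmpl)
      score <- if (polarity_invariant) C^2 else C
      new_labels <- max.col(score, ties.method = "first")
      if (all(new_labels == labels)) break
      labels <- new_labels
      for (j in seq_len(k)) {
        members <- which(labels == j)
        if (!length(members)) {
          # re-seed an empty cluster from the worst-fit time-point
          fit <- score[cbind(seq_len(n), labels)]
          tmpl[j, ] <- xr[which.min(fit), ]
          next
        }
        xm <- xr[members, , drop = FALSE]
        if (polarity_invariant) {
          sc <- crossprod(xm)
          tmpl[j, ] <- eigen(sc, symmetric = TRUE)$vectors[, 1]
        } else {
          tmpl[j, ] <- colMeans(xm)
        }
      }
    }
    g <- gev_fast(xr, labels, tmpl)
    if (is.null(best) || g > best$gev)
      best <- list(labels = canonicalize_labels(labels),
                   templates = tmpl, gev = g, k = k)
  }
  best
}

# GEV without per-row sd checks (internal hot path).
gev_fast <- function(x, labels, tmpl) {
  g <- sqrt(rowMeans((x - rowMeans(x))^2))
  C <- row_template_correlation(x, tmpl)
  r <- C[cbind(seq_len(nrow(x)), labels)]
  sum((g * r)^2) / sum(g^2)
}

#' Atomize-and-agglomerate hierarchical clustering (AAHC)
#'
#' Starts from singleton clusters; repeatedly dissolves the cluster
#' contributing least to the global explained variance and reassigns each of
#' its members to the remaining cluster whose template map it correlates with
#' best, until `k` clusters remain. Deterministic.
#'
#' @param x Time-points x channels matrix.
#' @param k Target number of clusters (`<= nrow(x)`).
#' @return List with `labels`, `templates`, `k`.
#' @export
aahc <- function(x, k) {
  n <- nrow(x)
  if (k > n) stop("k > number of time-points", call. = FALSE)
  g <- apply(x, 1, gfp)
  xc <- avg_reference_rows(x)
  norms <- sqrt(rowSums(xc^2))
  norms[norms == 0] <- 1
  xn <- xc / norms
  labels <- seq_len(n)
  tmpl <- xn                      # row c = normalized template of cluster c
  active <- rep(TRUE, n)
  fit <- rep(1, n)                # cor(x_i, template of its cluster)
  while (sum(active) > k) {
    ids <- which(active)
    contrib <- vapply(ids, function(cl) {
      m <- labels == cl
      sum((g[m] * fit[m])^2)
    }, numeric(1))
    worst <- ids[which.min(contrib)]
    members <- which(labels == worst)
    active[worst] <- FALSE
    rest <- which(active)
    C <- xn[members, , drop = FALSE] %*% t(tmpl[rest, , drop = FALSE])
    target <- rest[max.col(C, ties.method = "first")]
    labels[members] <- target
    fit[members] <- C[cbind(seq_along(members), match(target, rest))]
    for (cl in unique(target)) {
      m <- labels == cl
      v <- colMeans(xc[m, , drop = FALSE])
      nv <- sqrt(sum(v^2)); if (nv == 0) nv <- 1
      tmpl[cl, ] <- v / nv
      fit[m] <- xn[m, , drop = FALSE] %*% tmpl[cl, ]
    }
  }
  lab <- canonicalize_labels(labels)
  ids <- sort(unique(lab))
  templates <- t(vapply(ids, function(j)
    colMeans(x[lab == j, , drop = FALSE]), numeric(ncol(x))))
  list(labels = lab, templates = templates, k = as.integer(k))
}
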