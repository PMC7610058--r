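#' Rand index of two partitions
#'
#' Fraction of object pairs on which two partitions agree (placed together in
#' both, or apart in both): `(N11 + N00) / (n (n - 1) / 2)`.
#'
#' @param a,b Label vectors (or `erp_partition`s) of equal length `n >= 2`.
#' @return Value in `[0, 1]`; 1 iff the partitions are identical up to
#'   relabelling.
#' @export
#' @examples
#' rand_index(c(1, 1, 2, 2), c(1, 2, 1, 2))   # 1/3
rand_index <- function(a, b) {
  a <- as_labels(a); b <- as_labels(b)
  n <- length(a)
  if (length(b) != n) stop("partitions have different lengths", call. = FALSE)
  if (n < 2) stop("need n >= 2", call. = FALSE)
  tab <- table(a, b)
  n11 <- sum(choose(tab, 2))
  n00 <- choose(n, 2) - sum(choose(rowSums(tab), 2)) -
    sum(choose(colSums(tab), 2)) + n11
  (n11 + n00) / choose(n, 2)
}

#' Co-association matrix of a partition ensemble
#'
#' Entry `(i, j)` is the fraction of partitions placing time-points `i` and
#' `j` in the same cluster — the substrate of the CSPA consensus function.
#'
#' @param partitions List of label vectors / `erp_partition`s of equal
#'   length.
#' @return `n x n` symmetric matrix with unit diagonal; attribute
#'   `"n_partitions"` records the ensemble size.
#' @export
coassociation <- function(partitions) {
  labs <- lapply(partitions, as_labels)
  if (!length(labs)) stop("need at least one partition", call. = FALSE)
  n <- length(labs[[1]])
  if (any(vapply(labs, length, 1L) != n))
    stop("partitions have different lengths", call. = FALSE)
  M <- matrix(0, n, n)
  for (l in labs) M <- M + outer(l, l, "==")
  M <- M / length(labs)
  attr(M, "n_partitions") <- length(labs)
  M
}

#' CSPA consensus partition
#'
#' Cluster-based similarity partitioning: average-linkage agglomeration on
#' the distance `1 - coassociation`, cut at `k`. Deterministic in its inputs
#' and invariant to relabelling of the member partitions.
#'
#' @param partitions List of label vectors / `erp_partition`s.
#' @param k Number of consensus clusters.
#' @return An `erp_partition` (method `"cspa"`).
#' @export
cspa <- function(partitions, k) {
  M <- coassociation(partitions)
  n <- nrow(M)
  if (k > n) stop("k > number of time-points", call. = FALSE)
  if (k < 2) stop("k must be >= 2", call. = FALSE)
  lab <- stats::cutree(stats::hclust(stats::as.dist(1 - M), method = "average"), k)
  new_partition(lab, k, "cspa")
}

#' Stabilize a stochastic clusterer by consensus over repetitions
#'
#' Runs the base method `Mr` times with derived sub-seeds. For `r = 2..Mr`
#' the consensus of the first `r` runs is formed with [cspa()] and its
#' mutual similarity to the previous consensus is measured with
#' [rand_index()] (`R_r`). The chosen repetition count `r_opt` is the
#' smallest `r` in `3..(Mr-1)` with
#' `max(|R_r - R_{r-1}|, |R_r - R_{r+1}|) <= eps` and
#' `min(R_{r-1}, R_r, R_{r+1}) >= tau`; if no `r` qualifies, `r_opt = Mr`
#' and `converged = FALSE`.
#'
#' @param x Time-points x channels matrix (typically the grand average).
#' @param k Number of clusters.
#' @param method Method name or [method_params()]. Deterministic methods are
#'   allowed and trivially stabilize (`R_r` identically 1).
#' @param Mr Maximum repetitions (>= 4).
#' @param tau Similarity threshold on the Rand scale (default 0.90).
#' @param eps Maximum allowed change between successive similarities
#'   (default 0.03).
#' @param seed Master seed; repeat `r` uses `derive_seed(seed, "rep", r)`.
#' @return An `erp_stabilization`: `r_opt`, `R_series` (values for
#'   `r = 2..Mr`), `partition` (consensus at `r_opt`), `converged`, `runs`.
#' @export
stabilize_method <- function(x, k, method = "kmeans", Mr = 20L,
                             tau = 0.90, eps = 0.03, seed = 1L) {
  if (Mr < 4) stop("Mr must be >= 4", call. = FALSE)
  params <- if (inherits(method, "method_params")) method else method_params(method)
  runs <- lapply(seq_len(Mr), function(r)
    run_base(x, k, params, seed = derive_seed(seed, "rep", r)))
  consensus <- vector("list", Mr)
  R <- rep(NA_real_, Mr)            # R[r] = R_r, defined for r >= 2
  consensus[[1]] <- runs[[1]]
  for (r in 2:Mr) {
    consensus[[r]] <- cspa(runs[seq_len(r)], k)
    R[r] <- rand_index(consensus[[r]], consensus[[r - 1]])
  }
  r_opt <- NA_integer_; converged <- FALSE
  for (r in 3:(Mr - 1)) {
    if (max(abs(R[r] - R[r - 1]), abs(R[r] - R[r + 1])) <= eps &&
        min(R[r - 1], R[r], R[r + 1]) >= tau) {
      r_opt <- r; converged <- TRUE; break
    }
  }
  if (!converged) r_opt <- Mr
  structure(
    list(method = params$method, r_opt = as.integer(r_opt),
         R_series = R[2:Mr], converged = converged,
         partition = consensus[[r_opt]], runs = runs,
         tau = tau, eps = eps, Mr = as.integer(Mr), seed = as.integer(seed)),
    class = "erp_stabilization"
  )
}

#' @export
print.erp_stabilization <- function(x, ...) {
  cat(sprintf("<erp_stabilization: %s, r_opt = %d (%s)>\n", x$method, x$r_opt,
              if (x$converged) "converged" else "not converged"))
  invisible(x)
}

# Stabilized partition of one dataset at a known repetition count:
# consensus of r_opt runs for stochastic methods, plain run otherwise.
stabilized_partition <- function(x, k, method, r_opt, seed) {
  if (method %in% stochastic_methods() && r_opt > 1) {
    runs <- lapply(seq_len(r_opt), function(r)
      run_base(x, k, method, seed = derive_seed(seed, "rep", r)))
    p <- cspa(runs, k)
    p$method <- paste0("stabilized_", method)
    p
  } else {
    run_base(x, k, method, seed = seed)
  }
}

#' Select base methods by similarity to a benchmark clusterer
#'
#' Clusters every subject's concatenated data with each candidate method and
#' the benchmark (modified k-means by default; stochastic methods
#' stabilized), measures per-subject Rand similarity to the benchmark, and
#' keeps the candidates that reach `sim_threshold` on at least a `majority`
#' fraction of subjects. The benchmark is always selected. Repetition counts
#' are calibrated once on the grand average.
#'
#' @param study An `erp_study`.
#' @param k Number of clusters.
#' @param candidates Character vector of candidate methods.
#' @param benchmark Benchmark method (default `"modified_kmeans"`).
#' @param sim_threshold Rand similarity a subject must reach (default 0.8).
#' @param majority Minimum fraction of subjects above threshold
#'   (default 0.5).
#' @param Mr,tau,eps Stabilization parameters (see [stabilize_method()]).
#' @param seed Master seed.
#' @return An `erp_selection`: `rand` (subjects x candidates), `counts`,
#'   `selected`, `r_opt` per method, and cached per-subject `partitions`.
#' @export
select_methods <- function(study, k,
                           candidates = c("kmeans", "hierarchical_corr", "aahc"),
                           benchmark = "modified_kmeans",
                           sim_threshold = 0.8, majority = 0.5,
                           Mr = 20L, tau = 0.90, eps = 0.03, seed = 1L) {
  stopifnot(inherits(study, "erp_study"))
  p <- length(study$subjects)
  xbar <- grand_average(study)
  all_methods <- unique(c(benchmark, candidates))
  r_opt <- vapply(all_methods, function(m) {
    if (m %in% stochastic_methods())
      stabilize_method(xbar, k, m, Mr = Mr, tau = tau, eps = eps,
                       seed = derive_seed(seed, "stab", m))$r_opt
    else 1L
  }, integer(1))
  partitions <- lapply(seq_len(p), function(i) {
    xi <- study$subjects[[i]]$concat
    ps <- lapply(all_methods, function(m)
      stabilized_partition(xi, k, m, r_opt[[m]],
                           seed = derive_seed(seed, "subject", i, m)))
    names(ps) <- all_methods
    ps
  })
  rand <- t(vapply(partitions, function(ps)
    vapply(candidates, function(m) rand_index(ps[[m]], ps[[benchmark]]),
           numeric(1)),
    numeric(length(candidates))))
  if (length(candidates) == 1L) rand <- matrix(rand, ncol = 1L,
                                               dimnames = list(NULL, candidates))
  counts <- colSums(rand >= sim_threshold)
  selected <- candidates[counts / p >= majority]
  structure(
    list(rand = rand, counts = counts, selected = selected,
         benchmark = benchmark, sim_threshold = sim_threshold,
         majority = majority, r_opt = r_opt, partitions = partitions,
         seed = as.integer(seed)),
    class = "erp_selection"
  )
}

#' @export
print.erp_selection <- function(x, ...) {
  cat("<erp_selection>\n  counts:",
      paste(sprintf("%s=%d", names(x$counts), x$counts), collapse = ", "),
      "\n  selected:", paste(x$selected, collapse = ", "),
      sprintf("(+ benchmark %s)\n", x$benchmark))
  invisible(x)
}

#' Subject-level consensus partition
#'
#' CSPA consensus over the selected methods' (stabilized) partitions of one
#' subject's concatenated matrix.
#'
#' @param x The subject's time-points x channels matrix.
#' @param methods Character vector of methods entering the consensus.
#' @param k Number of clusters.
#' @param seed Seed for the stochastic members.
#' @param r_opt Named repetition counts (from stabilization); default 1 each.
#' @return An `erp_partition`.
#' @export
subject_consensus <- function(x, methods, k, seed = 1L, r_opt = NULL) {
  if (!length(methods)) stop("no methods to combine", call. = FALSE)
  ps <- lapply(methods, function(m)
    stabilized_partition(x, k, m, (r_opt[[m]] %||% 1L),
                         seed = derive_seed(seed, m)))
  if (length(ps) == 1L) return(ps[[1]])
  out <- cspa(ps, k)
  out$method <- "subject_consensus"
  out
}

#' Group-level consensus partition
#'
#' CSPA consensus across subject-level partitions. All partitions must share
#' the common concatenated epoch grid.
#'
#' @param partitions List of subject partitions.
#' @param k Number of clusters.
#' @return An `erp_partition`.
#' @export
group_consensus <- function(partitions, k) {
  if (!length(partitions)) stop("no subject partitions", call. = FALSE)
  out <- cspa(partitions, k)
  out$method <- "group_consensus"
  out
}

#' Choose the number of clusters by time-window quality
#'
#' Runs the full pipeline for every `k` in `k_range` and scores each by the
#' mean of `inner_similarity x overlap` of the detected windows over target
#' components and conditions; returns the arg-max with the quality trace.
#'
#' @param study An `erp_study`.
#' @param k_range Integer vector of candidate cluster counts.
#' @param config Pipeline configuration, see [pipeline_config()].
#' @return List with `k` (chosen), `quality` (named trace), `results`.
#' @export
choose_k <- function(study, k_range, config = pipeline_config()) {
  if (!length(k_range)) stop("empty k_range", call. = FALSE)
  quality <- stats::setNames(numeric(length(k_range)), k_range)
  results <- list()
  for (i in seq_along(k_range)) {
    cfg <- config
    cfg$k <- k_range[i]
    res <- run_pipeline(study, cfg)
    w <- res$group_windows
    quality[i] <- if (nrow(w)) mean(w$inner_similarity * w$overlap) else 0
    results[[as.character(k_range[i])]] <- res
  }
  list(k = k_range[which.max(quality)], quality = quality, results = results)
}
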