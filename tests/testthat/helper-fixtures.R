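# Shared fixtures. Everything is generated in code; nothing is read from disk.

# k well-separated template maps (rows) on f channels, average-referenced
make_templates <- function(k, f, seed = 1) {
  set.seed(seed)
  m <- matrix(rnorm(k * f), k, f)
  m <- m - rowMeans(m)
  q <- qr.Q(qr(t(m)))[, seq_len(k)]     # orthonormal in channel space
  t(q) - rowMeans(t(q))
}

# n_per points per template, each an exact template scaled by a random
# positive factor, plus optional isotropic noise
template_series <- function(k = 3, f = 12, n_per = 10, noise_sd = 0,
                            seed = 1) {
  tmpl <- make_templates(k, f, seed)
  set.seed(seed + 1)
  labels <- rep(seq_len(k), each = n_per)
  scales <- runif(k * n_per, 0.8, 1.2)
  x <- tmpl[labels, , drop = FALSE] * scales
  if (noise_sd > 0) x <- x + matrix(rnorm(length(x), 0, noise_sd), nrow(x))
  list(x = x, labels = labels, templates = tmpl)
}

# two far-separated blobs of topographies: distinct spatial patterns far
# apart in both Euclidean and correlation geometry
blob_fixture <- function(n_per = 20, f = 5, sep = 50, seed = 1) {
  tm <- make_templates(2, f, seed)
  set.seed(seed)
  x <- tm[rep(1:2, each = n_per), ] * sep +
    matrix(rnorm(2 * n_per * f), 2 * n_per, f)
  list(x = x, labels = rep(1:2, each = n_per))
}

# O(n^2) pair-enumeration Rand index, independent of the package route
rand_oracle <- function(a, b) {
  n <- length(a)
  agree <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    same_a <- a[i] == a[j]
    same_b <- b[i] == b[j]
    if (same_a == same_b) agree <- agree + 1
  }
  agree / (n * (n - 1) / 2)
}

# exhaustive signed-area window: scan every contiguous interval containing
# the extremum, keep the shortest reaching the area target
signed_area_oracle <- function(w, polarity, idx, frac) {
  v <- polarity * w[idx]
  ext <- which.max(v)
  total <- sum(v)
  best <- NULL
  for (a in seq_len(ext)) for (b in ext:length(v)) {
    if (sum(v[a:b]) >= frac * total - 1e-12) {
      len <- b - a + 1
      if (is.null(best) || len < best$len ||
          (len == best$len && a < best$a)) best <- list(a = a, b = b, len = len)
    }
  }
  idx[c(best$a, best$b)]
}

# small complete study for pipeline-level tests (full channel count, fewer
# subjects)
small_study <- function(n_subjects = 4, seed = 3, snr_db = 20,
                        jitter = 5) {
  simulate_study(study_spec(n_subjects = n_subjects, snr_db = snr_db,
                            jitter_max_samples = jitter, seed = seed))
}

# The paper-scale run used by the acceptance tests is expensive; compute it
# once per test session.
.acceptance_env <- new.env(parent = emptyenv())
acceptance_run <- function() {
  if (is.null(.acceptance_env$res)) {
    study <- simulate_study(study_spec(seed = 1))
    res <- run_pipeline(study, pipeline_config(seed = derive_seed(1, "pipeline")))
    .acceptance_env$study <- study
    .acceptance_env$res <- res
  }
  list(study = .acceptance_env$study, res = .acceptance_env$res)
}
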