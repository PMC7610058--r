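#' Write a study to a directory of TSV matrices plus a manifest
#'
#' One tab-separated matrix per subject and condition (header row = channel
#' labels) and a `manifest.json` recording subjects, groups, condition
#' order, grid metadata, the seed and any ground-truth windows.
#'
#' @param study An `erp_study`.
#' @param dir Output directory (created if needed).
#' @return The manifest path, invisibly.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- list()
  for (s in study$subjects) {
    for (cond in study$conditions) {
      fn <- sprintf("%s_%s.tsv", s$id, cond)
      m <- s$data[[cond]]
      colnames(m) <- study$montage$labels
      utils::write.table(m, file.path(dir, fn), sep = "\t",
                         row.names = FALSE, quote = FALSE)
      files[[paste(s$id, cond, sep = "/")]] <- fn
    }
  }
  gt <- lapply(study$ground_truth, function(cond)
    lapply(cond, function(w) list(start_ms = w$start_ms, end_ms = w$end_ms)))
  targets <- tryCatch(default_targets(study), error = function(e) NULL)
  manifest <- list(
    subjects = vapply(study$subjects, `[[`, "", "id"),
    groups = vapply(study$subjects, `[[`, "", "group"),
    conditions = study$conditions,
    sfreq_hz = study$sfreq_hz,
    epoch_start_ms = study$epoch_start_ms,
    epoch_end_ms = study$epoch_end_ms,
    n_t = study$n_t,
    channels = study$montage$labels,
    montage_xy = unname(apply(study$montage$positions, 1, function(r) r,
                              simplify = FALSE)),
    seed = study$spec$seed,
    files = files,
    ground_truth = gt,
    targets = targets)
  path <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read a study from a directory written by [write_study()]
#'
#' Validates that every matrix carries the manifest's channel header and row
#' count; mismatches are reported with the offending file named.
#'
#' @param dir Directory containing `manifest.json` and the TSV matrices.
#' @return An `erp_study` (without a simulator spec; `ground_truth` restored
#'   from the manifest).
#' @export
read_study <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = TRUE)
  channels <- manifest$channels
  n_t <- manifest$n_t
  subjects <- vector("list", length(manifest$subjects))
  for (i in seq_along(manifest$subjects)) {
    id <- manifest$subjects[i]
    data <- list()
    for (cond in manifest$conditions) {
      fn <- file.path(dir, manifest$files[[paste(id, cond, sep = "/")]])
      m <- utils::read.table(fn, sep = "\t", header = TRUE,
                             check.names = FALSE, colClasses = "numeric")
      if (!identical(colnames(m), channels))
        stop(sprintf("channel header mismatch in '%s'", fn), call. = FALSE)
      if (nrow(m) != n_t)
        stop(sprintf("row-count mismatch in '%s': %d != %d",
                     fn, nrow(m), n_t), call. = FALSE)
      data[[cond]] <- as.matrix(m)
    }
    concat <- do.call(rbind, data[manifest$conditions])
    dimnames(concat) <- NULL
    subjects[[i]] <- list(id = id, group = manifest$groups[i],
                          data = lapply(data, function(x) {
                            dimnames(x) <- NULL; x
                          }),
                          concat = concat, jitter = NULL)
  }
  pos <- manifest$montage_xy
  if (is.list(pos)) pos <- do.call(rbind, pos)
  pos <- as.matrix(pos)
  colnames(pos) <- c("x", "y")
  montage <- structure(list(labels = channels, positions = pos, seed = NA_integer_),
                       class = "erp_montage")
  gt <- lapply(manifest$ground_truth, function(cond)
    lapply(cond, function(w) time_window(w$start_ms, w$end_ms)))
  targets <- lapply(manifest$targets, function(tg)
    list(interval_ms = as.numeric(tg$interval_ms),
         electrodes = as.character(tg$electrodes)))
  structure(
    list(montage = montage, sfreq_hz = manifest$sfreq_hz,
         epoch_start_ms = manifest$epoch_start_ms,
         epoch_end_ms = manifest$epoch_end_ms,
         n_t = n_t, conditions = manifest$conditions,
         subjects = subjects, ground_truth = gt,
         targets = if (length(targets)) targets else NULL,
         topographies = NULL, spec = NULL),
    class = "erp_study"
  )
}

#' Write pipeline outputs with a checksummed manifest
#'
#' Writes the group and subject partitions (two-column TSV: sample index,
#' cluster), the detected windows (TSV + JSON), the TOST/ANOVA reports
#' (JSON) and a manifest with an MD5 checksum per artifact.
#'
#' @param result An `erp_pipeline_result`.
#' @param dir Output directory.
#' @param coassoc Optional co-association matrix to dump as TSV.
#' @return The manifest path, invisibly.
#' @export
write_outputs <- function(result, dir, coassoc = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character()
  wr_tsv <- function(df, fn) {
    utils::write.table(df, file.path(dir, fn), sep = "\t",
                       row.names = FALSE, quote = FALSE)
    paths[[fn]] <<- fn
  }
  wr_tsv(data.frame(sample = seq_along(result$group_partition$labels),
                    cluster = result$group_partition$labels),
         "group_partition.tsv")
  for (i in seq_along(result$subject_partitions))
    wr_tsv(data.frame(sample = seq_along(result$subject_partitions[[i]]$labels),
                      cluster = result$subject_partitions[[i]]$labels),
           sprintf("subject_partition_%02d.tsv", i))
  wr_tsv(result$group_windows, "group_windows.tsv")
  wr_tsv(result$subject_windows, "subject_windows.tsv")
  jsonlite::write_json(result$group_windows, file.path(dir, "group_windows.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  paths[["group_windows.json"]] <- "group_windows.json"
  reports <- list(tost = result$tost,
                  anova = lapply(result$anova, function(a) a$effects),
                  methods_used = result$methods_used,
                  config = result$config[c("k", "Mr", "tau", "eps",
                                           "sim_threshold", "innsim_min",
                                           "min_dur_ms", "delta_ms", "seed")])
  jsonlite::write_json(reports, file.path(dir, "reports.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows",
                       pretty = TRUE)
  paths[["reports.json"]] <- "reports.json"
  if (!is.null(coassoc)) {
    utils::write.table(round(coassoc, 6), file.path(dir, "coassociation.tsv"),
                       sep = "\t", row.names = FALSE, col.names = FALSE)
    paths[["coassociation.tsv"]] <- "coassociation.tsv"
  }
  sums <- tools::md5sum(file.path(dir, unlist(paths)))
  manifest <- list(artifacts = lapply(seq_along(paths), function(i)
    list(file = unname(unlist(paths)[i]), md5 = unname(sums[i]))),
    seed = result$config$seed,
    package_version = as.character(utils::packageVersion("erpconsensus")))
  path <- file.path(dir, "outputs_manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Reload a windows TSV written by [write_outputs()]
#'
#' @param path Path to `group_windows.tsv` / `subject_windows.tsv`.
#' @return `data.frame` with the original column types.
#' @export
read_windows <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
}
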