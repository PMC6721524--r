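#' Read and write arm count matrices (TSV)
#'
#' TSV layout: first column `sample`, remaining columns one per arm,
#' integer cells.
#'
#' @param m Count matrix (samples x arms) with dimnames.
#' @param path File path.
#' @return `read_arm_counts` returns the integer matrix; writers return
#'   the path invisibly.
#' @export
write_arm_counts <- function(m, path) {
  df <- data.frame(sample = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_arm_counts
#' @export
read_arm_counts <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (names(df)[1L] != "sample")
    stop(sprintf("%s: first column must be 'sample', found '%s'",
                 path, names(df)[1L]))
  m <- as.matrix(df[, -1L, drop = FALSE])
  if (any(is.na(m)) || any(m != round(m)) || any(m < 0))
    stop(sprintf("%s: count cells must be non-negative integers", path))
  storage.mode(m) <- "integer"
  rownames(m) <- df$sample
  m
}

#' Read and write binned log2-ratio tracks (BED-like TSV)
#'
#' Columns: `arm`, `start`, `end`, `log2ratio`; 0-based half-open
#' coordinates; bins must be sorted and non-overlapping within arm.
#'
#' @param bins `bin_series` data frame.
#' @param path File path.
#' @export
write_bins <- function(bins, path) {
  utils::write.table(bins[, c("arm", "start", "end", "log2ratio")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_bins
#' @export
read_bins <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("arm", "start", "end", "log2ratio")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop(sprintf("%s: missing column(s) %s", path, paste(miss, collapse = ", ")))
  bad <- which(df$end <= df$start)
  if (length(bad))
    stop(sprintf("%s: line %d: empty or inverted bin", path, bad[1L] + 1L))
  for (a in unique(df$arm)) {
    sub <- df[df$arm == a, ]
    if (is.unsorted(sub$start))
      stop(sprintf("%s: bins of arm %s are not sorted", path, a))
    if (nrow(sub) > 1L && any(sub$start[-1L] < sub$end[-nrow(sub)]))
      stop(sprintf("%s: overlapping bins on arm %s", path, a))
  }
  class(df) <- c("bin_series", "data.frame")
  df
}

#' Read a clinical cohort (patients + samples CSV pair)
#'
#' Validates the documented column dictionaries: `patients.csv` needs
#' `patient`, `os_months`, `os_event`, `pfs_months`, `pfs_event`;
#' `samples.csv` needs `patient`, `sample`, `week`, `category`.
#'
#' @param patients_path,samples_path CSV paths.
#' @return List with `patients` and `samples` data frames.
#' @export
read_cohort <- function(patients_path, samples_path) {
  pat <- utils::read.csv(patients_path, stringsAsFactors = FALSE)
  smp <- utils::read.csv(samples_path, stringsAsFactors = FALSE)
  need_p <- c("patient", "os_months", "os_event", "pfs_months", "pfs_event")
  need_s <- c("patient", "sample", "week", "category")
  miss_p <- setdiff(need_p, names(pat))
  if (length(miss_p))
    stop(sprintf("%s: missing column(s) %s", patients_path,
                 paste(miss_p, collapse = ", ")))
  miss_s <- setdiff(need_s, names(smp))
  if (length(miss_s))
    stop(sprintf("%s: missing column(s) %s", samples_path,
                 paste(miss_s, collapse = ", ")))
  bad_cat <- setdiff(unique(smp$category),
                     c("baseline", "treatment", "progression"))
  if (length(bad_cat))
    stop(sprintf("%s: unknown timepoint category %s", samples_path,
                 paste(bad_cat, collapse = ", ")))
  list(patients = pat, samples = smp)
}

#' Run the full pipeline end to end on simulated data
#'
#' simulate -> score -> estimate tumor fraction -> clinical analysis, with
#' every artifact written under `out_dir` and listed, with its MD5
#' checksum, in a JSON run manifest.  Re-running with the same seed and
#' configuration reproduces identical outputs.
#'
#' @param cfg [sim_config()].
#' @param seed Master seed (defaults to `cfg$seed`).
#' @param out_dir Output directory (created if absent); `NULL` skips all
#'   file output.
#' @param cutoffs Candidate z-score cutoffs for the survival scan.
#' @return List of class `pipeline_run`: `cohort`, `scores`, `tf`
#'   (per-sample estimates), `concordance`, `scan`, `cox`, `lmm`,
#'   `spearman`, `manifest`.
#' @export
run_end_to_end <- function(cfg = sim_config(), seed = cfg$seed,
                           out_dir = NULL, cutoffs = c(2, 3, 4, 5)) {
  t0 <- Sys.time()
  cohort <- simulate_longitudinal_cohort(cfg, seed = seed)
  scores <- score_samples(cohort$counts, cohort$panel)
  tf_hat <- vapply(cohort$bins, function(b)
    fit_tumor_fraction(segment_bins(b, min_gap = 3 * cfg$bin_noise_sd))$tf,
    numeric(1))
  tf_tab <- data.frame(sample = names(tf_hat), tf_hat = unname(tf_hat),
                       stringsAsFactors = FALSE)
  merged <- merge(merge(cohort$samples, scores, by = "sample"),
                  tf_tab, by = "sample")
  conc <- concordance_analysis(merged$Z, merged$tf_hat)

  pat <- cohort$patients
  base <- merged[merged$category == "baseline", ]
  base <- base[match(pat$patient, base$patient), ]
  scan <- scan_cutoffs(base$Z, pat$os_months, pat$os_event,
                       pat$pfs_months, pat$pfs_event, cutoffs = cutoffs)
  cox <- cox_ph(pat$os_months, pat$os_event,
                data.frame(zgroup = as.integer(base$Z >= scan$selected),
                           subtype = pat$subtype))
  lmm <- lmm_random_intercept(merged, value_col = "Z",
                              omit_post_progression = TRUE)
  sp <- spearman_matrix(merged[, c("Z", "ctc", "cea", "ca153")])

  run <- list(cohort = cohort, scores = scores, tf = tf_tab,
              concordance = conc, scan = scan, cox = cox, lmm = lmm,
              spearman = sp, manifest = NULL)
  class(run) <- "pipeline_run"

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    fp <- function(f) file.path(out_dir, f)
    write_arm_counts(cohort$controls, fp("controls.tsv"))
    write_arm_counts(cohort$counts, fp("arm_counts.tsv"))
    utils::write.csv(pat, fp("patients.csv"), row.names = FALSE)
    utils::write.csv(cohort$samples, fp("samples.csv"), row.names = FALSE)
    utils::write.table(scores, fp("scores.tsv"), sep = "\t", quote = FALSE,
                       row.names = FALSE)
    utils::write.table(merged, fp("merged.tsv"), sep = "\t", quote = FALSE,
                       row.names = FALSE)
    utils::write.table(scan$table, fp("cutoff_scan.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(round(sp$r, 3), fp("spearman.tsv"), sep = "\t",
                       quote = TRUE)
    jsonlite::write_json(
      list(selected_cutoff = scan$selected,
           concordance = conc,
           lmm_means = lmm$means,
           lmm_wald_p = lmm$wald_overall$p,
           cox = data.frame(term = names(cox$hr), hr = cox$hr,
                            p = cox$p)),
      fp("analysis.json"), auto_unbox = TRUE, digits = NA, pretty = TRUE)
    files <- list.files(out_dir, full.names = TRUE)
    files <- files[!grepl("manifest\\.json$", files)]
    manifest <- list(
      seed = seed,
      config_hash = unname(digest_config(cfg)),
      created = format(t0, "%Y-%m-%dT%H:%M:%S"),
      files = data.frame(file = basename(files),
                         md5 = unname(tools::md5sum(files)),
                         stringsAsFactors = FALSE))
    jsonlite::write_json(manifest, fp("manifest.json"), auto_unbox = TRUE,
                         pretty = TRUE)
    run$manifest <- manifest
  }
  run
}

# stable hash of the configuration via its serialized text form
digest_config <- function(cfg) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(yaml::as.yaml(unclass(cfg)), tmp)
  unname(tools::md5sum(tmp))
}

#' @export
print.pipeline_run <- function(x, ...) {
  cat("End-to-end pipeline run\n")
  print(x$cohort)
  cat(sprintf("  cohort-wide Z ~ tf concordance: r = %.3f, R^2 = %.3f\n",
              x$concordance$spearman_r[1L], x$concordance$r_squared[1L]))
  cat(sprintf("  selected z-score cutoff: %g (OS log-rank p = %.4f)\n",
              x$scan$selected,
              x$scan$table$p_os[x$scan$table$cutoff == x$scan$selected]))
  invisible(x)
}
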