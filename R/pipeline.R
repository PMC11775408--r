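# End-to-end drivers: markers over a cohort manifest, cohort comparison
# reports, in-memory cohort simulation and replicate rejection-rate studies.

#' Compute markers for every subject and condition of a manifest
#'
#' Per-subject failures are logged as warnings and skipped; the run fails only
#' if no subject succeeds. Outputs one CSV row per subject x condition.
#'
#' @param manifest path to a manifest CSV or a data.frame from
#'   [read_manifest()].
#' @param out_csv optional output CSV path.
#' @param target_spacing isotropic analysis spacing, mm; `NULL` selects, per
#'   pair, the smallest native axis spacing, floored at 0.5 mm.
#' @return data.frame of marker rows; attribute `n_failed` counts skipped
#'   subject-conditions.
#' @export
run_markers <- function(manifest, out_csv = NULL, target_spacing = NULL) {
  df <- if (is.character(manifest)) read_manifest(manifest) else manifest
  if (nrow(df) == 0) stop("empty manifest", call. = FALSE)
  rows <- list()
  failed <- 0L
  for (i in seq_len(nrow(df))) {
    paths <- c(highquality = df$highquality_path[i], clinical = df$clinical_path[i])
    masks <- list()
    tgt <- target_spacing
    ok <- TRUE
    for (cond in names(paths)) {
      masks[[cond]] <- tryCatch(load_mask(paths[[cond]]), error = function(e) {
        warning(sprintf("subject %s (%s): %s", df$subject_id[i], cond,
                        conditionMessage(e)), call. = FALSE)
        NULL
      })
      if (is.null(masks[[cond]])) ok <- FALSE
    }
    if (ok && is.null(tgt))
      tgt <- max(min(c(masks$highquality$spacing, masks$clinical$spacing)), 0.5)
    for (cond in names(paths)) {
      if (!ok || is.null(masks[[cond]])) { failed <- failed + 1L; next }
      row <- tryCatch(
        markers_as_row(compute_markers(masks[[cond]], target_spacing = tgt),
                       subject_id = df$subject_id[i], condition = cond),
        error = function(e) {
          warning(sprintf("subject %s (%s): %s", df$subject_id[i], cond,
                          conditionMessage(e)), call. = FALSE)
          NULL
        })
      if (is.null(row)) failed <- failed + 1L else rows[[length(rows) + 1L]] <- row
    }
  }
  if (length(rows) == 0) stop("no subject could be processed", call. = FALSE)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (!is.null(out_csv)) write.csv(out, out_csv, row.names = FALSE)
  attr(out, "n_failed") <- failed
  out
}

#' Cohort comparison reports
#'
#' Builds the paired table, runs the main comparison, the volume-threshold
#' sensitivity comparison, and writes per-marker Bland-Altman tables.
#'
#' @param markers marker data.frame from [run_markers()] or a CSV path.
#' @param out_dir optional directory for report CSVs.
#' @param threshold_cm3 sensitivity volume threshold (cm^3); default 10.
#' @param alpha significance level.
#' @return list with `main` and `sensitivity` (class `cohort_comparison`) and
#'   `paired_table`.
#' @export
run_comparison <- function(markers, out_dir = NULL, threshold_cm3 = 10, alpha = 0.05) {
  df <- if (is.character(markers)) read.csv(markers, stringsAsFactors = FALSE) else markers
  tab <- build_paired_table(df)
  main <- compare_cohort(tab, alpha = alpha)
  sens_tab <- sensitivity_filter(tab, threshold_cm3 = threshold_cm3)
  sens <- if (length(unique(sens_tab$subject_id)) >= 5)
    compare_cohort(sens_tab, alpha = alpha) else NULL
  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    write.csv(main$summary, file.path(out_dir, "comparison.csv"), row.names = FALSE)
    if (!is.null(sens))
      write.csv(sens$summary, file.path(out_dir, "comparison_sensitivity.csv"),
                row.names = FALSE)
    for (mk in names(main$bland_altman)) {
      ba <- main$bland_altman[[mk]]$points
      ba$subject_id <- sort(unique(tab$subject_id))
      write.csv(ba[, c("subject_id", "mean", "difference")],
                file.path(out_dir, sprintf("bland_altman_%s.csv", mk)),
                row.names = FALSE)
    }
  }
  list(main = main, sensitivity = sens, paired_table = tab)
}

#' Simulate a paired cohort in memory and compute its markers
#'
#' The fast path used by replicate studies: no files are written; the
#' generator, degradation and marker pipeline are identical to
#' [make_paired_cohort()] + [run_markers()].
#'
#' @param scenario a [scenario()].
#' @param n_subjects cohort size.
#' @param master_seed integer seed.
#' @param calibration optional precomputed [calibrate_threshold()] curves
#'   (list with `hq`, `cl`); computed from the scenario when `NULL`.
#' @return marker data.frame (one row per subject x condition).
#' @export
simulate_cohort_markers <- function(scenario, n_subjects, master_seed,
                                    calibration = NULL) {
  if (is.null(calibration)) calibration <- scenario_calibration(scenario)
  rows <- vector("list", 2L * n_subjects)
  for (i in seq_len(n_subjects)) {
    sub <- simulate_subject(scenario, derive_seed(master_seed, i), calibration)
    sid <- sprintf("S%03d", i)
    rows[[2 * i - 1]] <- markers_as_row(
      compute_markers(sub$highquality, target_spacing = scenario$target_spacing),
      subject_id = sid, condition = "highquality")
    rows[[2 * i]] <- markers_as_row(
      compute_markers(sub$clinical, target_spacing = scenario$target_spacing),
      subject_id = sid, condition = "clinical")
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Replicate-cohort rejection rates
#'
#' Runs `n_cohorts` independent cohorts of `n_subjects` under a scenario and
#' records, per marker, the fraction of cohorts whose paired Wilcoxon test
#' rejects at `alpha`, plus the fraction rejecting with the high-quality
#' condition in the stated direction (higher volume/CI/FD, lower
#' convexity/solidity).
#'
#' @param scenario a [scenario()].
#' @param n_cohorts number of replicate cohorts.
#' @param n_subjects subjects per cohort.
#' @param master_seed integer seed.
#' @param alpha significance level.
#' @return data.frame: `marker`, `rejection_rate`, `directional_rate`,
#'   `mean_diff`.
#' @export
rejection_rates <- function(scenario, n_cohorts, n_subjects = 28L,
                            master_seed = 1L, alpha = 0.05) {
  calib <- scenario_calibration(scenario)
  rej <- setNames(numeric(length(MARKER_NAMES)), MARKER_NAMES)
  dir_rej <- rej
  dsum <- rej
  up <- c(volume_ml = 1, convexity = -1, solidity = -1,
          concavity_index = 1, fractal_dimension = 1)
  for (r in seq_len(n_cohorts)) {
    mk <- simulate_cohort_markers(scenario, n_subjects,
                                  derive_seed(master_seed, 5000L + r), calib)
    tab <- build_paired_table(mk)
    for (nm in MARKER_NAMES) {
      tt <- tab[tab$marker_name == nm, ]
      wt <- tryCatch(wilcoxon_signed_rank(tt$value_highquality, tt$value_clinical),
                     error = function(e) list(p = 1))
      d_med <- median(tt$value_highquality - tt$value_clinical)
      hit <- !is.na(wt$p) && wt$p <= alpha
      rej[nm] <- rej[nm] + hit
      dir_rej[nm] <- dir_rej[nm] + (hit && sign(d_med) == up[nm])
      dsum[nm] <- dsum[nm] + mean(tt$value_highquality - tt$value_clinical)
    }
  }
  data.frame(marker = MARKER_NAMES,
             rejection_rate = as.numeric(rej) / n_cohorts,
             directional_rate = as.numeric(dir_rej) / n_cohorts,
             mean_diff = as.numeric(dsum) / n_cohorts,
             stringsAsFactors = FALSE)
}
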