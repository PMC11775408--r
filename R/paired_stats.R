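MARKER_NAMES <- c("volume_ml", "convexity", "solidity",
                  "concavity_index", "fractal_dimension")

#' Median and interquartile range
#'
#' Percentiles by linear interpolation between order statistics
#' (`stats::quantile` type 7, the inclusive convention).
#'
#' @param values numeric vector, n >= 1.
#' @return named numeric: `median`, `q25`, `q75`.
#' @export
median_iqr <- function(values) {
  v <- as.numeric(values)
  if (length(v) == 0 || any(!is.finite(v))) stop("need at least one finite value", call. = FALSE)
  q <- quantile(v, c(0.5, 0.25, 0.75), type = 7, names = FALSE)
  c(median = q[1], q25 = q[2], q75 = q[3])
}

#' Paired Wilcoxon signed-rank test
#'
#' Differences d = a - b; zero differences are dropped (classical treatment);
#' absolute differences are ranked with mid-ranks for ties;
#' W = min(W+, W-). For n_effective <= 25 the two-sided p-value is exact over
#' all 2^n sign assignments, computed by convolution of the doubled-rank
#' generating polynomial (identical to full enumeration, tie-safe); above
#' that, a normal approximation with tie and continuity correction is used.
#' With fewer than 5 non-zero differences the statistic is returned with
#' `p = NA`.
#'
#' @param a,b paired measurements, or `a` a two-column matrix with `b` NULL.
#' @return list: `statistic` (W), `w_plus`, `p`, `n_effective`, `method`.
#' @export
wilcoxon_signed_rank <- function(a, b = NULL) {
  if (is.null(b)) { b <- a[, 2]; a <- a[, 1] }
  d <- as.numeric(a) - as.numeric(b)
  if (any(!is.finite(d))) stop("non-finite differences", call. = FALSE)
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) stop("degenerate input: all differences are zero", call. = FALSE)
  r <- rank(abs(d))
  w_plus <- sum(r[d > 0])
  w_minus <- sum(r[d < 0])
  W <- min(w_plus, w_minus)
  if (n < 5)
    return(list(statistic = W, w_plus = w_plus, p = NA_real_,
                n_effective = n, method = "too few pairs"))
  if (n <= 25) {
    r2 <- as.integer(round(2 * r))        # doubled ranks are integers under mid-ranks
    T2 <- sum(r2)
    dp <- numeric(T2 + 1)
    dp[1] <- 1
    for (ri in r2) {
      shifted <- c(numeric(ri), dp[seq_len(T2 + 1 - ri)])
      dp <- (dp + shifted) / 2
    }
    centre <- T2 / 2
    dev <- abs(2 * w_plus - centre)
    p <- sum(dp[abs(seq(0, T2) - centre) >= dev - 1e-9])
    p <- min(1, p)
    method <- "exact (sign-assignment enumeration)"
  } else {
    Tsum <- sum(r)
    mu <- Tsum / 2
    sdv <- sqrt(sum(r^2) / 4)             # mid-ranks embed the tie correction
    z <- (w_plus - mu)
    z <- (z - sign(z) * 0.5) / sdv        # continuity correction toward the mean
    p <- min(1, 2 * pnorm(-abs(z)))
    method <- "normal approximation (tie + continuity corrected)"
  }
  list(statistic = W, w_plus = w_plus, p = p, n_effective = n, method = method)
}

#' Bland-Altman agreement statistics
#'
#' Differences d = a - b; limits of agreement are the mean difference plus or
#' minus 1.96 sample standard deviations (n - 1 denominator).
#'
#' @param a,b paired measurements.
#' @return list: `mean_diff`, `sd_diff`, `loa_low`, `loa_high`, `n`, and a
#'   data.frame `points` with per-pair means and differences.
#' @export
bland_altman <- function(a, b) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) != length(b) || length(a) < 2) stop("need at least 2 pairs", call. = FALSE)
  d <- a - b
  m <- mean(d)
  s <- if (length(d) > 1) sd(d) else 0
  list(mean_diff = m, sd_diff = s,
       loa_low = m - 1.96 * s, loa_high = m + 1.96 * s,
       n = length(d),
       points = data.frame(mean = (a + b) / 2, difference = d))
}

#' @importFrom stats sd
NULL

#' Build a paired cohort table from a marker data.frame
#'
#' @param markers data.frame as written by [run_markers()]: columns
#'   `subject_id`, `condition` (`"highquality"` / `"clinical"`), and the five
#'   marker columns.
#' @return long data.frame: `subject_id`, `marker_name`, `value_highquality`,
#'   `value_clinical` (one row per subject x marker, both values finite).
#' @export
build_paired_table <- function(markers) {
  stopifnot(all(c("subject_id", "condition") %in% names(markers)))
  hq <- markers[markers$condition == "highquality", , drop = FALSE]
  cl <- markers[markers$condition == "clinical", , drop = FALSE]
  common <- intersect(hq$subject_id, cl$subject_id)
  if (length(common) == 0) stop("no complete subject pairs", call. = FALSE)
  hq <- hq[match(common, hq$subject_id), ]
  cl <- cl[match(common, cl$subject_id), ]
  out <- do.call(rbind, lapply(MARKER_NAMES, function(mk) {
    data.frame(subject_id = common, marker_name = mk,
               value_highquality = hq[[mk]], value_clinical = cl[[mk]],
               stringsAsFactors = FALSE)
  }))
  ok <- is.finite(out$value_highquality) & is.finite(out$value_clinical)
  if (!all(ok)) stop("non-finite marker values in paired table", call. = FALSE)
  rownames(out) <- NULL
  out
}

#' Volume-based sensitivity filter
#'
#' Removes every marker row of subjects whose total lesion volume is below
#' `threshold_cm3` in either condition (so the paired design stays intact),
#' mirroring a sensitivity analysis that excludes small lesions whose shape
#' estimates are dominated by few voxels.
#'
#' @param table paired cohort table from [build_paired_table()].
#' @param threshold_cm3 volume threshold in cm^3 (= mL); default 10.
#' @return filtered table (attribute `n_excluded` records removals).
#' @export
sensitivity_filter <- function(table, threshold_cm3 = 10) {
  vol <- table[table$marker_name == "volume_ml", , drop = FALSE]
  subs <- unique(table$subject_id)
  if (!setequal(vol$subject_id, subs))
    stop("table lacks volume_ml rows for some subjects", call. = FALSE)
  keep <- vol$subject_id[vol$value_highquality >= threshold_cm3 &
                         vol$value_clinical >= threshold_cm3]
  out <- table[table$subject_id %in% keep, , drop = FALSE]
  attr(out, "n_excluded") <- length(subs) - length(keep)
  attr(out, "threshold_cm3") <- threshold_cm3
  rownames(out) <- NULL
  out
}

#' Cohort-level paired comparison
#'
#' Per marker: median and IQR per condition, paired Wilcoxon signed-rank test
#' and Bland-Altman agreement (high-quality minus clinical). No
#' multiple-testing correction is applied (five markers at the stated alpha).
#'
#' @param table paired cohort table from [build_paired_table()].
#' @param alpha significance level; default 0.05.
#' @return object of class `cohort_comparison`: list with `summary`
#'   (data.frame shaped like a per-marker report), `bland_altman` (named list
#'   of per-marker results), `n`, `alpha`.
#' @export
compare_cohort <- function(table, alpha = 0.05) {
  if (!is.numeric(alpha) || alpha < 0 || alpha > 1) stop("alpha must lie in [0,1]", call. = FALSE)
  subs <- unique(table$subject_id)
  if (length(subs) < 5) stop("need at least 5 complete pairs", call. = FALSE)
  ba <- list()
  rows <- lapply(MARKER_NAMES, function(mk) {
    tt <- table[table$marker_name == mk, , drop = FALSE]
    tt <- tt[order(tt$subject_id), , drop = FALSE]   # order-invariant output
    qa <- median_iqr(tt$value_highquality)
    qb <- median_iqr(tt$value_clinical)
    wt <- tryCatch(wilcoxon_signed_rank(tt$value_highquality, tt$value_clinical),
                   error = function(e) list(statistic = NA_real_, p = 1, n_effective = 0,
                                            method = conditionMessage(e)))
    bb <- bland_altman(tt$value_highquality, tt$value_clinical)
    ba[[mk]] <<- bb
    data.frame(marker = mk,
               median_highquality = qa["median"], q25_highquality = qa["q25"],
               q75_highquality = qa["q75"],
               median_clinical = qb["median"], q25_clinical = qb["q25"],
               q75_clinical = qb["q75"],
               W = wt$statistic, p_value = wt$p, n = nrow(tt),
               significant = !is.na(wt$p) & wt$p <= alpha,
               mean_diff = bb$mean_diff, loa_low = bb$loa_low, loa_high = bb$loa_high,
               stringsAsFactors = FALSE)
  })
  summary <- do.call(rbind, rows)
  rownames(summary) <- NULL
  structure(list(summary = summary, bland_altman = ba,
                 n = length(subs), alpha = alpha,
                 metadata = list(zero_differences = "dropped",
                                 sided = "two-sided",
                                 percentile_type = 7L,
                                 multiple_testing = "none")),
            class = "cohort_comparison")
}

#' @export
print.cohort_comparison <- function(x, ...) {
  cat(sprintf("Paired cohort comparison (n = %d, alpha = %g)\n", x$n, x$alpha))
  s <- x$summary
  for (i in seq_len(nrow(s))) {
    cat(sprintf("  %-18s HQ %7.3f (%.3f-%.3f)  CL %7.3f (%.3f-%.3f)  p = %s%s\n",
                s$marker[i],
                s$median_highquality[i], s$q25_highquality[i], s$q75_highquality[i],
                s$median_clinical[i], s$q25_clinical[i], s$q75_clinical[i],
                format(signif(s$p_value[i], 3)),
                ifelse(isTRUE(s$significant[i]), " *", "")))
  }
  invisible(x)
}

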