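# Aggregation and comparison logic of the paired design: slice-level metric
# records are averaged to subject level, subject-level values to cohort level
# (unweighted), overall and per vendor; methods are compared against each
# other and against the two clinical-significance anchors (the original
# low-vs-high baseline, and the repeat-scan IDP variability floor).

#' Build slice-level metric records
#'
#' The atom of all aggregation: one row per
#' (subject, vendor, comparison, metric, psi, slice).
#'
#' @param subject_id,vendor,comparison,metric Character scalars/vectors.
#' @param psi Threshold for IDP rows, `NA` otherwise.
#' @param slice Slice index.
#' @param value Metric value.
#' @return A `data.frame` with class `metric_records`.
#' @export
metric_records <- function(subject_id, vendor, comparison, metric,
                           psi = NA_real_, slice = NA_integer_, value) {
  df <- data.frame(subject_id = subject_id, vendor = vendor,
                   comparison = comparison, metric = metric, psi = psi,
                   level = "slice", slice = slice, value = value,
                   stringsAsFactors = FALSE)
  class(df) <- c("metric_records", "data.frame")
  df
}

psi_key <- function(psi) ifelse(is.na(psi), "none", as.character(psi))

#' Aggregate slice records to subject and cohort level
#'
#' Averages slice values per subject, then subject values per cohort
#' (unweighted means, matching a slices-then-subjects averaging scheme), for
#' each comparison present; cohort means are also stratified by vendor. All
#' rows must share one metric (and one psi for IDP) — mixing metrics in one
#' aggregation call is an error.
#'
#' @param records Slice-level `metric_records`.
#' @return A list with `subject` (one row per subject x comparison), `cohort`
#'   (one row per comparison, `vendor = "all"`), and `by_vendor` (one row per
#'   vendor x comparison), each carrying `n` counts.
#' @export
aggregate_records <- function(records) {
  if (nrow(records) == 0) stopf("no records to aggregate")
  if (length(unique(records$metric)) != 1)
    stopf("mixed metrics in one aggregation call")
  if (length(unique(psi_key(records$psi))) != 1)
    stopf("mixed psi thresholds in one aggregation call")
  subj <- stats::aggregate(value ~ subject_id + vendor + comparison + metric + psi,
                           data = transform(records, psi = psi_key(psi)),
                           FUN = mean)
  subj$level <- "subject"
  coh <- stats::aggregate(value ~ comparison + metric + psi, data = subj, FUN = mean)
  coh$n <- stats::aggregate(value ~ comparison + metric + psi, data = subj,
                            FUN = length)$value
  coh$vendor <- "all"
  coh$level <- "cohort"
  byv <- stats::aggregate(value ~ vendor + comparison + metric + psi,
                          data = subj, FUN = mean)
  byv$n <- stats::aggregate(value ~ vendor + comparison + metric + psi,
                            data = subj, FUN = length)$value
  byv$level <- "cohort"
  list(subject = subj, cohort = coh, by_vendor = byv)
}

#' Pairwise comparison of two methods on the same subjects
#'
#' Paired comparison of subject-level (or slice-level) metric values between
#' two comparisons (methods). `paired_t` runs a paired t-test on subject-level
#' differences with its analytic 95% CI. `cluster_robust` regresses the
#' slice-level differences on an intercept and uses subject-clustered robust
#' (CR) standard errors, with t critical values on (clusters - 1) degrees of
#' freedom. Two-sided p-values.
#'
#' @param records_a,records_b Slice-level `metric_records` for the two
#'   methods, covering the same subjects (same metric and psi).
#' @param method `"paired_t"` or `"cluster_robust"`.
#' @param conf_level Confidence level (default 0.95).
#' @return A list of class `pairwise_comparison`: `metric`, `psi`,
#'   `method_a`, `method_b`, `mean_difference` (a minus b), `ci95`,
#'   `p_value`, `n_subjects`, `stat_method`.
#' @export
compare_pairwise <- function(records_a, records_b,
                             method = c("paired_t", "cluster_robust"),
                             conf_level = 0.95) {
  method <- match.arg(method)
  if (length(unique(c(records_a$metric, records_b$metric))) != 1)
    stopf("records must share one metric")
  subj <- sort(intersect(unique(records_a$subject_id), unique(records_b$subject_id)))
  if (length(subj) == 0) stopf("non-overlapping subject sets")
  if (!setequal(unique(records_a$subject_id), unique(records_b$subject_id)))
    stopf("both comparisons must cover the same subjects")
  out <- list(metric = records_a$metric[1], psi = records_a$psi[1],
              method_a = records_a$comparison[1],
              method_b = records_b$comparison[1],
              n_subjects = length(subj), stat_method = method)
  if (method == "paired_t") {
    va <- vapply(subj, function(s) mean(records_a$value[records_a$subject_id == s]), 0)
    vb <- vapply(subj, function(s) mean(records_b$value[records_b$subject_id == s]), 0)
    d <- va - vb
    m <- mean(d)
    if (any(!is.finite(d))) {
      # infinite metric values (e.g. PSNR of an exact-copy oracle) make the
      # paired test degenerate: report the sign, not a t statistic
      out$mean_difference <- m
      out$ci95 <- c(m, m)
      out$p_value <- if (is.nan(m) || m == 0) 1 else 0
      return(structure(out, class = "pairwise_comparison"))
    }
    if (stats::sd(d) < .Machine$double.eps * max(1, abs(m))) {
      # zero-variance differences: degenerate CI; p = 1 if no shift, else
      # below any representable two-sided threshold
      out$mean_difference <- m
      out$ci95 <- c(m, m)
      out$p_value <- if (m == 0) 1 else 0
    } else {
      tt <- stats::t.test(va, vb, paired = TRUE, conf.level = conf_level)
      out$mean_difference <- unname(tt$estimate)
      out$ci95 <- as.numeric(tt$conf.int)
      out$p_value <- tt$p.value
    }
  } else {
    key_a <- paste(records_a$subject_id, records_a$slice)
    b_map <- stats::setNames(records_b$value, paste(records_b$subject_id, records_b$slice))
    if (!all(key_a %in% names(b_map)))
      stopf("cluster_robust needs matching (subject, slice) rows in both sets")
    d <- records_a$value - as.numeric(b_map[key_a])
    cl <- records_a$subject_id
    fit <- stats::lm(d ~ 1)
    vc <- sandwich::vcovCL(fit, cluster = cl)
    ct <- lmtest::coeftest(fit, vcov. = vc, df = length(unique(cl)) - 1)
    se <- ct[1, 2]
    m <- ct[1, 1]
    tcrit <- stats::qt(1 - (1 - conf_level) / 2, df = length(unique(cl)) - 1)
    out$mean_difference <- m
    out$ci95 <- c(m - tcrit * se, m + tcrit * se)
    out$p_value <- ct[1, 4]
  }
  structure(out, class = "pairwise_comparison")
}

#' @export
print.pairwise_comparison <- function(x, ...) {
  cat(sprintf("%s vs %s [%s%s]: diff=%.5g, 95%% CI (%.5g, %.5g), p=%.3g (%s, n=%d)\n",
              x$method_a, x$method_b, x$metric,
              if (is.na(x$psi)) "" else sprintf(", psi=%s", format(x$psi)),
              x$mean_difference, x$ci95[1], x$ci95[2], x$p_value,
              x$stat_method, x$n_subjects))
  invisible(x)
}

better_direction <- function(metric) {
  # lower is better for idp/perceptual, higher for psnr/ssim
  if (metric %in% c("idp", "perceptual")) "lower" else "higher"
}

#' Anchor-point analysis
#'
#' Scores every method against the two clinical-significance anchors:
#' \enumerate{
#'   \item the baseline comparison between the original low-field and
#'     high-field images — a method "beats the baseline" when its index is
#'     statistically significantly better (one-sided paired test at `alpha`)
#'     than the baseline index;
#'   \item the repeat-scan IDP — the measurement-variability floor; each
#'     method's cohort IDP is reported as a signed gap above that floor
#'     (positive expected; smaller is better, and a gap below the floor is
#'     flagged).
#' }
#'
#' @param records Slice-level `metric_records` for all methods including the
#'   baseline comparison.
#' @param repeat_records Slice-level IDP records for repeat-scan pairs
#'   (>= 2 subjects).
#' @param baseline Name of the baseline comparison
#'   (default `"orig1.5_vs_3"`).
#' @param alpha Significance level for anchor 1 (default 0.001).
#' @return A list of class `anchor_report`: `baseline_subject_values`,
#'   `repeat_scan_idp` (cohort mean), and `verdicts` (one row per method x
#'   metric x psi with `beats_baseline`, `p_value`, `gap_to_repeat_baseline`,
#'   `below_repeat_floor`).
#' @export
anchor_analysis <- function(records, repeat_records, baseline = "orig1.5_vs_3",
                            alpha = 0.001) {
  if (!baseline %in% records$comparison)
    stopf("missing baseline comparison '%s'", baseline)
  if (length(unique(repeat_records$subject_id)) < 2)
    stopf("repeat-scan records must cover >= 2 subjects")
  rep_agg <- aggregate_records(repeat_records)
  rep_idp <- rep_agg$cohort$value[1]
  rep_psi <- repeat_records$psi[1]
  keys <- unique(records[records$comparison != baseline,
                         c("comparison", "metric", "psi")])
  verdicts <- NULL
  for (i in seq_len(nrow(keys))) {
    k <- keys[i, ]
    sel <- records$metric == k$metric & psi_key(records$psi) == psi_key(k$psi)
    meth <- records[sel & records$comparison == k$comparison, ]
    base <- records[sel & records$comparison == baseline, ]
    if (nrow(base) == 0) next
    cmp <- compare_pairwise(meth, base, method = "paired_t")
    dir <- better_direction(k$metric)
    # one-sided p in the "method better than baseline" direction
    improves <- isTRUE(if (dir == "lower") cmp$mean_difference < 0
                       else cmp$mean_difference > 0)
    p_one <- if (improves) cmp$p_value / 2 else 1 - cmp$p_value / 2
    beats <- improves && p_one < alpha
    # anchor 2 is only meaningful at the repeat records' own threshold
    gap <- if (k$metric == "idp" && psi_key(k$psi) == psi_key(rep_psi)) {
      m_coh <- aggregate_records(meth)$cohort$value[1]
      m_coh - rep_idp
    } else NA_real_
    verdicts <- rbind(verdicts, data.frame(
      comparison = k$comparison, metric = k$metric, psi = k$psi,
      mean_difference_vs_baseline = cmp$mean_difference,
      p_value = p_one, beats_baseline = beats,
      gap_to_repeat_baseline = gap,
      below_repeat_floor = !is.na(gap) & gap < 0,
      stringsAsFactors = FALSE))
  }
  base_subj <- aggregate_records(
    records[records$comparison == baseline &
              records$metric == records$metric[1] &
              psi_key(records$psi) == psi_key(records$psi[1]), ])$subject
  structure(list(baseline = baseline, alpha = alpha,
                 baseline_subject_values = base_subj,
                 repeat_scan_idp = rep_idp, verdicts = verdicts),
            class = "anchor_report")
}

#' Rank methods by cohort-level metric value
#'
#' Sorts methods by their cohort mean: ascending for IDP and perceptual
#' distance (lower is better), descending for PSNR and SSIM. Ties are broken
#' alphabetically and flagged.
#'
#' @param records Slice-level `metric_records` (one metric, one psi) covering
#'   >= 2 comparisons.
#' @param metric,psi Select which records to rank (defaults: take from the
#'   records).
#' @return A data frame ordered best-first with columns `comparison`, `value`,
#'   `rank`, `tied`.
#' @export
rank_methods <- function(records, metric = records$metric[1], psi = NULL) {
  if (!metric %in% c("psnr", "ssim", "perceptual", "idp"))
    stopf("unknown metric '%s'", metric)
  sel <- records$metric == metric
  if (!is.null(psi)) sel <- sel & psi_key(records$psi) == psi_key(psi)
  records <- records[sel, ]
  if (length(unique(records$comparison)) < 2)
    stopf("ranking needs >= 2 methods")
  coh <- aggregate_records(records)$cohort
  decreasing <- better_direction(metric) == "higher"
  ord <- order(coh$value, coh$comparison, decreasing = c(decreasing, FALSE),
               method = "radix")
  coh <- coh[ord, ]
  coh$rank <- seq_len(nrow(coh))
  coh$tied <- duplicated(coh$value) | duplicated(coh$value, fromLast = TRUE)
  coh[, c("comparison", "value", "rank", "tied")]
}

#' Gray-level difference overlay
#'
#' Marks every pixel with at least one quantized gray level of difference
#' between a reference and a candidate slice; the count equals
#' `idp(pair, psi = 0)$n_qualifying` on the same pair, and the marked set is
#' symmetric in the two inputs.
#'
#' @param reference,candidate Slices (float `[0,1]` matrices or integer
#'   `[0,255]` matrices) of matched dimensions.
#' @return A list with `overlay` (logical matrix) and `count`.
#' @export
difference_overlay <- function(reference, candidate) {
  pr <- quantized_pair(reference, candidate)
  ov <- abs(pr$reference - pr$candidate) >= 1
  list(overlay = ov, count = sum(ov))
}
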