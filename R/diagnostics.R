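#' Validate / normalize a per-vessel record table
#'
#' Checks the columns the evaluation functions rely on and flags gray-zone
#' vessels (invasive FFR in `[0.75, 0.80]`, where classification is least
#' certain).
#'
#' @param records tibble with at least `ctp_ffr` and `invasive_ffr` in
#'   (0, 1]; optionally `qca_percent`, `cac_class`, `vessel_name`,
#'   `lesion_location`, `patient_id`.
#' @return the tibble with a `gray_zone` logical column appended.
#' @export
vessel_records <- function(records) {
  records <- as_tibble(records)
  stopifnot(all(c("ctp_ffr", "invasive_ffr") %in% names(records)))
  for (col in c("ctp_ffr", "invasive_ffr")) {
    v <- records[[col]]
    if (any(!is.finite(v)) || any(v <= 0) || any(v > 1)) {
      abort(sprintf("`%s` must lie in (0, 1]", col),
            class = "ctpffr_domain_error")
    }
  }
  if ("qca_percent" %in% names(records) &&
      (any(records$qca_percent < 30) || any(records$qca_percent > 90))) {
    abort("`qca_percent` must lie in [30, 90]", class = "ctpffr_domain_error")
  }
  records$gray_zone <- records$invasive_ffr >= 0.75 &
    records$invasive_ffr <= 0.80
  records
}

#' Cross-classify index against reference FFR at a threshold
#'
#' A vessel is positive (hemodynamically significant) when its FFR is at or
#' below the threshold; the boundary value 0.80 itself is positive.
#'
#' @param records a [vessel_records()] table.
#' @param index_threshold positivity cutoff for `ctp_ffr`. Default 0.80.
#' @param reference_threshold cutoff for `invasive_ffr`. Default 0.80.
#' @param index column name of the index test. Default `"ctp_ffr"`.
#' @return a list of class `confusion_table`: `tp`, `fp`, `tn`, `fn`.
#' @export
classify <- function(records, index_threshold = 0.80,
                     reference_threshold = 0.80, index = "ctp_ffr") {
  if (nrow(records) == 0) abort("no records", class = "ctpffr_domain_error")
  pred <- records[[index]] <= index_threshold
  ref <- records$invasive_ffr <= reference_threshold
  confusion_table(tp = sum(pred & ref), fp = sum(pred & !ref),
                  tn = sum(!pred & !ref), fn = sum(!pred & ref))
}

#' @rdname classify
#' @param tp,fp,tn,fn cell counts.
#' @export
confusion_table <- function(tp, fp, tn, fn) {
  counts <- c(tp = tp, fp = fp, tn = tn, fn = fn)
  stopifnot(all(counts >= 0), sum(counts) > 0)
  structure(as.list(counts), class = "confusion_table")
}

#' @export
print.confusion_table <- function(x, ...) {
  cat(sprintf("<confusion_table> TP %d  FP %d  TN %d  FN %d (n = %d)\n",
              x$tp, x$fp, x$tn, x$fn, x$tp + x$fp + x$tn + x$fn))
  invisible(x)
}

#' Diagnostic metrics with exact binomial confidence intervals
#'
#' Sensitivity, specificity, accuracy, PPV and NPV with Clopper-Pearson
#' 95% CIs. A metric with a zero denominator is reported as `NA` (undefined)
#' rather than 0.
#'
#' @param table a [confusion_table()].
#' @param conf_level confidence level. Default 0.95.
#' @return tibble: `metric`, `numerator`, `denominator`, `estimate`,
#'   `conf_low`, `conf_high`.
#' @export
confusion_metrics <- function(table, conf_level = 0.95) {
  with(table, {
    defs <- list(
      sensitivity = c(tp, tp + fn),
      specificity = c(tn, tn + fp),
      accuracy = c(tp + tn, tp + fp + tn + fn),
      ppv = c(tp, tp + fp),
      npv = c(tn, tn + fn)
    )
    purrr::imap_dfr(defs, function(d, name) {
      if (d[2] == 0) {
        return(tibble(metric = name, numerator = d[1], denominator = 0,
                      estimate = NA_real_, conf_low = NA_real_,
                      conf_high = NA_real_))
      }
      ci <- stats::binom.test(d[1], d[2], conf.level = conf_level)$conf.int
      tibble(metric = name, numerator = d[1], denominator = d[2],
             estimate = d[1] / d[2], conf_low = ci[1], conf_high = ci[2])
    })
  })
}

#' ROC curve area with DeLong variance
#'
#' AUC by the Mann-Whitney statistic with half credit for ties, oriented so
#' that a *lower* index value indicates a positive (ischemic) vessel - the
#' natural direction for an FFR-like score. The variance is DeLong's
#' structural-component estimate.
#'
#' @param scores numeric index values, one per record.
#' @param labels logical (or 0/1) reference positives.
#' @param direction `"lower_positive"` (default; FFR-like) or
#'   `"higher_positive"` (probability-like).
#' @return a list of class `ctp_roc`: `auc`, `var`, `n_pos`, `n_neg`, `roc`
#'   (the underlying `pROC::roc` object).
#' @export
roc_auc <- function(scores, labels,
                    direction = c("lower_positive", "higher_positive")) {
  direction <- match.arg(direction)
  labels <- as.logical(labels)
  if (length(unique(labels)) < 2) {
    abort("both classes must be present", class = "ctpffr_domain_error")
  }
  r <- pROC::roc(response = labels, predictor = scores,
                 direction = if (direction == "lower_positive") ">" else "<",
                 levels = c(FALSE, TRUE), quiet = TRUE)
  structure(list(auc = as.numeric(pROC::auc(r)),
                 # degenerate (AUC = 1) curves legitimately have zero variance
                 var = suppressWarnings(
                   as.numeric(pROC::var(r, method = "delong"))),
                 n_pos = sum(labels), n_neg = sum(!labels), roc = r),
            class = "ctp_roc")
}

#' @export
print.ctp_roc <- function(x, ...) {
  cat(sprintf("<ctp_roc> AUC %.3f (DeLong SE %.3f), %d positive / %d negative\n",
              x$auc, sqrt(x$var), x$n_pos, x$n_neg))
  invisible(x)
}

#' DeLong test for two correlated AUCs
#'
#' Paired comparison of two index tests scored on the same vessels, using
#' DeLong's structural-component covariance; the z statistic is referred to
#' the standard normal, two-sided.
#'
#' @param scores_a,scores_b paired score vectors.
#' @param labels reference positives.
#' @param direction as in [roc_auc()], applied to both tests.
#' @return tibble: `auc_a`, `auc_b`, `z`, `p_value`.
#' @export
delong_test <- function(scores_a, scores_b, labels,
                        direction = c("lower_positive", "higher_positive")) {
  direction <- match.arg(direction)
  ra <- roc_auc(scores_a, labels, direction)
  rb <- roc_auc(scores_b, labels, direction)
  if (isTRUE(all.equal(scores_a, scores_b))) {
    # identical classifiers: zero AUC difference with zero variance
    return(tibble(auc_a = ra$auc, auc_b = rb$auc, z = 0, p_value = 1))
  }
  tt <- pROC::roc.test(ra$roc, rb$roc, method = "delong", paired = TRUE)
  if (!is.finite(tt$statistic)) {
    abort("degenerate DeLong comparison (zero variance)",
          class = "ctpffr_degenerate_test")
  }
  tibble(auc_a = ra$auc, auc_b = rb$auc,
         z = as.numeric(tt$statistic), p_value = tt$p.value)
}

#' McNemar test from discordant-pair counts
#'
#' By default: exact two-sided binomial test when the discordant total is
#' below `exact_threshold`, otherwise the continuity-corrected chi-square
#' (the branching SPSS applies). Both branches are conservative - their
#' true level is strictly below nominal because the discordant count is
#' discrete - so a mid-p variant (`midp = TRUE`; the binomial tail minus
#' half the observed point mass, at any discordant total) is provided for
#' analyses where calibration close to the nominal level matters.
#' `b = c = 0` returns p = 1 by convention, flagged.
#'
#' @param discordant_b,discordant_c discordant-pair counts.
#' @param exact_threshold switch point between the exact and chi-square
#'   branches. Default 25.
#' @param midp use the mid-p exact test instead of the default branches.
#' @return tibble: `b`, `c`, `method`, `statistic`, `p_value`, `degenerate`.
#' @export
mcnemar_test <- function(discordant_b, discordant_c, exact_threshold = 25,
                         midp = FALSE) {
  b <- discordant_b; c <- discordant_c
  stopifnot(b >= 0, c >= 0)
  n <- b + c
  if (n == 0) {
    warn("no discordant pairs; p = 1 by convention")
    return(tibble(b = b, c = c, method = "degenerate", statistic = NA_real_,
                  p_value = 1, degenerate = TRUE))
  }
  if (midp) {
    k <- min(b, c)
    p <- min(1, 2 * stats::pbinom(k, n, 0.5) - stats::dbinom(k, n, 0.5))
    tibble(b = b, c = c, method = "midp", statistic = NA_real_,
           p_value = p, degenerate = FALSE)
  } else if (n < exact_threshold) {
    p <- stats::binom.test(b, n, 0.5)$p.value
    tibble(b = b, c = c, method = "exact", statistic = NA_real_,
           p_value = p, degenerate = FALSE)
  } else {
    stat <- (abs(b - c) - 1)^2 / n
    tibble(b = b, c = c, method = "chisq_cc", statistic = stat,
           p_value = stats::pchisq(stat, df = 1, lower.tail = FALSE),
           degenerate = FALSE)
  }
}

#' Pearson correlation with Fisher-z confidence interval
#'
#' @param x,y paired numeric vectors, `n >= 3`, non-constant.
#' @param conf_level confidence level. Default 0.95.
#' @return tibble: `r`, `conf_low`, `conf_high`, `p_value`, `n`.
#' @export
pearson_with_ci <- function(x, y, conf_level = 0.95) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  if (sd(x) == 0 || sd(y) == 0) {
    abort("constant input", class = "ctpffr_domain_error")
  }
  ct <- stats::cor.test(x, y, conf.level = conf_level)
  tibble(r = as.numeric(ct$estimate), conf_low = ct$conf.int[1],
         conf_high = ct$conf.int[2], p_value = ct$p.value, n = length(x))
}

#' Bland-Altman limits of agreement
#'
#' Differences `x - y`; limits are the mean difference +/- 1.96 times the
#' sample SD (denominator n - 1).
#'
#' @param x,y paired measurements, `n >= 2`.
#' @return a list of class `ctp_bland_altman`: `mean_diff`, `lower`,
#'   `upper`, `sd_diff`, `data` (tibble `mean`, `diff`).
#' @export
bland_altman <- function(x, y) {
  stopifnot(length(x) == length(y))
  if (length(x) < 2) abort("need n >= 2 pairs", class = "ctpffr_domain_error")
  d <- x - y
  m <- mean(d); s <- sd(d)
  structure(list(mean_diff = m, lower = m - 1.96 * s, upper = m + 1.96 * s,
                 sd_diff = s,
                 data = tibble(mean = (x + y) / 2, diff = d)),
            class = "ctp_bland_altman")
}

#' @export
print.ctp_bland_altman <- function(x, ...) {
  cat(sprintf("<ctp_bland_altman> mean difference %.4f, 95%% limits [%.4f, %.4f]\n",
              x$mean_diff, x$lower, x$upper))
  invisible(x)
}

# stratum factor for each record under a named scheme
stratum_of <- function(records, scheme) {
  needed <- c(qca = "qca_percent", cac = "cac_class",
              vessel_name = "vessel_name",
              lesion_location = "lesion_location")
  if (scheme %in% names(needed) && is.null(records[[needed[[scheme]]]])) {
    abort(sprintf("records lack column '%s' required by scheme '%s'",
                  needed[[scheme]], scheme),
          class = "ctpffr_domain_error")
  }
  switch(scheme,
    qca = cut(records$qca_percent, c(30, 50, 70, 90),
              labels = c("30-49%", "50-69%", ">=70%"),
              right = FALSE, include.lowest = TRUE),
    cac = factor(records$cac_class, levels = c("<400", ">=400")),
    vessel_name = factor(records$vessel_name, levels = c("LAD", "LCX")),
    lesion_location = factor(records$lesion_location,
                             levels = c("proximal", "middle", "distal",
                                        "serial")),
    ffr_band = cut(records$invasive_ffr, c(0, 0.70, 0.80, 0.90, 1),
                   labels = c("<=0.70", "0.70-0.80", "0.80-0.90", ">0.90"),
                   right = TRUE),
    all = factor(rep("all", nrow(records))),
    abort(sprintf("unknown stratification scheme '%s'", scheme),
          class = "ctpffr_domain_error")
  )
}

#' Stratified diagnostic performance
#'
#' Partitions the records under one of the study's stratification schemes
#' (`qca` severity bands, `cac` calcium classes, `vessel_name`,
#' `lesion_location`, invasive `ffr_band`, or the trivial `all`) and
#' computes per-stratum confusion counts and metrics. The partition is
#' exhaustive and disjoint; a record that cannot be placed raises an error.
#'
#' @param records a [vessel_records()] table.
#' @param scheme stratification scheme name.
#' @param index_threshold,reference_threshold as in [classify()].
#' @return tibble with one row per (stratum, metric), plus the stratum
#'   counts `n`, `tp`, `fp`, `tn`, `fn` and per-stratum `n_correct`.
#' @export
stratify <- function(records, scheme, index_threshold = 0.80,
                     reference_threshold = 0.80) {
  f <- stratum_of(records, scheme)
  if (anyNA(f)) {
    abort(sprintf("%d record(s) not classifiable under scheme '%s'",
                  sum(is.na(f)), scheme),
          class = "ctpffr_domain_error")
  }
  purrr::map_dfr(levels(droplevels(f)), function(lev) {
    sub <- records[f == lev, ]
    tab <- classify(sub, index_threshold, reference_threshold)
    met <- confusion_metrics(tab)
    met$stratum <- lev
    met$n <- nrow(sub)
    met$tp <- tab$tp; met$fp <- tab$fp; met$tn <- tab$tn; met$fn <- tab$fn
    met$n_correct <- tab$tp + tab$tn
    dplyr::relocate(met, "stratum", "n")
  })
}

#' Combine several index tests into one positivity call
#'
#' Logical combination of per-record positivity across index tests:
#' `"any"` (a vessel is positive if any test calls it positive — maximizes
#' sensitivity) or `"all"` (positive only if every test agrees — maximizes
#' specificity). Published multi-test columns rarely state their
#' combination rule, so no equivalence with any particular one is claimed;
#' this is the explicit, documented version.
#'
#' @param positives list (or data frame) of logical vectors, one per test,
#'   equal lengths.
#' @param rule `"any"` or `"all"`.
#' @return logical vector of combined calls.
#' @export
combine_tests <- function(positives, rule = c("any", "all")) {
  rule <- match.arg(rule)
  mat <- vapply(positives, as.logical, logical(length(positives[[1]])))
  if (!is.matrix(mat)) mat <- matrix(mat, nrow = 1)
  if (rule == "any") apply(mat, 1, any) else apply(mat, 1, all)
}

#' Worst-vessel per-patient aggregation
#'
#' Collapses per-vessel records to one row per patient: a patient is
#' positive if any vessel is positive, represented by the vessel with the
#' lowest FFR on each side (index and reference taken as their per-patient
#' minima).
#'
#' @param records a [vessel_records()] table with `patient_id`.
#' @return per-patient tibble with `ctp_ffr` and `invasive_ffr` minima.
#' @export
aggregate_per_patient <- function(records) {
  stopifnot("patient_id" %in% names(records))
  dplyr::summarise(dplyr::group_by(records, .data$patient_id),
                   ctp_ffr = min(.data$ctp_ffr),
                   invasive_ffr = min(.data$invasive_ffr),
                   n_vessels = dplyr::n(), .groups = "drop")
}

#' Full diagnostic evaluation of a cohort
#'
#' Runs the whole per-vessel evaluation at the 0.80/0.80 thresholds:
#' confusion metrics with exact CIs, ROC/AUC with DeLong variance, Pearson
#' correlation, Bland-Altman agreement, and the standard stratifications.
#'
#' @param records a [vessel_records()] table.
#' @param index_threshold,reference_threshold positivity cutoffs.
#' @return an object of class `ffr_diagnostics`.
#' @export
evaluate_cohort <- function(records, index_threshold = 0.80,
                            reference_threshold = 0.80) {
  records <- vessel_records(records)
  tab <- classify(records, index_threshold, reference_threshold)
  labels <- records$invasive_ffr <= reference_threshold
  roc <- if (length(unique(labels)) == 2) {
    roc_auc(records$ctp_ffr, labels)
  } else NULL
  needed <- c(qca = "qca_percent", cac = "cac_class",
              vessel_name = "vessel_name",
              lesion_location = "lesion_location")
  schemes <- c("ffr_band", names(needed)[needed %in% names(records)])
  strata <- purrr::map(setNames(schemes, schemes),
                       function(s) stratify(records, s, index_threshold,
                                            reference_threshold))
  pear <- if (nrow(records) >= 3 && sd(records$ctp_ffr) > 0 &&
                sd(records$invasive_ffr) > 0) {
    pearson_with_ci(records$ctp_ffr, records$invasive_ffr)
  } else NULL
  ba <- if (nrow(records) >= 2) {
    bland_altman(records$ctp_ffr, records$invasive_ffr)
  } else NULL
  structure(
    list(records = records, table = tab, metrics = confusion_metrics(tab),
         roc = roc,
         pearson = pear,
         bland_altman = ba,
         strata = strata,
         thresholds = c(index = index_threshold,
                        reference = reference_threshold)),
    class = "ffr_diagnostics"
  )
}

#' @export
print.ffr_diagnostics <- function(x, ...) {
  cat(sprintf("<ffr_diagnostics> %d vessels, prevalence %.1f%%\n",
              nrow(x$records),
              100 * mean(x$records$invasive_ffr <= x$thresholds["reference"])))
  print(x$table)
  m <- x$metrics
  for (i in seq_len(nrow(m))) {
    cat(sprintf("  %-11s %5.1f%% (%.1f-%.1f)\n", m$metric[i],
                100 * m$estimate[i], 100 * m$conf_low[i],
                100 * m$conf_high[i]))
  }
  if (!is.null(x$roc) && !is.null(x$pearson) && !is.null(x$bland_altman)) {
    cat(sprintf("  AUC %.3f   Pearson r %.3f   Bland-Altman limits [%.3f, %.3f]\n",
                x$roc$auc, x$pearson$r, x$bland_altman$lower,
                x$bland_altman$upper))
  }
  invisible(x)
}
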