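test_that("band-count reconstruction yields the expected contingency table", {
  rec <- vessel_records(banded_records())
  tab <- classify(rec)
  expect_equal(tab$tp, 41)
  expect_equal(tab$fp, 7)
  expect_equal(tab$tn, 49)
  expect_equal(tab$fn, 6)
  # a vessel exactly at 0.80 counts positive on both axes
  at_cut <- vessel_records(tibble::tibble(ctp_ffr = 0.80, invasive_ffr = 0.80))
  t2 <- classify(at_cut)
  expect_equal(t2$tp, 1)
  # saturated threshold: everything positive
  t3 <- classify(rec, index_threshold = 1, reference_threshold = 1)
  expect_equal(t3$tn + t3$fn, 0)
  expect_error(classify(rec[0, ]), class = "ctpffr_domain_error")
})

test_that("confusion metrics and exact CIs reproduce hand-checked values", {
  m <- confusion_metrics(confusion_table(tp = 41, fp = 7, tn = 49, fn = 6))
  est <- setNames(round(100 * m$estimate, 1), m$metric)
  # accuracy 90/103 rounds to 87.4; the clinical table truncates it to 87.3
  expect_equal(unname(est[c("sensitivity", "specificity", "accuracy",
                            "ppv", "npv")]),
               c(87.2, 87.5, 87.4, 85.4, 89.1))
  expect_equal(round(m$estimate, 3),
               c(0.872, 0.875, 0.874, 0.854, 0.891))
  sens <- m[m$metric == "sensitivity", ]
  expect_equal(round(100 * sens$conf_low, 1), 74.3)
  expect_equal(round(100 * sens$conf_high, 1), 95.2)
  # all CIs contain their estimates and live in [0, 1]
  expect_true(all(m$conf_low <= m$estimate & m$estimate <= m$conf_high))
  expect_true(all(m$conf_low >= 0 & m$conf_high <= 1))

  perfect <- confusion_metrics(confusion_table(10, 0, 10, 0))
  expect_true(all(perfect$estimate == 1))
  balanced <- confusion_metrics(confusion_table(1, 1, 1, 1))
  expect_true(all(balanced$estimate == 0.5))
  degenerate <- confusion_metrics(confusion_table(0, 0, 5, 0))
  expect_true(is.na(degenerate$estimate[degenerate$metric == "sensitivity"]))
})

test_that("AUC matches exhaustive pair counting and handles ties", {
  # perfect separation (lower score = positive)
  sep <- roc_auc(c(0.2, 0.3, 0.7, 0.9), c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(sep$auc, 1)
  tied <- roc_auc(rep(0.5, 8), rep(c(TRUE, FALSE), 4))
  expect_equal(tied$auc, 0.5)
  toy <- roc_auc(c(0.4, 0.6, 0.5, 0.8), c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(toy$auc,
               brute_auc(c(0.4, 0.6, 0.5, 0.8), c(TRUE, TRUE, FALSE, FALSE)))
  withr::with_seed(51, {
    s <- round(runif(40), 2)   # induce some ties
    l <- runif(40) < 0.4
    expect_equal(roc_auc(s, l)$auc, brute_auc(s, l))
    # invariance under strictly monotone transforms
    expect_equal(roc_auc(exp(3 * s) - 1, l)$auc, roc_auc(s, l)$auc)
  })
  expect_error(roc_auc(1:5, rep(TRUE, 5)), class = "ctpffr_domain_error")
})

test_that("DeLong comparison is directional and null for identical scores", {
  withr::with_seed(52, {
    l <- rep(c(TRUE, FALSE), each = 30)
    s <- ifelse(l, rnorm(60, 0.6, 0.15), rnorm(60, 0.85, 0.15))
    same <- delong_test(s, s, l)
    expect_equal(same$z, 0)
    expect_equal(same$p_value, 1)
    # classifier A separates, B is noise: sign(z) tracks the AUC difference
    noise <- rnorm(60)
    dl <- delong_test(s, noise, l)
    expect_equal(sign(dl$z), sign(dl$auc_a - dl$auc_b))
    expect_gt(dl$auc_a, dl$auc_b)
  })
})

test_that("DeLong variance agrees with the bootstrap within 20%", {
  withr::with_seed(53, {
    n <- 100
    l <- rep(c(TRUE, FALSE), each = n / 2)
    s <- ifelse(l, rnorm(n, 0.65, 0.12), rnorm(n, 0.85, 0.12))
    dl_var <- roc_auc(s, l)$var
    fast_auc <- function(s, l) {
      r <- rank(s)
      np <- sum(l); nn <- sum(!l)
      (sum(r[!l]) - nn * (nn + 1) / 2) / (np * nn)  # P(score_pos < score_neg)
    }
    expect_equal(fast_auc(s, l), roc_auc(s, l)$auc)
    boots <- replicate(1000, {
      i <- sample.int(n, replace = TRUE)
      if (length(unique(l[i])) < 2) NA_real_ else fast_auc(s[i], l[i])
    })
    bv <- var(boots, na.rm = TRUE)
    expect_lt(abs(dl_var - bv) / bv, 0.2)
  })
})

test_that("McNemar branches match hand-computed references", {
  # b = 6, c = 0: exact two-sided p = 2 * (1/2)^6
  expect_equal(mcnemar_test(6, 0)$p_value, 0.03125)
  expect_gte(mcnemar_test(10, 10)$p_value, 0.99)
  big <- mcnemar_test(40, 20)
  expect_equal(big$method, "chisq_cc")
  exact_big <- stats::binom.test(40, 60, 0.5)$p.value
  expect_lt(abs(big$p_value - exact_big), 0.02)
  expect_warning(deg <- mcnemar_test(0, 0))
  expect_equal(deg$p_value, 1)
  expect_true(deg$degenerate)
  # mid-p variant sits between the exact p and its point-mass-free core
  expect_lt(mcnemar_test(6, 0, midp = TRUE)$p_value,
            mcnemar_test(6, 0)$p_value)
})

test_that("mid-p McNemar calibrates near the nominal level", {
  withr::with_seed(54, {
    n <- 60; acc <- 0.7
    p <- replicate(400, {
      ea <- runif(n) > acc; eb <- runif(n) > acc
      mcnemar_test(sum(ea & !eb), sum(!ea & eb), midp = TRUE)$p_value
    })
    expect_gt(mean(p < 0.05), 0.03)
    expect_lt(mean(p < 0.05), 0.08)
  })
})

test_that("Pearson correlation matches the covariance formula", {
  x <- c(0.61, 0.72, 0.55, 0.83, 0.90)
  y <- c(0.58, 0.75, 0.60, 0.80, 0.93)
  pc <- pearson_with_ci(x, y)
  hand <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(pc$r, hand)
  expect_true(pc$conf_low <= pc$r && pc$r <= pc$conf_high)
  expect_equal(pearson_with_ci(x, x)$r, 1)
  expect_equal(pearson_with_ci(x, -x)$r, -1)
  expect_error(pearson_with_ci(x, rep(1, 5)), class = "ctpffr_domain_error")
})

test_that("Bland-Altman limits are mean +/- 1.96 sample SD", {
  x <- c(0.62, 0.71, 0.55, 0.80, 0.88, 0.93)
  y <- c(0.60, 0.74, 0.59, 0.77, 0.90, 0.90)
  ba <- bland_altman(x, y)
  d <- x - y
  expect_equal(ba$mean_diff, mean(d))
  expect_equal(ba$lower, mean(d) - 1.96 * sd(d))
  expect_equal(ba$upper, mean(d) + 1.96 * sd(d))
  ident <- bland_altman(x, x)
  expect_equal(c(ident$mean_diff, ident$lower, ident$upper), c(0, 0, 0))
  offset <- bland_altman(x, x - 0.05)
  expect_equal(c(offset$mean_diff, offset$lower, offset$upper),
               rep(0.05, 3))
  expect_error(bland_altman(1, 1), class = "ctpffr_domain_error")
})

test_that("FFR-band stratification reproduces the per-band accuracies", {
  rec <- vessel_records(banded_records())
  st <- stratify(rec, "ffr_band")
  acc <- st[st$metric == "accuracy", ]
  expect_equal(acc$n_correct, c(22, 19, 37, 12))
  expect_equal(acc$n, c(22, 25, 44, 12))
  expect_equal(sum(acc$n), nrow(rec))
  # trivial single-stratum scheme reproduces the global table
  all_st <- stratify(rec, "all")
  glob <- confusion_metrics(classify(rec))
  expect_equal(all_st$estimate, glob$estimate)
  # pooled counts equal the sum of per-stratum counts
  expect_equal(sum(acc$tp), classify(rec)$tp)
  expect_equal(sum(acc$fp), classify(rec)$fp)
  expect_error(stratify(rec, "qca"), class = "ctpffr_domain_error")
})

test_that("gray-zone flag and per-patient aggregation behave as documented", {
  rec <- vessel_records(tibble::tibble(
    patient_id = c(1, 1, 2, 3),
    ctp_ffr = c(0.70, 0.90, 0.95, 0.77),
    invasive_ffr = c(0.76, 0.92, 0.88, 0.60)))
  expect_equal(rec$gray_zone, c(TRUE, FALSE, FALSE, FALSE))
  pat <- aggregate_per_patient(rec)
  expect_equal(nrow(pat), 3)
  expect_equal(pat$invasive_ffr[pat$patient_id == 1], 0.76)
  expect_equal(pat$n_vessels, c(2, 1, 1))
  expect_error(vessel_records(tibble::tibble(ctp_ffr = 1.2,
                                             invasive_ffr = 0.8)),
               class = "ctpffr_domain_error")
})

test_that("test combination follows the stated any/all rules", {
  a <- c(TRUE, TRUE, FALSE, FALSE)
  b <- c(TRUE, FALSE, TRUE, FALSE)
  expect_equal(combine_tests(list(a, b), "any"), c(TRUE, TRUE, TRUE, FALSE))
  expect_equal(combine_tests(list(a, b), "all"), c(TRUE, FALSE, FALSE, FALSE))
  # the "any" rule can only gain sensitivity over either component
  ref <- c(TRUE, TRUE, TRUE, FALSE)
  sens <- function(pred) sum(pred & ref) / sum(ref)
  expect_gte(sens(combine_tests(list(a, b), "any")), max(sens(a), sens(b)))
})

test_that("cohort evaluation assembles all components coherently", {
  rec <- banded_records()
  ev <- evaluate_cohort(rec)
  expect_s3_class(ev, "ffr_diagnostics")
  expect_equal(ev$table$tp, 41)
  g <- glance(ev)
  expect_equal(g$n_vessels, 103)
  expect_gt(g$auc, 0.8)
  expect_true(all(tidy(ev)$conf_low <= tidy(ev)$estimate, na.rm = TRUE))
  expect_s3_class(autoplot(ev), "ggplot")
  expect_s3_class(autoplot(ev$roc), "ggplot")
  expect_s3_class(autoplot(ev$bland_altman), "ggplot")
})
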