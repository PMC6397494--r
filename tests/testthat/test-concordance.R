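test_that("germline calls require two-run replicate agreement", {
  expect_equal(call_germline("AG", "AG"), "carrier")
  expect_equal(call_germline("GG", "GG"), "carrier")
  # discordant single replicate is uninformative
  expect_equal(call_germline("AG", "AA"), "indeterminate")
  expect_equal(call_germline("AA", "AA"), "noncarrier")
  expect_equal(call_germline("fail", "fail"), "indeterminate")
  # existential over replicates: one concordant positive wins
  expect_equal(call_germline(c("AA", "GG"), c("AA", "GG")), "carrier")
  # a concordant negative plus a discordant replicate is still a noncarrier
  expect_equal(call_germline(c("AA", "AG"), c("AA", "AA")), "noncarrier")
})

test_that("somatic calls are positive on any single G run", {
  expect_equal(call_somatic("AA", "AG"), "carrier")
  expect_equal(call_somatic("AA", "AA"), "noncarrier")
  expect_equal(call_somatic("fail", "fail"), "indeterminate")
  expect_equal(call_somatic("fail", "AA"), "noncarrier")
  expect_equal(call_somatic(c("AA", "AA"), c("AA", "GG")), "carrier")
})

make_assay <- function(person, source, r1, r2) {
  tibble::tibble(
    sample_id = sprintf("s%02d", seq_along(person)),
    person_id = person, source = source,
    replicate = 1L, run1_call = r1, run2_call = r2
  )
}

test_that("resolve_calls is per-person, order-invariant, and can impute", {
  assay <- make_assay(
    person = c("p1", "p1", "p2", "p3", "p3", "p4"),
    source = c("germline", "somatic", "somatic", "germline", "somatic",
               "germline"),
    r1 = c("AG", "AA", "AA", "AA", "AA", "AG"),
    r2 = c("AG", "AA", "AG", "AA", "AA", "AA")
  )
  calls <- resolve_calls(assay)
  expect_equal(calls$germline_call[calls$person_id == "p1"], "carrier")
  expect_equal(calls$somatic_call[calls$person_id == "p1"], "noncarrier")
  expect_equal(calls$germline_call[calls$person_id == "p2"], "none")
  expect_equal(calls$germline_call[calls$person_id == "p4"], "indeterminate")
  # order invariance
  shuffled <- resolve_calls(assay[c(6, 2, 4, 1, 5, 3), ])
  expect_equal(calls, shuffled)
  # imputation fills somatic-only and indeterminate germline persons
  imp <- resolve_calls(assay, impute_germline = TRUE)
  expect_true(imp$carrier[imp$person_id == "p2"])
  expect_true(imp$imputed[imp$person_id == "p2"])
  # p4 has no somatic record: nothing to impute from, stays unresolved
  expect_true(is.na(imp$carrier[imp$person_id == "p4"]))
  expect_false(imp$imputed[imp$person_id == "p1"])
})

test_that("confusion matrix takes germline as truth and logs exclusions", {
  assay <- make_assay(
    person = c("a", "a", "b", "b", "c", "c", "d"),
    source = c("germline", "somatic", "germline", "somatic",
               "germline", "somatic", "germline"),
    r1 = c("AG", "AG", "AA", "AG", "AA", "AA", "AA"),
    r2 = c("AG", "AA", "AA", "AA", "AA", "AA", "AA")
  )
  calls <- resolve_calls(assay)
  expect_message(conf <- confusion_matrix(calls), "excluded")
  expect_equal(conf$tp, 1)  # a: carrier/carrier
  expect_equal(conf$fp, 1)  # b: noncarrier germline, positive somatic
  expect_equal(conf$tn, 1)  # c
  expect_equal(conf$fn, 0)
  expect_equal(conf$n_excluded, 1)  # d has no somatic sample
})

test_that("all-agree assay gives a diagonal confusion matrix", {
  assay <- make_assay(
    person = rep(c("x", "y"), each = 2),
    source = rep(c("germline", "somatic"), 2),
    r1 = c("AG", "AG", "AA", "AA"),
    r2 = c("AG", "AG", "AA", "AA")
  )
  conf <- confusion_matrix(resolve_calls(assay))
  expect_equal(conf$fp + conf$fn, 0)
  rep <- diagnostic_report(conf)
  expect_equal(rep$estimate[rep$metric == "accuracy"], 1)
})

test_that("Clopper-Pearson bounds satisfy the binomial tail equations", {
  for (n in c(14, 24, 38)) {
    for (k in 1:(n - 1)) {
      ci <- clopper_pearson(k, n)
      expect_equal(binom_ge_direct(k, n, ci$ci_low), 0.025, tolerance = 1e-8)
      expect_equal(binom_le_direct(k, n, ci$ci_high), 0.025, tolerance = 1e-8)
      # independent route: stats' exact binomial test
      bt <- stats::binom.test(k, n)$conf.int
      expect_equal(c(ci$ci_low, ci$ci_high), as.numeric(bt),
                   tolerance = 1e-10)
    }
  }
  expect_equal(clopper_pearson(0, 20)$ci_low, 0)
  expect_equal(clopper_pearson(20, 20)$ci_high, 1)
  expect_error(clopper_pearson(5, 0), "at least 1")
  expect_error(clopper_pearson(6, 5), "in \\[0, n\\]")
})

test_that("predictive values follow Bayes and recover the raw table", {
  pv <- predictive_values(0.857, 0.958, 0.40)
  expect_equal(round(pv$ppv, 3), 0.932)
  expect_equal(round(pv$npv, 3), 0.909)
  expect_equal(predictive_values(0.9, 0.8, 1)$ppv, 1)
  expect_warning(predictive_values(0.5, 1, 0), "degenerate")
  # with prevalence = table positive fraction, ppv reduces to tp/(tp+fp)
  tp <- 12; fn <- 2; fp <- 1; tn <- 23
  sens <- tp / (tp + fn); spec <- tn / (tn + fp)
  prev <- (tp + fn) / (tp + fn + fp + tn)
  pv2 <- predictive_values(sens, spec, prev)
  expect_equal(pv2$ppv, tp / (tp + fp))
  expect_equal(pv2$npv, tn / (tn + fn))
})

test_that("diagnostic report has coherent estimates, CIs and methods", {
  conf <- structure(list(tp = 12, fn = 2, fp = 1, tn = 23, n_excluded = 0),
                    class = "confusion")
  rep <- diagnostic_report(conf, prevalence = 0.40)
  est <- setNames(rep$estimate, rep$metric)
  expect_equal(est[["sensitivity"]], 12 / 14)
  expect_equal(est[["specificity"]], 23 / 24)
  expect_equal(est[["accuracy"]], 35 / 38)
  with_ci <- rep[rep$metric %in% c("sensitivity", "specificity", "accuracy"), ]
  expect_true(all(with_ci$ci_low <= with_ci$estimate &
                    with_ci$estimate <= with_ci$ci_high))
  # PPV/NPV intervals deliberately absent
  expect_true(all(is.na(rep$ci_low[rep$metric %in% c("ppv", "npv")])))
  gl <- glance(rep)
  expect_equal(gl$n_paired, 38L)
  expect_equal(gl$prevalence_used, 0.40)
  expect_s3_class(tidy(rep), "tbl_df")
  expect_s3_class(autoplot(rep), "ggplot")
})
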