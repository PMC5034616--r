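test_that("confusion counts partition the panel", {
  cc <- confusion(c(1, 1, 0, 0), c(1, 0, 0, 1))
  expect_equal(cc$tp, 1L); expect_equal(cc$fn, 1L)
  expect_equal(cc$tn, 1L); expect_equal(cc$fp, 1L)
  same <- confusion(c(1, 0, 1), c(1, 0, 1))
  expect_equal(same$fp + same$fn, 0L)
  flipped <- confusion(c(1, 0, 1), c(0, 1, 0))
  expect_equal(flipped$tp + flipped$tn, 0L)
  expect_error(confusion(c(1, 0), c(1, 0, 1)),
               class = "qsarens_validation_error")
  expect_error(confusion(c(1, 2), c(1, 0)),
               class = "qsarens_validation_error")
})

test_that("metrics match hand arithmetic and flag zero denominators", {
  r <- classification_metrics(qsarens:::confusion_counts(tp = 3, fn = 1,
                                                         tn = 4, fp = 2))
  expect_equal(r$accuracy, 0.7)
  expect_equal(r$sensitivity, 0.75)
  expect_equal(r$specificity, 2 / 3)
  expect_equal(r$balanced_accuracy, (0.75 + 2 / 3) / 2)
  expect_equal(r$ppv, 0.6)
  expect_equal(r$npv, 0.8)
  expect_equal(r$kappa, 0.4)  # p_o = 0.7, p_e = 0.5

  perfect <- classification_metrics(qsarens:::confusion_counts(2, 0, 3, 0))
  for (s in c("accuracy", "sensitivity", "specificity", "balanced_accuracy",
              "ppv", "npv"))
    expect_equal(perfect[[s]], 1)
  expect_equal(perfect$kappa, 1)

  nopos <- classification_metrics(qsarens:::confusion_counts(0, 0, 4, 1))
  expect_true(is.na(nopos$sensitivity))
  expect_true(is.na(nopos$balanced_accuracy))
  expect_error(classification_metrics(qsarens:::confusion_counts(0, 0, 0, 0)),
               class = "qsarens_validation_error")
})

test_that("metric identities hold on random confusion matrices", {
  set.seed(42)
  for (rep in 1:100) {
    truth <- rbinom(50, 1, runif(1, 0.2, 0.8))
    pred <- rbinom(50, 1, runif(1, 0.2, 0.8))
    cc <- confusion(truth, pred)
    r <- classification_metrics(cc)
    lh <- longhand_metrics(truth, pred)
    n <- r$n
    expect_equal(cc$tp + cc$fn + cc$tn + cc$fp, 50L)
    expect_equal(r$accuracy, lh$accuracy)
    if (!is.na(r$sensitivity) && !is.na(r$specificity)) {
      # accuracy decomposes over the class-conditional rates
      expect_equal(r$accuracy,
                   (r$sensitivity * (cc$tp + cc$fn) +
                    r$specificity * (cc$tn + cc$fp)) / n)
      expect_equal(r$balanced_accuracy, (r$sensitivity + r$specificity) / 2)
    }
    expect_equal(r$kappa, lh$kappa)
  }
})

test_that("kappa handles agreement extremes and the degenerate margin", {
  expect_equal(cohen_kappa(qsarens:::confusion_counts(5, 0, 5, 0)), 1)
  expect_equal(cohen_kappa(qsarens:::confusion_counts(1, 1, 1, 1)), 0)
  expect_true(is.na(cohen_kappa(qsarens:::confusion_counts(4, 0, 0, 0))))
})

test_that("kappa bands follow the literal published cuts, gaps included", {
  expect_equal(kappa_band(0), "none")
  expect_equal(kappa_band(0.5), "moderate")
  expect_equal(kappa_band(0.63), "substantial")
  expect_equal(kappa_band(1), "perfect")
  expect_equal(kappa_band(0.605), "other")
  expect_equal(kappa_band(0.3), "other")
  expect_equal(kappa_band(-0.2), "other")
  expect_error(kappa_band(1.5), class = "qsarens_validation_error")
})

test_that("LOOCV reproduces literal held-out refits", {
  for (seed in 1:5) {
    panel <- random_panel(n = 40, m = 3, seed = seed)
    for (alpha in c(0, 0.5)) {
      cfg <- ensemble_config(cutoff = 0.5, smoothing_alpha = alpha)
      fast <- loocv(panel, cfg)
      expect_identical(fast$predictions, naive_loocv_predictions(panel, cfg))
    }
  }
})

test_that("LOOCV hand-traced edge cases behave as derived", {
  # tools that echo the truth: every fold classifies its holdout correctly
  labels <- rep(c(1L, 0L), 5)
  echo <- prediction_panel(cbind(labels, labels), labels,
                           tool_names = c("echo_a", "echo_b"))
  expect_equal(loocv(echo, ensemble_config(cutoff = 0.5))$metrics$accuracy, 1)

  # two chemicals sharing a key with opposite labels: each fold trains on
  # the other one only, so the held-out posterior is its opposite's label
  pair <- toy_panel(list(c(1, 0), c(1, 0)), c(1L, 0L))
  cv <- loocv(pair, ensemble_config(cutoff = 0.5))
  expect_equal(cv$posteriors, c(0, 1))
  expect_equal(cv$metrics$accuracy, 0)

  # sole occupant of its key: held-out posterior comes from the policy
  solo <- toy_panel(list(c(1, 1), c(0, 0), c(0, 0), c(0, 0)),
                    c(1L, 0L, 0L, 1L))
  cv_prior <- loocv(solo, ensemble_config(cutoff = 0.5, unseen_policy = "prior"))
  expect_true(cv_prior$unseen[1])
  expect_equal(cv_prior$posteriors[1], 1 / 3)  # fold prior: 1 positive of 3
  cv_neg <- loocv(solo, ensemble_config(unseen_policy = "abstain-as-negative"))
  expect_equal(cv_neg$posteriors[1], 0)
  cv_pos <- loocv(solo, ensemble_config(unseen_policy = "abstain-as-positive"))
  expect_equal(cv_pos$posteriors[1], 1)

  expect_error(loocv(toy_panel(list(c(1, 0)), 1L), ensemble_config()),
               class = "qsarens_validation_error")
})

test_that("LOOCV metrics are invariant to row order, duplicates included", {
  panel <- random_panel(n = 30, m = 3, seed = 13)
  # append a duplicate of chemical 1 under a fresh id
  dup <- prediction_panel(rbind(panel$predictions, panel$predictions[1, ]),
                          c(panel$labels, panel$labels[1]),
                          chemical_ids = c(panel$chemical_ids, "dup_1"),
                          tool_names = panel$tool_names)
  cfg <- ensemble_config(cutoff = 0.5)
  base <- loocv(dup, cfg)$metrics
  set.seed(99)
  for (rep in 1:5) {
    perm <- sample(dup$n)
    shuffled <- prediction_panel(dup$predictions[perm, ], dup$labels[perm],
                                 chemical_ids = dup$chemical_ids[perm],
                                 tool_names = dup$tool_names)
    got <- loocv(shuffled, cfg)$metrics
    for (s in c("accuracy", "sensitivity", "specificity", "balanced_accuracy",
                "ppv", "npv", "kappa"))
      expect_equal(got[[s]], base[[s]])
  }
})

test_that("the default ROC grid has 11 points with the boundary behaviour", {
  panel <- random_panel(n = 80, m = 3, seed = 21)
  roc <- roc_curve(panel)
  expect_equal(nrow(roc$points), 11L)
  expect_equal(roc$points$cutoff, seq(0, 1, by = 0.1))
  at0 <- roc$points[roc$points$cutoff == 0, ]
  expect_equal(at0$sensitivity, 1)
  expect_equal(at0$fpr, 1)
  expect_error(roc_curve(panel, grid = numeric(0)),
               class = "qsarens_validation_error")
  expect_error(roc_curve(panel, grid = c(0, 1.2)),
               class = "qsarens_validation_error")
})

test_that("ROC is monotone in the cut-off on many random panels", {
  for (seed in 1:100) {
    panel <- random_panel(n = 40, m = 3, seed = 1000 + seed,
                          flip = runif(1, 0.1, 0.45))
    roc <- roc_curve(panel)
    expect_true(all(diff(roc$points$sensitivity) <= 1e-12))
    expect_true(all(diff(roc$points$fpr) <= 1e-12))
  }
})

test_that("an always-correct tool drives the traced AUC to 1", {
  # 6 chemicals; tool 1 is an oracle, tool 2 is uninformative. Hand
  # trace: every fold leaves the holdout's key occupied by two same-label
  # chemicals, so held-out posteriors are 1 for every carcinogen and 0
  # for every non-carcinogen, and the grid trace passes through (0, 1).
  panel <- toy_panel(list(c(1, 0), c(1, 0), c(1, 0), c(0, 0), c(0, 0), c(0, 0)),
                     c(1L, 1L, 1L, 0L, 0L, 0L))
  cv <- loocv(panel, ensemble_config())
  expect_equal(cv$posteriors, c(1, 1, 1, 0, 0, 0))
  roc <- roc_curve(panel)
  expect_equal(roc$auc, 1)
})

test_that("AUC equals the manual trapezoid sum, anchors included", {
  expect_equal(roc_auc(data.frame(fpr = c(0, 0, 1), sensitivity = c(0, 1, 1))), 1)
  diagonal <- data.frame(fpr = seq(0, 1, 0.25), sensitivity = seq(0, 1, 0.25))
  expect_equal(roc_auc(diagonal), 0.5)
  stair <- data.frame(fpr = c(0.1, 0.3, 0.6, 0.9),
                      sensitivity = c(0.4, 0.6, 0.8, 0.95))
  fpr <- c(0, stair$fpr, 1); tpr <- c(0, stair$sensitivity, 1)
  expect_equal(roc_auc(stair), manual_trapezoid(fpr, tpr))
  expect_error(roc_auc(data.frame(fpr = 0.5, sensitivity = 0.5)),
               class = "qsarens_validation_error")
})

test_that("paired comparison matches hand-computed t statistics", {
  set.seed(7)
  a <- rbinom(20, 1, 0.8); b <- rbinom(20, 1, 0.5)
  d <- a - b
  res <- paired_comparison(a, b)
  expect_equal(res$statistic, mean(d) / (sd(d) / sqrt(20)))
  expect_equal(res$p_value,
               2 * pt(abs(res$statistic), df = 19, lower.tail = FALSE))
  expect_equal(res$significant, res$p_value < 0.05)
})

test_that("paired comparison flags the degenerate difference patterns", {
  same <- paired_comparison(rep(1, 10), rep(1, 10))
  expect_true(is.na(same$statistic))
  expect_true(is.na(same$significant))
  # a always correct, b always wrong: constant nonzero difference
  extreme <- paired_comparison(rep(1, 10), rep(0, 10))
  expect_true(is.infinite(extreme$statistic))
  expect_true(extreme$significant)
  expect_lt(extreme$p_value, 0.05)
  expect_error(paired_comparison(c(1, 0), c(1, 0, 1)),
               class = "qsarens_validation_error")
})

test_that("McNemar alternative agrees with the base test on discordant pairs", {
  a <- c(rep(1, 30), rep(0, 10), rep(1, 5), rep(0, 5))
  b <- c(rep(1, 30), rep(1, 10), rep(0, 5), rep(0, 5))
  res <- paired_comparison(a, b, method = "mcnemar")
  ref <- mcnemar.test(table(factor(a, 0:1), factor(b, 0:1)))
  expect_equal(res$statistic, unname(ref$statistic))
  expect_equal(res$p_value, ref$p.value)
  none <- paired_comparison(c(1, 1, 0), c(1, 1, 0), method = "mcnemar")
  expect_true(is.na(none$significant))
})

test_that("metrics reports serialise to CSV and JSON", {
  panel <- random_panel(n = 50, m = 3, seed = 17)
  cv <- loocv(panel, ensemble_config())
  reports <- list(bayes = cv$metrics,
                  tool_1 = classification_metrics(
                    confusion(panel$labels, panel$predictions[, 1])))
  csv <- withr::local_tempfile(fileext = ".csv")
  jsn <- withr::local_tempfile(fileext = ".json")
  write_metrics_report(reports, csv, "csv")
  write_metrics_report(reports, jsn, "json")
  back <- utils::read.csv(csv)
  expect_identical(back$Model, c("bayes", "tool_1"))
  expect_equal(back$Kappa[1], cv$metrics$kappa)
  jback <- jsonlite::read_json(jsn, simplifyVector = TRUE)
  expect_equal(jback$Accuracy[2],
               mean(panel$labels == panel$predictions[, 1]))
})
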