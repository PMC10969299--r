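test_that("support-weighted metrics reproduce the worked confusion outcomes", {
  # 16 patients: 12 wildtype with 2 errors, 4 mutant all correct
  labels <- c(rep("IDHwt", 12), rep("IDHmut", 4))
  decisions <- c(rep("IDHwt", 10), rep("IDHmut", 2), rep("IDHmut", 4))
  scores <- ifelse(decisions == "IDHmut", 0.9, 0.1)
  r <- evaluate(scores, labels, decisions)
  expect_equal(r$accuracy, 0.875)
  expect_equal(r$precision, 0.917, tolerance = 5e-4)
  expect_equal(r$errors, 2L)
  # 33 patients with 6 errors: accuracy 0.818
  labels2 <- c(rep("IDHwt", 21), rep("IDHmut", 12))
  dec2 <- labels2
  dec2[c(1:3, 22:24)] <- rev(c("IDHwt", "IDHwt", "IDHwt",
                               "IDHmut", "IDHmut", "IDHmut"))
  r2 <- evaluate(ifelse(dec2 == "IDHmut", 0.8, 0.2), labels2, dec2)
  expect_equal(r2$accuracy, 0.818, tolerance = 5e-4)
  expect_equal(r2$errors, 6L)
  # perfect predictions
  r3 <- evaluate(ifelse(labels == "IDHmut", 0.99, 0.01), labels)
  for (f in c("accuracy", "sensitivity", "specificity", "precision",
              "f_score", "auroc"))
    expect_equal(r3[[f]], 1.0)
  expect_error(evaluate(numeric(0), character(0)), "empty")
})

test_that("weighted accuracy equals plain accuracy (algebraic identity)", {
  set.seed(1)
  for (i in 1:100) {
    n <- sample(10:60, 1)
    labels <- sample(c("IDHwt", "IDHmut"), n, TRUE, prob = c(0.7, 0.3))
    if (length(unique(labels)) < 2) next
    decisions <- sample(c("IDHwt", "IDHmut"), n, TRUE)
    r <- suppressWarnings(evaluate(runif(n), labels, decisions))
    # support-weighted recall is algebraically the overall accuracy
    expect_equal(r$sensitivity, mean(decisions == labels), tolerance = 1e-12)
    expect_equal(r$accuracy, mean(decisions == labels), tolerance = 1e-12)
  }
})

test_that("AUROC behaves as a rank statistic", {
  set.seed(2)
  labels <- rep(c("IDHwt", "IDHmut"), each = 500)
  # shuffled scores: chance level
  expect_lt(abs(auroc(runif(1000), labels) - 0.5), 0.05)
  # monotone-transform invariance
  s <- rnorm(1000) + (labels == "IDHmut")
  expect_identical(auroc(s, labels), auroc(exp(3 * s) + 7, labels))
  # ties handled by midranks: all-equal scores give exactly 0.5
  expect_equal(auroc(rep(1, 1000), labels), 0.5)
  # cross-check against an established ROC implementation
  skip_if_not_installed("pROC")
  p <- suppressMessages(pROC::auc(pROC::roc(labels, s, levels = c("IDHwt", "IDHmut"),
                                            direction = "<", quiet = TRUE)))
  expect_equal(auroc(s, labels), as.numeric(p), tolerance = 1e-12)
})

test_that("the results matrix mirrors the metrics-by-model-category layout", {
  mk <- function(model, cat, acc) {
    labels <- c(rep("IDHwt", 8), rep("IDHmut", 4))
    k <- round(12 * (1 - acc))
    dec <- labels; if (k > 0) dec[seq_len(k)] <- "IDHmut"
    evaluate(ifelse(dec == "IDHmut", 0.9, 0.1), labels, dec,
             model = model, category = cat)
  }
  models <- c("ABoost", "MLP", "RF", "CNN1D", "LSTM")
  cats <- c("cmri", "oxymet", "vam", "oxyvam")
  reports <- list()
  for (m in models) for (cat in cats)
    reports[[paste(m, cat)]] <- mk(m, cat, 0.9)
  tab <- results_matrix(reports, models, cats)
  expect_equal(ncol(tab), 21L)     # metric column + 5 models x 4 categories
  expect_equal(tab$metric, c("accuracy", "sensitivity", "specificity",
                             "precision", "f_score", "auroc", "errors"))
  # a missing cell is an explicit NA column, not a silent drop
  tab2 <- results_matrix(reports[-1], models, cats)
  expect_true(all(is.na(tab2[["ABoost.cmri"]])))
  expect_error(results_matrix(c(reports, reports[1])), "duplicate")
})

test_that("a single-class cohort triggers the exclusion warning", {
  labels <- rep("IDHwt", 8)
  expect_warning(evaluate(runif(8), labels), "one class")
})
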