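#' Area under the ROC curve (rank-sum formulation)
#'
#' Mann-Whitney statistic with midrank tie correction:
#' `AUROC = (sum of positive-class ranks - n_pos(n_pos+1)/2) / (n_pos n_neg)`.
#' Invariant under strictly monotone transforms of the scores.
#'
#' @param scores numeric scores (higher = more positive-class).
#' @param labels class labels; `positive` names the positive class.
#' @param positive positive-class label.
#' @return AUROC in [0, 1]; NA if a class is absent.
#' @export
auroc <- function(scores, labels, positive = "IDHmut") {
  pos <- labels == positive
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(scores)
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Confusion-matrix metrics, support-weighted over the two classes
#'
#' Computes per-class (one-vs-rest) sensitivity/recall, specificity,
#' precision, and F-score (F1), combines them by support-weighted mean (the
#' appropriate summary for unbalanced test cohorts), and adds accuracy, the
#' rank-sum AUROC, and the raw error count. If a class is absent from the
#' labels its metrics are undefined and it is excluded from the weighting
#' with a warning.
#'
#' @param scores predicted probabilities of the positive (IDHmut) class.
#' @param labels true class labels.
#' @param decisions optional hard class decisions (default: scores > 0.5).
#' @param model,category,cohort optional identifiers stored in the report.
#' @return Object of class `evaluation_report`: `accuracy`, `sensitivity`,
#'   `specificity`, `precision`, `f_score`, `auroc`, `errors`, `n`,
#'   `per_class`, `confusion`, plus identifiers.
#' @export
evaluate <- function(scores, labels, decisions = NULL, model = NA_character_,
                     category = NA_character_, cohort = NA_character_) {
  labels <- as.character(labels)
  n <- length(labels)
  if (n == 0) stop("empty input")
  if (is.null(decisions)) decisions <- ifelse(scores > 0.5, "IDHmut", "IDHwt")
  stopifnot(length(decisions) == n, length(scores) == n)
  classes <- c("IDHwt", "IDHmut")
  present <- classes[classes %in% labels]
  if (length(present) < 2L)
    warning("only one class present; absent class excluded from weighting")
  per_class <- lapply(present, function(cl) {
    tp <- sum(decisions == cl & labels == cl)
    fp <- sum(decisions == cl & labels != cl)
    fn <- sum(decisions != cl & labels == cl)
    tn <- sum(decisions != cl & labels != cl)
    list(class = cl, support = tp + fn, tp = tp, fp = fp, fn = fn, tn = tn,
         sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
         specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
         precision = if (tp + fp > 0) tp / (tp + fp) else 0,
         f_score = if (2 * tp + fp + fn > 0) 2 * tp / (2 * tp + fp + fn) else 0)
  })
  names(per_class) <- present
  w <- vapply(per_class, function(p) p$support, 0)
  wmean <- function(field) {
    v <- vapply(per_class, function(p) p[[field]], 0)
    ok <- !is.na(v)
    sum(v[ok] * w[ok]) / sum(w[ok])
  }
  correct <- sum(decisions == labels)
  confusion <- table(predicted = factor(decisions, classes),
                     truth = factor(labels, classes))
  structure(list(accuracy = correct / n,
                 sensitivity = wmean("sensitivity"),
                 specificity = wmean("specificity"),
                 precision = wmean("precision"),
                 f_score = wmean("f_score"),
                 auroc = auroc(scores, labels),
                 errors = n - correct, n = n,
                 per_class = per_class, confusion = confusion,
                 model = model, category = category, cohort = cohort),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("<evaluation %s/%s: acc %.3f, prec %.3f, AUROC %s, %d/%d errors>\n",
              x$model, x$category, x$accuracy, x$precision,
              ifelse(is.na(x$auroc), "NA", sprintf("%.3f", x$auroc)),
              x$errors, x$n))
  invisible(x)
}

#' Assemble evaluation reports into the results matrix
#'
#' Metrics-by-(model, category) table in the fixed metric order: accuracy,
#' sensitivity, specificity, precision, F-score, AUROC, and classification
#' errors. Missing (model, category) cells are explicit NA columns; duplicate
#' cells are rejected.
#'
#' @param reports list of `evaluation_report`s.
#' @param models,categories orderings for the columns (defaults: those seen).
#' @return data.frame with a `metric` column and one column per
#'   `model.category` pair.
#' @export
results_matrix <- function(reports, models = NULL, categories = NULL) {
  stopifnot(length(reports) >= 1)
  metrics <- c("accuracy", "sensitivity", "specificity", "precision",
               "f_score", "auroc", "errors")
  keys <- vapply(reports, function(r) paste(r$model, r$category, sep = "."), "")
  if (anyDuplicated(keys)) stop("duplicate (model, category) report")
  if (is.null(models)) models <- unique(vapply(reports, `[[`, "", "model"))
  if (is.null(categories))
    categories <- unique(vapply(reports, `[[`, "", "category"))
  out <- data.frame(metric = metrics)
  for (m in models) for (cat in categories) {
    key <- paste(m, cat, sep = ".")
    i <- match(key, keys)
    out[[key]] <- if (is.na(i)) NA_real_ else
      vapply(metrics, function(f) as.numeric(reports[[i]][[f]]), 0)
  }
  out
}

#' Radiomic feature matrices for a whole cohort
#'
#' Simulates (lazily), maps, and extracts features for every patient of a
#' cohort; one row per patient per requested category.
#'
#' @param cohort from [simulate_cohort()] (lazy or materialised).
#' @param categories data categories to extract.
#' @param verbose print progress.
#' @return List: `features` (named list of matrices), `labels`.
#' @export
cohort_features <- function(cohort, categories = "oxymet", verbose = FALSE) {
  n <- length(cohort$labels)
  rows <- lapply(categories, function(cat) NULL)
  names(rows) <- categories
  for (i in seq_len(n)) {
    bundle <- if (!is.null(cohort$patients)) cohort$patients[[i]] else cohort$build(i)
    maps <- map_patient(bundle)
    for (cat in categories) {
      v <- patient_features(maps, cat)
      rows[[cat]] <- rbind(rows[[cat]], v)
    }
    if (verbose && i %% 10 == 0) message("  mapped patient ", i, "/", n)
  }
  feats <- lapply(rows, function(m) { rownames(m) <- NULL; m })
  list(features = feats, labels = cohort$labels)
}

#' Run a full simulate / map / select / train / evaluate experiment
#'
#' Generates a training cohort and one or two test cohorts (internal: same
#' protocol; external: the other site's protocol), extracts features for the
#' requested categories, runs the selection + SMOTE + training pipeline per
#' (model, category), and evaluates on every test cohort. Deterministic for
#' a fixed config.
#'
#' @param config list with `n_train`, `n_test`, `seed`, `categories`,
#'   `models`, `effects`, `train_protocol`, `test_protocols` (named list),
#'   `grid_shape`, `noise_sd`, and optional `model_args` (per-kind overrides)
#'   and `wrapper_learner`.
#' @param verbose print progress.
#' @return List: `reports` (list of `evaluation_report`), `results`
#'   (results matrix per cohort), `models`, `features`, `config`.
#' @export
run_experiment <- function(config, verbose = FALSE) {
  cf <- config
  cf$categories <- cf$categories %||% "oxymet"
  cf$models <- cf$models %||% c("MLP", "RF")
  cf$effects <- cf$effects %||% class_effect_model()
  cf$train_protocol <- cf$train_protocol %||% "site_A_separate"
  cf$test_protocols <- cf$test_protocols %||% list(internal = cf$train_protocol)
  cf$grid_shape <- cf$grid_shape %||% c(32, 32, 32)
  cf$noise_sd <- cf$noise_sd %||% 0.01
  cf$seed <- cf$seed %||% 1L

  if (verbose) message("simulating + mapping training cohort (n=", cf$n_train, ")")
  train <- simulate_cohort(cf$n_train, cf$effects, cf$train_protocol,
                           seed = cf$seed, grid_shape = cf$grid_shape,
                           noise_sd = cf$noise_sd, lazy = TRUE)
  ftr <- cohort_features(train, cf$categories, verbose = verbose)
  tests <- list()
  for (nm in names(cf$test_protocols)) {
    if (verbose) message("simulating + mapping ", nm, " test cohort (n=", cf$n_test, ")")
    co <- simulate_cohort(cf$n_test, cf$effects, cf$test_protocols[[nm]],
                          seed = cf$seed + 1000L + match(nm, names(cf$test_protocols)),
                          grid_shape = cf$grid_shape, noise_sd = cf$noise_sd,
                          lazy = TRUE)
    tests[[nm]] <- cohort_features(co, cf$categories, verbose = verbose)
  }

  reports <- list(); trained <- list()
  for (cat in cf$categories) {
    for (kind in cf$models) {
      if (verbose) message("training ", kind, " on ", cat)
      args <- c(list(kind = kind, seed = cf$seed), cf$model_args[[kind]])
      spec <- do.call(model_spec, args)
      model <- train_pipeline(ftr$features[[cat]], ftr$labels, spec,
                              wrapper_learner = cf$wrapper_learner %||% "logistic",
                              seed = cf$seed)
      trained[[paste(kind, cat, sep = ".")]] <- model
      for (nm in names(tests)) {
        p <- predict_model(model, tests[[nm]]$features[[cat]])
        reports[[paste(kind, cat, nm, sep = ".")]] <-
          evaluate(p, tests[[nm]]$labels, model = kind, category = cat,
                   cohort = nm)
      }
    }
  }
  results <- lapply(names(tests), function(nm)
    results_matrix(Filter(function(r) r$cohort == nm, reports),
                   models = cf$models, categories = cf$categories))
  names(results) <- names(tests)
  list(reports = reports, results = results, models = trained,
       features = list(train = ftr, tests = tests), config = cf)
}
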