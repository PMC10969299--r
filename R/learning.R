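#' ReliefF feature relevance ranking
#'
#' Standard ReliefF: features are scaled to [0, 1]; for every instance the
#' `k_neighbors` nearest hits (same class) and nearest misses (other class,
#' prevalence-weighted) are found under Manhattan distance, and each
#' feature's weight accumulates the expected nearest-miss minus nearest-hit
#' feature difference. Optionally neighbours are weighted by an exponential
#' rank kernel with decay `sigma`. Ties in the final ranking are broken by
#' feature-name order, making the ranking fully deterministic.
#'
#' @param x numeric matrix, patients x features (named columns).
#' @param y class labels (two classes).
#' @param k_neighbors nearest neighbours per class.
#' @param sigma rank-decay parameter, used when `weight_by_distance = TRUE`.
#' @param weight_by_distance weight neighbours by their rank distance.
#' @return List of class `relieff_ranking`: `weights` (named), `ranking`
#'   (feature names, best first), `top25` (the top-25% shortlist).
#' @export
relieff_rank <- function(x, y, k_neighbors = 10L, sigma = 2,
                         weight_by_distance = FALSE) {
  y <- as.character(y)
  classes <- unique(y)
  if (length(classes) < 2L) stop("labels are constant")
  x <- as.matrix(x)
  n <- nrow(x); nf <- ncol(x)
  if (min(table(y)) < k_neighbors + 1L)
    stop("each class needs at least k_neighbors + 1 members")
  rng <- apply(x, 2, range)
  span <- rng[2, ] - rng[1, ]
  span[span == 0] <- 1
  xs <- sweep(sweep(x, 2, rng[1, ]), 2, span, `/`)
  prior <- table(y) / n
  D <- as.matrix(stats::dist(xs, method = "manhattan"))
  w <- numeric(nf)
  kw <- if (weight_by_distance) exp(-((seq_len(k_neighbors)) / sigma)^2) else
    rep(1, k_neighbors)
  kw <- kw / sum(kw)
  for (i in seq_len(n)) {
    for (cl in classes) {
      pool <- setdiff(which(y == cl), i)
      nb <- pool[order(D[i, pool])][seq_len(k_neighbors)]
      diffs <- abs(sweep(xs[nb, , drop = FALSE], 2, xs[i, ]))
      contrib <- colSums(diffs * kw)
      if (cl == y[i]) {
        w <- w - contrib / n
      } else {
        pw <- prior[[cl]] / (1 - prior[[y[i]]])
        w <- w + pw * contrib / n
      }
    }
  }
  names(w) <- colnames(x)
  ord <- order(-w, names(w))
  ranking <- colnames(x)[ord]
  structure(list(weights = w, ranking = ranking,
                 top25 = ranking[seq_len(ceiling(0.25 * nf))]),
            class = "relieff_ranking")
}

# minimal fast learners usable inside the wrapper search
.fit_predict <- function(spec, xtr, ytr, xte) {
  ytr <- factor(ytr, levels = c("IDHwt", "IDHmut"))
  kind <- if (is.character(spec)) spec else spec$kind
  if (kind == "logistic") {
    df <- data.frame(xtr, check.names = FALSE)
    fit <- suppressWarnings(stats::glm(y ~ ., data = cbind(df, y = ytr),
                                       family = stats::binomial()))
    p <- stats::predict(fit, newdata = data.frame(xte, check.names = FALSE),
                        type = "response")
    ifelse(p > 0.5, "IDHmut", "IDHwt")
  } else if (kind == "tree") {
    df <- cbind(data.frame(xtr, check.names = FALSE), y = ytr)
    fit <- rpart::rpart(y ~ ., data = df, method = "class",
                        parms = list(split = "information"))
    as.character(stats::predict(fit, data.frame(xte, check.names = FALSE),
                                type = "class"))
  } else {
    m <- train_classical(xtr, ytr, model_spec(kind), cv_folds = 0)
    ifelse(predict_model(m, xte) > 0.5, "IDHmut", "IDHwt")
  }
}

# stratified fold assignment
.make_folds <- function(y, k, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  f <- integer(length(y))
  for (cl in unique(y)) {
    id <- sample(which(y == cl))
    f[id] <- rep(seq_len(k), length.out = length(id))
  }
  f
}

#' Wrapper feature selection (best-first forward search with CV scoring)
#'
#' Learner-based selection over a ReliefF shortlist: a best-first forward
#' search grows a feature subset, scoring every candidate subset by the
#' wrapped classifier's stratified k-fold cross-validation accuracy, and
#' stops when the best expansion improves the score by less than
#' `threshold`. A feature enters the selected set if it was chosen in at
#' least one accepted expansion. Folds in which the classifier cannot be
#' trained are skipped with a warning; at least 8 valid folds are required
#' per evaluation.
#'
#' @param shortlist candidate feature names.
#' @param x feature matrix (named columns).
#' @param y class labels.
#' @param classifier_spec `"logistic"`, `"tree"`, or a [model_spec()].
#' @param folds number of CV folds per subset evaluation.
#' @param threshold minimum accuracy improvement to keep expanding.
#' @param seed RNG seed for fold assignment.
#' @param max_features cap on the subset size.
#' @return List of class `selection_report`: `selected`, `trace` (accepted
#'   expansions with scores), `shortlist`, `folds`, `seed`.
#' @export
wrapper_select <- function(shortlist, x, y, classifier_spec = "logistic",
                           folds = 10L, threshold = 0.01, seed = 1L,
                           max_features = 10L) {
  stopifnot(length(shortlist) > 0)
  x <- as.matrix(x)[, shortlist, drop = FALSE]
  y <- as.character(y)
  fold_id <- .make_folds(y, folds, seed = seed)
  cv_score <- function(cols) {
    hits <- 0L; total <- 0L; ok_folds <- 0L
    for (f in seq_len(folds)) {
      tr <- fold_id != f; te <- !tr
      if (length(unique(y[tr])) < 2L || !any(te)) next
      pred <- tryCatch(
        .fit_predict(classifier_spec, x[tr, cols, drop = FALSE], y[tr],
                     x[te, cols, drop = FALSE]),
        error = function(e) NULL)
      if (is.null(pred)) { warning("wrapper fold skipped"); next }
      hits <- hits + sum(pred == y[te]); total <- total + sum(te)
      ok_folds <- ok_folds + 1L
    }
    if (ok_folds < min(8L, folds)) return(NA_real_)
    hits / total
  }
  sel <- character(0)
  best_acc <- max(table(y)) / length(y)   # majority-class baseline
  trace <- list()
  repeat {
    cand <- setdiff(shortlist, sel)
    if (!length(cand) || length(sel) >= max_features) break
    accs <- vapply(cand, function(fn) cv_score(c(sel, fn)), 0)
    if (all(is.na(accs))) break
    bi <- which.max(accs)
    if (is.na(accs[bi]) || accs[bi] < best_acc + threshold) break
    sel <- c(sel, cand[bi])
    trace[[length(trace) + 1L]] <- list(feature = cand[bi], score = accs[bi])
    best_acc <- accs[bi]
  }
  if (!length(sel)) sel <- shortlist[1]   # degenerate: keep the top-ranked
  structure(list(selected = sel, trace = trace, shortlist = shortlist,
                 folds = folds, seed = seed),
            class = "selection_report")
}

#' SMOTE class balancing
#'
#' Synthetic minority oversampling: new minority samples are linear
#' interpolations between a minority point and one of its `k` nearest
#' minority neighbours, generated until the class counts are equal, followed
#' by a seeded row shuffle of the whole matrix (randomisation filter).
#'
#' @param x feature matrix.
#' @param y class labels (two classes).
#' @param k nearest neighbours used for interpolation.
#' @param seed RNG seed.
#' @return List: `x` (balanced matrix), `y` (labels), `synthetic` (logical).
#' @export
smote_balance <- function(x, y, k = 5L, seed = 1L) {
  x <- as.matrix(x); y <- as.character(y)
  tab <- table(y)
  if (length(tab) != 2L) stop("SMOTE expects exactly two classes")
  min_cl <- names(tab)[which.min(tab)]
  n_min <- min(tab); n_maj <- max(tab)
  set.seed(seed)
  if (n_min == n_maj) {
    ord <- sample(nrow(x))
    return(list(x = x[ord, , drop = FALSE], y = y[ord],
                synthetic = rep(FALSE, nrow(x))[ord]))
  }
  if (n_min < k + 1L) stop("minority class needs at least k + 1 members")
  mi <- which(y == min_cl)
  xm <- x[mi, , drop = FALSE]
  D <- as.matrix(stats::dist(xm))
  diag(D) <- Inf
  nn <- t(apply(D, 1, function(d) order(d)[seq_len(k)]))
  n_new <- n_maj - n_min
  parent <- rep(seq_len(n_min), length.out = n_new)
  mate <- nn[cbind(parent, sample.int(k, n_new, replace = TRUE))]
  gap <- stats::runif(n_new)
  synth <- xm[parent, , drop = FALSE] +
    gap * (xm[mate, , drop = FALSE] - xm[parent, , drop = FALSE])
  bx <- rbind(x, synth)
  by <- c(y, rep(min_cl, n_new))
  flag <- c(rep(FALSE, nrow(x)), rep(TRUE, n_new))
  ord <- sample(nrow(bx))
  list(x = bx[ord, , drop = FALSE], y = by[ord], synthetic = flag[ord])
}

#' Model specification
#'
#' Hyperparameter container for the five classifier kinds. Classical models:
#' `MLP` (single hidden layer, width = number of features + number of
#' classes), `ABoost` (adaptive boosting of entropy-split pruned decision
#' trees, a C4.5-style stand-in), `RF` (random forest, 100 trees). Deep
#' models: `CNN1D` and `LSTM` (see [train_cnn1d()], [train_lstm()]).
#'
#' @param kind one of "MLP", "ABoost", "RF", "CNN1D", "LSTM".
#' @param seed RNG seed for training.
#' @param ... kind-specific overrides (`ntree`, `iterations`, `maxit`,
#'   `epochs`, `hidden`, `filters`, `kernels`, `lr`, `batch_size`, ...).
#' @return Object of class `model_spec`.
#' @export
model_spec <- function(kind = c("MLP", "ABoost", "RF", "CNN1D", "LSTM"),
                       seed = 1L, ...) {
  kind <- match.arg(kind)
  defaults <- switch(kind,
    MLP = list(maxit = 200, decay = 1e-4, learning_rate = 0.3, momentum = 0.2),
    ABoost = list(iterations = 10L),
    RF = list(ntree = 100L),
    CNN1D = list(filters = c(32L, 64L, 64L), kernels = c(7L, 5L, 3L),
                 pool = 2L, dense = 64L, dropout = 0.2, epochs = 300L,
                 lr = 1e-3, batch_size = 28L, val_frac = 0.2),
    LSTM = list(hidden = 64L, dense = 32L, dropout = 0.2, epochs = 300L,
                lr = 1e-3, beta1 = 0.9, beta2 = 0.999, eps = 1e-8,
                batch_size = 28L, val_batch_size = 10L, val_frac = 0.2,
                seq_len = 107L))
  over <- list(...)
  defaults[names(over)] <- over
  structure(c(list(kind = kind, seed = as.integer(seed)), defaults),
            class = "model_spec")
}

# AdaBoost.M1 over entropy-split rpart trees
.fit_aboost <- function(x, y, iterations = 10L) {
  n <- nrow(x)
  w <- rep(1 / n, n)
  df <- data.frame(x, check.names = FALSE)
  models <- list(); alphas <- numeric(0)
  yy <- factor(y, levels = c("IDHwt", "IDHmut"))
  for (it in seq_len(iterations)) {
    fit <- rpart::rpart(yy ~ ., data = cbind(df, yy = yy), weights = w,
                        method = "class",
                        parms = list(split = "information"),
                        control = rpart::rpart.control(cp = 0.01, minsplit = 5))
    pred <- stats::predict(fit, df, type = "class")
    err <- sum(w * (pred != yy)) / sum(w)
    if (err >= 0.5) break
    err <- max(err, 1e-10)
    a <- 0.5 * log((1 - err) / err)
    models[[length(models) + 1L]] <- fit
    alphas <- c(alphas, a)
    w <- w * exp(ifelse(pred != yy, a, -a))
    w <- w / sum(w)
    if (err < 1e-9) break
  }
  if (!length(models)) {
    fit <- rpart::rpart(yy ~ ., data = cbind(df, yy = yy), method = "class",
                        parms = list(split = "information"))
    models <- list(fit); alphas <- 1
  }
  list(models = models, alphas = alphas)
}

.predict_aboost <- function(fit, x) {
  df <- data.frame(x, check.names = FALSE)
  margin <- rep(0, nrow(df))
  for (i in seq_along(fit$models)) {
    pred <- stats::predict(fit$models[[i]], df, type = "class")
    margin <- margin + fit$alphas[i] * ifelse(pred == "IDHmut", 1, -1)
  }
  1 / (1 + exp(-2 * margin))   # squash boosting margin to a score
}

#' Train a classical classifier (MLP, ABoost, or RF)
#'
#' MLP: single-hidden-layer perceptron with hidden width equal to the number
#' of input features plus the number of classes. ABoost: AdaBoost.M1 over
#' entropy-split pruned decision trees. RF: random forest with 100 trees.
#' A stratified 10-fold cross-validation accuracy on the training matrix is
#' reported alongside the fitted model.
#'
#' @param x feature matrix (typically SMOTE-balanced).
#' @param y class labels ("IDHwt"/"IDHmut").
#' @param spec [model_spec()] of kind MLP, ABoost, or RF.
#' @param cv_folds folds for the reported CV accuracy (0 to skip).
#' @return Object of class `trained_model`: `fit`, `spec`, `features`,
#'   `cv_accuracy`.
#' @export
train_classical <- function(x, y, spec, cv_folds = 10L) {
  stopifnot(inherits(spec, "model_spec"),
            spec$kind %in% c("MLP", "ABoost", "RF"))
  x <- as.matrix(x); y <- as.character(y)
  set.seed(spec$seed)
  fit_one <- function(xtr, ytr) {
    yy <- factor(ytr, levels = c("IDHwt", "IDHmut"))
    switch(spec$kind,
      MLP = {
        # attribute standardization (the perceptron is scale-sensitive)
        mu <- colMeans(xtr)
        sdv <- apply(xtr, 2, stats::sd)
        sdv[!is.finite(sdv) | sdv == 0] <- 1
        xs <- sweep(sweep(xtr, 2, mu), 2, sdv, `/`)
        size <- ncol(xtr) + 2L
        fit <- nnet::nnet(xs, nnet::class.ind(yy), size = size, softmax = TRUE,
                          maxit = spec$maxit, decay = spec$decay, trace = FALSE,
                          MaxNWts = 1e6)
        list(fit = fit, mu = mu, sd = sdv)
      },
      ABoost = .fit_aboost(xtr, ytr, iterations = spec$iterations),
      RF = randomForest::randomForest(xtr, yy, ntree = spec$ntree))
  }
  predict_one <- function(fit, xte) {
    switch(spec$kind,
      MLP = {
        xs <- sweep(sweep(xte, 2, fit$mu), 2, fit$sd, `/`)
        stats::predict(fit$fit, xs)[, "IDHmut"]
      },
      ABoost = .predict_aboost(fit, xte),
      RF = stats::predict(fit, xte, type = "prob")[, "IDHmut"])
  }
  cv_acc <- NA_real_
  if (cv_folds > 0L) {
    fold_id <- .make_folds(y, cv_folds)
    hits <- 0L
    for (f in seq_len(cv_folds)) {
      tr <- fold_id != f
      if (length(unique(y[tr])) < 2L) { fold_id <- .make_folds(y, cv_folds); tr <- fold_id != f }
      m <- fit_one(x[tr, , drop = FALSE], y[tr])
      p <- predict_one(m, x[!tr, , drop = FALSE])
      hits <- hits + sum((p > 0.5) == (y[!tr] == "IDHmut"))
    }
    cv_acc <- hits / length(y)
  }
  fit <- fit_one(x, y)
  structure(list(fit = fit, spec = spec, features = colnames(x),
                 cv_accuracy = cv_acc, predict_one = predict_one),
            class = "trained_model")
}

#' Predict mutant-class probabilities from any trained model
#'
#' @param model `trained_model` from [train_classical()], [train_cnn1d()] or
#'   [train_lstm()].
#' @param x feature matrix whose columns match the training manifest.
#' @return Probabilities of the IDH-mutant class, in [0, 1].
#' @export
predict_model <- function(model, x) {
  x <- as.matrix(x)
  if (!is.null(model$features)) {
    if (is.null(colnames(x))) {
      if (ncol(x) != length(model$features))
        stop(sprintf("feature count mismatch: model expects %d, got %d",
                     length(model$features), ncol(x)))
    } else {
      missing <- setdiff(model$features, colnames(x))
      if (length(missing))
        stop("missing features: ", paste(utils::head(missing, 5), collapse = ", "))
      x <- x[, model$features, drop = FALSE]
    }
  }
  p <- if (!is.null(model$predict_one)) model$predict_one(model$fit, x)
       else nn_predict(model$fit, x)
  pmin(pmax(as.numeric(p), 0), 1)
}

#' Full selection + balancing + training pipeline for one model
#'
#' Fixed stage order: ReliefF top-25% shortlist, wrapper selection with the
#' model as (or a fast stand-in for) the wrapped learner, SMOTE balancing of
#' the training data only, seeded shuffle, then training.
#'
#' @param x training feature matrix, y labels.
#' @param y class labels.
#' @param spec [model_spec()].
#' @param wrapper_learner fast learner for the wrapper search
#'   ("logistic" or "tree"); deep models skip wrapper selection and use the
#'   full feature vector, as their sequence layout requires all 107 features
#'   per map.
#' @param seed pipeline seed (fans out to selection, SMOTE, training).
#' @return `trained_model` with `selection` attached.
#' @export
train_pipeline <- function(x, y, spec, wrapper_learner = "logistic",
                           seed = spec$seed) {
  x <- as.matrix(x)
  deep <- spec$kind %in% c("CNN1D", "LSTM")
  if (!deep) {
    rk <- relieff_rank(x, y)
    sel <- wrapper_select(rk$top25, x, y, classifier_spec = wrapper_learner,
                          seed = seed)
    xs <- x[, sel$selected, drop = FALSE]
  } else {
    rk <- NULL; sel <- NULL; xs <- x
  }
  bal <- smote_balance(xs, y, seed = seed)
  spec$seed <- seed
  model <- switch(spec$kind,
                  CNN1D = train_cnn1d(bal$x, bal$y, spec),
                  LSTM = train_lstm(bal$x, bal$y, spec),
                  train_classical(bal$x, bal$y, spec))
  model$selection <- sel
  model$relieff <- rk
  model
}
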