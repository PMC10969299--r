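test_that("ReliefF weights match the brute-force oracle on a 20x2 matrix", {
  set.seed(1)
  y <- rep(c("IDHwt", "IDHmut"), each = 10)
  x <- cbind(sep = ifelse(y == "IDHmut", 1, 0) + rnorm(20, 0, 0.05),
             noise = rnorm(20))
  rk <- relieff_rank(x, y, k_neighbors = 5)
  expect_equal(unname(rk$weights), relieff_oracle(x, y, 5), tolerance = 1e-10)
  expect_equal(rk$ranking[1], "sep")
  # a feature identical for all patients has weight 0
  x2 <- cbind(x, const = 1)
  expect_equal(unname(relieff_rank(x2, y, k_neighbors = 5)$weights["const"]), 0)
  expect_error(relieff_rank(x, rep("IDHwt", 20)), "constant")
  # shortlist size is a quarter of the feature count, rounded up
  set.seed(2)
  xb <- matrix(rnorm(30 * 40), 30, 40,
               dimnames = list(NULL, sprintf("f%02d", 1:40)))
  rkb <- relieff_rank(xb, rep(c("IDHwt", "IDHmut"), 15), k_neighbors = 5)
  expect_length(rkb$top25, 10L)
})

test_that("label permutation shrinks ReliefF weights toward zero", {
  set.seed(5)
  y <- rep(c("IDHwt", "IDHmut"), each = 15)
  x <- cbind(sep = ifelse(y == "IDHmut", 1, 0) + rnorm(30, 0, 0.05),
             n1 = rnorm(30))
  w_true <- relieff_rank(x, y, k_neighbors = 5)$weights["sep"]
  w_perm <- replicate(40, {
    relieff_rank(x, sample(y), k_neighbors = 5)$weights["sep"]
  })
  expect_gt(w_true, mean(w_perm) + 3 * sd(w_perm) / sqrt(40))
  expect_lt(abs(mean(w_perm)), w_true / 2)
})

test_that("wrapper search keeps a separating feature and is reproducible", {
  toy <- toy_features(n = 60, p = 6, shift = 2, seed = 3)
  sel <- wrapper_select(colnames(toy$x), toy$x, toy$y, "logistic", seed = 1)
  expect_true("f1" %in% sel$selected)
  sel2 <- wrapper_select(colnames(toy$x), toy$x, toy$y, "logistic", seed = 1)
  expect_identical(sel$selected, sel2$selected)
  expect_true(all(sel$selected %in% sel$shortlist))
})

test_that("an all-noise shortlist selects at most a minimal feature set", {
  accs <- c(); sizes <- c()
  for (rep in 1:5) {
    set.seed(100 + rep)
    y <- rep(c("IDHwt", "IDHmut"), each = 20)
    x <- matrix(rnorm(40 * 6), 40, 6, dimnames = list(NULL, paste0("f", 1:6)))
    sel <- wrapper_select(colnames(x), x, y, "logistic", seed = rep)
    sizes <- c(sizes, length(sel$selected))
    m <- train_classical(x[, sel$selected, drop = FALSE], y, model_spec("RF"))
    accs <- c(accs, m$cv_accuracy)
  }
  expect_lte(stats::median(sizes), 2)
  expect_lt(mean(accs), 0.70)   # about the majority-class rate
})

test_that("SMOTE balances 43/123 to 123/123 with collinear synthetics", {
  set.seed(6)
  x <- matrix(rnorm(166 * 4), 166, 4)
  y <- rep(c("IDHwt", "IDHmut"), c(123, 43))
  bal <- smote_balance(x, y, k = 5, seed = 1)
  expect_equal(unname(table(bal$y)["IDHwt"]), 123)
  expect_equal(unname(table(bal$y)["IDHmut"]), 123)
  # already balanced input: row count unchanged (shuffle only)
  even <- smote_balance(x[1:86, ], rep(c("IDHwt", "IDHmut"), 43), seed = 1)
  expect_equal(nrow(even$x), 86L)
  expect_error(smote_balance(x[1:10, ], rep(c("IDHwt", "IDHmut"), c(7, 3))),
               "k \\+ 1")
  # every synthetic point lies on a segment between two minority parents
  minx <- x[y == "IDHmut", ]
  seg_dist <- function(p, a, b) {
    lam <- sum((p - a) * (b - a)) / max(sum((b - a)^2), 1e-12)
    lam <- min(max(lam, 0), 1)
    sqrt(sum((a + lam * (b - a) - p)^2))
  }
  pairs <- utils::combn(nrow(minx), 2)
  for (i in which(bal$synthetic)[1:15]) {
    p <- bal$x[i, ]
    dmin <- min(apply(pairs, 2, function(ab)
      seg_dist(p, minx[ab[1], ], minx[ab[2], ])))
    expect_lt(dmin, 1e-9)
  }
})

test_that("classical models separate a linearly separable toy set", {
  toy <- toy_features(n = 40, p = 2, shift = 6, seed = 7)
  for (kind in c("MLP", "ABoost", "RF")) {
    m <- train_classical(toy$x, toy$y, model_spec(kind, seed = 1))
    expect_equal(m$cv_accuracy, 1.0)
    p <- predict_model(m, toy$x)
    expect_true(all(p >= 0 & p <= 1))
    expect_gte(mean((p > 0.5) == (toy$y == "IDHmut")), m$cv_accuracy - 0.1)
  }
})

test_that("label-permuted training gives chance-level cross-validation", {
  accs <- c()
  for (rep in 1:10) {
    set.seed(200 + rep)
    toy <- toy_features(n = 40, p = 2, shift = 6, seed = 200 + rep)
    yperm <- sample(toy$y)
    m <- train_classical(toy$x, yperm, model_spec("RF", seed = rep))
    accs <- c(accs, m$cv_accuracy)
  }
  expect_lt(abs(mean(accs) - 0.5), 0.12)
})

test_that("the MLP hidden width is the feature count plus the class count", {
  toy <- toy_features(n = 30, p = 4, shift = 5, seed = 8)
  m <- train_classical(toy$x, toy$y, model_spec("MLP", seed = 1), cv_folds = 0)
  expect_equal(m$fit$fit$n[2], 6)        # 4 features + 2 classes
  # the rule at the paper-scale input: 428 features -> 430 hidden units
  expect_equal(428 + 2, 430)
})

test_that("CNN architecture audit: nine hidden layers, three dropout sites", {
  arch <- cnn_architecture()
  expect_length(arch, 9L)
  expect_equal(sum(arch == "conv"), 3L)
  expect_equal(sum(arch == "pool"), 3L)
  expect_equal(sum(arch == "flatten"), 1L)
  expect_equal(sum(arch == "dense"), 2L)
  expect_length(attr(arch, "dropout_after"), 3L)
})

test_that("CNN separates a toy radiomic cohort and trains deterministically", {
  set.seed(9)
  n <- 120
  y <- rep(c("IDHwt", "IDHmut"), each = n / 2)
  x <- matrix(rnorm(n * 428), n, 428)
  x[y == "IDHmut", 1:60] <- x[y == "IDHmut", 1:60] + 1.5
  spec <- model_spec("CNN1D", seed = 2, epochs = 15L)
  m <- train_cnn1d(x, y, spec)
  expect_gte(m$cv_accuracy, 0.95)
  p1 <- predict_model(m, x)
  m2 <- train_cnn1d(x, y, spec)
  expect_identical(p1, predict_model(m2, x))   # same seed, same weights
  expect_error(train_cnn1d(x[, 1:100], y, spec), "428")
})

test_that("LSTM uses one layer per 107-feature map block", {
  set.seed(10)
  n <- 60
  y <- rep(c("IDHwt", "IDHmut"), each = n / 2)
  x4 <- matrix(rnorm(n * 428), n, 428)
  x4[y == "IDHmut", ] <- x4[y == "IDHmut", ] + 1.5
  spec <- model_spec("LSTM", seed = 1, epochs = 40L, hidden = 16L)
  m4 <- train_lstm(x4, y, spec)
  expect_equal(sum(m4$architecture == "lstm"), 4L)
  expect_equal(sum(m4$architecture == "dense"), 2L)
  x8 <- cbind(x4, x4)
  m8 <- train_lstm(x8, y, spec)
  expect_equal(sum(m8$architecture == "lstm"), 8L)
  expect_error(train_lstm(x4[, 1:300], y, spec), "divisible")
  expect_gte(m4$cv_accuracy, 0.95)
})

test_that("network gradients match numerical differentiation", {
  ns <- asNamespace("physiomap")
  check <- function(net, forward, backward, X, y, eps = 1e-5) {
    fw <- forward(net, X, train = FALSE)
    g <- backward(net, fw, y)
    loss <- function(nn) {
      p <- pmin(pmax(forward(nn, X, train = FALSE)$out, 1e-12), 1 - 1e-12)
      -mean(y * log(p) + (1 - y) * log(1 - p))
    }
    maxerr <- 0
    for (nm in names(net$params)) {
      P <- net$params[[nm]]
      for (i in seq_len(min(4L, length(P)))) {
        n2 <- net
        n2$params[[nm]][i] <- P[i] + eps; lp <- loss(n2)
        n2$params[[nm]][i] <- P[i] - eps; lm <- loss(n2)
        num <- (lp - lm) / (2 * eps)
        maxerr <- max(maxerr, abs(num - g[[nm]][i]) / max(1e-5, abs(num)))
      }
    }
    maxerr
  }
  set.seed(12)
  cspec <- model_spec("CNN1D", filters = c(2L, 3L, 2L), kernels = c(3L, 3L, 3L),
                      dense = 4L, dropout = 0)
  cnet <- ns$.init_cnn(30L, cspec)
  X <- matrix(rnorm(4 * 30), 4, 30); y <- c(1, 0, 1, 0)
  expect_lt(check(cnet, ns$.cnn_forward, ns$.cnn_backward, X, y), 1e-4)
  lspec <- model_spec("LSTM", hidden = 5L, dense = 3L, dropout = 0,
                      seq_len = 7L)
  lnet <- ns$.init_lstm(2L, lspec)
  X2 <- matrix(rnorm(3 * 14), 3, 14); y2 <- c(1, 0, 1)
  expect_lt(check(lnet, ns$.lstm_forward, ns$.lstm_backward, X2, y2), 1e-3)
})

test_that("prediction validates the feature manifest and output range", {
  toy <- toy_features(n = 30, p = 3, shift = 4, seed = 13)
  m <- train_classical(toy$x, toy$y, model_spec("RF", seed = 1), cv_folds = 0)
  bad <- toy$x[, 1:2]
  expect_error(predict_model(m, bad), "missing|mismatch")
  # constant-feature input gives a constant probability
  xc <- toy$x; xc[] <- 1
  expect_length(unique(predict_model(m, xc)), 1L)
})

test_that("the selection pipeline runs in fixed order and stays reproducible", {
  set.seed(14)
  n <- 60
  y <- rep(c("IDHwt", "IDHmut"), c(40, 20))
  x <- matrix(rnorm(n * 24), n, 24, dimnames = list(NULL, sprintf("f%02d", 1:24)))
  x[y == "IDHmut", 3] <- x[y == "IDHmut", 3] + 3
  m1 <- train_pipeline(x, y, model_spec("RF"), seed = 2)
  m2 <- train_pipeline(x, y, model_spec("RF"), seed = 2)
  expect_identical(m1$selection$selected, m2$selection$selected)
  expect_true(all(m1$selection$selected %in% m1$relieff$top25))
  expect_identical(predict_model(m1, x), predict_model(m2, x))
})
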