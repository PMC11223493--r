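test_that("training separates two classes with disjoint duration supports", {
  ts <- make_tensor_set(120, list(
    short = list(ev_len = 8, jitter = 1),
    long  = list(ev_len = 60, jitter = 5)), seed = 301)
  net <- build_classifier(2, class_levels = c("long", "short"))
  net <- train_classifier(net, ts$x, ts$labels, epochs = 8, restarts = 1,
                          seed = 302)
  pred <- predict(net, ts$x, type = "class")
  expect_gt(mean(pred == ts$labels), 0.99)
  pr <- predict(net, ts$x, type = "prob")
  expect_equal(rowSums(pr), rep(1, nrow(ts$x)), tolerance = 1e-6)
})

test_that("restart bookkeeping and oversampling contracts hold", {
  ts <- make_tensor_set(40, list(
    a = list(ev_len = 8, jitter = 1),
    b = list(ev_len = 60, jitter = 5)), seed = 303)
  # 4:1 imbalance
  keep <- c(1:40, 41:50)
  net <- build_classifier(2, class_levels = c("a", "b"))
  net <- train_classifier(net, ts$x[keep, ], ts$labels[keep], epochs = 3,
                          restarts = 2, seed = 304)
  expect_equal(length(net$restart_accuracy), 2L)
  expect_equal(nrow(net$log), 2L * 3L)
  # the imbalanced input really is 4:1
  expect_equal(as.numeric(table(ts$labels[keep])), c(40, 10))
  # minority class is still learned despite the imbalance
  pred <- predict(net, ts$x[41:80, ], type = "class")
  expect_gt(mean(pred == "b"), 0.9)
})

test_that("training is reproducible under a seed", {
  ts <- make_tensor_set(30, list(
    a = list(ev_len = 8, jitter = 1),
    b = list(ev_len = 60, jitter = 5)), seed = 305)
  n1 <- train_classifier(build_classifier(2, class_levels = c("a", "b")),
                         ts$x, ts$labels, epochs = 2, restarts = 1,
                         seed = 306)
  n2 <- train_classifier(build_classifier(2, class_levels = c("a", "b")),
                         ts$x, ts$labels, epochs = 2, restarts = 1,
                         seed = 306)
  expect_identical(n1$params, n2$params)
  expect_identical(n1$log, n2$log)
})

test_that("a class with zero events is rejected by name", {
  ts <- make_tensor_set(20, list(a = list(ev_len = 10),
                                 b = list(ev_len = 50)), seed = 307)
  net <- build_classifier(3, class_levels = c("a", "b", "c"))
  expect_error(train_classifier(net, ts$x, ts$labels, epochs = 1,
                                restarts = 1, seed = 1),
               "zero events.*c")
})

test_that("grouped cross-validation never splits a trace across folds", {
  ts <- make_tensor_set(150, list(
    a = list(ev_len = 8, jitter = 1),
    b = list(ev_len = 60, jitter = 5)), seed = 308)
  # 10 events per pseudo-trace, 15 traces per class
  tid <- paste0(ts$labels, "_t", rep(rep(1:15, each = 10), 2))
  cv <- grouped_cross_validate(ts$x, ts$labels, tid, k = 3, epochs = 4,
                               restarts = 1, seed = 309)
  # every trace maps to exactly one fold and all events follow it
  expect_equal(sort(names(cv$folds)), sort(unique(tid)))
  expect_equal(length(cv$models), 3L)
  expect_false(anyNA(cv$predictions))
  # separable classes: near-identity mean confusion matrix, rows sum to 1
  expect_equal(rowSums(cv$confusion_mean), c(a = 1, b = 1),
               tolerance = 1e-10)
  expect_gt(min(diag(cv$confusion_mean)), 0.95)
  expect_gt(cv$accuracy, 0.95)
})

test_that("KNN baseline matches an exhaustive neighbour search", {
  set.seed(310)
  tr_x <- cbind(rnorm(60), rnorm(60))
  tr_y <- sample(c("p", "q", "r"), 60, replace = TRUE)
  te_x <- cbind(rnorm(25), rnorm(25))
  got <- knn_baseline(tr_x, tr_y, te_x, k = 3)
  # oracle: per-point loop with explicit standardization and vote
  mu <- colMeans(tr_x); sv <- apply(tr_x, 2, sd)
  trs <- sweep(sweep(tr_x, 2, mu), 2, sv, "/")
  tes <- sweep(sweep(te_x, 2, mu), 2, sv, "/")
  for (i in 1:25) {
    dd <- sqrt(rowSums((trs - matrix(tes[i, ], 60, 2, byrow = TRUE))^2))
    nn <- order(dd)[1:3]
    votes <- table(tr_y[nn])
    winners <- names(votes)[votes == max(votes)]
    exp_lab <- if (length(winners) == 1) winners else
      tr_y[nn][which(tr_y[nn] %in% winners)[1]]
    expect_equal(as.character(got[i]), exp_lab)
  }
})

test_that("KNN trivial vote and error contracts", {
  tr_x <- rbind(c(0, 0), c(0, 0), c(0, 0), c(5, 5))
  tr_y <- c("a", "a", "a", "b")
  expect_equal(as.character(knn_baseline(tr_x, tr_y, rbind(c(0, 0)))), "a")
  expect_error(knn_baseline(tr_x[0, , drop = FALSE], character(0),
                            rbind(c(0, 0))), "empty")
  expect_error(knn_baseline(tr_x, tr_y, rbind(c(0, 0)), k = 10), "exceeds")
})
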