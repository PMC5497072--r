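# Under-sampling, fold plans, binary training and cross-validation.

# a small separable task: positives carry feature 1, negatives feature 2
separable_task <- function(n = 40, flip = 0) {
  y <- rep(c(TRUE, FALSE), each = n / 2)
  x <- cbind(as.numeric(y), as.numeric(!y), 0)
  if (flip > 0) {
    idx <- seq_len(flip)
    x[idx, 1:2] <- x[idx, 2:1]
  }
  sp <- data.frame(type = rep("bow", 3), key = c("a", "b", "c"),
                   index = 1:3)
  class(sp) <- c("chq_feature_space", "data.frame")
  list(x = x, y = y, space = sp)
}

test_that("under-sampling balances by trimming whichever class is larger", {
  ids <- seq_len(2000)
  labels <- c(rep(TRUE, 136), rep(FALSE, 1864))
  kept <- under_sample(ids, labels, seed = 3)
  expect_length(kept, 272)
  expect_setequal(intersect(kept, which(labels)), which(labels)) # minority verbatim
  expect_equal(sum(labels[kept]), sum(!labels[kept]))
  # positives can be the majority (prevalent topics)
  labels2 <- c(rep(TRUE, 1167), rep(FALSE, 833))
  kept2 <- under_sample(ids, labels2, seed = 3)
  expect_length(kept2, 2 * 833)
  expect_true(all(which(!labels2) %in% kept2))
  # already balanced input is returned whole
  labels3 <- rep(c(TRUE, FALSE), 10)
  expect_setequal(under_sample(1:20, labels3, seed = 1), 1:20)
  expect_error(under_sample(1:5, rep(TRUE, 5)),
               class = "chqclass_invalid_input")
})

test_that("under-sampling is deterministic and a subset of the input", {
  ids <- paste0("q", 1:100)
  labels <- rep(c(TRUE, FALSE), c(20, 80))
  a <- under_sample(ids, labels, seed = 11)
  b <- under_sample(ids, labels, seed = 11)
  expect_identical(a, b)
  expect_true(all(a %in% ids))
  c_ <- under_sample(ids, labels, seed = 12)
  expect_false(identical(a, c_)) # different seed, different majority draw
})

test_that("fold plans partition ids with sizes differing by at most one", {
  plan <- make_folds(1:272, k = 10, seed = 5)
  sizes <- table(unname(plan))
  expect_equal(sum(sizes), 272)
  expect_lte(diff(range(sizes)), 1)
  expect_setequal(as.integer(names(sizes)), 0:9)
  # singleton folds
  plan2 <- make_folds(1:10, k = 10, seed = 5)
  expect_true(all(table(unname(plan2)) == 1))
  # determinism
  expect_identical(make_folds(1:50, seed = 9), make_folds(1:50, seed = 9))
  expect_error(make_folds(1:5, k = 10), class = "chqclass_invalid_input")
})

test_that("stratified fold plans balance classes within every fold", {
  y <- rep(c(TRUE, FALSE), each = 136)
  plan <- make_folds(seq_along(y), k = 10, seed = 5, strata = y)
  sizes <- table(unname(plan))
  expect_lte(diff(range(sizes)), 1)
  expect_equal(sort(unname(as.vector(sizes)), decreasing = TRUE)[1:2],
               c(28, 28)) # two folds of 28, eight of 27
  for (f in 0:9) {
    in_fold <- unname(plan) == f
    expect_lte(abs(sum(y[in_fold]) - sum(!y[in_fold])), 1)
  }
})

test_that("a separable task trains to perfect accuracy", {
  task <- separable_task()
  m <- train_binary("toy", task$x, task$y, task$space, select = FALSE)
  expect_equal(predict(m, task$x), task$y)
  # with Phi selection on: the informative columns survive and accuracy holds
  m2 <- train_binary("toy", task$x, task$y, task$space, select = TRUE)
  expect_equal(predict(m2, task$x), task$y)
  expect_error(train_binary("toy", task$x, rep(TRUE, nrow(task$x)),
                            task$space),
               class = "chqclass_invalid_input")
})

test_that("baseline classifier families train and predict", {
  task <- separable_task()
  for (clf in c("naive_bayes", "logistic")) {
    m <- train_binary("toy", task$x, task$y, task$space, classifier = clf,
                      select = FALSE)
    expect_equal(predict(m, task$x), task$y)
  }
})

test_that("training and prediction are deterministic", {
  set.seed(83)
  n <- 60
  x <- matrix(rbinom(n * 20, 1, 0.4), nrow = n)
  y <- rbinom(n, 1, 0.5) == 1
  if (sum(y) < 2 || sum(!y) < 2) y[1:4] <- c(TRUE, TRUE, FALSE, FALSE)
  sp <- data.frame(type = rep("bow", 20), key = paste0("k", 1:20),
                   index = 1:20)
  class(sp) <- c("chq_feature_space", "data.frame")
  m1 <- train_binary("t", x, y, sp)
  m2 <- train_binary("t", x, y, sp)
  expect_identical(predict(m1, x), predict(m2, x))
})

test_that("multi-label prediction unions binary decisions with Other fallback", {
  task <- separable_task()
  m <- train_binary("A", task$x, task$y, task$space, select = FALSE)
  m_not <- train_binary("B", task$x, !task$y, task$space, select = FALSE)
  models <- list(A = m, B = m_not)
  pos_row <- task$x[1, , drop = FALSE]             # positive for A only
  neg_row <- task$x[nrow(task$x), , drop = FALSE]  # positive for B only
  labs <- predict_topics(rbind(pos_row, neg_row), models)
  expect_equal(labs[[1]], "A")
  expect_equal(labs[[2]], "B")
  # two models trained on the same labels both fire
  both <- predict_topics(pos_row, list(A = m, A2 = m))
  expect_setequal(both[[1]], c("A", "A2"))
  # no model fires -> the residual Other topic
  none <- predict_topics(neg_row, list(A = m))
  expect_equal(none[[1]], "Other")
  expect_error(predict_topics(matrix(0, 1, 1), list(A = m)),
               class = "chqclass_invalid_input")
})

test_that("cross-validation is perfect on separable data and leakage-free", {
  task <- separable_task()
  cv <- cross_validate(task$x, task$y, task$space, k = 10, seed = 7)
  expect_equal(unname(cv$mean[["f1"]]), 1)
  expect_equal(unname(cv$sd[["f1"]]), 0)
  # every case tested exactly once
  expect_equal(sum(cv$folds$tp + cv$folds$fp + cv$folds$fn + cv$folds$tn),
               nrow(task$x))
  # reported means equal the arithmetic mean of the folds
  expect_equal(cv$mean[["precision"]], mean(cv$folds$precision))
  expect_equal(cv$mean[["recall"]], mean(cv$folds$recall))
})

test_that("feature selection inside CV ignores held-out labels", {
  # permuting the labels of a held-out fold must not change the features
  # selected on the training folds
  set.seed(89)
  n <- 40
  x <- matrix(rbinom(n * 15, 1, 0.4), nrow = n)
  y <- rep(c(TRUE, FALSE), each = n / 2)
  plan <- make_folds(seq_len(n), k = 10, seed = 13, strata = y)
  test <- which(unname(plan) == 0)
  train <- setdiff(seq_len(n), test)
  sel1 <- select_features(phi_scores(x[train, ], y[train]),
                          rep("bow", ncol(x)))
  y_perm <- y
  y_perm[test] <- sample(y[test])
  sel2 <- select_features(phi_scores(x[train, ], y_perm[train]),
                          rep("bow", ncol(x)))
  expect_identical(sel1$phi$selected, sel2$phi$selected)
  expect_identical(sel1$thresholds, sel2$thresholds)
})

test_that("label-randomised data scores near chance under CV", {
  set.seed(97)
  n <- 100
  x <- matrix(rbinom(n * 30, 1, 0.3), nrow = n)
  y <- rep(c(TRUE, FALSE), each = n / 2) # labels independent of x
  sp <- data.frame(type = rep("bow", 30), key = paste0("k", 1:30),
                   index = 1:30)
  class(sp) <- c("chq_feature_space", "data.frame")
  cv <- cross_validate(x, y, sp, k = 10, seed = 17)
  # binomial 3-sigma band around 0.5 at n test points
  expect_lt(abs(cv$mean[["f1"]] - 0.5), 3 * sqrt(0.25 / n) + 0.1)
})
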