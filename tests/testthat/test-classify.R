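toy_patterns <- function(n = 40, nc = 4, K = 3) {
  idx <- rbind(matrix(0L, n, nc), matrix(K - 1L, n, nc))
  attr(idx, "K") <- K
  attr(idx, "labels") <- factor(rep(c("A", "B"), each = n))
  idx
}

test_that("a separable toy problem is learned perfectly and reproducibly", {
  idx <- toy_patterns()
  m1 <- train_classifier(idx, hidden = 8, epochs = 50, seed = 1)
  pred <- predict(m1, idx)
  expect_equal(mean(pred == attr(idx, "labels")), 1)
  # fixed seed and data give identical weights
  m2 <- train_classifier(idx, hidden = 8, epochs = 50, seed = 1)
  expect_identical(m1$W1, m2$W1)
  expect_identical(m1$W2, m2$W2)
  # loss curve is recorded, finite, and improves
  expect_length(m1$loss, 50)
  expect_true(all(is.finite(m1$loss)))
  expect_lt(m1$loss[50], m1$loss[1])
})

test_that("prediction scores are normalized and class order only permutes them", {
  idx <- toy_patterns()
  m <- train_classifier(idx, hidden = 8, epochs = 30, seed = 2)
  set.seed(3)
  probe <- matrix(sample(0:2, 40, replace = TRUE), 10, 4)
  attr(probe, "K") <- 3L
  p <- predict(m, probe, type = "prob")
  expect_equal(rowSums(p), rep(1, 10), tolerance = 1e-9)
  # retrain with permuted class order
  idx2 <- idx
  attr(idx2, "labels") <- factor(as.character(attr(idx, "labels")),
                                 levels = c("B", "A"))
  m2 <- train_classifier(idx2, hidden = 8, epochs = 30, seed = 2)
  p2 <- predict(m2, probe, type = "prob")
  expect_equal(p2[, c("A", "B")], p[, c("A", "B")], tolerance = 1e-9)
})

test_that("degenerate training sets are rejected", {
  idx <- toy_patterns(n = 5)
  expect_error(train_classifier(idx), "fewer than 10")
  one <- matrix(0L, 30, 4)
  attr(one, "K") <- 3L
  expect_error(train_classifier(one, labels = rep("A", 30), K = 3),
               "two classes")
  m <- train_classifier(toy_patterns(), hidden = 4, epochs = 10, seed = 1)
  expect_error(predict(m, matrix(0L, 3, 7)), "channels")
})

test_that("the nearest-centroid baseline solves the toy problem too", {
  idx <- toy_patterns()
  cc <- centroid_classifier(idx)
  expect_equal(mean(predict(cc, idx) == attr(idx, "labels")), 1)
})

test_that("majority vote follows its tie and window rules", {
  expect_identical(
    as.character(majority_vote(factor(c("A", "A", "B")), 3)),
    c("A", "A", "A"))
  # constants pass through
  x <- factor(rep("C", 20), levels = c("A", "C"))
  expect_identical(majority_vote(x, 5), x)
  # a single flip inside a long run is removed
  y <- rep("A", 20); y[10] <- "B"
  expect_true(all(majority_vote(factor(y, levels = c("A", "B")), 5) == "A"))
  expect_error(majority_vote(factor("A"), 4), "odd")
  expect_error(majority_vote(factor("A"), 0), "vote_span")
})

test_that("majority vote never invents labels and helps on steady runs", {
  set.seed(13)
  for (r in 1:10) {
    truth <- factor(rep(sample(letters[1:4]), each = 60))
    noisy <- truth
    flip <- sample(length(truth), 30)
    noisy[flip] <- sample(letters[1:4], 30, replace = TRUE)
    sm <- majority_vote(noisy, 11)
    # every smoothed label occurred inside its trailing window
    for (t in seq_along(sm)) {
      w <- noisy[max(1, t - 10):t]
      expect_true(sm[t] %in% w)
    }
    expect_gte(mean(sm == truth), mean(noisy == truth))
  }
})

test_that("evaluation counts the confusion matrix correctly", {
  truth <- rep(c("a", "b", "c", "d", "e"), each = 10)
  ev <- evaluate(truth, truth)
  expect_equal(ev$accuracy, 1)
  expect_true(all(ev$confusion[row(ev$confusion) != col(ev$confusion)] == 0))
  # constant predictor on balanced 5-class truth
  ev2 <- evaluate(truth, rep("a", 50))
  expect_equal(ev2$accuracy, 0.2)
  # swapping two predictions changes at most two off-diagonal counts
  pred <- truth; pred[c(1, 11)] <- pred[c(11, 1)]
  ev3 <- evaluate(truth, pred)
  expect_equal(sum(ev3$confusion != ev$confusion), 4)
  expect_equal(ev3$accuracy, 48 / 50)
  expect_error(evaluate(truth, truth[-1]), "length")
  expect_error(evaluate(truth, rep("z", 50), classes = letters[1:5]),
               "outside")
})
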