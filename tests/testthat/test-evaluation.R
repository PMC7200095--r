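# independent oracle: all metrics computed directly from label pairs
oracle_metrics <- function(truth, pred) {
  classes <- sort(unique(truth))
  n <- length(truth)
  po <- mean(truth == pred)
  pe <- sum(vapply(classes, function(cl)
    mean(truth == cl) * mean(pred == cl), numeric(1)))
  per_class <- lapply(classes, function(cl) {
    tp <- sum(truth == cl & pred == cl)
    fn <- sum(truth == cl & pred != cl)
    fp <- sum(truth != cl & pred == cl)
    tn <- n - tp - fn - fp
    c(recall = if (tp + fn > 0) tp / (tp + fn) else 0,
      precision = if (tp + fp > 0) tp / (tp + fp) else 0,
      accuracy = (tp + tn) / n)
  })
  list(kappa = (po - pe) / (1 - pe),
       per_class = do.call(rbind, per_class), classes = classes)
}

test_that("confusion matrix counts truth x predicted, reject as extra column", {
  truth <- rep(c("a", "b"), 5)
  cm <- confusion(truth, truth)
  expect_equal(sum(diag(cm)), 10)
  expect_equal(sum(cm) - sum(diag(cm)), 0)
  # the wild-transfer failure mode: everything predicted as one class
  cm2 <- confusion(c("resting", "trotting", "walking"),
                   rep("grooming", 3), classes = ethogram()$classes)
  expect_equal(sum(cm2[, "grooming"]), 3)
  expect_equal(sum(cm2[, colnames(cm2) != "grooming"]), 0)
  cm3 <- confusion(character(0), character(0))
  expect_equal(sum(cm3), 0)
  cm4 <- confusion(c("a", "b"), c("a", "other"))
  expect_true("other" %in% colnames(cm4))
  expect_false("other" %in% rownames(cm4))
})

test_that("per-class metrics match a hand-counted 2x2 case", {
  truth <- rep(c("pos", "neg"), c(10, 10))
  pred <- c(rep("pos", 8), rep("neg", 2), "pos", rep("neg", 9))
  m <- per_class_metrics(confusion(truth, pred))
  pos <- m[m$class == "pos", ]
  expect_equal(pos$recall, 0.8)
  expect_equal(pos$precision, 8 / 9)
  expect_equal(pos$accuracy, 0.85)
})

test_that("perfect agreement gives all-1 metrics and kappa 1", {
  truth <- rep(c("a", "b", "c"), each = 4)
  m <- per_class_metrics(confusion(truth, truth))
  expect_true(all(m$recall == 1) && all(m$precision == 1) &&
                all(m$accuracy == 1))
  expect_equal(cohens_kappa(confusion(truth, truth)), 1)
})

test_that("a class absent from truth has flagged zero recall", {
  cm <- confusion(c("a", "a"), c("a", "b"), classes = c("a", "b"))
  m <- per_class_metrics(cm)
  expect_equal(m$recall[m$class == "b"], 0)
  expect_false(m$recall_defined[m$class == "b"])
})

test_that("independent margins force kappa to zero", {
  # counts = outer product of margins => po == pe
  truth <- rep(c("a", "b"), c(30, 70))
  set.seed(40)
  pred <- unlist(lapply(c("a", "b"), function(cl)
    rep(c("a", "b"), round(c(0.4, 0.6) * sum(truth == cl)))))
  cm <- confusion(truth, pred)
  expect_equal(cohens_kappa(cm), 0, tolerance = 1e-12)
})

test_that("kappa equals the label-pair oracle on random instances", {
  set.seed(41)
  for (i in 1:200) {
    k <- sample(2:6, 1)
    n <- sample(20:200, 1)
    truth <- sample(letters[1:k], n, replace = TRUE)
    pred <- sample(letters[1:k], n, replace = TRUE)
    if (length(unique(truth)) < 2) next
    orc <- oracle_metrics(truth, pred)
    cm <- confusion(truth, pred, classes = sort(unique(c(truth, pred))))
    expect_equal(cohens_kappa(cm), orc$kappa, tolerance = 1e-12)
  }
})

test_that("the printed-variant chance term is exposed but distinct", {
  truth <- rep(c("a", "b", "c"), c(20, 30, 10))
  set.seed(42)
  pred <- sample(truth)
  cm <- confusion(truth, pred)
  k1 <- cohens_kappa(cm, chance = "margins")
  k2 <- cohens_kappa(cm, chance = "tn_product")
  expect_true(is.finite(k1) && is.finite(k2))
  expect_false(isTRUE(all.equal(k1, k2)))
})

test_that("selection score averages mean recall, mean precision, 1 - other", {
  expect_equal(selection_score(list(recall = 1, precision = 1,
                                    other_proportion = 0)), 1)
  expect_equal(selection_score(list(recall = 0.8, precision = 0.6,
                                    other_proportion = 0.1)),
               (0.8 + 0.6 + 0.9) / 3)
  expect_equal(selection_score(list(recall = 0, precision = 0,
                                    other_proportion = 1)), 0)
  # invariant to class order
  r <- c(0.2, 0.9, 0.5); p <- c(0.4, 0.3, 0.8)
  expect_equal(selection_score(list(recall = r, precision = p,
                                    other_proportion = 0.2)),
               selection_score(list(recall = rev(r), precision = rev(p),
                                    other_proportion = 0.2)))
})

test_that("difference-quotient slopes of a linear fit are constant", {
  sel <- smooth_and_select(data.frame(size = 20:60,
                                      score = 0.3 + 0.005 * (20:60)))
  s <- sel$curve$slope
  expect_lt(diff(range(s[2:(length(s) - 1)])), 1e-6)
})

test_that("selection prefers the smallest qualifying window", {
  sizes <- 60:100
  # exact parabola peaking inside the range
  sel <- smooth_and_select(data.frame(size = sizes,
                                      score = 1 - (sizes - 79)^2 / 2000))
  expect_equal(sel$chosen, 79L)
  # plateau: smallest size
  expect_equal(smooth_and_select(data.frame(size = 20:40,
                                            score = rep(0.5, 21)))$chosen,
               20L)
  # strictly increasing: the maximum (largest size) wins by fallback
  expect_equal(smooth_and_select(data.frame(
    size = 20:60, score = seq(0.2, 0.9, length.out = 41)))$chosen, 60L)
  expect_error(smooth_and_select(data.frame(size = 1:3, score = 1:3)),
               "at least 4 points")
})

test_that("a window-size sweep runs, is deterministic, and is bounded", {
  cap <- generate_captive_dataset(counts = c(resting = 12, trotting = 12,
                                             walking = 12), seed = 50)
  spec <- model_spec("ann", hyperparameters = list(epochs = 8), seed = 51)
  sizes <- c(30, 60, 90, 110)
  c1 <- sweep_window_sizes(cap, sizes = sizes, spec = spec, seed = 52)
  c2 <- sweep_window_sizes(cap, sizes = sizes, spec = spec, seed = 52)
  expect_equal(c1, c2)
  expect_true(all(c1$score >= 0 & c1$score <= 1))
  expect_equal(c1$size, sizes)
  # single size = full burst: one window per burst, still a valid point
  c3 <- sweep_window_sizes(cap, sizes = 110, spec = spec, seed = 52)
  expect_equal(nrow(c3), 1)
})
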