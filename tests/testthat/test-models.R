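test_that("all three back-ends separate linearly separable classes", {
  blobs <- make_blobs(n_per_class = 40, k = 2, p = 4, sep = 8)
  for (kind in c("svm", "rf", "ann")) {
    m <- train_model(blobs$X, blobs$y, model_spec(kind, seed = 3))
    pred <- apply_threshold(predict_probs(m, blobs$X), tau = 0)
    expect_equal(mean(pred == blobs$y), 1.0, info = kind)
  }
})

test_that("training is reproducible: same spec and seed, same predictions", {
  blobs <- make_blobs(n_per_class = 30, k = 3, p = 5, sep = 4, seed = 9)
  held <- make_blobs(n_per_class = 10, k = 3, p = 5, sep = 4, seed = 10)
  for (kind in c("svm", "rf", "ann")) {
    m1 <- train_model(blobs$X, blobs$y, model_spec(kind, seed = 7))
    m2 <- train_model(blobs$X, blobs$y, model_spec(kind, seed = 7))
    expect_identical(predict_probs(m1, held$X), predict_probs(m2, held$X),
                     info = kind)
  }
})

test_that("permuted labels yield near-zero held-out agreement", {
  set.seed(21)
  n <- 600
  X <- matrix(rnorm(n * 6), n, 6)
  colnames(X) <- paste0("f", 1:6)
  y <- sample(rep(c("a", "b", "c"), each = n / 3))
  tr <- sample(n, 420)
  m <- train_model(X[tr, ], y[tr], model_spec("rf", seed = 22))
  pred <- apply_threshold(predict_probs(m, X[-tr, ]), tau = 0)
  k <- cohens_kappa(confusion(y[-tr], pred))
  expect_lt(abs(k), 0.1)
})

test_that("single-class training input is a degenerate-training error", {
  X <- matrix(rnorm(40), 10, 4)
  expect_error(train_model(X, rep("resting", 10), model_spec("rf")),
               "degenerate training")
})

test_that("the probability threshold is strict and validates its input", {
  expect_equal(apply_threshold(c(feeding = 0.71, resting = 0.29)), "feeding")
  expect_equal(apply_threshold(c(feeding = 0.69, resting = 0.31)), "other")
  u <- setNames(rep(1 / 6, 6), ethogram()$classes)
  expect_equal(apply_threshold(u), "other")
  expect_equal(apply_threshold(c(a = 0.7, b = 0.3), tau = 0.7), "other")
  expect_error(apply_threshold(c(a = 0.5, b = 0.2)), "malformed probability")
})

test_that("raising tau never converts a rejection into a named class", {
  set.seed(23)
  for (i in 1:50) {
    p <- runif(4); p <- p / sum(p); names(p) <- letters[1:4]
    taus <- sort(runif(5))
    out <- vapply(taus, function(tau) apply_threshold(p, tau), character(1))
    named <- out != "other"
    expect_true(all(diff(named) <= 0))  # once other, always other
  }
})

test_that("burst vote requires an absolute majority", {
  expect_equal(burst_vote(c(rep("trotting", 20), rep("resting", 12))),
               "trotting")
  expect_equal(burst_vote(rep("walking", 5)), "walking")
  expect_equal(burst_vote(c(rep("a", 16), rep("b", 16))), "other")
  expect_equal(burst_vote("resting"), "resting")
  expect_error(burst_vote(character(0)), "empty vote")
})

test_that("predict_bursts skips short bursts with a logged reason", {
  model <- behaviour_signal_model()
  meta <- data.frame(burst_id = c("b1", "b2"), animal_id = "w",
                     burst_start = as.POSIXct("2018-06-01", tz = "UTC") +
                       c(0, 120),
                     sampling_rate = 33.33, label = NA_character_)
  samples <- list(generate_burst("resting", model, n = 110, seed = 1),
                  generate_burst("resting", model, n = 40, seed = 2))
  b <- acc_bursts(meta, samples)
  cap <- generate_captive_dataset(counts = c(resting = 15, trotting = 15),
                                  seed = 3)
  f <- expand(cap, window_plan(79))
  m <- train_model(f, f$label, model_spec("ann", seed = 4))
  preds <- predict_bursts(m, b, window_plan(79))
  expect_equal(nrow(preds), 1)
  lg <- run_log(preds)
  expect_true(any(vapply(lg, function(e)
    e$event == "bursts_skipped_shorter_than_window", logical(1))))
})

test_that("synthetic resting bursts are recovered; tau = 0 disables rejection", {
  cap <- generate_captive_dataset(counts = c(resting = 20, trotting = 20,
                                             walking = 20), seed = 5)
  f <- expand(cap, window_plan(79))
  m <- train_model(f, f$label, model_spec("ann", seed = 6))
  rest <- generate_captive_dataset(counts = c(resting = 10, trotting = 2,
                                              walking = 2), seed = 7)
  rest$meta$label <- NA_character_
  preds <- predict_bursts(m, rest, window_plan(79), tau = 0.7)
  expect_equal(sum(preds$behaviour == "resting"), 10)
  preds0 <- predict_bursts(m, rest, window_plan(79), tau = 0)
  expect_false(any(preds0$behaviour == "other"))
  expect_true(all(preds0$vote_fraction > 0.5))
})

test_that("models survive persistence with identical predictions", {
  blobs <- make_blobs(n_per_class = 20, k = 2, p = 3, sep = 6, seed = 30)
  m <- train_model(blobs$X, blobs$y, model_spec("ann", seed = 31))
  path <- withr::local_tempfile(fileext = ".rds")
  save_model(m, path)
  m2 <- load_model(path)
  expect_identical(predict_probs(m, blobs$X), predict_probs(m2, blobs$X))
  expect_error(load_model(withr::local_tempfile(fileext = ".rds") |>
                            (\(p) { saveRDS(1, p); p })()),
               "not an accbehav model archive")
})

test_that("a model refuses feature tables missing its predictors", {
  blobs <- make_blobs(n_per_class = 15, k = 2, p = 4, sep = 6, seed = 33)
  m <- train_model(blobs$X, blobs$y, model_spec("rf", seed = 34))
  expect_error(predict_probs(m, blobs$X[, 1:2]), "feature mismatch")
})
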