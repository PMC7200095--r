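# Three classifier back-ends sharing one surface: radial-kernel SVM
# (e1071), random forest with 500 trees (randomForest) and the in-package
# feed-forward neural network (ann.R). All back-ends expose calibrated
# class-probability prediction; the rejection threshold and the burst-level
# absolute-majority vote sit on top and are back-end independent.

#' Specify a classifier back-end
#'
#' Defaults follow the reference configuration: SVM with radial kernel,
#' random forest with 500 trees, and a three-layer feed-forward network
#' (input, one rectifier hidden layer of width `max(64, 2 * n_classes)`,
#' softmax output) trained with a fixed epoch budget. Features are
#' z-score standardized (fit on the training split only) for `svm` and
#' `ann`; the forest is scale-invariant and takes raw features.
#'
#' @param kind One of `"ann"`, `"svm"`, `"rf"`.
#' @param hyperparameters Named list overriding back-end defaults
#'   (`svm`: `cost`, `gamma`; `rf`: `ntree`; `ann`: `hidden`, `epochs`,
#'   `batch_size`, `lr`, `l2`).
#' @param feature_scaling Logical; `NULL` (default) resolves to `TRUE`
#'   for svm/ann and `FALSE` for rf.
#' @param class_weights Optional named numeric class weights (svm/rf
#'   only). The default (`NULL`) preserves the natural class imbalance.
#' @param seed Integer seed making training reproducible.
#' @return Object of class `"model_spec"`.
#' @export
model_spec <- function(kind = c("ann", "svm", "rf"),
                       hyperparameters = list(),
                       feature_scaling = NULL,
                       class_weights = NULL,
                       seed = 1L) {
  kind <- match.arg(kind)
  if (is.null(feature_scaling)) feature_scaling <- kind %in% c("svm", "ann")
  defaults <- switch(kind,
    svm = list(cost = 1, gamma = NULL),
    rf = list(ntree = 500L),
    ann = list(hidden = NULL, epochs = 30L, batch_size = 256L,
               lr = 1e-3, l2 = 1e-4))
  hp <- utils::modifyList(defaults, hyperparameters)
  structure(list(kind = kind, hyperparameters = hp,
                 feature_scaling = feature_scaling,
                 class_weights = class_weights,
                 seed = as.integer(seed)),
            class = "model_spec")
}

strip_meta <- function(features) {
  cols <- setdiff(names(features), c("burst_id", "window_offset", "label"))
  as.matrix(features[cols])
}

#' Train a behaviour classifier
#'
#' @param features Feature table from [expand()] (meta columns are
#'   ignored) or a plain numeric matrix/data frame of predictors.
#' @param labels Behaviour label per row (character or factor). At least
#'   two classes must be present.
#' @param spec A [model_spec()].
#' @return Object of class `"acc_model"` carrying the fitted back-end,
#'   the class set, the scaling parameters and the feature roster.
#' @export
train_model <- function(features, labels, spec = model_spec()) {
  stopifnot(inherits(spec, "model_spec"))
  X <- if (is.matrix(features)) features else strip_meta(features)
  y <- factor(as.character(labels))
  if (nlevels(y) < 2)
    stop("degenerate training: need at least 2 classes, got ", nlevels(y))
  if (nrow(X) != length(y)) stop("features and labels length mismatch")

  scaling <- NULL
  if (spec$feature_scaling) {
    ctr <- colMeans(X)
    scl <- apply(X, 2, stats::sd)
    scl[scl == 0] <- 1
    scaling <- list(center = ctr, scale = scl)
    X <- scale(X, center = ctr, scale = scl)
  }

  hp <- spec$hyperparameters
  set.seed(spec$seed)
  fit <- switch(spec$kind,
    svm = {
      gamma <- if (is.null(hp$gamma)) 1 / ncol(X) else hp$gamma
      e1071::svm(x = X, y = y, kernel = "radial", cost = hp$cost,
                 gamma = gamma, probability = TRUE, scale = FALSE,
                 class.weights = spec$class_weights)
    },
    rf = randomForest::randomForest(
      x = X, y = y, ntree = hp$ntree,
      classwt = spec$class_weights),
    ann = ann_fit(X, y, hidden = hp$hidden, epochs = hp$epochs,
                  batch_size = hp$batch_size, lr = hp$lr, l2 = hp$l2,
                  seed = spec$seed))

  structure(list(kind = spec$kind, spec = spec, fit = fit,
                 classes = levels(y), scaling = scaling,
                 feature_names = colnames(X),
                 feature_set_version = "v1"),
            class = "acc_model")
}

#' @export
print.acc_model <- function(x, ...) {
  cat("<acc_model> back-end:", x$kind, "| classes:",
      paste(x$classes, collapse = ", "), "\n")
  cat("  features:", length(x$feature_names),
      "| scaled:", !is.null(x$scaling), "\n")
  invisible(x)
}

#' Per-window class probabilities
#'
#' Probability sources per back-end: softmax output (ann), tree-vote
#' fractions (rf), pairwise-coupling estimates (svm). Rows sum to 1.
#'
#' @param model An `acc_model`.
#' @param features Feature table or predictor matrix with the columns the
#'   model was trained on.
#' @return Numeric matrix, rows = windows, columns = model classes.
#' @export
predict_probs <- function(model, features) {
  X <- if (is.matrix(features)) features else strip_meta(features)
  miss <- setdiff(model$feature_names, colnames(X))
  if (length(miss))
    stop("feature mismatch: missing predictor(s): ",
         paste(utils::head(miss, 3), collapse = ", "))
  X <- X[, model$feature_names, drop = FALSE]
  if (!is.null(model$scaling))
    X <- scale(X, center = model$scaling$center, scale = model$scaling$scale)
  P <- switch(model$kind,
    svm = {
      pr <- stats::predict(model$fit, X, probability = TRUE)
      attr(pr, "probabilities")
    },
    rf = stats::predict(model$fit, X, type = "prob"),
    ann = ann_predict_probs(model$fit, X))
  P <- P[, model$classes, drop = FALSE]
  rownames(P) <- NULL
  P
}

#' Apply the probability rejection threshold to window probabilities
#'
#' A window is assigned its most probable class only when that probability
#' strictly exceeds `tau`; otherwise it falls into the rejection class.
#' The threshold guards against behaviours absent from the training
#' ethogram and against mixed-behaviour recordings, both of which should
#' surface as low-confidence assignments.
#'
#' @param probs Probability matrix (rows = windows, columns = classes) or
#'   a single probability vector. Each row must sum to 1 (tolerance 1e-6).
#' @param tau Acceptance threshold in \[0, 1\] (default 0.7). `tau = 0`
#'   disables rejection from thresholding.
#' @param reject Name of the rejection class (default `"other"`).
#' @return Character vector of class names (or `reject`), one per row.
#' @examples
#' apply_threshold(c(feeding = 0.71, resting = 0.29))        # "feeding"
#' apply_threshold(c(feeding = 0.69, resting = 0.31))        # "other"
#' @export
apply_threshold <- function(probs, tau = 0.7, reject = "other") {
  if (is.null(dim(probs))) probs <- matrix(probs, 1,
                                           dimnames = list(NULL, names(probs)))
  if (is.null(colnames(probs))) stop("probability columns must be named")
  if (any(probs < -1e-9) || any(abs(rowSums(probs) - 1) > 1e-6))
    stop("malformed probability vector: rows must be >= 0 and sum to 1")
  j <- max.col(probs, ties.method = "first")
  top <- probs[cbind(seq_len(nrow(probs)), j)]
  out <- colnames(probs)[j]
  out[top <= tau] <- reject
  out
}

#' Absolute-majority vote over a burst's window classes
#'
#' All window classifications within a burst count equally; the burst is
#' assigned the class (including the rejection class) held by strictly
#' more than half of its windows. Without an absolute majority the burst
#' is rejected — the conservative fallback consistent with the threshold's
#' purpose.
#'
#' @param window_classes Character vector of per-window classes.
#' @param reject Rejection class name returned when no class exceeds 50%.
#' @return Single class name.
#' @examples
#' burst_vote(c(rep("trotting", 20), rep("resting", 12)))  # "trotting"
#' @export
burst_vote <- function(window_classes, reject = "other") {
  if (length(window_classes) == 0) stop("empty vote: no window classes")
  tab <- table(window_classes)
  top <- which.max(tab)
  if (tab[top] * 2 > length(window_classes)) names(tab)[top] else reject
}

#' Classify bursts: slide, featurize, threshold, vote
#'
#' The full prediction path for unlabelled (e.g. free-ranging) bursts:
#' moving-window expansion, per-window class probabilities, rejection
#' threshold, then the absolute-majority vote collapsing each burst's
#' windows to a single behaviour.
#'
#' @param model An `acc_model`.
#' @param bursts An `acc_bursts` object. Bursts shorter than the window
#'   are skipped and logged.
#' @param plan A [window_plan()]; its window size must match the model.
#' @param tau Rejection threshold (default 0.7).
#' @param reject Rejection class name.
#' @param keep_window_detail If `TRUE`, attach per-burst window
#'   probabilities and classes as attribute `"window_detail"`.
#' @return Data frame with one row per classified burst: `burst_id`,
#'   `animal_id`, `burst_start`, `behaviour`, `vote_fraction` (share of
#'   windows agreeing with the voted class) and `n_windows`. Skipped
#'   bursts are recorded in [run_log()].
#' @export
predict_bursts <- function(model, bursts, plan, tau = 0.7, reject = "other",
                           keep_window_detail = FALSE) {
  meta <- bursts$meta
  log <- run_log(bursts)
  short <- meta$n < plan$window_size
  if (any(short)) {
    log <- append_log(log, "bursts_skipped_shorter_than_window",
                      n_skipped = sum(short),
                      burst_ids = meta$burst_id[short])
    bursts <- bursts[!short]
    meta <- bursts$meta
  }
  if (nrow(meta) == 0) {
    out <- data.frame(burst_id = character(0), animal_id = character(0),
                      burst_start = as.POSIXct(character(0), tz = "UTC"),
                      behaviour = character(0), vote_fraction = numeric(0),
                      n_windows = integer(0))
    attr(out, "run_log") <- log
    return(out)
  }
  feats <- expand(bursts, plan)
  P <- predict_probs(model, feats)
  wcls <- apply_threshold(P, tau = tau, reject = reject)
  split_idx <- split(seq_along(wcls),
                     factor(feats$burst_id, levels = meta$burst_id))
  behaviour <- character(nrow(meta))
  vote_fraction <- numeric(nrow(meta))
  for (b in seq_len(nrow(meta))) {
    cl <- wcls[split_idx[[b]]]
    v <- burst_vote(cl, reject = reject)
    behaviour[b] <- v
    vote_fraction[b] <- sum(cl == v) / length(cl)
  }
  out <- data.frame(burst_id = meta$burst_id, animal_id = meta$animal_id,
                    burst_start = meta$burst_start, behaviour = behaviour,
                    vote_fraction = vote_fraction,
                    n_windows = lengths(split_idx),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  if (keep_window_detail)
    attr(out, "window_detail") <- list(probs = P, classes = wcls,
                                       burst_id = feats$burst_id)
  attr(out, "run_log") <- log
  out
}

#' Persist / restore a trained model
#'
#' The archive carries the fitted state together with the feature-set
#' version, feature roster, scaling parameters and the full spec, so a
#' restored model refuses incompatible feature tables.
#'
#' @param model An `acc_model`.
#' @param path File path (RDS).
#' @return `path` invisibly (save) or the restored model (load).
#' @export
save_model <- function(model, path) {
  saveRDS(list(format = "accbehav-model", version = 1L, model = model), path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  obj <- readRDS(path)
  if (!is.list(obj) || !identical(obj$format, "accbehav-model"))
    stop("not an accbehav model archive")
  obj$model
}
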